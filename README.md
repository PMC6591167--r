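# DNBdetect

Detection of pre-disease states from two-group, time-course gene expression
data using dynamical network biomarker (DNB) theory.

## The problem

Many diseases arrive through an abrupt, hard-to-reverse shift — a critical
transition — from a healthy to a disease state. Immediately before such a
transition the system passes through a *pre-disease* state: still
functionally healthy, but unstable, and the best window for preventive
intervention. Critical-transition theory predicts that a small group of
variables (the dynamical network biomarker) signals this window by
transiently showing **unusually large fluctuations** and **strong mutual
correlations** while the rest of the system stays quiet.

DNBdetect implements this analysis for bulk transcriptomics: two groups
(a disease-model "case" strain and a control strain) sampled at several
time points with a few biological replicates each. It is aimed at
computational biologists who want a tested, reproducible implementation of
the DNB selection and scoring procedure, plus the surrounding pipeline
(preprocessing, differential expression, exploratory statistics,
enrichment) and a synthetic-data generator with planted ground truth for
validation.

## The method

Let `X` and `Y` be the case and control expression submatrices
(genes × samples) at the scored week, with gene-wise means `m_i`, standard
deviations `s_i` (sample, `K−1` denominator) and correlations `r_ij`.
Candidate genes are selected in three ranked steps:

1. **Fluctuation gain** — `v1_i = s_i(X) / s_i(Y)`; the top `θ1`% form `S1`.
2. **Specific correlation gain** —
   `v2_i = Σ_{j∈S1} (|r_ij(X)| − |r_ij(Y)|)` for `i ∈ S1`; the top `θ2`%
   form `S2`.
3. **Non-specific gain (exclusion)** —
   `v3_i = Σ_{j∈S0∖S1} (|r_ij(X)| − |r_ij(Y)|)` for `i ∈ S1`; the top `θ3`%
   form `S3`, and the DNB candidate set is `S* = S2 ∖ S3`.

Each candidate set is scored in every (group, week) condition slice `Z`
with `M` samples:

- `I_s = mean_{i∈S*} s_i(Z)` — average standard deviation;
- `I_r = mean_{i<j∈S*} |r_ij(Z)| − c(M)` — average correlation strength,
  corrected by the null expectation
  `c(M) = E|r|` of two independent standard-normal samples of size `M`
  (`c(4) = 0.50`, `c(5) = 4/(3π) ≈ 0.42`), which removes the small-sample
  inflation of `|r|`.

A simultaneous peak of `I_s` and `I_r` at one week in the case group marks
the pre-disease state. Robustness operations include leave-one-out
re-selection, swapping the control condition, a threshold sweep ranked by
peak sharpness, and the relative recovery rate `1/λ_max` of the candidate
covariance matrix (critical slowing down).

## Worked example

Simulate a study with a 50-gene module planted at week 5 in the case group
(the package default mirrors a two-strain, five-week design with 5
replicates per condition), run the selection at the preset thresholds
θ = (10, 50, 80), and score the planted module across conditions:

```r
library(DNBdetect)

sim <- simulateExpression(dnbSimConfig(seed = 7))
sim$dataset
#> DNBExperiment: 500 genes x 50 samples
#>   groups: case, control (case = case , control = control)
#>   weeks: wk3, wk4, wk5, wk6, wk7

selectDNB(sim$dataset, caseWeek = "wk5")
#> DNBSelection (theta = 10/50/80 %):
#>   |S0| = 500  |S1| = 50  |S2| = 25  |S3| = 40  |S*| = 4

scoreSeries(sim$dataset, sim$truth@dnbGenes)
#> DNBScoreSeries over 10 conditions:
#>    group week M     Is         Ir      c
#>     case  wk3 5 0.2694 -0.0002884 0.4244
#>  control  wk3 5 0.3015 -0.0094446 0.4244
#>     case  wk4 5 0.2896  0.0025657 0.4244
#>  control  wk4 5 0.2534 -0.0060349 0.4244
#>     case  wk5 5 0.8593  0.2095790 0.4244
#>  control  wk5 5 0.3272  0.0013780 0.4244
#>     case  wk6 5 0.2926 -0.0003951 0.4244
#>  control  wk6 5 0.2521  0.0007139 0.4244
#>     case  wk7 5 0.2899 -0.0001432 0.4244
#>  control  wk7 5 0.2794  0.0188339 0.4244
```

The planted module's average standard deviation triples (0.29 → 0.86,
matching the configured SD ratio of 3 on baseline noise 0.3) and its
corrected correlation strength rises from ~0 to 0.21 at week 5 in the case
group only — the joint `I_s`/`I_r` peak that defines the pre-disease
signature. The selection itself is nested by construction
(`S1 ⊇ S2, S3`; `S* = S2 ∖ S3`).

An end-to-end run (simulate → preprocess → DEG → DNB → exploratory →
enrichment) from one declarative config:

```r
runDNBPipeline(dnbRunConfig(sim = list(seed = 7), seed = 7),
               outdir = "dnb_run")
```

which writes per-stage TSVs and a machine-readable `summary.json`.

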