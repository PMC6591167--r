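---
title: "Detecting pre-disease states with dynamical network biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pre-disease states with dynamical network biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DNBdetect)
```

# The model and its assumptions

A system approaching a critical transition loses stability along one
direction of its state space. Near the tipping point, the variables loading
on that direction — the dynamical network biomarker (DNB) — respond to the
same slow fluctuations, so they exhibit (i) inflated variance and (ii)
strong mutual correlation, transiently and collectively, while the rest of
the system is largely unaffected. DNBdetect operationalizes this for
two-group, time-course expression studies:

* samples are cross-sectional (each animal measured once), so all statistics
  are computed *within* a condition slice — the submatrix of samples sharing
  one (group, week) label — never along an individual's trajectory;
* at least 3 samples per slice are required for any correlation-based
  statistic, and 4 for leave-one-out analysis;
* expression values are assumed log2-scale and normalized before analysis
  (the preprocessing module produces exactly this from raw probe
  intensities).

The method is a *screening* procedure: ranked selection with fixed
percentage cutoffs, not a hypothesis test. Its output (`S*`) is validated
by the behavior of the scores `I_s` and `I_r` across conditions and by
robustness checks, not by a p-value.

# The selection and scoring procedure

With case slice `X` and control slice `Y` at the scored week, gene-wise
sample standard deviations `s_i` and correlations `r_ij` (both with the
`K − 1` denominator):

1. `v1_i = s_i(X)/s_i(Y)` over all genes `S0`; keep the top `θ1`% as `S1`.
   Genes with zero standard deviation in either slice have an undefined
   ratio; they are excluded from the ranking and reported in the
   `excluded` slot rather than silently dropped.
2. `v2_i = Σ_{j∈S1}(|r_ij(X)| − |r_ij(Y)|)`, `i ∈ S1`; top `θ2`% → `S2`.
   The self term is included as written; it contributes zero.
3. `v3_i = Σ_{j∈S0∖S1}(|r_ij(X)| − |r_ij(Y)|)`, `i ∈ S1`; top `θ3`% → `S3`
   (genes whose correlation gain is indiscriminate), and `S* = S2 ∖ S3`.

`v2` and `v3` are implemented as sums over the printed index sets rather
than means. Because each ranking happens within a fixed set, a sum and a
mean differ by a constant factor and are rank-equivalent; the sum form is
kept because it is what the defining formulas state.

Scores per condition slice `Z` with `M` samples:

* `I_s` — mean of `s_i(Z)` over `S*`;
* `I_r` — mean of `|r_ij(Z)|` over unordered pairs, minus the correction
  `c(M)`.

## The correction term

For two independent standard-normal samples of size `M`, the sample
correlation has density proportional to `(1 − r²)^((M−4)/2)` on `[−1, 1]`.
Integrating `|r|` against it gives

`c(M) = 1 / ((a + 1) · B(1/2, a + 1))`, `a = (M − 4)/2`,

so `c(4) = 1/2` exactly and `c(5) = 4/(3π) ≈ 0.4244`. Without this term the
average `|r|` of even independent genes looks large at `M = 4–5`, and
comparisons between conditions with different sample counts are biased.
`correctionTerm()` evaluates the closed form for any `M ≥ 3` (the two
published constants are special cases); it is strictly decreasing and
vanishes as `M → ∞`.

# Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `thetas` | (10, 50, 80) % | the preset threshold triple; also the default grid center of `sweepParameters()` |
| DEG `q` | 0.05 | Benjamini–Hochberg FDR level per week |
| DEG `lfcThreshold` | 1 log2 unit | strict `>` 1, i.e. more than two-fold |
| clustering cutoff | 0.5 on `1 − r` | flat-cluster height under average linkage |
| parallel analysis | 100 shuffles, 95th percentile | permutation null for eigenvalues |
| normalization trim | 2% per tail | trimmed-mean scale factor per sample |

Decisions taken where the procedure's definition is open:

* **Trim count** — `floor(0.02 · n)` values per side, per observation.
  Rounding down keeps short columns intact (a 10-value column is simply
  averaged) and is the conservative reading.
* **Fold-change boundary** — a difference of exactly 1 log2 unit is *not* a
  candidate ("more than" read strictly).
* **BH scope** — applied per week across genes, mirroring the week-by-week
  two-group comparisons; not pooled across weeks. This is a documented
  assumption, not a claim about the original analysis.
* **Count rule and ties** — `topFraction()` takes
  `max(1, floor(θ/100 · n))` genes among those with defined scores; ties at
  the cutoff break by ascending gene id. Determinism here is required for
  leave-one-out statistics to be meaningful.
* **Collapsing before normalization** — probe collapsing averages *raw*
  intensities per gene symbol, then samples are normalized, then log2;
  the pipeline order follows the preprocessing description's paragraph
  order.
* **Parallel-analysis shuffling** — each gene's values are permuted across
  samples independently, which preserves every per-gene value multiset
  exactly while destroying inter-gene correlation. A whole-matrix shuffle
  would additionally destroy per-gene marginals; the within-gene scheme is
  the stricter null for *correlation* structure, which is what PCA
  eigenvalues measure here.
* **Sweep ranking** — "a sharp peak in both scores" is formalized as
  `min over {I_s, I_r} of (score at target week − max score at other
  weeks) / (max − min across weeks)`, computed on the case-group series.
  Positive sharpness means both scores peak exactly at the target week;
  empty candidate sets rank last with undefined sharpness.
* **Control-swap significance** — the overlap between the original and
  alternative-control selections is tested with the classic one-tailed
  hypergeometric tail, not the conservative DAVID-style variant, which is
  reserved for gene-set enrichment.

# Gene-set enrichment

`fisherP()` is the classic one-tailed Fisher/hypergeometric upper tail
`P(overlap ≥ x)`; `fisherPModified()` substitutes `x − 1` and `n1 − 1`
(the DAVID convention), which discounts one overlapping gene and is
uniformly more conservative. `enrichGeneSets()` filters at `p ≤ 0.05` and
overlap `≥ 2` and ranks by overlap size (ties: p ascending, then set name),
reporting the top 10. No multiple-testing correction is applied to
enrichment p-values: the filter is exploratory by design, and the universe
size `N` defaults to the processed gene universe but should be overridden
when an organism-wide universe is intended.

# What the synthetic generator emulates

`simulateExpression()` reproduces the *statistical* structure the method
targets, with known ground truth:

* two groups × five weekly time points × 5 replicates (4 is supported; the
  correction term handles both), ~500 genes by default — a deliberately
  reduced universe that keeps simulation-based tests fast while preserving
  the selection geometry of percentage thresholds;
* a planted DNB module (default 50 genes) that activates only in the case
  group at `peakWeek`: members follow a single shared latent factor,
  `x = baseline + b·f + ε`, with the loading and residual variance solved
  so that the population SD is `sdRatio` × baseline noise and the
  population pairwise correlation is `targetAbsCorr` (equicorrelated
  single-factor design — the two observable targets leave exactly these
  two degrees of freedom, which makes the construction solvable in closed
  form);
* planted differential-expression clusters (default 3 × 20 genes,
  ±2 log2 units from an onset week, alternating sign) disjoint from the
  module;
* baseline expression log-normal on the raw scale (normal on log2), noise
  SD 0.3 log2 units — a typical residual scale for well-normalized arrays.

Gene-level values are drawn directly on the normalized log2 scale, so the
configured moments hold exactly in the population. `simulateProbes()` maps
the same gene-level data to raw intensities (probe-specific offsets and
noise, multiplicative per-sample array scale factors, a configurable
fraction of unannotated probes) for testing the preprocessing path;
trimmed-mean normalization removes the array factors exactly.

What the generator does **not** emulate: heavy-tailed and heteroskedastic
microarray noise, probe cross-hybridization, batch structure beyond a
scalar array factor, correlated background modules, and any real biology of
a disease model (specific genes, pathways, effect time courses). Passing
the simulation-based tests therefore demonstrates that the implementation
recovers planted statistical structure under the stated model — not that
the method will behave identically on real arrays.

# Numerical and degenerate-input conventions

* Welch's test is computed from the explicit formulas with
  Welch–Satterthwaite degrees of freedom; two constant, equal groups give
  `t = 0, p = 1` (the gene stays in the universe), constant unequal groups
  give `p = 0`. The implementation is cross-checked against `stats::t.test`
  in the test suite.
* Correlations involving a zero-variance partner are undefined; in `v2`/`v3`
  such terms contribute 0, and zero-variance genes cannot enter `S1` in the
  first place (their `v1` is undefined).
* If `S1` collapses to a single gene (tiny universes), `v2` is the zero
  self-term and selection proceeds deterministically.
* An empty `S*` is a valid, reported outcome — scores are simply not
  defined for it, and the parameter sweep ranks such triples last.
* Eigenvalues use `eigen(symmetric = TRUE)`; covariance and SDs use the
  `K − 1` denominator throughout.

# Problem sizes used by the test suite

Simulation-backed tests run at reduced but structure-preserving sizes,
chosen once: moment-fidelity checks use 1,000 replicates per condition
(Monte-Carlo error ≪ the 5% tolerance); recovery and robustness checks use
150–500 genes with 5–20 replicates; the null calibration of `I_r` averages
100 seeds at `M = 5`; oracle-equivalence checks use ≤ 20 genes and ≤ 6
samples, where naive from-the-formula reimplementations are fast and
readable. Exact hypergeometric enumeration is restricted to universes of
≤ 12 genes, where all `C(N, n2)` draws can be listed.

# Known limitations

* Percentage-based cutoffs couple the sizes of `S1`, `S2`, `S3` rigidly to
  the universe size: `|S*| ≤ floor(θ2/100 · floor(θ1/100 · N))`. In small
  universes, or when a planted/true module is as large as `S1` itself, the
  exclusion step `S3` ranks within an essentially exchangeable set and
  removes members arbitrarily; candidate sets can then be much smaller than
  the underlying module. The `sweepParameters()` and `leaveOneOut()`
  operations exist precisely to expose such instability.
* The scores compare conditions; they do not test significance. Permutation
  calibration of peak sharpness is supported in principle via the sweep on
  relabeled data but is not built in.
* The two-dimensional embedding of the case/control dissimilarity
  (`dnbDissimilarity()`) is delegated to any standard implementation
  accepting precomputed dissimilarities (perplexity 100, early exaggeration
  10 were the reference settings); only the dissimilarity itself is
  computed here, and embedding axes carry no meaning.
* Full-scale replication of a published gene list requires the original
  arrays and annotation; enrichment results additionally depend on the
  annotation version of the supplied GMT collections.
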