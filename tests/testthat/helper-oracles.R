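# Independent, from-the-formulas reference implementations used as oracles.
# Deliberately naive (explicit loops, no shared code with the package).

naiveSd <- function(v) {
  m <- sum(v) / length(v)
  sqrt(sum((v - m)^2) / (length(v) - 1))
}

naiveCor <- function(a, b) {
  K <- length(a)
  ma <- mean(a); mb <- mean(b)
  sum((a - ma) * (b - mb)) / ((K - 1) * naiveSd(a) * naiveSd(b))
}

naiveV1 <- function(X, Y)
  sapply(seq_len(nrow(X)), function(i) naiveSd(X[i, ]) / naiveSd(Y[i, ]))

naiveV2 <- function(X, Y, S1) {
  sapply(S1, function(i) {
    tot <- 0
    for (j in S1)
      tot <- tot + abs(naiveCor(X[i, ], X[j, ])) -
        abs(naiveCor(Y[i, ], Y[j, ]))
    tot
  })
}

naiveV3 <- function(X, Y, S1) {
  outside <- setdiff(rownames(X), S1)
  sapply(S1, function(i) {
    tot <- 0
    for (j in outside)
      tot <- tot + abs(naiveCor(X[i, ], X[j, ])) -
        abs(naiveCor(Y[i, ], Y[j, ]))
    tot
  })
}

naiveIs <- function(Z, genes)
  mean(sapply(genes, function(i) naiveSd(Z[i, ])))

naiveIr <- function(Z, genes, c0) {
  tot <- 0; npair <- 0
  for (a in seq_along(genes)) for (b in seq_along(genes)) if (a < b) {
    tot <- tot + abs(naiveCor(Z[genes[a], ], Z[genes[b], ]))
    npair <- npair + 1
  }
  tot / npair - c0
}

# step-up BH by explicit evaluation of every threshold k*q/m
bruteBH <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  kmax <- 0
  for (k in seq_len(m)) if (p[ord][k] <= k * q / m) kmax <- k
  rej <- rep(FALSE, m)
  if (kmax > 0) rej[ord[seq_len(kmax)]] <- TRUE
  rej
}

# exhaustive hypergeometric upper tail: enumerate all C(N, n2) draws
enumFisherP <- function(N, n1, n2, x) {
  draws <- combn(N, n2)
  hits <- sum(apply(draws, 2, function(d) sum(d <= n1) >= x))
  hits / ncol(draws)
}

assayInt <- function(x) SummarizedExperiment::assay(x, "intensity")

randomSliceMatrix <- function(nGenes, nSamples) {
  m <- matrix(rnorm(nGenes * nSamples), nGenes, nSamples)
  rownames(m) <- sprintf("g%02d", seq_len(nGenes))
  colnames(m) <- sprintf("s%d", seq_len(nSamples))
  m
}
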