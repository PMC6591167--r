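# internal numeric helpers shared across modules

# per-gene standard deviation with the K-1 denominator
rowSds <- function(m) {
  k <- ncol(m)
  if (k < 2) stop("need at least 2 samples for a standard deviation")
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (k - 1))
}

# |cor| matrix across rows; zero-variance rows yield NA entries, which the
# caller decides how to treat
absCorRows <- function(m, m2 = NULL) {
  r <- if (is.null(m2)) suppressWarnings(cor(t(m)))
       else suppressWarnings(cor(t(m), t(m2)))
  abs(r)
}

# mean of |r| over unordered pairs of rows (diagonal excluded)
meanAbsPairCor <- function(m) {
  p <- nrow(m)
  if (p < 2) stop("need at least 2 genes for pairwise correlations")
  r <- absCorRows(m)
  (sum(r[upper.tri(r)])) / (p * (p - 1) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
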