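# Independent brute-force oracles used to cross-check the compiled /
# RANN-backed implementations. All are O(N^2) on the full distance matrix
# and share no code with the package internals they verify.

# per-point mean distance to the k nearest neighbors (self excluded)
oracleMeanKnnDistance <- function(m, k) {
  d <- as.matrix(stats::dist(m))
  diag(d) <- Inf
  unname(apply(d, 1L, function(r) mean(sort(r)[seq_len(k)])))
}

# statistical outlier removal keep-mask, threshold mu + alpha * sd
oracleOutlierMask <- function(m, k, alpha) {
  avg <- oracleMeanKnnDistance(m, k)
  avg <= mean(avg) + alpha * stats::sd(avg)
}

# fixed-radius connected components by union-find on all pairs
oracleComponents <- function(m, radius) {
  n <- nrow(m)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  d <- as.matrix(stats::dist(m))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (d[i, j] <= radius) {
      a <- find(i); b <- find(j)
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# do two labelings induce the same partition (ignoring label names)?
samePartition <- function(a, b) {
  identical(as.integer(factor(paste(a))), as.integer(factor(paste(b)))) ||
    all(tapply(b, a, function(x) length(unique(x))) == 1L) &&
    all(tapply(a, b, function(x) length(unique(x))) == 1L)
}

# a small colored cloud for I/O tests
makeColoredCloud <- function(n = 50L, seed = 7L) {
  set.seed(seed)
  pointCloud(cbind(runif(n, -2, 2), runif(n, -2, 2), runif(n, 0, 1.5)),
             matrix(runif(3L * n), ncol = 3L))
}

# symmetric max nearest-neighbor distance between two point sets (rows);
# compares detected centers with truth without assuming a shared ordering
maxMatchDistance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  k <- min(ncol(a), ncol(b))
  a <- a[, seq_len(k), drop = FALSE]; b <- b[, seq_len(k), drop = FALSE]
  da <- apply(a, 1, function(p) min(sqrt(colSums((t(b) - p)^2))))
  db <- apply(b, 1, function(p) min(sqrt(colSums((t(a) - p)^2))))
  max(c(da, db))
}
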