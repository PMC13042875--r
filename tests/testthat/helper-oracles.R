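# Independent brute-force oracles and tiny fixture builders used across
# the suite. These stay deliberately naive so they share no code with the
# implementations they check.

# DTW by exhaustive enumeration of all monotone warping paths
# (steps down/right/diagonal from (1,1) to (m,n)); exponential, fine for
# series of length <= 6.
dtw_brute_force <- function(a, b) {
  rec <- function(i, j) {
    c0 <- abs(a[i] - b[j])
    if (i == 1 && j == 1) return(c0)
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    c0 + best
  }
  rec(length(a), length(b))
}

# topological overlap by triple loop, straight from the definition
tom_brute_force <- function(a) {
  n <- nrow(a)
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(a[i, -i])
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      s <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) s <- s + a[i, u] * a[u, j]
      }
      tom[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# expression_matrix from a plain matrix, flagged log-normalized so scoring
# functions accept the values as-is
norm_em <- function(values, meta = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("c%03d", seq_len(ncol(values)))
  }
  expression_matrix(values, meta, normalized = TRUE)
}

# random valid adjacency (symmetric, zero diagonal, values in [0,1])
random_adjacency <- function(n) {
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}
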