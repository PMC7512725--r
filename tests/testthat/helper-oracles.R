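# Independent brute-force oracles used to cross-check the fast implementations.

# Naive nested-loop pattern recount: builds each embedded window explicitly
# and counts string keys, no radix encoding.
naive_pattern_counts <- function(u, m, d = 1, flavor = "dispersion") {
  n_emb <- length(u) - (m - 1) * d
  keys <- character(n_emb)
  for (i in seq_len(n_emb)) {
    w <- u[i + (0:(m - 1)) * d]
    if (flavor == "fluctuation") w <- w[-1] - w[-length(w)]
    keys[i] <- paste(w, collapse = ",")
  }
  table(keys)
}

# Brute-force sample entropy: explicit pairwise template comparison.
naive_sampen <- function(x, m = 2, r = 0.2) {
  tol <- r * sd(x)
  n_t <- length(x) - m
  A <- B <- 0
  for (i in 1:(n_t - 1)) for (j in (i + 1):n_t) {
    if (max(abs(x[i + 0:(m - 1)] - x[j + 0:(m - 1)])) <= tol) {
      B <- B + 1
      if (abs(x[i + m] - x[j + m]) <= tol) A <- A + 1
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# Brute-force strict-order realizations of a permutation over alphabet 1..c.
naive_implications <- function(perm, c) {
  m <- length(perm)
  grid <- as.matrix(expand.grid(rep(list(1:c), m)))
  keep <- apply(grid, 1, function(v)
    length(unique(v)) == m && all(rank(v) == perm))
  out <- grid[keep, , drop = FALSE]
  out[do.call(order, as.data.frame(out)), , drop = FALSE]
}

# Compare a pattern_distribution data frame against a naive table by name.
counts_match <- function(dist, oracle) {
  got <- setNames(dist$count, dist$pattern)
  want <- setNames(as.integer(oracle), names(oracle))
  identical(got[order(names(got))], want[order(names(want))])
}

worked_x1 <- c(3.6, 4.2, 1.2, 3.1, 4.2, 2.1, 3.3, 4.6, 6.8, 8.4)
worked_x2 <- c(3, 4.5, 6.2, 5.1, 3.2, 1.2, 3.5, 5.6, 4.9, 8.4)
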