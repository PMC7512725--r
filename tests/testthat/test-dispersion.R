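test_that("delay embedding enumerates exactly N - (m-1)d windows", {
  u <- c(2, 2, 1, 1, 2, 1, 1, 2, 3, 3)
  E <- embed_series(u, 2, 1)
  expect_equal(nrow(E), 9)
  expect_equal(E[1, ], c(2, 2))
  expect_equal(E[2, ], c(2, 1))
  expect_equal(E[9, ], c(3, 3))
  # boundary: minimal length gives one window
  expect_equal(nrow(embed_series(1:5, m = 3, d = 2)), 1)
  # stride
  expect_equal(embed_series(1:7, m = 3, d = 2),
               matrix(c(1, 2, 3, 3, 4, 5, 5, 6, 7), nrow = 3))
  expect_error(embed_series(1:4, m = 3, d = 2), "insufficient length")
})

test_that("fluctuation images collapse patterns equal up to an offset", {
  expect_equal(to_fluctuation(c(1, 3, 4)), c(2, 1))
  expect_equal(to_fluctuation(c(2, 4, 5)), c(2, 1))
  expect_equal(to_fluctuation(c(3, 3, 3)), c(0, 0))
  expect_equal(to_fluctuation(c(1, 1, 1)), c(0, 0))
  expect_equal(to_fluctuation(c(1, 1, 2)), c(0, 1))
  M <- rbind(c(1, 3, 4), c(2, 4, 5))
  expect_equal(to_fluctuation(M), rbind(c(2, 1), c(2, 1)))
  expect_error(to_fluctuation(c(2)), "length >= 2")
})

test_that("pattern distributions reproduce the worked-example censuses", {
  # three-class series of the DispEn example: three patterns occur twice,
  # three occur once, over 9 windows
  u1 <- classify(worked_x1, range(worked_x1), 3)
  d1 <- pattern_distribution(u1, m = 2, c = 3)
  expect_equal(attr(d1, "total"), 9)
  expect_equal(attr(d1, "space"), 9)
  expect_equal(sort(d1$count), c(1, 1, 1, 2, 2, 2))
  expect_equal(sum(d1$prob), 1, tolerance = 1e-12)

  # fluctuation census of the FDispEn example
  u2 <- classify(worked_x2, range(worked_x2), 2)
  d2 <- pattern_distribution(u2, m = 3, c = 2, flavor = "fluctuation")
  expect_equal(attr(d2, "total"), 8)
  expect_equal(attr(d2, "space"), 9)
  counts <- setNames(d2$count, d2$pattern)
  expect_equal(counts[["0,1"]], 2)
  expect_equal(counts[["1,0"]], 2)
  expect_equal(counts[["0,0"]], 2)
  expect_equal(counts[["0,-1"]], 1)
  expect_equal(counts[["-1,0"]], 1)

  # printed difference-pattern sequence, in order
  fl <- to_fluctuation(embed_series(u2, 3, 1))
  expect_equal(apply(fl, 1, paste, collapse = ","),
               c("0,1", "1,0", "0,-1", "-1,0", "0,0", "0,1", "1,0", "0,0"))

  # constant class series: a single pattern with probability one
  dc <- pattern_distribution(rep(2L, 30), m = 3, c = 4)
  expect_equal(nrow(dc), 1)
  expect_equal(dc$prob, 1)
})

test_that("DispEn and FDispEn reproduce the worked-example entropies", {
  e1 <- dispen(worked_x1, m = 2, c = 3, d = 1, mapping = "linear")
  expect_equal(round(e1$raw, 4), 1.7351)
  expect_equal(e1$normalized, e1$raw / log(9), tolerance = 1e-12)
  e2 <- fdispen(worked_x2, m = 3, c = 2, d = 1, mapping = "linear")
  expect_equal(round(e2$raw, 4), 1.5596)
  expect_equal(e2$normalized, e2$raw / log(9), tolerance = 1e-12)
})

test_that("entropy of a uniform pattern distribution is exactly log of its size", {
  expect_equal(shannon_entropy(rep(1 / 7, 7)), log(7), tolerance = 1e-12)
  # cyclic two-class series visiting all four pairs equally often
  u <- c(rep(c(1L, 1L, 2L, 2L), 25), 1L)
  d <- pattern_distribution(u, m = 2, c = 2)
  expect_equal(shannon_entropy(d), log(4), tolerance = 1e-12)
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
})

test_that("fast radix counting agrees with a naive recount on random inputs", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    m <- sample(2:4, 1)
    cc <- sample(2:4, 1)
    d <- sample(1:2, 1)
    u <- sample(1:cc, n, replace = TRUE)
    for (flavor in c("dispersion", "fluctuation")) {
      dist <- pattern_distribution(u, m = m, c = cc, d = d, flavor = flavor)
      oracle <- naive_pattern_counts(u, m, d, flavor)
      expect_true(counts_match(dist, oracle))
      expect_equal(sum(dist$count), n - (m - 1) * d)
      p <- dist$prob
      expect_equal(shannon_entropy(dist), -sum(p * log(p)))
    }
  }
})

test_that("normalized values stay in [0, 1] on fuzzed inputs", {
  set.seed(202)
  for (i in 1:60) {
    x <- switch(sample(3, 1),
                rnorm(sample(30:120, 1)),
                cumsum(rnorm(sample(30:120, 1))),
                round(runif(sample(30:120, 1)) * 4))
    if (sd(x) == 0) x[1] <- x[1] + 1
    mk <- sample(c("linear", "sorting", "logsig", "tansig", "ncdf"), 1)
    e1 <- dispen(x, m = sample(2:3, 1), c = sample(2:6, 1), mapping = mk)
    e2 <- fdispen(x, m = sample(2:3, 1), c = sample(2:6, 1), mapping = mk)
    expect_gte(e1$normalized, 0); expect_lte(e1$normalized, 1)
    expect_gte(e2$normalized, 0); expect_lte(e2$normalized, 1)
  }
})

test_that("FDispEn is invariant to constant class offsets", {
  set.seed(303)
  u <- sample(1:4, 150, replace = TRUE)
  d0 <- pattern_distribution(u, m = 3, c = 6, flavor = "fluctuation")
  d1 <- pattern_distribution(u + 2L, m = 3, c = 6, flavor = "fluctuation")
  expect_equal(shannon_entropy(d0), shannon_entropy(d1))
  expect_equal(d0[order(d0$pattern), c("pattern", "count")],
               d1[order(d1$pattern), c("pattern", "count")],
               ignore_attr = TRUE)
})

test_that("white-noise DispEn approaches the mapping-specific asymptote", {
  set.seed(404)
  x <- rnorm(10000)
  # ncdf classes of Gaussian input are uniform: normalized entropy near 1
  expect_equal(dispen(x, m = 2, c = 6, mapping = "ncdf")$normalized, 1,
               tolerance = 0.02)
  # logsig classes of Gaussian input have closed-form occupancies
  k <- 1:6
  p <- pnorm(qlogis(k / 6)) - pnorm(qlogis((k - 1) / 6))
  asymptote <- -sum(p * log(p)) / log(6)  # 0.9172
  expect_equal(dispen(x, m = 2, c = 6, mapping = "logsig")$normalized,
               asymptote, tolerance = 0.02)
})

test_that("forbidden censuses count missing patterns in each flavor", {
  # all four two-class pairs occur: nothing forbidden
  u <- c(rep(c(1, 1, 2, 2), 25), 1)
  cens <- forbidden_census(u, m = 2, c = 2, mapping = "linear",
                           flavor = "dispersion")
  expect_equal(cens$forbidden, 0)
  # short series miss ordinal patterns they could not yet visit
  cens <- forbidden_census(c(1, 2, 3, 2.1, 1, 4), m = 3,
                           flavor = "permutation")
  expect_equal(cens$observed, 4)
  expect_equal(cens$forbidden, 2)
  expect_equal(cens$space, 6)
})

test_that("forbidden fraction of the chaotic logistic map stays above one half", {
  x <- logistic_map(10000, alpha = 4, x0 = 0.23)
  for (flavor in c("dispersion", "fluctuation")) {
    cens <- forbidden_census(x, m = 3, c = 6, mapping = "logsig",
                             flavor = flavor)
    expect_gt(cens$normalized_forbidden, 0.5)
  }
  # stochastic full-support contrast: white noise leaves few patterns unseen
  set.seed(77)
  w <- rnorm(10000)
  cw <- forbidden_census(w, m = 3, c = 6, mapping = "logsig",
                         flavor = "dispersion")
  expect_lt(cw$normalized_forbidden, 0.05)
})

test_that("implied forbidden dispersion patterns match the strict-order list", {
  fi <- forbidden_implications(c(2, 3, 1), 6)
  reference_list <- rbind(
    c(2,3,1), c(2,4,1), c(2,5,1), c(2,6,1), c(3,4,1), c(3,5,1), c(3,6,1),
    c(4,5,1), c(4,6,1), c(5,6,1), c(3,4,2), c(3,5,2), c(3,6,2), c(4,5,2),
    c(4,6,2), c(5,6,2), c(4,5,3), c(4,6,3), c(5,6,3), c(5,6,4))
  ord <- function(M) M[do.call(order, as.data.frame(M)), , drop = FALSE]
  expect_equal(ord(unname(fi$dispersion)), ord(reference_list))
  # fluctuation images, duplicates retained
  flu <- apply(fi$fluctuation, 1, paste, collapse = ",")
  expect_equal(sum(flu == "1,-2"), 4)
  expect_true(all(c("2,-3", "3,-4", "4,-5", "1,-3", "2,-4", "1,-4",
                    "2,-5", "1,-5", "3,-5") %in% flu))
  expect_equal(nrow(fi$fluctuation), 20)

  # exhaustive small-alphabet oracle
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  for (cc in 2:4) for (perm in perms) {
    got <- forbidden_implications(perm, cc)$dispersion
    expect_equal(ord(unname(got)), unname(naive_implications(perm, cc)))
  }
  expect_error(forbidden_implications(c(1, 1, 2), 6), "permutation")
})
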