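#' Permutation entropy (PerEn)
#'
#' Shannon entropy (nats) of the ordinal patterns of delay-embedded windows,
#' normalized by \code{log(m!)}.  Equal values within a window are ranked by
#' their order of emergence (stable argsort, the Bandt-Pompe first
#' alternative), so e.g. the windows (1,2,2) and (1,2,3) share the pattern
#' (1,2,3) and the series {1,2,2,2} has entropy 0.
#'
#' @param x numeric signal.
#' @param m order / embedding dimension (default 3).
#' @param d time delay (default 1).
#' @return an \code{"entropy_estimate"} object.
#' @export
permutation_entropy <- function(x, m = 3L, d = 1L) {
  .check_signal(x, min_len = (m - 1L) * d + 1L)
  pats <- .ordinal_patterns(x, m, d)
  tab <- table(pats)
  total <- length(pats)
  dist <- data.frame(pattern = names(tab), count = as.integer(tab),
                     prob = as.integer(tab) / total, stringsAsFactors = FALSE)
  space <- factorial(m)
  attr(dist, "total") <- total; attr(dist, "space") <- space
  raw <- shannon_entropy(dist)
  .entropy_estimate("peren", raw, raw / log(space),
                    list(m = m, d = d), dist, total, space)
}

#' Sample entropy (SampEn)
#'
#' Negative natural log of the conditional probability that two templates of
#' length m within tolerance \code{r * sd(x)} (Chebyshev distance,
#' self-matches excluded) remain within tolerance at length m+1:
#' \code{-log(A/B)} with B the number of matching template pairs at length m
#' and A at length m+1.  For short series A (or B) can be zero; the value is
#' then explicitly undefined rather than numeric, with a machine-readable
#' reason in the result.
#'
#' @param x numeric signal.
#' @param m template length (default 2).
#' @param r tolerance as a multiple of the sample standard deviation of
#'   \code{x} (default 0.2).
#' @return an \code{"entropy_estimate"} object; \code{$undefined} is TRUE and
#'   \code{$raw} is NA when no matches exist at length m or m+1, or when the
#'   signal has zero standard deviation.
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2) {
  .check_signal(x, min_len = m + 2L)
  if (r <= 0) stop("tolerance r must be positive", call. = FALSE)
  params <- list(m = m, r = r)
  tol <- r * stats::sd(x)  # a constant series has tol 0 and still self-matches
  n_t <- length(x) - m  # templates of length m and m+1 counted over i in 1..n_t
  # running Chebyshev distance between all template pairs, one lag at a time
  D <- matrix(0, n_t, n_t)
  for (k in 0:(m - 1L)) {
    v <- x[(1:n_t) + k]
    D <- pmax(D, abs(outer(v, v, "-")))
  }
  B <- (sum(D <= tol) - n_t) / 2  # i < j pairs, self-matches removed
  v <- x[(1:n_t) + m]
  D <- pmax(D, abs(outer(v, v, "-")))
  A <- (sum(D <= tol) - n_t) / 2
  if (B == 0 || A == 0) {
    reason <- if (B == 0) "no template matches at length m"
              else "no template matches at length m+1"
    return(.entropy_estimate("sampen", NA_real_, NA_real_, params,
                             undefined = TRUE, reason = reason))
  }
  val <- -log(A / B)
  .entropy_estimate("sampen", val, val, params)
}

#' Lempel-Ziv complexity (LZC)
#'
#' Binarizes the signal at its median (values >= median become 1), parses the
#' binary string with the LZ76 exhaustive-history scheme (Kaspar-Schuster
#' algorithm) into c(n) components, and normalizes as
#' \code{c(n) * log2(n) / n}, which tends to 1 for an i.i.d. equiprobable
#' binary source.
#'
#' @param x numeric signal (length >= 2), or a logical/0-1 vector taken as the
#'   binary sequence directly.
#' @return an \code{"entropy_estimate"} object with \code{$raw} the component
#'   count c(n) and \code{$normalized} the normalized complexity.
#' @export
lempel_ziv_complexity <- function(x) {
  .check_signal(x, min_len = 2L)
  s <- if (is.logical(x) || all(x %in% c(0, 1))) as.integer(x)
       else as.integer(x >= stats::median(x))
  n <- length(s)
  cn <- .lz76_count(s)
  .entropy_estimate("lzc", cn, cn * log2(n) / n,
                    list(n = n, binarization = "median"))
}

## LZ76 exhaustive-history production count (Kaspar & Schuster recursion)
.lz76_count <- function(s) {
  n <- length(s)
  cn <- 1L; l <- 1L; i <- 0L; k <- 1L; k_max <- 1L
  repeat {
    if (s[i + k] == s[l + k]) {
      k <- k + 1L
      if (l + k > n) { cn <- cn + 1L; break }
    } else {
      if (k > k_max) k_max <- k
      i <- i + 1L
      if (i == l) {
        cn <- cn + 1L
        l <- l + k_max
        if (l + 1L > n) break
        i <- 0L; k <- 1L; k_max <- 1L
      } else {
        k <- 1L
      }
    }
  }
  cn
}

#' Hedges' g effect size
#'
#' Bias-corrected standardized mean difference between two groups:
#' \code{g = J * (mean(a) - mean(b)) / s_pooled}, with the pooled SD weighted
#' by n-1 and the small-sample correction \code{J = 1 - 3/(4(na + nb) - 9)}.
#'
#' @param a,b numeric samples (each of length >= 2).
#' @return the effect size (positive when \code{a} has the larger mean).
#' @export
hedges_g <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
             (na + nb - 2))
  if (sp == 0) stop("degenerate groups: zero pooled standard deviation",
                    call. = FALSE)
  J <- 1 - 3 / (4 * (na + nb) - 9)
  J * (mean(a) - mean(b)) / sp
}
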