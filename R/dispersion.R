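#' Delay embedding of a class series
#'
#' Returns the matrix whose i-th row is
#' \code{(u[i], u[i + d], ..., u[i + (m-1) d])}; there are exactly
#' \code{N - (m-1) d} rows.
#'
#' @param u integer (class) series.
#' @param m embedding dimension (>= 1).
#' @param d time delay (>= 1).
#' @return integer matrix with \code{m} columns.
#' @export
embed_series <- function(u, m, d = 1L) {
  n <- length(u)
  if (m < 1 || d < 1) stop("need m >= 1 and d >= 1", call. = FALSE)
  n_emb <- n - (m - 1L) * d
  if (n_emb < 1L)
    stop(sprintf("insufficient length: N = %d < (m-1)d + 1 = %d",
                 n, (m - 1L) * d + 1L), call. = FALSE)
  out <- vapply(0:(m - 1L), function(k) u[(1:n_emb) + k * d],
                numeric(n_emb))
  matrix(out, nrow = n_emb, ncol = m)
}

#' Fluctuation image of dispersion patterns
#'
#' Replaces each length-m dispersion pattern by its adjacent differences,
#' giving a length m-1 tuple with entries in \code{-(c-1) .. (c-1)}.  Patterns
#' that differ only by a constant offset (e.g. (1,3,4) and (2,4,5), or (1,1,1)
#' and (3,3,3)) share the same fluctuation image.
#'
#' @param pattern a length-m vector, or a matrix of patterns (one per row).
#' @return vector of length m-1, or matrix with m-1 columns.
#' @export
to_fluctuation <- function(pattern) {
  if (is.matrix(pattern)) {
    if (ncol(pattern) < 2L) stop("patterns must have length >= 2", call. = FALSE)
    m <- ncol(pattern)
    pattern[, 2:m, drop = FALSE] - pattern[, 1:(m - 1L), drop = FALSE]
  } else {
    if (length(pattern) < 2L) stop("pattern must have length >= 2", call. = FALSE)
    diff(pattern)
  }
}

## mixed-radix integer keys give O(N) counting; digits in 0..(radix-1)
.encode_keys <- function(mat, radix, offset) {
  m <- ncol(mat)
  key <- numeric(nrow(mat))
  for (j in seq_len(m)) key <- key * radix + (mat[, j] + offset)
  key
}

.decode_key <- function(key, m, radix, offset) {
  out <- integer(m)
  for (j in m:1) {
    out[j] <- key %% radix - offset
    key <- key %/% radix
  }
  out
}

#' Empirical distribution of dispersion or fluctuation patterns
#'
#' Embeds a class series and tabulates the relative frequency of every
#' observed pattern: m-tuples over 1..c for the \code{"dispersion"} flavor
#' (pattern space c^m), adjacent-difference (m-1)-tuples over
#' \code{-(c-1)..(c-1)} for the \code{"fluctuation"} flavor (pattern space
#' (2c-1)^(m-1)).
#'
#' @param u integer class series with alphabet 1..c.
#' @param m embedding dimension (>= 2 for the fluctuation flavor).
#' @param c alphabet size; defaults to \code{attr(u, "c")} or \code{max(u)}.
#' @param d time delay.
#' @param flavor \code{"dispersion"} or \code{"fluctuation"}.
#' @return data frame with columns \code{pattern} (comma-separated tuple),
#'   \code{count} and \code{prob}; attributes \code{total} (number of embedded
#'   vectors) and \code{space} (size of the potential pattern space).
#' @export
pattern_distribution <- function(u, m, c = NULL, d = 1L,
                                 flavor = c("dispersion", "fluctuation")) {
  flavor <- match.arg(flavor)
  if (is.null(c)) c <- if (!is.null(attr(u, "c"))) attr(u, "c") else max(u)
  c <- .check_classes(c)
  if (any(u < 1L | u > c)) stop("class series outside alphabet 1..c", call. = FALSE)
  if (flavor == "fluctuation" && m < 2L)
    stop("fluctuation flavor needs m >= 2", call. = FALSE)
  E <- embed_series(u, m, d)
  if (flavor == "fluctuation") {
    P <- to_fluctuation(E)
    radix <- 2L * c - 1L; offset <- c - 1L
    space <- radix^(m - 1L)
  } else {
    P <- E
    radix <- c; offset <- -1L
    space <- as.numeric(c)^m
  }
  keys <- .encode_keys(P, radix, offset)
  tab <- table(keys)
  key_vals <- as.numeric(names(tab))
  labels <- vapply(key_vals, function(k)
    paste(.decode_key(k, ncol(P), radix, offset), collapse = ","), character(1))
  total <- nrow(P)
  out <- data.frame(pattern = labels, count = as.integer(tab),
                    prob = as.integer(tab) / total,
                    stringsAsFactors = FALSE)
  attr(out, "total") <- total
  attr(out, "space") <- space
  attr(out, "flavor") <- flavor
  out
}

#' Shannon entropy of a pattern distribution (nats)
#'
#' \code{-sum(p log p)} over observed patterns, with \code{0 log 0 := 0}.
#'
#' @param dist a data frame from \code{\link{pattern_distribution}} or a
#'   numeric vector of probabilities.
#' @return entropy in nats.
#' @export
shannon_entropy <- function(dist) {
  p <- if (is.data.frame(dist)) dist$prob else dist
  p <- p[p > 0]
  if (abs(sum(p) - 1) > 1e-9)
    stop("probabilities must sum to 1", call. = FALSE)
  -sum(p * log(p))
}

.entropy_estimate <- function(method, raw, normalized, params,
                              distribution = NULL, n_embedded = NA_integer_,
                              space = NA_real_, undefined = FALSE,
                              reason = NA_character_) {
  observed <- if (!is.null(distribution)) nrow(distribution) else NA_integer_
  structure(list(method = method, raw = raw, normalized = normalized,
                 params = params, distribution = distribution,
                 n_embedded = n_embedded, space = space,
                 observed = observed,
                 forbidden = if (!is.na(space) && !is.na(observed))
                   space - observed else NA_real_,
                 undefined = undefined, reason = reason),
            class = "entropy_estimate")
}

#' Dispersion entropy (DispEn)
#'
#' Maps the signal to c classes, forms all delay-d windows of m classes
#' (dispersion patterns), and returns the Shannon entropy (natural log) of
#' their relative frequencies.  The normalized value divides by
#' \code{log(c^m)}, the maximum attained by a uniform pattern distribution.
#'
#' @param x numeric signal.
#' @param m embedding dimension (default 2).
#' @param c number of classes (default 6).
#' @param d time delay (default 1).
#' @param mapping mapping kind or a \code{\link{mapping_spec}} (default
#'   \code{"logsig"}; the worked examples in the references use
#'   \code{"linear"}).
#' @return an \code{"entropy_estimate"} object: raw and normalized entropy,
#'   the pattern distribution, and the observed/forbidden pattern census.
#' @examples
#' x <- c(3.6, 4.2, 1.2, 3.1, 4.2, 2.1, 3.3, 4.6, 6.8, 8.4)
#' dispen(x, m = 2, c = 3, mapping = "linear")  # raw value 1.7351
#' @export
dispen <- function(x, m = 2L, c = 6L, d = 1L, mapping = "logsig") {
  spec <- if (inherits(mapping, "mapping_spec")) mapping
          else mapping_spec(mapping, c)
  if (spec$c != c) spec$c <- .check_classes(c)
  u <- suppressWarnings(map_to_classes(x, spec))
  dist <- pattern_distribution(u, m = m, c = spec$c, d = d,
                               flavor = "dispersion")
  raw <- shannon_entropy(dist)
  .entropy_estimate("dispen", raw, raw / log(attr(dist, "space")),
                    list(m = m, c = spec$c, d = d, mapping = spec$kind),
                    dist, attr(dist, "total"), attr(dist, "space"))
}

#' Fluctuation-based dispersion entropy (FDispEn)
#'
#' As \code{\link{dispen}}, but each dispersion pattern is replaced by its
#' adjacent differences before counting, so only the local fluctuations of
#' the class series matter; constant offsets of a pattern are ignored.
#' Normalized by \code{log((2c-1)^(m-1))}.
#'
#' @inheritParams dispen
#' @param m embedding dimension (default 3).
#' @param c number of classes (default 5).
#' @examples
#' x <- c(3, 4.5, 6.2, 5.1, 3.2, 1.2, 3.5, 5.6, 4.9, 8.4)
#' fdispen(x, m = 3, c = 2, mapping = "linear")  # raw value 1.5596
#' @export
fdispen <- function(x, m = 3L, c = 5L, d = 1L, mapping = "logsig") {
  if (m < 2L) stop("FDispEn needs m >= 2", call. = FALSE)
  spec <- if (inherits(mapping, "mapping_spec")) mapping
          else mapping_spec(mapping, c)
  if (spec$c != c) spec$c <- .check_classes(c)
  u <- suppressWarnings(map_to_classes(x, spec))
  dist <- pattern_distribution(u, m = m, c = spec$c, d = d,
                               flavor = "fluctuation")
  raw <- shannon_entropy(dist)
  .entropy_estimate("fdispen", raw, raw / log(attr(dist, "space")),
                    list(m = m, c = spec$c, d = d, mapping = spec$kind),
                    dist, attr(dist, "total"), attr(dist, "space"))
}

#' Forbidden-pattern census
#'
#' Counts how many of the potential patterns never occur in the signal.
#' Persistent forbidden patterns as the series grows indicate deterministic
#' dynamics; an unconstrained stochastic source eventually visits the whole
#' pattern space and leaves none forbidden (missing patterns in short series
#' are finite-length "false forbidden" artifacts).
#'
#' @inheritParams dispen
#' @param flavor \code{"dispersion"} (space c^m), \code{"fluctuation"}
#'   (space (2c-1)^(m-1)) or \code{"permutation"} (ordinal patterns of the raw
#'   signal, space m!).
#' @return list with \code{observed}, \code{forbidden}, \code{space} and
#'   \code{normalized_forbidden} (forbidden / space).
#' @export
forbidden_census <- function(x, m = 3L, c = 6L, d = 1L, mapping = "logsig",
                             flavor = c("dispersion", "fluctuation",
                                        "permutation")) {
  flavor <- match.arg(flavor)
  if (flavor == "permutation") {
    pats <- .ordinal_patterns(x, m, d)
    observed <- length(unique(pats))
    space <- factorial(m)
  } else {
    spec <- if (inherits(mapping, "mapping_spec")) mapping
            else mapping_spec(mapping, c)
    u <- suppressWarnings(map_to_classes(x, spec))
    dist <- pattern_distribution(u, m = m, c = spec$c, d = d, flavor = flavor)
    observed <- nrow(dist)
    space <- attr(dist, "space")
  }
  forbidden <- space - observed
  list(observed = observed, forbidden = forbidden, space = space,
       normalized_forbidden = forbidden / space)
}

#' Dispersion patterns implied forbidden by a missing permutation
#'
#' If the ordinal (permutation) pattern \code{perm} never occurs in a signal,
#' then no dispersion pattern whose entries realize that order strictly can
#' occur either: classes are monotone in the signal, so strict inequalities
#' between classes force the same inequalities between the raw samples.
#' Returns every m-tuple over 1..c with distinct entries whose rank vector
#' equals \code{perm}, together with their fluctuation images.  (Tuples with
#' tied entries carry no implication: a class tie does not constrain the order
#' of the underlying samples.)
#'
#' @param perm integer permutation of 1..m, read as the rank of each position
#'   (e.g. \code{c(2, 3, 1)} means the third value is smallest, then first,
#'   then second).
#' @param c alphabet size.
#' @return list with \code{dispersion} (matrix, one pattern per row, in
#'   lexicographic order of the chosen values) and \code{fluctuation}
#'   (matrix of their difference images, duplicates retained).
#' @export
forbidden_implications <- function(perm, c) {
  m <- length(perm)
  if (!setequal(perm, seq_len(m)))
    stop("`perm` must be a permutation of 1..m", call. = FALSE)
  c <- .check_classes(c)
  if (c < m) {
    disp <- matrix(integer(0), ncol = m)
  } else {
    combos <- utils::combn(seq_len(c), m)  # increasing m-subsets of 1..c
    # place the k-th smallest chosen value at the position whose rank is k
    disp <- t(apply(combos, 2, function(v) v[perm]))
  }
  list(dispersion = disp, fluctuation = to_fluctuation(disp))
}

## ordinal pattern of each embedded window, ties ranked by order of emergence
.ordinal_patterns <- function(x, m, d = 1L) {
  E <- embed_series(x, m, d)
  apply(E, 1, function(r)
    paste(rank(r, ties.method = "first"), collapse = ","))
}
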