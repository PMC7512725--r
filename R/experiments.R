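#' Unified estimator front-end
#'
#' Dispatches to \code{\link{dispen}}, \code{\link{fdispen}},
#' \code{\link{permutation_entropy}}, \code{\link{sample_entropy}} or
#' \code{\link{lempel_ziv_complexity}}.  Used by the experiment drivers and
#' the command-line interface; arguments in \code{...} are passed through to
#' the selected estimator (\code{m}, \code{c}, \code{d}, \code{mapping},
#' \code{r}).
#'
#' @param x numeric signal.
#' @param estimator estimator id.
#' @param ... estimator arguments.
#' @return an \code{"entropy_estimate"} object.
#' @export
entropy <- function(x, estimator = c("dispen", "fdispen", "peren", "sampen",
                                     "lzc"), ...) {
  estimator <- match.arg(estimator)
  switch(estimator,
         dispen  = dispen(x, ...),
         fdispen = fdispen(x, ...),
         peren   = permutation_entropy(x, ...),
         sampen  = sample_entropy(x, ...),
         lzc     = lempel_ziv_complexity(x, ...))
}

## sequential child seeds derived from one master seed (kept below 2^31)
.child_seeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  set.seed(seed)
  as.list(sample.int(.Machine$integer.max - 1L, k))
}

#' Noise-sensitivity ratio NrmEntN
#'
#' Ratio of an estimator's value on a noisy series to its value on the clean
#' series.  A ratio near 1 means the estimator is insensitive to the added
#' noise; periodic signals (low clean entropy) inflate the ratio most.
#'
#' @param x the clean signal; \code{noisy} is its contaminated version (the
#'   same estimator settings are applied to both).
#' @param noisy numeric signal.
#' @param estimator estimator id (see \code{\link{entropy}}).
#' @param ... estimator arguments.
#' @return the ratio (NA with a warning if either value is undefined).
#' @export
nrm_ent_n <- function(x, noisy, estimator = "dispen", ...) {
  e0 <- entropy(x, estimator, ...)
  e1 <- entropy(noisy, estimator, ...)
  if (isTRUE(e0$undefined) || isTRUE(e1$undefined)) {
    warning("undefined entropy value; NrmEntN is undefined", call. = FALSE)
    return(NA_real_)
  }
  if (e0$raw == 0) stop("clean-series entropy is zero: ratio undefined",
                        call. = FALSE)
  e1$raw / e0$raw
}

#' Coefficient of variation
#'
#' Sample standard deviation (n-1) divided by the mean; used to compare the
#' stability of entropy estimates whose spread scales with their level.
#'
#' @param values numeric vector (length >= 2, non-zero mean); NAs are dropped.
#' @return SD / mean.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("zero mean: CV undefined", call. = FALSE)
  stats::sd(values) / m
}

#' Sliding-window entropy profile
#'
#' Moves a fixed-length window along the signal with step
#' \code{max(1, round(length * (1 - overlap)))} and evaluates the estimator in
#' each fully-contained window; the number of windows is
#' \code{floor((N - length)/step) + 1}.
#'
#' @param x numeric signal.
#' @param length window length in samples.
#' @param overlap fraction of overlap between consecutive windows, in [0, 1).
#' @param estimator estimator id.
#' @param ... estimator arguments.
#' @return data frame with one row per window: \code{window}, \code{start},
#'   \code{center}, \code{value} (normalized entropy; NA when undefined) and
#'   \code{undefined}.
#' @export
sliding_entropy_profile <- function(x, length, overlap = 0.8,
                                    estimator = "dispen", ...) {
  .check_signal(x, min_len = length)
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0,1)", call. = FALSE)
  n <- base::length(x)
  step <- max(1L, as.integer(round(length * (1 - overlap))))
  starts <- seq.int(1L, n - length + 1L, by = step)
  res <- lapply(starts, function(s) {
    e <- suppressWarnings(entropy(x[s:(s + length - 1L)], estimator, ...))
    data.frame(start = s, center = s + (length - 1) / 2,
               value = if (isTRUE(e$undefined)) NA_real_ else e$normalized,
               undefined = isTRUE(e$undefined))
  })
  out <- do.call(rbind, res)
  out <- cbind(window = seq_along(starts), out)
  out
}

#' Entropy versus signal length, over seeded realizations
#'
#' Generates \code{n_realizations} independent signals at every length and
#' evaluates the estimator on each; used for saturation curves (how many
#' samples an estimator needs to approach its asymptote) and for separating
#' signal families (e.g. white / pink / brown noise bands).
#'
#' @param generator a function \code{(n, seed)} returning a signal, or one of
#'   \code{"white"}, \code{"pink"}, \code{"brown"}.
#' @param lengths integer vector of signal lengths.
#' @param n_realizations realizations per length.
#' @param seed master seed; each (length, realization) gets a recorded child
#'   seed.
#' @param estimator estimator id.
#' @param ... estimator arguments.
#' @return long-format data frame: \code{length}, \code{realization},
#'   \code{seed}, \code{estimator}, \code{value} (normalized entropy),
#'   \code{undefined}.
#' @export
length_sweep <- function(generator, lengths, n_realizations = 40L, seed = 1L,
                         estimator = "dispen", ...) {
  if (is.character(generator)) {
    color <- match.arg(generator, c("white", "pink", "brown"))
    generator <- function(n, seed) colored_noise(n, color, seed)
  }
  seeds <- .child_seeds(seed, length(lengths) * n_realizations)
  rows <- list(); idx <- 0L
  for (li in seq_along(lengths)) {
    for (r in seq_len(n_realizations)) {
      idx <- idx + 1L
      s <- seeds[[idx]]
      x <- generator(lengths[li], s)
      e <- suppressWarnings(entropy(x, estimator, ...))
      rows[[idx]] <- data.frame(
        length = lengths[li], realization = r,
        seed = if (is.null(s)) NA_integer_ else s,
        estimator = estimator,
        value = if (isTRUE(e$undefined)) NA_real_ else e$normalized,
        undefined = isTRUE(e$undefined))
    }
  }
  do.call(rbind, rows)
}

#' Forbidden-pattern fraction versus signal length
#'
#' Computes the normalized number of forbidden patterns (forbidden / potential)
#' along growing prefixes of one fixed logistic-map trajectory, for the
#' dispersion, fluctuation and permutation flavors.  On a deterministic map
#' the fraction plateaus well above zero; on a stochastic full-support source
#' it decays to zero (short-length misses are "false forbidden" patterns).
#' The fraction is non-increasing in length on a fixed trajectory, since the
#' observed pattern set can only grow.
#'
#' @param lengths prefix lengths to evaluate.
#' @param alpha,x0 logistic-map parameter and initial state.
#' @param m,c,mapping embedding dimension, classes and mapping for the
#'   dispersion and fluctuation flavors.
#' @param m_perm ordinal-pattern length for the permutation flavor (default 5;
#'   at m = 3 the fully chaotic map forbids exactly one of the six patterns,
#'   so longer patterns are needed before forbidden ordinals dominate).
#' @return data frame: \code{length}, \code{flavor}, \code{observed},
#'   \code{space}, \code{normalized_forbidden}.
#' @export
forbidden_fraction_curve <- function(lengths, alpha = 4, x0 = 0.23,
                                     m = 3L, c = 6L, mapping = "logsig",
                                     m_perm = 5L) {
  x_full <- logistic_map(max(lengths), alpha = alpha, x0 = x0)
  rows <- list()
  for (n in sort(lengths)) {
    x <- x_full[seq_len(n)]
    for (flavor in c("dispersion", "fluctuation", "permutation")) {
      mm <- if (flavor == "permutation") m_perm else m
      cens <- if (n >= mm)
        forbidden_census(x, m = mm, c = c, mapping = mapping, flavor = flavor)
      else {
        space <- switch(flavor, dispersion = as.numeric(c)^mm,
                        fluctuation = (2 * c - 1)^(mm - 1),
                        permutation = factorial(mm))
        list(observed = 0, space = space, normalized_forbidden = 1)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        length = n, flavor = flavor, observed = cens$observed,
        space = cens$space, normalized_forbidden = cens$normalized_forbidden)
    }
  }
  do.call(rbind, rows)
}

#' Epoch-averaged entropy comparison between two groups of signals
#'
#' Splits every signal into consecutive non-overlapping epochs (the trailing
#' partial epoch is dropped), evaluates each estimator per epoch, averages the
#' defined values per signal, and summarizes the group difference with
#' Hedges' g.  Undefined epoch values (possible for SampEn on short epochs)
#' are excluded from the per-signal mean and reported as a count.
#'
#' @param group_a,group_b lists of numeric signals.
#' @param epoch_length epoch length in samples.
#' @param methods character vector of estimator ids.
#' @param params named list (by estimator id) of argument lists, e.g.
#'   \code{list(sampen = list(m = 2, r = 0.2))}.
#' @return data frame per estimator: group means of per-signal mean entropy,
#'   Hedges' g (a minus b), and undefined-epoch counts.
#' @export
epoch_group_comparison <- function(group_a, group_b, epoch_length,
                                   methods = c("dispen", "fdispen", "peren",
                                               "sampen", "lzc"),
                                   params = list()) {
  per_signal <- function(x, estimator, args) {
    n_ep <- length(x) %/% epoch_length
    if (n_ep < 1L) stop("signal shorter than one epoch", call. = FALSE)
    vals <- vapply(seq_len(n_ep), function(k) {
      ep <- x[((k - 1L) * epoch_length + 1L):(k * epoch_length)]
      e <- suppressWarnings(do.call(entropy, c(list(ep, estimator), args)))
      if (isTRUE(e$undefined)) NA_real_ else e$normalized
    }, numeric(1))
    c(mean = mean(vals, na.rm = TRUE), n_undefined = sum(is.na(vals)))
  }
  rows <- lapply(methods, function(method) {
    args <- if (!is.null(params[[method]])) params[[method]] else list()
    a <- vapply(group_a, per_signal, numeric(2), estimator = method, args = args)
    b <- vapply(group_b, per_signal, numeric(2), estimator = method, args = args)
    data.frame(estimator = method,
               mean_a = mean(a["mean", ]), mean_b = mean(b["mean", ]),
               g = hedges_g(a["mean", ], b["mean", ]),
               undefined_a = sum(a["n_undefined", ]),
               undefined_b = sum(b["n_undefined", ]))
  })
  do.call(rbind, rows)
}

#' Estimator stability on the MIX process (CV comparison)
#'
#' Generates seeded realizations of the MIX process at a fixed mixing
#' probability and compares the coefficient of variation of DispEn and
#' FDispEn across class counts with that of SampEn across tolerance values.
#' Dispersion-based estimators are expected to be markedly more stable
#' (smaller CV) than SampEn on this benchmark.
#'
#' @param n_realizations number of seeded realizations (default 20).
#' @param n signal length (default 1000).
#' @param p MIX mixing probability (default 0.5).
#' @param seed master seed.
#' @param c_grid class counts for DispEn (m = 2) and FDispEn (m = 3), logsig.
#' @param r_grid SampEn tolerances (multiples of the SD; m = 2).
#' @param mapping mapping for the dispersion estimators.
#' @return data frame: \code{estimator}, \code{param} (c or r), \code{cv},
#'   \code{n_undefined}.
#' @export
mix_cv_comparison <- function(n_realizations = 20L, n = 1000L, p = 0.5,
                              seed = 1L, c_grid = c(2L, 4L, 6L, 8L, 10L),
                              r_grid = seq(0.1, 0.5, by = 0.1),
                              mapping = "logsig") {
  seeds <- .child_seeds(seed, n_realizations)
  sigs <- lapply(seeds, function(s) mix_process(n, p = p, seed = s))
  cv_of <- function(f) {
    vals <- vapply(sigs, function(x) {
      e <- f(x)
      if (isTRUE(e$undefined)) NA_real_ else e$raw
    }, numeric(1))
    c(cv = coefficient_of_variation(vals), n_undefined = sum(is.na(vals)))
  }
  rows <- list()
  for (cc in c_grid) {
    rows[[length(rows) + 1L]] <- data.frame(
      estimator = "dispen", param = cc,
      t(cv_of(function(x) dispen(x, m = 2L, c = cc, mapping = mapping))))
    rows[[length(rows) + 1L]] <- data.frame(
      estimator = "fdispen", param = cc,
      t(cv_of(function(x) fdispen(x, m = 3L, c = cc, mapping = mapping))))
  }
  for (r in r_grid) {
    rows[[length(rows) + 1L]] <- data.frame(
      estimator = "sampen", param = r,
      t(cv_of(function(x) sample_entropy(x, m = 2L, r = r))))
  }
  out <- do.call(rbind, rows)
  names(out) <- c("estimator", "param", "cv", "n_undefined")
  out
}
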