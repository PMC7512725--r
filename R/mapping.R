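#' Signal-to-class mapping for dispersion-pattern analysis
#'
#' Dispersion entropy coarse-grains a real-valued series into an integer
#' alphabet 1..c before any pattern is formed.  Five mappings are supported:
#' \describe{
#'   \item{linear}{affine rescaling of the empirical \code{[min, max]} range;}
#'   \item{sorting}{rank-based assignment into c equal-occupancy classes;}
#'   \item{logsig}{log-sigmoid transfer \code{1/(1 + exp(-(x - mu)/sigma))};}
#'   \item{tansig}{tan-sigmoid transfer \code{2/(1 + exp(-2 (x - mu)/sigma)) - 1};}
#'   \item{ncdf}{standard normal CDF of the standardized sample.}
#' }
#' The sigmoid-family maps compress outliers: extreme samples saturate toward
#' the ends of a fixed theoretical range instead of stretching the class grid.
#' \code{mu} and \code{sigma} are the mean and population standard deviation
#' (divide by N) of the analysed signal itself.
#'
#' @name mapping
NULL

.check_signal <- function(x, min_len = 1L) {
  if (!is.numeric(x)) stop("signal must be numeric", call. = FALSE)
  if (length(x) < min_len)
    stop(sprintf("signal too short: need at least %d samples, got %d",
                 min_len, length(x)), call. = FALSE)
  if (any(!is.finite(x)))
    stop("signal contains non-finite values", call. = FALSE)
  invisible(x)
}

.sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

.check_classes <- function(c) {
  if (length(c) != 1L || !is.finite(c) || c < 2 || c != round(c))
    stop("number of classes `c` must be a single integer >= 2", call. = FALSE)
  as.integer(c)
}

.middle_class <- function(c) as.integer(floor((c + 1) / 2))

#' Mapping specification
#'
#' @param kind one of \code{"linear"}, \code{"sorting"}, \code{"logsig"},
#'   \code{"tansig"}, \code{"ncdf"}.
#' @param c number of classes (integer, at least 2).
#' @param range for the sigmoid-family maps, whether classification uses the
#'   fixed theoretical output range (\code{"theoretical"}, the default: (0,1)
#'   for logsig/ncdf, (-1,1) for tansig) or the empirical range of the mapped
#'   values (\code{"empirical"}).
#' @return an object of class \code{"mapping_spec"}.
#' @export
mapping_spec <- function(kind = c("logsig", "linear", "sorting", "tansig", "ncdf"),
                         c = 6L, range = c("theoretical", "empirical")) {
  kind <- match.arg(kind)
  structure(list(kind = kind, c = .check_classes(c), range = match.arg(range)),
            class = "mapping_spec")
}

#' @rdname mapping
#' @param x numeric signal.
#' @return \code{map_logsig}, \code{map_tansig}, \code{map_ncdf}: per-sample
#'   values in (0,1), (-1,1) and (0,1) respectively.
#' @export
map_logsig <- function(x) {
  .check_signal(x)
  s <- .sd_pop(x)
  if (s == 0) stop("degenerate signal: zero standard deviation", call. = FALSE)
  1 / (1 + exp(-(x - mean(x)) / s))
}

#' @rdname mapping
#' @export
map_tansig <- function(x) {
  .check_signal(x)
  s <- .sd_pop(x)
  if (s == 0) stop("degenerate signal: zero standard deviation", call. = FALSE)
  2 / (1 + exp(-2 * (x - mean(x)) / s)) - 1
}

#' @rdname mapping
#' @export
map_ncdf <- function(x) {
  .check_signal(x)
  s <- .sd_pop(x)
  if (s == 0) stop("degenerate signal: zero standard deviation", call. = FALSE)
  stats::pnorm(x, mean = mean(x), sd = s)
}

#' Assign mapped values to integer classes
#'
#' Linearly rescales \code{y} from the range \code{(alpha, beta)} onto
#' \code{[0.5, c + 0.5]} and rounds to the nearest class, i.e.
#' \code{u = floor(z + 0.5)} with \code{z = 0.5 + c (y - alpha)/(beta - alpha)},
#' clamped into \code{[1, c]} so both range endpoints land in a valid class
#' (round-half-up: z = 0.5 gives class 1, z = c + 0.5 gives class c).
#'
#' @param y numeric vector of mapped values.
#' @param range length-2 numeric \code{c(alpha, beta)}, \code{beta > alpha}.
#' @param c alphabet size.
#' @return integer vector of classes in 1..c.
#' @export
classify <- function(y, range, c) {
  c <- .check_classes(c)
  if (length(range) != 2L || !all(is.finite(range)) || range[2] <= range[1])
    stop("invalid range: need finite (alpha, beta) with beta > alpha",
         call. = FALSE)
  z <- 0.5 + c * (y - range[1]) / (range[2] - range[1])
  as.integer(pmin(pmax(floor(z + 0.5), 1), c))
}

#' Rank-based (sorting) mapping
#'
#' Sorts the samples and splits them into c classes of equal occupancy
#' (sizes differing by at most one).  With \code{r_j} the 1-based rank of
#' \code{x_j} (ties broken by order of emergence), the class is
#' \code{ceiling(r_j * c / n)}.  Invariant under any strictly increasing
#' transform of the signal.
#'
#' @param x numeric signal of length at least \code{c}.
#' @param c alphabet size.
#' @return integer vector of classes in 1..c.
#' @export
map_sorting <- function(x, c) {
  c <- .check_classes(c)
  .check_signal(x)
  if (length(x) < c)
    stop(sprintf("signal too short for sorting mapping: n = %d < c = %d",
                 length(x), c), call. = FALSE)
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * c / length(x)))
}

#' Map a signal to a class series
#'
#' Dispatches on the mapping kind: \code{linear} classifies over the empirical
#' \code{(min, max)}; \code{logsig}/\code{ncdf} over the theoretical (0,1) and
#' \code{tansig} over (-1,1) (or over the empirical range of the mapped values
#' when the spec requests it); \code{sorting} uses equal-occupancy ranks.
#' A constant signal cannot be standardized or ranged; every sample is then
#' assigned the middle class \code{floor((c+1)/2)} with a warning, so the
#' downstream entropy of a flat epoch is 0 rather than an error.
#'
#' @param x numeric signal.
#' @param spec a \code{\link{mapping_spec}}.
#' @return integer class series (attribute \code{"c"} records the alphabet).
#' @export
map_to_classes <- function(x, spec) {
  stopifnot(inherits(spec, "mapping_spec"))
  .check_signal(x)
  cc <- spec$c
  degenerate <- (.sd_pop(x) == 0)
  if (degenerate) {
    warning("constant signal: all samples assigned the middle class",
            call. = FALSE)
    u <- rep(.middle_class(cc), length(x))
  } else {
    u <- switch(spec$kind,
      linear  = classify(x, range(x), cc),
      sorting = map_sorting(x, cc),
      logsig  = {
        y <- map_logsig(x)
        classify(y, if (spec$range == "empirical") range(y) else c(0, 1), cc)
      },
      tansig  = {
        y <- map_tansig(x)
        classify(y, if (spec$range == "empirical") range(y) else c(-1, 1), cc)
      },
      ncdf    = {
        y <- map_ncdf(x)
        classify(y, if (spec$range == "empirical") range(y) else c(0, 1), cc)
      })
  }
  structure(as.integer(u), c = cc)
}
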