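#' Seeded synthetic-signal generators
#'
#' Benchmark inputs for entropy estimators: colored noise with prescribed
#' spectral slope, the logistic map across its periodic-to-chaotic range, the
#' MIX stochastic/periodic mixture, additive white Gaussian noise at a target
#' SNR, and a noisy sinusoid.  Every generator is a pure function of its
#' arguments and seed: the same seed reproduces the same signal bit for bit.
#'
#' @name signal_generators
NULL

.seed_if <- function(seed) if (!is.null(seed)) set.seed(seed)

#' @rdname signal_generators
#' @param n signal length.
#' @param color \code{"white"} (flat spectrum), \code{"pink"} (power ~ 1/f) or
#'   \code{"brown"} (power ~ 1/f^2).
#' @param seed RNG seed (integer) or NULL to use the current RNG state.
#' @return numeric vector of length \code{n}; pink and brown output is
#'   standardized to mean 0, SD 1.
#' @details Pink and brown noise are synthesized by Fourier-amplitude shaping
#'   of white Gaussian noise (multiplying the spectrum by f^(-1/2) or f^(-1)),
#'   which hits the target spectral slope exactly in expectation.
#' @export
colored_noise <- function(n, color = c("white", "pink", "brown"), seed = NULL) {
  color <- match.arg(color)
  if (n < 2) stop("need n >= 2", call. = FALSE)
  .seed_if(seed)
  w <- stats::rnorm(n)
  if (color == "white") return(w)
  gamma <- if (color == "pink") 1 else 2
  # frequency index of each FFT bin (0, 1, ..., folded); DC removed
  k <- c(0, pmin(1:(n - 1), n - 1:(n - 1)))
  H <- c(0, k[-1]^(-gamma / 2))
  x <- Re(stats::fft(stats::fft(w) * H, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

#' @rdname signal_generators
#' @param alpha logistic-map parameter (the periodic-to-chaotic range of
#'   interest is 3.5 to 4); may be a vector of length \code{n} giving a
#'   per-sample schedule.
#' @param x0 initial state in (0, 1), excluding the degenerate points
#'   0.25, 0.5 and 0.75 that collapse onto fixed points at alpha = 4.
#' @param burn_in iterations discarded before recording (default 0).
#' @return numeric vector: the orbit of x[t+1] = alpha x[t] (1 - x[t]).
#' @export
logistic_map <- function(n, alpha = 4, x0 = 0.23, burn_in = 0L) {
  if (n < 1) stop("need n >= 1", call. = FALSE)
  if (x0 <= 0 || x0 >= 1 || x0 %in% c(0.25, 0.5, 0.75))
    stop("x0 must lie in (0,1) away from {0.25, 0.5, 0.75}", call. = FALSE)
  if (length(alpha) == 1L) alpha <- rep(alpha, n)
  if (length(alpha) != n)
    stop("alpha must have length 1 or n", call. = FALSE)
  if (any(alpha <= 0 | alpha > 4))
    stop("invalid parameters: alpha must lie in (0, 4]", call. = FALSE)
  s <- x0
  for (t in seq_len(burn_in)) s <- alpha[1] * s * (1 - s)
  x <- numeric(n)
  x[1] <- alpha[1] * s * (1 - s)
  for (t in 2:n) x[t] <- alpha[t] * x[t - 1] * (1 - x[t - 1])
  if (any(x < 0 | x > 1)) stop("trajectory left [0,1]", call. = FALSE)
  x
}

#' @rdname signal_generators
#' @param alpha_from,alpha_to end points of a linear parameter sweep.
#' @export
logistic_sweep <- function(n, alpha_from = 3.5, alpha_to = 3.99, x0 = 0.23) {
  logistic_map(n, alpha = seq(alpha_from, alpha_to, length.out = n), x0 = x0)
}

#' @rdname signal_generators
#' @param p probability that a sample of the period-12 sinusoid is replaced by
#'   uniform noise; scalar, or a vector of length \code{n} for a schedule
#'   (e.g. \code{seq(0.99, 0.01, length.out = n)} sweeps from randomness to
#'   orderliness).
#' @param constants \code{"unit"} (default): sinusoid amplitude sqrt(2) and
#'   noise uniform on (-sqrt(3), sqrt(3)), both unit variance;
#'   \code{"literal"}: amplitude 2 and noise on (-3, 3).
#' @return MIX process \code{(1 - z) x + z y} with z ~ Bernoulli(p),
#'   x the sinusoid and y the uniform noise.
#' @export
mix_process <- function(n, p = 0.5, seed = NULL,
                        constants = c("unit", "literal")) {
  constants <- match.arg(constants)
  if (any(p < 0 | p > 1)) stop("p must lie in [0,1]", call. = FALSE)
  if (length(p) == 1L) p <- rep(p, n)
  if (length(p) != n) stop("p must have length 1 or n", call. = FALSE)
  .seed_if(seed)
  k <- seq_len(n)
  amp <- if (constants == "unit") sqrt(2) else 2
  bnd <- if (constants == "unit") sqrt(3) else 3
  xs <- amp * sin(2 * pi * k / 12)
  ys <- stats::runif(n, -bnd, bnd)
  z <- stats::rbinom(n, 1L, p)
  (1 - z) * xs + z * ys
}

#' @rdname signal_generators
#' @param x signal to contaminate (non-zero variance).
#' @param snr_db target signal-to-noise ratio in dB, defined as
#'   \code{10 log10(var(x) / var(noise))}; the generated Gaussian noise is
#'   rescaled so the realized variance ratio is exact.
#' @export
add_noise_at_snr <- function(x, snr_db, seed = NULL) {
  .check_signal(x, min_len = 2L)
  vx <- mean((x - mean(x))^2)
  if (vx == 0) stop("zero-variance signal: SNR undefined", call. = FALSE)
  .seed_if(seed)
  e <- stats::rnorm(length(x))
  e <- e - mean(e)
  e <- e * sqrt(vx / 10^(snr_db / 10)) / .sd_pop(e)
  x + e
}

#' @rdname signal_generators
#' @return \code{noisy_sinusoid}: \code{sin(i/20) + 0.3 U(0,1)} for
#'   i = 1..n (default n = 400), a slow sinusoid with small positive uniform
#'   noise that flips local order relations without moving amplitudes much.
#' @export
noisy_sinusoid <- function(n = 400L, seed = NULL) {
  if (n < 1) stop("need n >= 1", call. = FALSE)
  .seed_if(seed)
  i <- seq_len(n)
  sin(i / 20) + 0.3 * stats::runif(n)
}
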