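#' Methods for entropy estimates
#'
#' Every estimator in the package returns an \code{"entropy_estimate"}: the
#' raw value in nats (or the LZ76 production count for LZC), the normalized
#' value in [0, 1], the parameter record, and - for the pattern-based
#' estimators - the empirical pattern distribution and the observed/forbidden
#' census.
#'
#' @param x,object an \code{"entropy_estimate"}.
#' @param ... unused.
#' @name entropy_estimate
NULL

.method_label <- function(id) {
  switch(id,
         dispen = "dispersion entropy (DispEn)",
         fdispen = "fluctuation-based dispersion entropy (FDispEn)",
         peren = "permutation entropy (PerEn)",
         sampen = "sample entropy (SampEn)",
         lzc = "Lempel-Ziv complexity (LZ76)",
         id)
}

#' @rdname entropy_estimate
#' @export
print.entropy_estimate <- function(x, ...) {
  cat(.method_label(x$method), "\n")
  pstr <- paste(names(x$params),
                vapply(x$params, function(p) format(p), character(1)),
                sep = " = ", collapse = ", ")
  cat("  parameters:", pstr, "\n")
  if (isTRUE(x$undefined)) {
    cat("  value: undefined (", x$reason, ")\n", sep = "")
  } else if (x$method == "lzc") {
    cat(sprintf("  production count c(n): %d\n  normalized: %.6g\n",
                x$raw, x$normalized))
  } else {
    cat(sprintf("  raw: %.6g nats\n  normalized: %.6g\n",
                x$raw, x$normalized))
  }
  invisible(x)
}

#' @rdname entropy_estimate
#' @export
summary.entropy_estimate <- function(object, ...) {
  print(object)
  if (!is.null(object$distribution)) {
    cat(sprintf("  embedded vectors: %d\n", object$n_embedded))
    cat(sprintf("  pattern space: %g; observed: %d; forbidden: %g (%.3f)\n",
                object$space, object$observed, object$forbidden,
                object$forbidden / object$space))
    top <- utils::head(
      object$distribution[order(-object$distribution$count), ], 5L)
    cat("  most frequent patterns:\n")
    for (i in seq_len(nrow(top)))
      cat(sprintf("    (%s)  count %d  p = %.4f\n",
                  top$pattern[i], top$count[i], top$prob[i]))
  }
  invisible(object)
}

#' @rdname entropy_estimate
#' @export
plot.entropy_estimate <- function(x, ...) {
  if (is.null(x$distribution))
    stop("no pattern distribution to plot for this estimator", call. = FALSE)
  d <- x$distribution[order(-x$distribution$prob), ]
  graphics::barplot(d$prob, names.arg = d$pattern, las = 2,
                    ylab = "relative frequency",
                    main = .method_label(x$method), ...)
  invisible(x)
}

#' @rdname entropy_estimate
#' @export
as.numeric.entropy_estimate <- function(x, ...) {
  if (isTRUE(x$undefined)) NA_real_ else x$raw
}
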