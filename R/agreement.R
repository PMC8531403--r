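#' Bland-Altman agreement between predicted and actual scores
#'
#' Differences are taken as `predicted - actual` (fixed convention). The
#' bias is their mean, the SD uses the n-1 denominator, and the 95%
#' limits of agreement are `bias +/- 1.96 * sd` (classical
#' normal-quantile form, no small-sample t correction). Also reports the
#' fraction of points falling within the limits (inclusive).
#'
#' @param predicted,actual equal-length numeric vectors (>= 3 points).
#' @return object of class `bland_altman`: `bias`, `sd`, `loa_low`,
#'   `loa_high`, `within_loa` (fraction), `differences`, `means`.
#' @export
bland_altman <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("bland_altman: length mismatch")
  if (length(predicted) < 3) stop("bland_altman: need >= 3 points")
  d <- predicted - actual
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- bias + c(-1.96, 1.96) * s
  structure(list(bias = bias, sd = s, loa_low = loa[1], loa_high = loa[2],
                 within_loa = mean(d >= loa[1] & d <= loa[2]),
                 differences = d, means = (predicted + actual) / 2),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: bias %.4f, SD %.4f, LOA [%.4f, %.4f], %.0f%% within\n",
    x$bias, x$sd, x$loa_low, x$loa_high, 100 * x$within_loa))
  invisible(x)
}

#' Bland-Altman scatter of differences against means
#'
#' Base-graphics plot with the bias and limits of agreement as horizontal
#' lines.
#'
#' @param x a `bland_altman` object.
#' @param ... passed to `plot()`.
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences,
                 xlab = "mean of predicted and actual",
                 ylab = "predicted - actual", ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2), col = c("black", "grey40", "grey40"))
  invisible(x)
}
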