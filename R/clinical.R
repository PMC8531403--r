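#' JOA recovery score
#'
#' Postoperative minus preoperative Japanese Orthopedic Association score.
#' May be negative (deterioration). Both scores must lie on the 0-17 scale.
#'
#' @param pre,post JOA scores in \[0, 17\].
#' @return `post - pre`, in points.
#' @examples
#' joa_recovery(11.8, 15.7)  # 3.9
#' @export
joa_recovery <- function(pre, post) {
  check_joa(pre, "pre")
  check_joa(post, "post")
  post - pre
}

#' JOA recovery rate
#'
#' `(post - pre) / (17 - pre)`: the fraction of the maximum possible
#' improvement that was achieved. Undefined when `pre = 17` (no room to
#' improve); negative when the score deteriorated.
#'
#' @param pre,post JOA scores in \[0, 17\], `pre < 17`.
#' @return dimensionless ratio.
#' @examples
#' joa_recovery_rate(11, 14)  # 0.5
#' @export
joa_recovery_rate <- function(pre, post) {
  check_joa(pre, "pre")
  check_joa(post, "post")
  if (any(pre == 17))
    stop("joa_recovery_rate: undefined for pre = 17 (zero denominator)")
  (post - pre) / (17 - pre)
}

check_joa <- function(x, what) {
  if (anyNA(x) || any(x < 0 | x > 17))
    stop(sprintf("JOA %s score outside [0, 17]", what))
  invisible(x)
}
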