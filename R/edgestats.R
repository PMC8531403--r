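#' Edge-wise covariate-adjusted group comparison
#'
#' For every edge, fits the linear model
#' `edge ~ intercept + group + covariates` and reports the t-statistic and
#' two-sided p-value for the group coefficient. With no covariates this is
#' exactly the pooled-variance two-sample t-test. Vectorized over edges
#' (one QR decomposition of the shared design matrix).
#'
#' @param features subjects x edges numeric matrix of Fisher-z values.
#' @param group factor (or coercible) with exactly two levels; the
#'   reported direction is second level minus first level.
#' @param covariates optional subjects x C data.frame/matrix. Factors and
#'   character columns are expanded to indicator columns; constant columns
#'   (e.g. site within a single-site analysis) are dropped silently. A
#'   covariate collinear with the group indicator is an error.
#' @param q FDR level for the Benjamini-Hochberg pass flags.
#' @return data.frame with columns `edge`, `row`, `col` (when the edge
#'   count matches a parcellation), `t`, `p`, `direction`, `fdr_pass`.
#' @export
edgewise_group_test <- function(features, group, covariates = NULL,
                                q = 0.05) {
  features <- as.matrix(features)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2)
    stop("edgewise_group_test: group must have exactly two levels")
  if (min(table(group)) < 3)
    stop("edgewise_group_test: need at least 3 subjects per group")
  n <- nrow(features)
  if (length(group) != n)
    stop("edgewise_group_test: group length must match subjects")

  g <- as.numeric(group == levels(group)[2])
  xmat <- cbind(`(Intercept)` = 1, group = g)
  if (!is.null(covariates)) {
    cv <- expand_covariates(covariates, n)
    keep <- apply(cv, 2, function(col) stats::var(col) > 0)
    cv <- cv[, keep, drop = FALSE]
    if (ncol(cv) > 0) xmat <- cbind(xmat, cv)
  }
  qx <- qr(xmat)
  if (qx$rank < ncol(xmat)) {
    dropped <- colnames(xmat)[qx$pivot[(qx$rank + 1):ncol(xmat)]]
    stop("edgewise_group_test: design matrix rank-deficient; collinear ",
         "column(s): ", paste(dropped, collapse = ", "))
  }

  coefs <- qr.coef(qx, features)
  resid <- features - xmat %*% coefs
  df <- n - ncol(xmat)
  if (df < 1) stop("edgewise_group_test: no residual degrees of freedom")
  s2 <- colSums(resid^2) / df
  xtxi <- chol2inv(qr.R(qx))
  se <- sqrt(s2 * xtxi[2, 2])
  tval <- coefs["group", ] / se
  pval <- 2 * stats::pt(-abs(tval), df)

  lv <- levels(group)
  out <- data.frame(edge = seq_len(ncol(features)),
                    t = as.numeric(tval), p = as.numeric(pval),
                    direction = ifelse(tval >= 0,
                                       paste(lv[2], ">", lv[1]),
                                       paste(lv[1], ">", lv[2])),
                    stringsAsFactors = FALSE)
  r_guess <- (1 + sqrt(1 + 8 * ncol(features))) / 2
  if (r_guess == round(r_guess)) {
    ei <- edge_index(as.integer(r_guess))
    out$row <- ei$row
    out$col <- ei$col
    out <- out[, c("edge", "row", "col", "t", "p", "direction")]
  }
  out$fdr_pass <- fdr_correct(out$p, q = q)
  attr(out, "df") <- df
  out
}

expand_covariates <- function(covariates, n) {
  cv <- as.data.frame(covariates, stringsAsFactors = FALSE)
  if (nrow(cv) != n) stop("covariates must have one row per subject")
  cols <- lapply(names(cv), function(nm) {
    col <- cv[[nm]]
    if (is.numeric(col)) {
      out <- matrix(col, ncol = 1, dimnames = list(NULL, nm))
    } else {
      f <- droplevels(as.factor(col))
      out <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(out) <- paste0(nm, levels(f)[-1])
    }
    out
  })
  do.call(cbind, cols)
}

#' Benjamini-Hochberg FDR pass flags
#'
#' Step-up procedure: sort p-values ascending, find the largest k with
#' `p(k) <= k q / m`, flag everything at or below `p(k)`. Implemented via
#' `stats::p.adjust(method = "BH")`, which is algebraically the same rule.
#'
#' @param pvals vector of p-values in (0, 1\].
#' @param q FDR level in (0, 1).
#' @return logical vector of pass flags.
#' @export
fdr_correct <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) stop("fdr_correct: empty p-value vector")
  if (anyNA(pvals) || any(pvals <= 0 | pvals > 1))
    stop("fdr_correct: p-values must lie in (0, 1]")
  if (q <= 0 || q >= 1) stop("fdr_correct: q must lie in (0, 1)")
  stats::p.adjust(pvals, method = "BH") <= q
}
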