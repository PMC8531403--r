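#' Univariate correlation feature filter
#'
#' Each feature is Pearson-correlated with the training labels; the
#' two-sided p-value comes from the `t = r sqrt((n-2)/(1-r^2))` transform
#' with n-2 degrees of freedom. Features with `p < alpha` (strict) are
#' kept. The returned set may be empty. Zero-variance features are never
#' selected.
#'
#' @param features training subjects x features matrix.
#' @param labels numeric training labels (non-constant).
#' @param alpha selection level, default 0.05.
#' @return sorted integer vector of selected feature indices (possibly
#'   empty).
#' @export
correlation_feature_filter <- function(features, labels, alpha = 0.05) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 4) stop("correlation_feature_filter: need at least 4 subjects")
  if (alpha <= 0 || alpha >= 1)
    stop("correlation_feature_filter: alpha in (0, 1)")
  if (stats::sd(labels) == 0)
    stop("correlation_feature_filter: zero-variance labels")
  r <- suppressWarnings(as.numeric(stats::cor(features, labels)))
  p <- pearson_p(r, n)
  which(!is.na(p) & p < alpha)
}

# two-sided p of a Pearson correlation via the t transform, |r| = 1 -> 0
pearson_p <- function(r, n) {
  df <- n - 2
  p <- rep(NA_real_, length(r))
  one <- !is.na(r) & abs(r) >= 1
  p[one] <- 0
  ok <- !is.na(r) & abs(r) < 1
  tt <- r[ok] * sqrt(df / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(tt), df)
  p
}

#' Correlation and RMSE between predicted and actual scores
#'
#' @param predicted,actual equal-length numeric vectors (>= 3 points);
#'   `actual` must be non-constant for the correlation.
#' @return list with `r` (Pearson) and `rmse`
#'   (`sqrt(mean((predicted - actual)^2))`, native score units). When the
#'   predictions are constant the correlation is undefined and reported
#'   as 0 (so permutation counting remains well defined).
#' @export
evaluate_prediction <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("evaluate_prediction: length mismatch")
  if (length(actual) < 3) stop("evaluate_prediction: need >= 3 points")
  if (stats::sd(actual) == 0)
    stop("evaluate_prediction: constant actual scores")
  r <- if (stats::sd(predicted) == 0) 0
       else stats::cor(predicted, actual)
  list(r = r, rmse = sqrt(mean((predicted - actual)^2)))
}

# rescale training labels to [0, 1]; returns the forward map
minmax_scaler <- function(y_train) {
  rng <- range(y_train)
  if (diff(rng) == 0) stop("minmax scaling: constant training labels")
  function(y) (y - rng[1]) / (rng[2] - rng[1])
}

# filter + epsilon-SVR fit on a training set; returns a predict closure
fit_filtered_svr <- function(x_train, y_train, alpha,
                             sel = NULL, scale = FALSE) {
  if (is.null(sel)) sel <- correlation_feature_filter(x_train, y_train, alpha)
  if (length(sel) == 0) {
    mu <- mean(y_train)
    pred_fun <- function(newx) rep(mu, nrow(newx))
  } else {
    m <- e1071::svm(x_train[, sel, drop = FALSE], y_train,
                    type = "eps-regression", kernel = "linear",
                    cost = 1, epsilon = 0.1, scale = scale)
    pred_fun <- function(newx)
      as.numeric(stats::predict(m, newx[, sel, drop = FALSE]))
  }
  list(predict = pred_fun, selected = sel)
}

#' Leave-one-out cross-validated epsilon-SVR with per-fold correlation
#' filtering
#'
#' For each fold, features are filtered on the training subjects only
#' (Pearson p < `alpha`), a linear epsilon-SVR (C = 1, epsilon = 0.1,
#' library defaults) is trained on the selected features, and the
#' held-out subject is predicted. Folds whose filter returns an empty set
#' fall back to predicting the training-label mean (routine under
#' permuted labels). The final r and RMSE are computed on the assembled
#' predicted vector.
#'
#' `label_scaling = "minmax"` rescales the labels to \[0, 1\] using each
#' training fold's range (the held-out actual is mapped with the same
#' fold's scaler), and r/RMSE are then on that scale.
#' `filter_scope = "all"` is a deliberately broken negative control that
#' filters once on the complete data set (including each test subject)
#' before cross-validation; it leaks label information and exists only to
#' demonstrate that leakage.
#'
#' @param features subjects x edges matrix.
#' @param labels numeric scores (non-constant).
#' @param alpha per-fold filter level.
#' @param label_scaling `"native"` or `"minmax"`.
#' @param filter_scope `"fold"` (correct) or `"all"` (leaky control).
#' @param scale SVM-internal standardization flag (default off).
#' @return object of class `regression_run`: `predicted`, `actual`
#'   (evaluation scale), `r`, `rmse`, per-fold `selected` sets,
#'   `label_scaling`.
#' @export
loocv_regress <- function(features, labels, alpha = 0.05,
                          label_scaling = c("native", "minmax"),
                          filter_scope = c("fold", "all"), scale = FALSE) {
  label_scaling <- match.arg(label_scaling)
  filter_scope <- match.arg(filter_scope)
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  n <- nrow(features)
  if (n < 5) stop("loocv_regress: need at least 5 subjects")
  if (length(labels) != n) stop("loocv_regress: label length mismatch")
  if (anyNA(labels)) stop("loocv_regress: missing labels")
  if (stats::sd(labels) == 0) stop("loocv_regress: constant labels")

  sel_all <- if (filter_scope == "all")
    correlation_feature_filter(features, labels, alpha) else NULL

  predicted <- actual <- numeric(n)
  selected <- vector("list", n)
  for (i in seq_len(n)) {
    xt <- features[-i, , drop = FALSE]
    yt <- labels[-i]
    if (label_scaling == "minmax") {
      sc <- minmax_scaler(yt)
      yt <- sc(yt)
      actual[i] <- sc(labels[i])
    } else {
      actual[i] <- labels[i]
    }
    fit <- fit_filtered_svr(xt, yt, alpha, sel = sel_all, scale = scale)
    selected[[i]] <- fit$selected
    predicted[i] <- fit$predict(features[i, , drop = FALSE])
  }
  ev <- evaluate_prediction(predicted, actual)
  structure(list(predicted = predicted, actual = actual, r = ev$r,
                 rmse = ev$rmse, selected = selected,
                 label_scaling = label_scaling,
                 filter_scope = filter_scope, n = n),
            class = "regression_run")
}

#' @export
print.regression_run <- function(x, ...) {
  cat(sprintf(
    "LOOCV epsilon-SVR (%d folds, %s labels): r = %.3f, RMSE = %.3f\n",
    x$n, x$label_scaling, x$r, x$rmse))
  invisible(x)
}

#' Permutation test for SVR correlation and RMSE
#'
#' Each permutation shuffles the labels once and reruns the complete
#' filtered pipeline (LOOCV, or the cross-site fit when a test set is
#' given). `p_r` is the proportion of null correlations greater than or
#' equal to the observed one; `p_rmse` the proportion of null RMSEs less
#' than or equal to the observed one (a good model has a *small* RMSE).
#' Zero counts are reported as "< 1/n_perm" with floor flags.
#'
#' @inheritParams loocv_regress
#' @param n_perm number of permutations.
#' @param x_test,y_test optional test-site data; when given, the observed
#'   and null statistics come from training on (`features`, `labels`) and
#'   predicting the test site, with training labels shuffled.
#' @return list with `r` and `rmse` components, each a `perm_null`, plus
#'   the observed `regression_run`.
#' @export
permutation_test_regression <- function(features, labels, alpha = 0.05,
                                        n_perm = 1000,
                                        label_scaling = c("native", "minmax"),
                                        x_test = NULL, y_test = NULL,
                                        scale = FALSE) {
  stopifnot(n_perm >= 1)
  label_scaling <- match.arg(label_scaling)
  run <- function(y) {
    if (is.null(x_test)) {
      fit <- loocv_regress(features, y, alpha = alpha,
                           label_scaling = label_scaling, scale = scale)
    } else {
      fit <- site_regress(features, y, x_test, y_test, alpha = alpha,
                          label_scaling = label_scaling, scale = scale)
    }
    c(r = fit$r, rmse = fit$rmse)
  }
  obs_run <- if (is.null(x_test)) {
    loocv_regress(features, labels, alpha = alpha,
                  label_scaling = label_scaling, scale = scale)
  } else {
    site_regress(features, labels, x_test, y_test, alpha = alpha,
                 label_scaling = label_scaling, scale = scale)
  }
  null <- t(vapply(seq_len(n_perm), function(b) run(sample(labels)),
                   numeric(2)))
  list(r = perm_null(c(r = obs_run$r), null[, "r", drop = FALSE],
                     n_perm, tail = "ge"),
       rmse = perm_null(c(rmse = obs_run$rmse),
                        null[, "rmse", drop = FALSE], n_perm, tail = "le"),
       observed = obs_run)
}

# train on one full site, predict another
site_regress <- function(x_train, y_train, x_test, y_test, alpha = 0.05,
                         label_scaling = c("native", "minmax"),
                         scale = FALSE) {
  label_scaling <- match.arg(label_scaling)
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  if (ncol(x_train) != ncol(x_test))
    stop("cross-site regression: feature dimensionality differs")
  y_train <- as.numeric(y_train); y_test <- as.numeric(y_test)
  if (stats::sd(y_train) == 0) stop("cross-site regression: constant labels")
  actual <- y_test
  if (label_scaling == "minmax") {
    sc <- minmax_scaler(y_train)
    y_train <- sc(y_train)
    actual <- sc(y_test)
  }
  fit <- fit_filtered_svr(x_train, y_train, alpha, scale = scale)
  predicted <- fit$predict(x_test)
  ev <- evaluate_prediction(predicted, actual)
  structure(list(predicted = predicted, actual = actual, r = ev$r,
                 rmse = ev$rmse, selected = list(fit$selected),
                 label_scaling = label_scaling, filter_scope = "fold",
                 n = length(y_test)),
            class = "regression_run")
}

#' Cross-site SVR: train on one site, test on the other, both directions
#'
#' Features are filtered and the model fitted on the full training site;
#' every test-site subject is predicted and r/RMSE evaluated on the test
#' site.
#'
#' @param x1,y1 features and scores of site 1 (patients with the target
#'   score).
#' @param x2,y2 features and scores of site 2.
#' @inheritParams loocv_regress
#' @return list with one `regression_run` per direction
#'   (`"1->2"`, `"2->1"`).
#' @export
cross_site_regress <- function(x1, y1, x2, y2, alpha = 0.05,
                               label_scaling = c("native", "minmax"),
                               scale = FALSE) {
  label_scaling <- match.arg(label_scaling)
  list(`1->2` = site_regress(x1, y1, x2, y2, alpha = alpha,
                             label_scaling = label_scaling, scale = scale),
       `2->1` = site_regress(x2, y2, x1, y1, alpha = alpha,
                             label_scaling = label_scaling, scale = scale))
}
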