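#' Fisher z-transformation of correlation coefficients
#'
#' `atanh(r)` after clipping `|r|` to `1 - 1e-7`, so that degenerate
#' correlations of exactly +/-1 (which occur on synthetic edge cases) map to
#' large finite values rather than Inf. Odd and strictly increasing.
#'
#' @param r numeric vector of correlations in \[-1, 1\].
#' @return numeric vector of z-values.
#' @examples
#' fisher_z(0.5)  # 0.5493061
#' @export
fisher_z <- function(r) {
  if (anyNA(r)) stop("fisher_z: NA correlations")
  if (any(abs(r) > 1)) stop("fisher_z: correlations outside [-1, 1]")
  lim <- 1 - 1e-7
  atanh(pmin(pmax(r, -lim), lim))
}

#' Clean ROI time series: detrend, regress confounds, bandpass filter
#'
#' Mirrors standard resting-state BOLD cleaning: each column (ROI) is
#' linearly detrended, nuisance covariates are regressed out by ordinary
#' least squares, and a zero-phase 4th-order Butterworth bandpass
#' (forward-backward, `signal::filtfilt`) is applied, in that order.
#'
#' @param x T x R numeric matrix (rows = time points, columns = ROIs).
#' @param tr repetition time in seconds; defines Nyquist = 1/(2 tr).
#' @param confounds optional T x C matrix of nuisance regressors (e.g.
#'   motion parameters, global/WM/CSF signals). An intercept is always
#'   included. Rank-deficient confounds trigger a warning and a
#'   pseudo-inverse projection.
#' @param band `c(low, high)` passband in Hz, or `NULL` to skip filtering.
#'   `high` must not exceed the Nyquist frequency. A band with `low = 0`
#'   and `high` at 99% of Nyquist or above is treated as all-pass (no
#'   filtering), so the full band reduces to detrending alone.
#' @return matrix of the same shape as `x`.
#' @export
clean_series <- function(x, tr, confounds = NULL, band = c(0.01, 0.08)) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("clean_series: missing values in series")
  n_t <- nrow(x)
  if (n_t < 3) stop("clean_series: need at least 3 time points")
  nyq <- 1 / (2 * tr)
  if (!is.null(band)) {
    if (length(band) != 2 || band[1] < 0 || band[2] <= band[1])
      stop("clean_series: band must be c(low, high) with 0 <= low < high")
    if (band[2] > nyq)
      stop(sprintf(
        "clean_series: high cutoff %.4g Hz exceeds Nyquist %.4g Hz (tr = %g s)",
        band[2], nyq, tr))
  }

  # 1. linear detrend (intercept + time index)
  xd <- qr.resid(qr(cbind(1, seq_len(n_t))), x)

  # 2. confound regression (confounds detrended the same way, so a
  #    confound equal to the signal removes it entirely)
  if (!is.null(confounds)) {
    cf <- as.matrix(confounds)
    if (nrow(cf) != n_t)
      stop("clean_series: confounds must have one row per time point")
    cf <- qr.resid(qr(cbind(1, seq_len(n_t))), cf)
    xm <- cbind(1, cf)
    qx <- qr(xm)
    if (qx$rank < ncol(xm)) {
      warning("clean_series: rank-deficient confounds; using pseudo-inverse")
      xd <- xd - xm %*% (MASS::ginv(xm) %*% xd)
    } else {
      xd <- qr.resid(qx, xd)
    }
  }

  # 3. zero-phase Butterworth bandpass
  if (!is.null(band) && !(band[1] <= 0 && band[2] >= 0.99 * nyq)) {
    w <- band / nyq
    filt <- if (band[1] <= 0) {
      signal::butter(4, w[2], type = "low")
    } else if (band[2] >= 0.99 * nyq) {
      signal::butter(4, w[1], type = "high")
    } else {
      signal::butter(4, w, type = "pass")
    }
    xd <- apply(xd, 2, function(col) signal::filtfilt(filt, col))
  }
  dimnames(xd) <- dimnames(x)
  xd
}

#' Pearson functional-connectivity matrix from ROI time series
#'
#' @param x T x R matrix; every column must have nonzero variance.
#' @return R x R symmetric correlation matrix with unit diagonal.
#' @export
compute_fc <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("compute_fc: missing values in series")
  if (nrow(x) < 3) stop("compute_fc: need at least 3 time points")
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    lab <- if (!is.null(colnames(x))) colnames(x)[bad[1]] else bad[1]
    stop("compute_fc: zero-variance time series for ROI ", lab)
  }
  fc <- stats::cor(x)
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  fc
}

#' Vectorize an FC matrix into the canonical Fisher-z edge vector
#'
#' Extracts the strict lower triangle in the canonical column-major edge
#' order (see [edge_index()]), discards diagonal and upper triangle, and
#' applies the Fisher z-transformation. For a 116-ROI parcellation this is
#' the 6,670-edge feature vector.
#'
#' @param fc square symmetric correlation matrix.
#' @param tol maximum tolerated asymmetry.
#' @return named numeric vector of length R(R-1)/2 with attribute `n_rois`.
#' @export
vectorize_fc <- function(fc, tol = 1e-10) {
  fc <- as.matrix(fc)
  if (nrow(fc) != ncol(fc)) stop("vectorize_fc: matrix not square")
  if (max(abs(fc - t(fc))) > tol) stop("vectorize_fc: matrix not symmetric")
  z <- fisher_z(fc[lower.tri(fc)])
  names(z) <- edge_names(length(z))
  attr(z, "n_rois") <- nrow(fc)
  z
}

#' Rebuild a correlation matrix from a canonical Fisher-z edge vector
#'
#' Inverse of [vectorize_fc()] (up to the +/-1 clipping).
#'
#' @param z edge vector in canonical order.
#' @param n_rois number of ROIs; defaults to the vector's `n_rois` attribute.
#' @return R x R correlation matrix with unit diagonal.
#' @export
devectorize_fc <- function(z, n_rois = attr(z, "n_rois")) {
  if (is.null(n_rois)) stop("devectorize_fc: n_rois not given")
  if (length(z) != n_edges(n_rois))
    stop("devectorize_fc: length does not match n_rois")
  m <- matrix(0, n_rois, n_rois)
  m[lower.tri(m)] <- tanh(as.numeric(z))
  m <- m + t(m)
  diag(m) <- 1
  m
}

#' Cohort feature table: subjects x edges Fisher-z matrix
#'
#' Applies [compute_fc()] and [vectorize_fc()] to every subject's series;
#' optionally cleans each series first.
#'
#' @param series named list of T x R matrices (one per subject).
#' @param clean if TRUE, [clean_series()] is applied first.
#' @param tr,confounds,band passed to [clean_series()] when `clean = TRUE`;
#'   `tr` may be a single value or one per subject.
#' @return subjects x edges numeric matrix, rownames = subject ids.
#' @export
fc_feature_table <- function(series, clean = FALSE, tr = NULL,
                             confounds = NULL, band = c(0.01, 0.08)) {
  stopifnot(length(series) >= 1)
  if (clean && is.null(tr)) stop("fc_feature_table: tr required for cleaning")
  if (!is.null(tr) && length(tr) == 1) tr <- rep(tr, length(series))
  rows <- lapply(seq_along(series), function(i) {
    x <- series[[i]]
    if (clean) x <- clean_series(x, tr[i], confounds = confounds, band = band)
    vectorize_fc(compute_fc(x))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(series)
  out
}
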