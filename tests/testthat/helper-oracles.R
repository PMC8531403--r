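# Independent brute-force oracles used to check the package's
# implementations. Deliberately naive: direct formulas and enumeration,
# no shared code with R/.

# Pearson correlation from the covariance/sigma-sigma definition
oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# two-sided p of a correlation via t = r sqrt((n-2)/(1-r^2))
oracle_pearson_p <- function(r, n) {
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tt), n - 2)
}

# pooled-variance two-sample t statistic (textbook formula)
oracle_pooled_t <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(b) - mean(a)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# Benjamini-Hochberg step-up by literal enumeration
oracle_bh_flags <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) * q / m)
  if (length(k) == 0) return(rep(FALSE, m))
  p <- p
  p <= ps[max(k)]
}

# AUC by exhaustive positive-negative pair counting, ties count 1/2
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]
  sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# small two-class Gaussian data set with a given mean separation
make_gaussian_classes <- function(n_per, p, delta) {
  x <- rbind(matrix(rnorm(n_per * p), n_per),
             matrix(rnorm(n_per * p), n_per) + delta)
  y <- factor(rep(c("control", "patient"), each = n_per),
              levels = c("control", "patient"))
  list(x = x, y = y)
}
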