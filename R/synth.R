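#' Configuration for the two-site synthetic cohort generator
#'
#' Defines the statistical structure the downstream analyses assume: a
#' shared base correlation matrix over `n_rois` regions, a sparse set of
#' group-discriminative edges shifted by `disc_effect` on the Fisher-z
#' scale in patients, a sparse set of edges linearly linked to a JOA-like
#' preoperative score, and two acquisition sites differing in series
#' length, TR and measurement-noise level.
#'
#' Site defaults mirror a two-scanner asymmetry: site 1 acquires 180
#' volumes at TR 2.0 s with the first 10 discarded (170 usable), site 2
#' acquires 450 volumes at TR 0.8 s (440 usable). Default group sizes are
#' 27/11 (site 1 patients/controls) and 26/36 (site 2).
#'
#' @param n_rois number of regions (default 116, AAL-sized).
#' @param n_patient,n_control per-site subject counts, length 2.
#' @param t_volumes usable volumes per site, length 2.
#' @param tr repetition time in seconds per site, length 2.
#' @param n_disc_edges number of group-discriminative edges (0 = pure null).
#' @param disc_effect Fisher-z shift added at discriminative edges in
#'   patients.
#' @param n_score_edges number of edges linearly linked to the
#'   preoperative JOA score (0 = score is pure noise).
#' @param score_noise_sd residual SD of the JOA score, in points.
#' @param score_signal_sd SD of the score's FC-driven component, in points.
#' @param subject_z_sd SD of the per-subject Fisher-z jitter around the
#'   group matrix; this is what gives subjects distinct true connectomes
#'   (and makes score-linked edges informative).
#' @param base_corr_mean average off-diagonal level of the base
#'   correlation matrix (~0.2 mimics dense weak FC).
#' @param measurement_noise_sd SD of additive white measurement noise at
#'   site 1 (series have unit signal scale).
#' @param site_noise_scale multiplier on the measurement-noise SD at
#'   site 2 relative to site 1.
#' @param joa_pre_mean baseline preoperative JOA level, points.
#' @param recovery_mean,recovery_sd postoperative gain distribution, points.
#' @param seed master integer seed; all subject-level randomness is drawn
#'   from counter-split sub-streams of it.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_rois = 116,
                             n_patient = c(27, 26),
                             n_control = c(11, 36),
                             t_volumes = c(170, 440),
                             tr = c(2.0, 0.8),
                             n_disc_edges = 50,
                             disc_effect = 0.3,
                             n_score_edges = 30,
                             score_noise_sd = 1.0,
                             score_signal_sd = 1.2,
                             subject_z_sd = 0.2,
                             base_corr_mean = 0.2,
                             measurement_noise_sd = 0.3,
                             site_noise_scale = 2,
                             joa_pre_mean = 11.4,
                             recovery_mean = 3.5,
                             recovery_sd = 1.8,
                             seed = 1L) {
  cfg <- list(n_rois = as.integer(n_rois),
              n_patient = as.integer(n_patient),
              n_control = as.integer(n_control),
              t_volumes = as.integer(t_volumes),
              tr = as.numeric(tr),
              n_disc_edges = as.integer(n_disc_edges),
              disc_effect = as.numeric(disc_effect),
              n_score_edges = as.integer(n_score_edges),
              score_noise_sd = as.numeric(score_noise_sd),
              score_signal_sd = as.numeric(score_signal_sd),
              subject_z_sd = as.numeric(subject_z_sd),
              base_corr_mean = as.numeric(base_corr_mean),
              measurement_noise_sd = as.numeric(measurement_noise_sd),
              site_noise_scale = as.numeric(site_noise_scale),
              joa_pre_mean = as.numeric(joa_pre_mean),
              recovery_mean = as.numeric(recovery_mean),
              recovery_sd = as.numeric(recovery_sd),
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_rois >= 2,
            length(cfg$n_patient) == 2, length(cfg$n_control) == 2,
            length(cfg$t_volumes) == 2, length(cfg$tr) == 2,
            all(cfg$n_patient >= 1), all(cfg$n_control >= 1),
            all(cfg$t_volumes >= 3), all(cfg$tr > 0),
            cfg$n_disc_edges >= 0, cfg$n_score_edges >= 0,
            cfg$score_noise_sd >= 0, cfg$subject_z_sd >= 0,
            cfg$measurement_noise_sd >= 0, cfg$site_noise_scale > 0,
            cfg$base_corr_mean >= 0, cfg$base_corr_mean < 1)
  if (cfg$n_disc_edges + cfg$n_score_edges > n_edges(cfg$n_rois))
    stop("synthetic_config: more ground-truth edges than edges exist")
  invisible(cfg)
}

#' Random base correlation matrix with a given average off-diagonal level
#'
#' A Wishart-style draw blended with an equicorrelation component: both
#' parts are PSD, so the result is a valid correlation matrix with mean
#' off-diagonal approximately `avg`.
#' @keywords internal
base_correlation <- function(n_rois, avg = 0.2, df = NULL) {
  if (is.null(df)) df <- max(2L * n_rois, 20L)
  a <- matrix(stats::rnorm(df * n_rois), df, n_rois)
  q <- stats::cov2cor(crossprod(a) / df)
  out <- avg * matrix(1, n_rois, n_rois) + (1 - avg) * q
  diag(out) <- 1
  (out + t(out)) / 2
}

#' Project to a PSD correlation matrix while pinning selected entries
#'
#' A single eigenvalue clip would shrink imposed entries appreciably, so
#' the repair alternates between projecting onto the PSD cone and
#' re-imposing the pinned entries (and unit diagonal) until both hold
#' within tolerance. Errors if the pins cannot be preserved.
#'
#' @param m symmetric matrix (approximately a correlation matrix).
#' @param edges canonical edge indices whose values are pinned.
#' @param z_values Fisher-z values to pin at those edges.
#' @param tol maximum tolerated z-scale deviation at the pinned edges.
#' @keywords internal
pin_psd_corr <- function(m, edges, z_values, tol = 0.01, max_iter = 500,
                         eps = 1e-9) {
  if (length(edges) == 0) return(nearest_pd_corr(m))
  ei <- edge_index(nrow(m))[edges, ]
  target <- tanh(z_values)
  impose <- function(x) {
    x[cbind(ei$row, ei$col)] <- target
    x[cbind(ei$col, ei$row)] <- target
    diag(x) <- 1
    x
  }
  m <- impose(m)
  for (iter in seq_len(max_iter)) {
    e <- eigen(m, symmetric = TRUE)
    if (min(e$values) >= -eps) break
    m <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    m <- impose((m + t(m)) / 2)
  }
  m <- nearest_pd_corr(m, eps = 1e-8)
  got <- fisher_z(m[cbind(ei$row, ei$col)])
  if (max(abs(got - z_values)) > tol)
    stop("pin_psd_corr: PSD repair could not preserve the pinned edges")
  m
}

#' Apply a Fisher-z shift at selected edges and repair to PSD
#'
#' @param corr correlation matrix; `edges` canonical edge indices;
#'   `delta` z-scale shift.
#' @keywords internal
shift_edges_z <- function(corr, edges, delta) {
  if (length(edges) == 0 || delta == 0) return(corr)
  want <- fisher_z(corr[lower.tri(corr)])[edges] + delta
  z <- fisher_z(corr[lower.tri(corr)])
  z[edges] <- want
  out <- tryCatch(
    pin_psd_corr(devectorize_fc(z, n_rois = nrow(corr)), edges, want,
                 tol = 0.02 * abs(delta) + 0.01),
    error = function(e) stop(sprintf(
      "shift_edges_z: PSD repair could not preserve the z shift of %g",
      delta)))
  out
}

#' Generate a two-site synthetic cohort
#'
#' For each subject a T x R series is drawn from a multivariate normal
#' whose correlation matrix is a shared base matrix, shifted by
#' `disc_effect` on the Fisher-z scale at the discriminative edges for
#' patients, jittered per subject (`subject_z_sd`), and projected back to
#' the nearest PSD correlation matrix. White measurement noise is added
#' (site 2 at `site_noise_scale` times the site-1 SD). Patients receive a
#' preoperative JOA score that is a clipped affine function of their true
#' Fisher-z values at the score-linked edges plus Gaussian noise, and a
#' postoperative score adding a random surgical gain; controls have no
#' JOA scores. Scores are rounded to one decimal and clipped to \[0, 17\].
#'
#' Deterministic given the config (including its seed): equal configs give
#' bitwise-identical cohorts.
#'
#' @param config a [synthetic_config()].
#' @return object of class `fc_cohort`: list with `phenotype` (data.frame:
#'   subject_id, site, group, age, sex, education, joa_pre, joa_post),
#'   `series` (named list of T x R matrices), `truth` (list: `disc_edges`,
#'   `score_edges`, canonical indices), and `config`.
#' @export
generate_cohort <- function(config) {
  cfg <- validate_synthetic_config(unclass(config))
  r <- cfg$n_rois
  n_edge <- n_edges(r)

  set.seed(derive_seed(cfg$seed, 0L, stream = 1L))
  base <- nearest_pd_corr(base_correlation(r, avg = cfg$base_corr_mean))
  gt <- sample.int(n_edge, cfg$n_disc_edges + cfg$n_score_edges)
  disc_edges <- sort(gt[seq_len(cfg$n_disc_edges)])
  score_edges <- sort(gt[cfg$n_disc_edges + seq_len(cfg$n_score_edges)])

  pat <- shift_edges_z(base, disc_edges, cfg$disc_effect)
  group_corr <- list(patient = pat, control = base)
  base_z <- fisher_z(base[lower.tri(base)])
  # score coefficient sized so the FC-driven score component has
  # SD ~ score_signal_sd given the subject-level z jitter
  beta <- if (cfg$n_score_edges > 0 && cfg$subject_z_sd > 0) {
    cfg$score_signal_sd / (cfg$subject_z_sd * sqrt(cfg$n_score_edges))
  } else 0

  phen <- list()
  series <- list()
  idx <- 0L
  for (site in 1:2) {
    for (grp in c("patient", "control")) {
      n_sub <- if (grp == "patient") cfg$n_patient[site] else cfg$n_control[site]
      for (k in seq_len(n_sub)) {
        idx <- idx + 1L
        set.seed(derive_seed(cfg$seed, idx, stream = 2L))
        zg <- fisher_z(group_corr[[grp]][lower.tri(group_corr[[grp]])])
        zs <- zg
        if (cfg$subject_z_sd > 0)
          zs <- zs + stats::rnorm(n_edge, 0, cfg$subject_z_sd)
        # patients: pin the score-linked edges through the PSD repair so
        # the score really is an affine function of the subject's true
        # edge values (an unpinned repair shrinks the jitter, and the
        # shrinkage grows with the parcellation size)
        cs <- if (grp == "patient" && cfg$n_score_edges > 0 &&
                    cfg$subject_z_sd > 0) {
          pin_psd_corr(devectorize_fc(zs, n_rois = r), score_edges,
                       zs[score_edges], tol = 0.05)
        } else {
          nearest_pd_corr(devectorize_fc(zs, n_rois = r))
        }
        z_true <- fisher_z(cs[lower.tri(cs)])

        t_len <- cfg$t_volumes[site]
        noise_sd <- cfg$measurement_noise_sd *
          if (site == 1) 1 else cfg$site_noise_scale
        x <- matrix(stats::rnorm(t_len * r), t_len, r) %*% chol(cs)
        if (noise_sd > 0)
          x <- x + matrix(stats::rnorm(t_len * r, 0, noise_sd), t_len, r)

        age <- round(min(max(stats::rnorm(1, 55, 8.5), 30), 78))
        sex <- sample(c("female", "male"), 1)
        edu <- round(min(max(stats::rnorm(1, 11, 2.5), 3), 20))
        joa_pre <- joa_post <- NA_real_
        if (grp == "patient") {
          signal <- if (cfg$n_score_edges > 0)
            sum(beta * (z_true[score_edges] - base_z[score_edges])) else 0
          joa_pre <- cfg$joa_pre_mean + signal +
            stats::rnorm(1, 0, cfg$score_noise_sd)
          # preoperative ceiling kept below 17: surgical candidates have
          # deficits, and the recovery rate is undefined at pre = 17
          joa_pre <- round(min(max(joa_pre, 0), 16.5), 1)
          gain <- stats::rnorm(1, cfg$recovery_mean, cfg$recovery_sd)
          joa_post <- round(min(max(joa_pre + gain, 0), 17), 1)
        }
        sid <- sprintf("s%d_%s_%02d", site, substr(grp, 1, 3), k)
        phen[[idx]] <- data.frame(
          subject_id = sid, site = site, group = grp, age = age, sex = sex,
          education = edu, joa_pre = joa_pre, joa_post = joa_post,
          stringsAsFactors = FALSE)
        series[[sid]] <- x
      }
    }
  }
  out <- list(phenotype = do.call(rbind, phen), series = series,
              truth = list(disc_edges = disc_edges,
                           score_edges = score_edges),
              config = cfg)
  class(out) <- "fc_cohort"
  out
}

#' @export
print.fc_cohort <- function(x, ...) {
  ph <- x$phenotype
  cat(sprintf("Synthetic FC cohort: %d subjects, %d ROIs (%d edges)\n",
              nrow(ph), x$config$n_rois, n_edges(x$config$n_rois)))
  print(table(site = ph$site, group = ph$group))
  cat(sprintf("ground truth: %d discriminative edges, %d score-linked edges\n",
              length(x$truth$disc_edges), length(x$truth$score_edges)))
  invisible(x)
}

#' Write a cohort to disk as plain-text artifacts
#'
#' `phenotype.csv`, headerless per-subject series under `series/`, and
#' `truth.json` (ground-truth edge indices plus a config echo).
#'
#' @param cohort an `fc_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fc_cohort"))
  dir.create(file.path(dir, "series"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$phenotype, file.path(dir, "phenotype.csv"),
                   row.names = FALSE)
  for (sid in names(cohort$series)) {
    utils::write.table(round(cohort$series[[sid]], 6),
                       file.path(dir, "series", paste0(sid, ".txt")),
                       row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(
    list(disc_edges = cohort$truth$disc_edges,
         score_edges = cohort$truth$score_edges,
         config = unclass(cohort$config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `phenotype.csv` and `series/`.
#' @return list with `phenotype` and `series` (and `truth` if present).
#' @export
read_cohort <- function(dir) {
  ph <- utils::read.csv(file.path(dir, "phenotype.csv"),
                        stringsAsFactors = FALSE)
  series <- lapply(ph$subject_id, function(sid) {
    as.matrix(utils::read.table(file.path(dir, "series",
                                          paste0(sid, ".txt"))))
  })
  names(series) <- ph$subject_id
  out <- list(phenotype = ph, series = series)
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) out$truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  out
}
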