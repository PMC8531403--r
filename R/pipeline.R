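#' Default pipeline configuration
#'
#' Returns the full configuration list understood by [run_pipeline()];
#' override entries via `...` (unknown keys are an error). `synthetic`
#' holds arguments for [synthetic_config()]; alternatively set `input` to
#' `list(phenotype = <csv>, series_dir = <dir>)` to analyse real data
#' (exactly one of the two must be used).
#'
#' @param ... overrides for the defaults.
#' @return named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    synthetic = list(),
    input = NULL,
    clean = FALSE,
    band = c(0.01, 0.08),
    stages = c("edgestats", "classify", "predict", "agreement"),
    grid = list(from = 0.05, to = 1, by = 0.05),
    n_perm = 0L,
    fdr_q = 0.05,
    filter_alpha = 0.05,
    family_alpha = 0.05,
    targets = c("joa_pre", "recovery", "recovery_rate"),
    cross_site = TRUE,
    label_scaling = "native")
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("pipeline_config: unknown key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full FC-MVPA pipeline
#'
#' Executes, in dependency order: cohort simulation (or loading), feature
#' construction, edge-wise group statistics, LOOCV and cross-site SVM
#' classification with permutation inference, SVR score prediction, and
#' Bland-Altman agreement. Every artifact is written under `out_dir` as
#' plain text (CSV/JSON); `manifest.json` records the configuration, the
#' package version and an MD5 per artifact, so a rerun with identical
#' config is byte-identical.
#'
#' @param config a list from [pipeline_config()], or a path to a YAML
#'   file with the same keys.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1)
    config <- read_pipeline_config(config)
  cfg <- do.call(pipeline_config, config)   # validates keys
  if (!is.null(cfg$input) && length(cfg$synthetic))
    stop("run_pipeline: give either synthetic parameters or input paths, not both")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list(config = cfg)

  # --- cohort -------------------------------------------------------------
  if (is.null(cfg$input)) {
    syn <- do.call(synthetic_config,
                   c(cfg$synthetic,
                     if (is.null(cfg$synthetic$seed)) list(seed = cfg$seed)))
    cohort <- generate_cohort(syn)
    write_cohort(cohort, out_dir)
  } else {
    cohort <- read_cohort_paths(cfg$input)
  }
  ph <- cohort$phenotype
  results$phenotype <- ph

  # --- features -----------------------------------------------------------
  tr_by_site <- if (is.null(cohort$config)) NULL else cohort$config$tr
  tr_vec <- if (cfg$clean && !is.null(tr_by_site)) tr_by_site[ph$site] else NULL
  feats <- fc_feature_table(cohort$series, clean = cfg$clean, tr = tr_vec,
                            band = cfg$band)
  utils::write.csv(
    data.frame(subject_id = rownames(feats), round(feats, 8),
               check.names = FALSE),
    file.path(out_dir, "features.csv"), row.names = FALSE)
  results$features <- feats
  grid <- fraction_grid(cfg$grid$from, cfg$grid$to, cfg$grid$by)
  group <- factor(ph$group, levels = c("control", "patient"))

  # --- edge-wise statistics ----------------------------------------------
  if ("edgestats" %in% cfg$stages) {
    set.seed(derive_seed(cfg$seed, 1L, stream = 10L))
    covars <- ph[, c("age", "sex", "education", "site")]
    runs <- list(combined = seq_len(nrow(ph)),
                 site1 = which(ph$site == 1),
                 site2 = which(ph$site == 2))
    es <- do.call(rbind, lapply(names(runs), function(nm) {
      idx <- runs[[nm]]
      res <- edgewise_group_test(feats[idx, , drop = FALSE], group[idx],
                                 covariates = covars[idx, , drop = FALSE],
                                 q = cfg$fdr_q)
      cbind(analysis = nm, res)
    }))
    utils::write.csv(es, file.path(out_dir, "edgestats.csv"),
                     row.names = FALSE)
    results$edgestats <- es
  }

  # --- classification -----------------------------------------------------
  if ("classify" %in% cfg$stages) {
    set.seed(derive_seed(cfg$seed, 2L, stream = 10L))
    report <- list()
    for (s in 1:2) {
      idx <- which(ph$site == s)
      if (cfg$n_perm > 0) {
        pt <- permutation_test_accuracy(feats[idx, , drop = FALSE],
                                        group[idx], grid = grid,
                                        n_perm = cfg$n_perm)
        cv <- pt$cv
        bonf <- bonferroni_adjust(pt$p, alpha = cfg$family_alpha)
        pinfo <- list(p = pt$p, p_label = pt$p_label,
                      bonferroni_threshold = bonf$threshold,
                      significant = bonf$flags)
      } else {
        cv <- loocv_classify(feats[idx, , drop = FALSE], group[idx],
                             grid = grid)
        pinfo <- NULL
      }
      auc <- vapply(seq_along(grid), function(j)
        roc_auc(cv$decision_values[, j], cv$truth,
                positive = cv$positive)$auc, numeric(1))
      report[[paste0("site", s)]] <-
        c(list(fractions = grid, accuracy = unname(cv$accuracy),
               auc = auc), pinfo)
    }
    if (isTRUE(cfg$cross_site)) {
      i1 <- which(ph$site == 1); i2 <- which(ph$site == 2)
      xs <- cross_site_classify(feats[i1, , drop = FALSE], group[i1],
                                feats[i2, , drop = FALSE], group[i2],
                                grid = grid)
      report$cross_site <- list(
        fractions = grid,
        accuracy_1to2 = unname(xs$directions[["1->2"]]$accuracy),
        accuracy_2to1 = unname(xs$directions[["2->1"]]$accuracy),
        mean_accuracy = unname(xs$mean_accuracy),
        auc_1to2 = vapply(xs$directions[["1->2"]]$roc, `[[`, numeric(1), "auc"),
        auc_2to1 = vapply(xs$directions[["2->1"]]$roc, `[[`, numeric(1), "auc"),
        best = xs$best)
      results$cross_site_classify <- xs
    }
    jsonlite::write_json(report, file.path(out_dir, "classify_report.json"),
                         auto_unbox = TRUE, digits = NA)
    results$classify <- report
  }

  # --- prediction + agreement --------------------------------------------
  if ("predict" %in% cfg$stages) {
    set.seed(derive_seed(cfg$seed, 3L, stream = 10L))
    pat <- ph[ph$group == "patient" & !is.na(ph$joa_pre), ]
    labels_for <- function(rows, target) {
      switch(target,
             joa_pre = rows$joa_pre,
             recovery = joa_recovery(rows$joa_pre, rows$joa_post),
             recovery_rate = joa_recovery_rate(rows$joa_pre, rows$joa_post),
             stop("unknown prediction target: ", target))
    }
    pred_rows <- list()
    report <- list()
    for (target in cfg$targets) {
      for (s in 1:2) {
        rows <- pat[pat$site == s, ]
        y <- labels_for(rows, target)
        x <- feats[rows$subject_id, , drop = FALSE]
        if (cfg$n_perm > 0) {
          pt <- permutation_test_regression(
            x, y, alpha = cfg$filter_alpha, n_perm = cfg$n_perm,
            label_scaling = cfg$label_scaling)
          fit <- pt$observed
          pinfo <- list(p_r = unname(pt$r$p), p_r_label = unname(pt$r$p_label),
                        p_rmse = unname(pt$rmse$p),
                        p_rmse_label = unname(pt$rmse$p_label))
        } else {
          fit <- loocv_regress(x, y, alpha = cfg$filter_alpha,
                               label_scaling = cfg$label_scaling)
          pinfo <- NULL
        }
        key <- paste0(target, "_site", s)
        report[[key]] <- c(list(r = fit$r, rmse = fit$rmse,
                                label_scaling = fit$label_scaling), pinfo)
        pred_rows[[key]] <- data.frame(
          subject_id = rows$subject_id, target = target,
          analysis = paste0("site", s), actual = fit$actual,
          predicted = fit$predicted, stringsAsFactors = FALSE)
      }
      if (isTRUE(cfg$cross_site)) {
        r1 <- pat[pat$site == 1, ]; r2 <- pat[pat$site == 2, ]
        xs <- cross_site_regress(
          feats[r1$subject_id, , drop = FALSE], labels_for(r1, target),
          feats[r2$subject_id, , drop = FALSE], labels_for(r2, target),
          alpha = cfg$filter_alpha, label_scaling = cfg$label_scaling)
        for (d in names(xs)) {
          key <- paste0(target, "_train", substr(d, 1, 1))
          report[[key]] <- list(r = xs[[d]]$r, rmse = xs[[d]]$rmse,
                                label_scaling = xs[[d]]$label_scaling)
          rows <- if (d == "1->2") r2 else r1
          pred_rows[[key]] <- data.frame(
            subject_id = rows$subject_id, target = target,
            analysis = paste0("train_site", substr(d, 1, 1)),
            actual = xs[[d]]$actual, predicted = xs[[d]]$predicted,
            stringsAsFactors = FALSE)
        }
      }
    }
    predictions <- do.call(rbind, pred_rows)
    rownames(predictions) <- NULL
    utils::write.csv(predictions, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "predict_report.json"),
                         auto_unbox = TRUE, digits = NA)
    results$predict <- report
    results$predictions <- predictions

    if ("agreement" %in% cfg$stages) {
      keys <- unique(predictions[, c("target", "analysis")])
      agree <- do.call(rbind, lapply(seq_len(nrow(keys)), function(k) {
        sub <- predictions[predictions$target == keys$target[k] &
                             predictions$analysis == keys$analysis[k], ]
        ba <- bland_altman(sub$predicted, sub$actual)
        data.frame(target = keys$target[k], analysis = keys$analysis[k],
                   bias = ba$bias, sd = ba$sd, loa_low = ba$loa_low,
                   loa_high = ba$loa_high, within_loa = ba$within_loa)
      }))
      utils::write.csv(agree, file.path(out_dir, "agreement.csv"),
                       row.names = FALSE)
      results$agreement <- agree
    }
  }

  # --- manifest -----------------------------------------------------------
  arts <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                       "manifest.json"))
  manifest <- list(
    package = "fcmvpa",
    version = as.character(utils::packageVersion("fcmvpa")),
    seed = cfg$seed,
    config = cfg,
    artifacts = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, arts))), arts)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

read_cohort_paths <- function(input) {
  stopifnot(is.list(input), !is.null(input$phenotype),
            !is.null(input$series_dir))
  ph <- utils::read.csv(input$phenotype, stringsAsFactors = FALSE)
  series <- lapply(ph$subject_id, function(sid) {
    f <- file.path(input$series_dir, paste0(sid, ".txt"))
    if (!file.exists(f)) stop("run_pipeline: missing series file ", f)
    as.matrix(utils::read.table(f))
  })
  names(series) <- ph$subject_id
  list(phenotype = ph, series = series, config = NULL)
}
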