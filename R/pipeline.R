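# End-to-end orchestration: simulate (or read) a cohort, QC scans, score
# difference maps against matched controls, fit and bootstrap the two task
# PLS analyses per modality, calibrate and apply cluster-extent thresholds,
# compute ROI effect statistics, and run the clinical battery. Every
# stochastic stage draws its seed deterministically from the master seed.

stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 69069 + h * 1013904223) %% 2147483647)
}

#' Pipeline configuration
#'
#' Defaults are the analysis constants the pipeline is built around: Huber
#' k = 1.35, 1000 bootstrap iterations, voxel p = .005 with cluster-level
#' alpha = .05, SOFT-IMPUTE threshold chosen by 200 cross-validation repeats
#' with 5% holdout, and FDR q = 0.05.
#'
#' @param sim a [sim_config()] (simulated cohort), or `NULL` when reading
#'   data via `manifest_path`/`mask_path`/`volume_dir`.
#' @param manifest_path,mask_path,volume_dir on-disk cohort (ignored when
#'   `sim` is given).
#' @param modalities modalities to analyse (default: those present).
#' @param criteria [match_criteria()].
#' @param huber_k Huber tuning constant.
#' @param n_boot bootstrap iterations.
#' @param voxel_p,cluster_alpha,n_sim,connectivity cluster-inference
#'   settings.
#' @param cv_n_iter,cv_holdout SOFT-IMPUTE cross-validation settings.
#' @param impute_max_rank rank cap for the low-rank completion (the
#'   subject-by-session structure rarely supports more than a few
#'   components; capping keeps the completion well-posed and fast).
#' @param fdr_q FDR level for session and clinical tests.
#' @param run_qc run the intensity and multivariate QC screens and exclude
#'   flagged scans.
#' @param qc_alpha QC nominal level.
#' @param seed master seed.
#' @param output_dir optional directory for NIfTI/CSV/JSON outputs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), manifest_path = NULL,
                            mask_path = NULL, volume_dir = NULL,
                            modalities = NULL,
                            criteria = match_criteria(), huber_k = 1.35,
                            n_boot = 1000L, voxel_p = 0.005,
                            cluster_alpha = 0.05, n_sim = 2000L,
                            connectivity = 6L, cv_n_iter = 200L,
                            cv_holdout = 0.05, impute_max_rank = 10L,
                            fdr_q = 0.05,
                            run_qc = TRUE, qc_alpha = 0.05,
                            seed = 1L, output_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

subset_modality <- function(maps, mod) {
  rows <- which(maps$info$modality == mod)
  map_set(maps$values[rows, , drop = FALSE],
          maps$info[rows, , drop = FALSE], maps$geometry)
}

drop_rows <- function(maps, rows) {
  if (length(rows) == 0L) return(maps)
  map_set(maps$values[-rows, , drop = FALSE],
          maps$info[-rows, , drop = FALSE], maps$geometry)
}

residual_maps <- function(deltas) {
  V <- dim(deltas$delta)[3]
  out <- list(); r <- 0L
  for (t in 1:3) {
    rows <- which(deltas$available[, t])
    if (length(rows) < 2L) next
    block <- deltas$delta[rows, t, , drop = FALSE][, 1, ]
    r <- r + 1L
    out[[r]] <- sweep(block, 2L, colMeans(block), `-`)
  }
  do.call(rbind, out)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

analyse_modality <- function(deltas, analysis, config, lambda, seed_tag,
                             thr_cache = new.env(parent = emptyenv())) {
  boot <- bootstrap_pls(deltas, analysis = analysis, n_boot = config$n_boot,
                        seed = stage_seed(config$seed,
                                          paste0("boot_", seed_tag)),
                        lambda = lambda,
                        impute_max_rank = config$impute_max_rank)
  sm <- estimate_fwhm(residual_maps(deltas), deltas$geometry)
  # the Monte-Carlo null depends only on (mask, smoothness, thresholds), so
  # thresholds are shared across analyses whose smoothness estimates agree
  # to 0.1 mm; one simulation seed keeps the whole pipeline deterministic
  fwhm_use <- round(sm$fwhm_mean, 1)
  key <- sprintf("%0.1f", fwhm_use)
  if (is.null(thr_cache[[key]]))
    thr_cache[[key]] <- simulate_cluster_threshold(deltas$geometry, fwhm_use,
      voxel_p = config$voxel_p, alpha = config$cluster_alpha,
      n_sim = config$n_sim, connectivity = config$connectivity,
      seed = stage_seed(config$seed, "clustsim"))
  min_size <- thr_cache[[key]]
  clusters <- extract_clusters(boot$voxel_bsr, deltas$geometry,
    voxel_p = config$voxel_p, min_size = min_size,
    connectivity = config$connectivity)
  sig_sessions <- SESSIONS[fdr_adjust(pmax(boot$session_p,
    .Machine$double.xmin), config$fdr_q)$reject]
  roi <- NULL
  if (nrow(clusters) > 0L) {
    vox <- sort(unique(unlist(attr(clusters, "voxels"))))
    roi <- roi_statistics(deltas, vox,
      groups = if (analysis == "MEAN") "all" else c("male", "female"),
      n_boot = config$n_boot,
      seed = stage_seed(config$seed, paste0("roi_", seed_tag)),
      lambda = lambda,
      contrast_sessions = if (length(sig_sessions)) sig_sessions else SESSIONS,
      q = config$fdr_q)
  }
  list(analysis = analysis, bootstrap = boot, smoothness = sm,
       min_cluster_size = min_size, clusters = clusters,
       significant_sessions = sig_sessions, roi = roi)
}

#' Run the full analysis pipeline
#'
#' Simulate (or read) a cohort, QC and exclude flagged scans, convert the
#' concussed athletes' maps to matched-control difference scores, then per
#' modality run the main-effect (session means) and sex-effect (session-wise
#' sex correlations) task PLS analyses with repeated-measures bootstrap,
#' SOFT-IMPUTE missing-session completion, cluster-extent thresholding and
#' ROI statistics; finish with the clinical battery and an attrition check.
#'
#' @param config a [pipeline_config()].
#' @return results bundle (class `pipeline_result`): `subjects`, `qc`,
#'   `modalities` (per modality: `deltas` summary, `imputation`, `MEAN` and
#'   `SEXCORR` analysis blocks), `clinical`, `attrition`, `config`, `log`.
#' @export
run_pipeline <- function(config) {
  log <- list()
  if (!is.null(config$sim)) {
    sim <- run_stage("simulate", simulate_cohort(config$sim))
    subjects <- sim$subjects; maps <- sim$maps; symptoms <- sim$symptoms
    truth <- sim$truth
  } else {
    cohort <- run_stage("read",
      read_cohort(config$manifest_path, config$volume_dir, config$mask_path))
    subjects <- cohort$subjects; maps <- cohort$maps
    symptoms <- NULL; truth <- NULL
    symp_path <- file.path(dirname(config$manifest_path), "symptoms.csv")
    if (file.exists(symp_path)) symptoms <- read.csv(symp_path)
  }
  modalities <- config$modalities %||% unique(maps$info$modality)

  qc <- list()
  if (isTRUE(config$run_qc)) {
    qc <- run_stage("qc", {
      out <- list()
      for (mod in modalities) {
        mm <- subset_modality(maps, mod)
        rep <- qc_report(mm, alpha = config$qc_alpha)
        ctrl_rows <- which(mm$info$session == "CONTROL")
        mv <- multivariate_outliers(mm$values, alpha = config$qc_alpha,
                                    reference_rows = ctrl_rows)
        rep$mv_flagged <- as.logical(mv)
        out[[mod]] <- rep
      }
      out
    })
  }

  results <- list()
  thr_cache <- new.env(parent = emptyenv())
  for (mod in modalities) {
    mm <- subset_modality(maps, mod)
    if (length(qc)) {
      bad <- which(qc[[mod]]$flagged | qc[[mod]]$mv_flagged)
      log[[paste0("qc_excluded_", mod)]] <-
        paste(qc[[mod]]$subject_id[bad], qc[[mod]]$session[bad], sep = "/")
      mm <- drop_rows(mm, bad)
    }
    deltas <- run_stage(paste0("score_", mod),
      difference_maps(subjects, mm, criteria = config$criteria,
                      k = config$huber_k))
    log[[paste0("matched_median_", mod)]] <-
      median(deltas$match_report$n_matched)

    X <- flatten_deltas(deltas)
    imp <- NULL
    lambda <- NULL
    if (anyNA(X)) {
      imp <- run_stage(paste0("impute_cv_", mod),
        select_lambda_cv(X, n_iter = config$cv_n_iter,
                         holdout_frac = config$cv_holdout,
                         max_rank = config$impute_max_rank,
                         seed = stage_seed(config$seed, paste0("cv_", mod))))
      lambda <- imp$chosen_lambda
      log[[paste0("lambda_", mod)]] <- lambda
    }
    res <- list(deltas = deltas, imputation = imp)
    for (analysis in c("MEAN", "SEXCORR"))
      res[[analysis]] <- run_stage(paste0(analysis, "_", mod),
        analyse_modality(deltas, analysis, config, lambda,
                         paste0(mod, "_", analysis), thr_cache))
    results[[mod]] <- res
  }

  clinical <- NULL
  attrition <- NULL
  if (!is.null(symptoms)) {
    clinical <- run_stage("clinical",
      clinical_report(subjects, symptoms, q = config$fdr_q))
    first <- results[[modalities[1]]]$deltas
    conc <- first$athletes
    item_cols <- grep("^item_", names(symptoms))
    base_sev <- score_symptoms(symptoms[symptoms$session == "baseline",
                                        item_cols])$total_severity
    names(base_sev) <- symptoms$subject_id[symptoms$session == "baseline"]
    vars <- data.frame(age = conc$age, sex = conc$sex, hoc = conc$hoc,
                       days_to_rtp = conc$days_to_rtp,
                       baseline_severity =
                         unname(base_sev[conc$subject_id]))
    attrition <- run_stage("attrition",
      attrition_check(first$available, vars, q = config$fdr_q))
  }

  bundle <- structure(list(subjects = subjects, qc = qc,
                           modalities = results, clinical = clinical,
                           attrition = attrition, truth = truth,
                           config = config, log = log),
                      class = "pipeline_result")
  if (!is.null(config$output_dir))
    run_stage("write", write_pipeline_outputs(bundle, config$output_dir))
  bundle
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", length(x$modalities), "modalities x {MEAN, SEXCORR}\n")
  for (mod in names(x$modalities)) {
    for (a in c("MEAN", "SEXCORR")) {
      blk <- x$modalities[[mod]][[a]]
      cat(sprintf("  %s %s: %%cov %.1f [%s], %d cluster(s), min size %d vox\n",
                  mod, a, blk$bootstrap$pct_cov,
                  paste(sprintf("%.1f", blk$bootstrap$pct_cov_ci), collapse = ", "),
                  nrow(blk$clusters), blk$min_cluster_size))
    }
  }
  invisible(x)
}

#' Write pipeline outputs to disk
#'
#' NIfTI voxel BSR and salience maps, cluster and ROI CSV tables, the QC,
#' clinical and attrition reports, and a JSON summary (seeds, chosen
#' lambdas, FWHM estimates, cluster thresholds, matched-control medians).
#'
#' @param bundle a `pipeline_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(seed = bundle$config$seed, log = bundle$log)
  for (mod in names(bundle$modalities)) {
    res <- bundle$modalities[[mod]]
    geom <- res$deltas$geometry
    for (a in c("MEAN", "SEXCORR")) {
      blk <- res[[a]]
      tag <- paste0(mod, "_", tolower(a))
      bsr <- blk$bootstrap$voxel_bsr
      bsr[!is.finite(bsr)] <- sign(bsr[!is.finite(bsr)]) * 1e6
      write_stat_map(bsr, geom, file.path(dir, paste0(tag, "_bsr.nii.gz")))
      write_stat_map(blk$bootstrap$component$voxel_salience, geom,
                     file.path(dir, paste0(tag, "_salience.nii.gz")))
      write.csv(as.data.frame(blk$clusters),
                file.path(dir, paste0(tag, "_clusters.csv")), row.names = FALSE)
      if (!is.null(blk$roi)) {
        write.csv(blk$roi$table, file.path(dir, paste0(tag, "_roi.csv")),
                  row.names = FALSE)
        write.csv(blk$roi$contrast,
                  file.path(dir, paste0(tag, "_contrast.csv")),
                  row.names = FALSE)
      }
      summary[[tag]] <- list(
        pct_covariance = blk$bootstrap$pct_cov,
        pct_covariance_ci = blk$bootstrap$pct_cov_ci,
        session_bsr = blk$bootstrap$session_bsr,
        session_p = blk$bootstrap$session_p,
        significant_sessions = blk$significant_sessions,
        fwhm_mm = blk$smoothness$fwhm,
        min_cluster_size_vox = blk$min_cluster_size,
        n_clusters = nrow(blk$clusters))
    }
    write.csv(res$deltas$match_report,
              file.path(dir, paste0(mod, "_matches.csv")), row.names = FALSE)
    if (!is.null(res$imputation))
      write.csv(data.frame(lambda = res$imputation$lambda_grid,
                           cv_mse = res$imputation$cv_error),
                file.path(dir, paste0(mod, "_cv_curve.csv")),
                row.names = FALSE)
  }
  if (length(bundle$qc))
    for (mod in names(bundle$qc))
      write.csv(bundle$qc[[mod]], file.path(dir, paste0(mod, "_qc.csv")),
                row.names = FALSE)
  if (!is.null(bundle$clinical))
    write.csv(bundle$clinical, file.path(dir, "clinical.csv"),
              row.names = FALSE)
  if (!is.null(bundle$attrition))
    write.csv(bundle$attrition, file.path(dir, "attrition.csv"),
              row.names = FALSE)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
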