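#' Per-patient report bundle
#'
#' Collects every stage output for one patient into a named list mirroring
#' the study's figure content as data: filter report, per-sample burden
#' metrics, cluster trajectories, clone tree, emergence/lead-time calls and
#' the lesion-association sign table. Patients with fewer than
#' `min_timepoints` samples get a bundle without the cluster/tree/emergence
#' sections and an explicit reason; any other missing stage is recorded as
#' an explicit gap rather than dropped silently. Re-running on unchanged
#' inputs gives the same bundle.
#'
#' @param series filtered [patient_series].
#' @param filter_report per-sample count table from [apply_filter_cascade()].
#' @param metrics table from [burden_metrics()].
#' @param fit optional `clone_fit` for the patient.
#' @param tree optional `clone_tree`.
#' @param scans optional per-scan data.frame for the patient.
#' @param pd_day first PD scan day (`NA` if none).
#' @param min_timepoints clustering eligibility threshold (default 3).
#' @return named list of class `patient_report` with elements
#'   `patient_id`, `eligible`, `filter_report`, `metrics`, `trajectories`,
#'   `tree`, `emergence`, `lesion_association`, `gaps`.
#' @export
patient_report <- function(series, filter_report, metrics, fit = NULL,
                           tree = NULL, scans = NULL, pd_day = NA,
                           min_timepoints = 3) {
  stopifnot(inherits(series, "patient_series"))
  eligible <- length(series$days) >= min_timepoints
  gaps <- character()
  trajectories <- emergence <- tree_out <- lesions <- NULL
  if (!eligible) {
    gaps <- c(gaps, paste0("clustering skipped: ", length(series$days),
                           " time points (need ", min_timepoints, ")"))
  } else {
    if (is.null(fit)) gaps <- c(gaps, "cluster stage missing")
    else {
      trajectories <- summarize_trajectories(fit)
      emergence <- emergence_calls(fit, pd_day = pd_day)
      if (is.null(tree)) gaps <- c(gaps, "tree stage missing")
      else tree_out <- list(edges = tree$edges,
                            valid = as.logical(validate_clone_tree(tree)))
      if (!is.null(scans))
        lesions <- lesion_association(trajectories, scans)
    }
  }
  structure(list(patient_id = series$patient_id, eligible = eligible,
                 filter_report = filter_report, metrics = metrics,
                 trajectories = trajectories, tree = tree_out,
                 emergence = emergence, lesion_association = lesions,
                 gaps = gaps),
            class = "patient_report")
}

#' @export
print.patient_report <- function(x, ...) {
  cat("<patient_report> ", x$patient_id,
      if (x$eligible) " (cluster-eligible)" else " (not cluster-eligible)",
      "\n", sep = "")
  if (length(x$gaps)) cat("gaps: ", paste(x$gaps, collapse = "; "), "\n")
  invisible(x)
}

#' Cohort-level summary across patient reports
#'
#' @param reports list of [patient_report()] bundles.
#' @return data.frame with one row per patient: sample count, eligibility,
#'   passing-variant totals, cluster count, tree validity.
#' @export
cohort_report <- function(reports) {
  rows <- lapply(reports, function(r) {
    data.frame(patient_id = r$patient_id,
               n_samples = nrow(r$metrics),
               eligible = r$eligible,
               n_passing = sum(r$metrics$n_passing),
               n_clusters = if (is.null(r$trajectories)) NA_integer_
                 else length(unique(r$trajectories$cluster)),
               tree_valid = if (is.null(r$tree)) NA else r$tree$valid,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline from a config
#'
#' Executes filter, metrics, cluster, tree and stats in order over a cohort
#' on disk, writing per-stage outputs (filtered VCFs, FilterReport TSV,
#' metrics TSV, cluster/tree JSON, stats JSON, per-patient report JSON) and
#' a run log with the seed and per-stage variant counts. Any stage failure
#' aborts naming the stage and the input that failed.
#'
#' @param config named list or path to a YAML/JSON config with entries
#'   `sample_sheet`, `clinical_table`, `scan_table` (optional), `popdb`,
#'   `normal_evidence`, `out_dir`, `seed`, optional `stages` (character
#'   subset of filter/metrics/cluster/tree/stats; empty = validate only)
#'   and optional `params` (thresholds: `min_total_depth`, `af_threshold`,
#'   `max_normal_reads`, `vaf_threshold`, `delta_threshold`, `panel_bp`,
#'   `min_timepoints`, `dp_iterations`, `dp_burnin`, `dp_thin`).
#' @return named list of per-patient bundles plus `cohort` and `stats`
#'   (invisibly).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("[.]ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  need <- c("sample_sheet", "clinical_table", "popdb", "normal_evidence",
            "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config missing entries: ",
                         paste(miss, collapse = ", "))
  p <- config$params
  par <- function(name, default) if (!is.null(p[[name]])) p[[name]] else default
  stages <- if (is.null(config$stages))
    c("filter", "metrics", "cluster", "tree", "stats") else config$stages
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cohort <- stage("read", read_cohort(config$sample_sheet,
                                      min_total_depth = par("min_total_depth", 100)))
  popdb <- stage("read", read_popdb(config$popdb))
  normal <- stage("read", read_normal_evidence(config$normal_evidence))
  clin <- stage("read", read_clinical_table(config$clinical_table,
                                            config$scan_table))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  log_lines <- c(paste0("ctdnaclone ",
                        as.character(utils::packageVersion("ctdnaclone"))),
                 paste0("R ", getRversion()),
                 paste0("seed ", seed),
                 paste0("stages ", paste(stages, collapse = ",")))
  if (!length(stages)) {
    writeLines(c(log_lines, "validation-only run"),
               file.path(out_dir, "run_log.txt"))
    return(invisible(list(cohort = NULL, stats = NULL)))
  }

  min_tp <- par("min_timepoints", 3)
  control <- dp_control(iterations = par("dp_iterations", 5000),
                        burnin = par("dp_burnin", 1000),
                        thin = par("dp_thin", 5))
  reports <- list(); all_metrics <- list(); all_freports <- list()

  for (pid in names(cohort)) {
    series <- cohort[[pid]]
    filtered <- stage("filter", apply_filter_cascade(
      series, popdb, normal,
      af_threshold = par("af_threshold", 0.001),
      max_normal_reads = par("max_normal_reads", 2),
      vaf_threshold = par("vaf_threshold", 0.20),
      delta_threshold = par("delta_threshold", 0.02)))
    # filtered VCFs: passing + removed calls with their FILTER labels
    dir.create(file.path(out_dir, "filtered_vcf"), showWarnings = FALSE)
    for (d in series$days) {
      keep <- filtered$series$variants[filtered$series$variants$day == d, ,
                                       drop = FALSE]
      rem <- filtered$removed[filtered$removed$day == d, , drop = FALSE]
      write_vcf(rbind(keep, rem),
                file.path(out_dir, "filtered_vcf",
                          sprintf("%s_day%03d.vcf", pid, d)),
                sample_id = pid)
    }
    all_freports[[pid]] <- filtered$report
    metrics <- if ("metrics" %in% stages)
      stage("metrics", burden_metrics(filtered$series,
                                      panel_bp = par("panel_bp", 637000)))
    else NULL
    all_metrics[[pid]] <- metrics

    fit <- tree <- NULL
    if ("cluster" %in% stages && length(series$days) >= min_tp &&
        any(filtered$series$variants$filter_status == "PASS")) {
      fit <- stage("cluster", cluster_series(filtered$series,
                                             control = control,
                                             seed = seed + match(pid, names(cohort)),
                                             min_timepoints = min_tp))
      if ("tree" %in% stages)
        tree <- stage("tree", build_tree(fit$phi, fit$days))
    }
    scans_p <- if (!is.null(clin$scans))
      clin$scans[clin$scans$patient_id == pid, , drop = FALSE] else NULL
    pd_day <- if (!is.null(scans_p) && any(scans_p$response %in% "PD"))
      min(scans_p$day[scans_p$response %in% "PD"]) else NA
    reports[[pid]] <- patient_report(filtered$series, filtered$report,
                                     metrics, fit, tree, scans_p, pd_day,
                                     min_timepoints = min_tp)
    log_lines <- c(log_lines, sprintf(
      "%s: input=%d passing=%d", pid, sum(filtered$report$input),
      sum(filtered$report$passing)))
  }

  wt <- function(df, name) write.table(df, file.path(out_dir, name),
                                       sep = "\t", quote = FALSE,
                                       row.names = FALSE)
  wt(do.call(rbind, all_freports), "filter_report.tsv")
  metrics_all <- do.call(rbind, all_metrics)
  if (!is.null(metrics_all)) {
    rownames(metrics_all) <- NULL
    wt(metrics_all, "metrics.tsv")
  }
  for (pid in names(reports)) {
    r <- reports[[pid]]
    jsonlite::write_json(
      list(patient_id = r$patient_id, eligible = r$eligible,
           filter_report = r$filter_report, metrics = r$metrics,
           trajectories = r$trajectories, tree = r$tree,
           emergence = r$emergence,
           lesion_association = r$lesion_association, gaps = r$gaps),
      file.path(out_dir, paste0("report_", pid, ".json")),
      auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  }

  stats_out <- NULL
  if ("stats" %in% stages && !is.null(metrics_all) &&
      nrow(clin$patients) > 0) {
    stats_out <- stage("stats", cohort_stats(metrics_all, clin$patients,
                                             clin$scans))
    jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(reports = reports, cohort = cohort_report(reports),
                 stats = stats_out))
}

#' Cohort association statistics
#'
#' The statistics stage: baseline-bTMB median-split log-rank on PFS, the
#' pooled Spearman correlation between per-sample MSAF and the
#' contemporaneous lesion-diameter sum, and the PR versus SD/PD Mann-Whitney
#' comparisons of sample-level MSAF and of patient-level mean MSAF.
#'
#' @param metrics pooled per-sample metrics table.
#' @param patients clinical table.
#' @param scans per-scan table (or NULL to skip scan-matched statistics).
#' @return nested list of test results.
#' @export
cohort_stats <- function(metrics, patients, scans = NULL) {
  out <- list()
  baseline <- metrics[metrics$day == 0, , drop = FALSE]
  idx <- match(patients$patient_id, baseline$patient_id)
  ok <- !is.na(idx) & !is.na(patients$pfs_days)
  if (sum(ok) >= 4) {
    sp <- try(median_split_logrank(patients$pfs_days[ok],
                                   patients$event[ok],
                                   baseline$btmb[idx[ok]]), silent = TRUE)
    if (!inherits(sp, "try-error"))
      out$btmb_pfs <- list(median_btmb = sp$median, chisq = sp$chisq,
                           p = sp$p,
                           n_low = sum(sp$group == "low"),
                           n_high = sum(sp$group == "high"))
  }
  if (!is.null(scans) && "diameter_sum_cm" %in% names(scans)) {
    m <- merge(metrics, scans[c("patient_id", "day", "diameter_sum_cm")],
               by = c("patient_id", "day"))
    if (nrow(m) >= 3) {
      sc <- spearman_corr(m$msaf, m$diameter_sum_cm)
      out$msaf_tumor_burden <- list(rho = sc$rho, p = sc$p, n = sc$n)
    }
    grp <- msaf_response_groups(metrics, scans)
    if (nrow(grp) && length(unique(grp$response_group)) == 2) {
      mw <- mann_whitney_u(grp$msaf[grp$response_group == "SD/PD"],
                           grp$msaf[grp$response_group == "PR"])
      out$msaf_response_samples <- list(
        U = mw$U, p = mw$p, method = mw$method,
        n_sdpd = sum(grp$response_group == "SD/PD"),
        n_pr = sum(grp$response_group == "PR"))
    }
  }
  on_tx <- metrics[metrics$day > 0, , drop = FALSE]
  if (nrow(on_tx)) {
    mm <- aggregate(msaf ~ patient_id, on_tx, mean)
    mm$group <- ifelse(
      patients$best_response[match(mm$patient_id,
                                   patients$patient_id)] == "PR",
      "PR", "SD/PD")
    if (length(unique(mm$group)) == 2) {
      mw <- mann_whitney_u(mm$msaf[mm$group == "SD/PD"],
                           mm$msaf[mm$group == "PR"])
      out$mmsaf_response_patients <- list(
        U = mw$U, p = mw$p, method = mw$method,
        n_sdpd = sum(mm$group == "SD/PD"), n_pr = sum(mm$group == "PR"))
    }
  }
  out
}
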