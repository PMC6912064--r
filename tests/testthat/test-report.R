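# End-to-end runs use a small cohort and a short chain; the dedicated
# clustering tests cover accuracy at realistic sizes.
small_params <- list(dp_iterations = 600, dp_burnin = 200, dp_thin = 2)

write_test_config <- function(dir, ...) {
  cfg <- c(list(sample_sheet = file.path(dir, "sample_sheet.tsv"),
                clinical_table = file.path(dir, "clinical.tsv"),
                scan_table = file.path(dir, "scans.tsv"),
                popdb = file.path(dir, "popdb.tsv"),
                normal_evidence = file.path(dir, "normal_evidence.tsv"),
                out_dir = file.path(dir, "out"), seed = 1,
                params = small_params),
           list(...))
  cfg
}

test_that("pipeline runs end to end on a simulated cohort and writes every stage", {
  dir <- tempfile()
  co <- simulate_cohort(
    sim_config(n_patients = 3, timepoints_per_patient = c(2, 3, 4),
               archetypes = c("stable", "responder", "stable")),
    seed = 3)
  write_cohort(co, dir)
  res <- suppressMessages(run_pipeline(write_test_config(dir)))
  out <- file.path(dir, "out")
  expect_true(file.exists(file.path(out, "filter_report.tsv")))
  expect_true(file.exists(file.path(out, "metrics.tsv")))
  expect_true(file.exists(file.path(out, "stats.json")))
  expect_true(file.exists(file.path(out, "run_log.txt")))
  expect_length(list.files(file.path(out, "filtered_vcf")), 9)
  expect_equal(nrow(res$cohort), 3)
  # eligibility: only the 3- and 4-sample patients cluster
  expect_equal(sum(res$cohort$eligible), 2)
  expect_true(all(res$cohort$tree_valid[res$cohort$eligible]))
  # filtered VCFs partition the input: every call is PASS or a filter label
  v <- read_vcf(file.path(out, "filtered_vcf",
                          list.files(file.path(out, "filtered_vcf"))[1]),
                min_total_depth = 1)
  expect_true(all(v$filter_status %in%
                    c("PASS", "common_germline", "matched_normal",
                      "private_germline")))
})

test_that("validation-only runs and broken inputs fail loudly", {
  dir <- tempfile()
  co <- simulate_cohort(sim_config(n_patients = 2,
                                   timepoints_per_patient = c(2, 2)),
                        seed = 4)
  write_cohort(co, dir)
  cfg <- write_test_config(dir, stages = character(0))
  res <- run_pipeline(cfg)
  expect_true(file.exists(file.path(dir, "out", "run_log.txt")))
  expect_false(file.exists(file.path(dir, "out", "metrics.tsv")))

  cfg2 <- write_test_config(dir)
  sheet <- read.delim(cfg2$sample_sheet)
  sheet$vcf_path[1] <- "missing_file.vcf"
  write.table(sheet, cfg2$sample_sheet, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(run_pipeline(cfg2), "missing_file.vcf")
  expect_error(run_pipeline(list(sample_sheet = "x")), "config missing")
})

test_that("patient report bundles all sections or records explicit gaps", {
  co <- simulate_cohort(sim_config(n_patients = 2,
                                   timepoints_per_patient = c(4, 2),
                                   archetypes = c("stable", "stable")),
                        seed = 9)
  popdb <- co$popdb; normal <- co$normal_evidence

  s1 <- suppressMessages(apply_filter_cascade(co$series[[1]], popdb, normal))
  m1 <- burden_metrics(s1$series)
  fit <- cluster_series(s1$series, seed = 2,
                        control = dp_control(iterations = 600, burnin = 200,
                                             thin = 2))
  tree <- build_tree(fit$phi, fit$days)
  scans <- co$scans[co$scans$patient_id == names(co$series)[1], ]
  rep1 <- patient_report(s1$series, s1$report, m1, fit, tree, scans,
                         pd_day = NA)
  expect_true(rep1$eligible)
  expect_length(rep1$gaps, 0)
  expect_false(is.null(rep1$trajectories))
  expect_false(is.null(rep1$tree))
  expect_true(rep1$tree$valid)
  expect_false(is.null(rep1$emergence))
  expect_false(is.null(rep1$lesion_association))

  # idempotence: same inputs, same bundle
  rep1b <- patient_report(s1$series, s1$report, m1, fit, tree, scans,
                          pd_day = NA)
  expect_identical(rep1[names(rep1) != "tree"], rep1b[names(rep1b) != "tree"])
  expect_identical(rep1$tree, rep1b$tree)

  # two time points: no cluster/tree sections, reason recorded
  s2 <- suppressMessages(apply_filter_cascade(co$series[[2]], popdb, normal))
  rep2 <- patient_report(s2$series, s2$report, burden_metrics(s2$series))
  expect_false(rep2$eligible)
  expect_null(rep2$trajectories)
  expect_null(rep2$tree)
  expect_match(rep2$gaps, "time points", all = FALSE)
})

test_that("an eligibility mix of 5 in 12 yields exactly 5 cluster-bearing bundles", {
  tp <- c(2, 2, 2, 2, 2, 2, 2, 3, 3, 4, 4, 5)
  co <- simulate_cohort(sim_config(n_patients = 12,
                                   timepoints_per_patient = tp,
                                   archetypes = rep("stable", 12)),
                        seed = 12)
  reports <- lapply(names(co$series), function(pid) {
    f <- suppressMessages(apply_filter_cascade(co$series[[pid]], co$popdb,
                                               co$normal_evidence))
    m <- burden_metrics(f$series)
    fit <- NULL
    if (length(f$series$days) >= 3)
      fit <- cluster_series(f$series, seed = 1,
                            control = dp_control(iterations = 400,
                                                 burnin = 100, thin = 2))
    tree <- if (!is.null(fit)) build_tree(fit$phi, fit$days)
    patient_report(f$series, f$report, m, fit, tree)
  })
  summary <- cohort_report(reports)
  expect_equal(sum(summary$eligible), 5)
  expect_equal(sum(!is.na(summary$n_clusters)), 5)
})
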