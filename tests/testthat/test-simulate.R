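test_that("same config and seed reproduce the cohort and its files byte for byte", {
  co1 <- simulate_cohort(sim_config(n_patients = 3), seed = 5)
  co2 <- simulate_cohort(sim_config(n_patients = 3), seed = 5)
  expect_identical(co1$series, co2$series)
  expect_identical(co1$clinical, co2$clinical)
  expect_identical(co1$truth, co2$truth)

  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  write_cohort(co1, d1); write_cohort(co2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
})

test_that("truth covers every emitted variant", {
  co <- simulate_cohort(sim_config(n_patients = 4), seed = 6)
  for (pid in names(co$series)) {
    keys <- unique(variant_key(co$series[[pid]]$variants))
    expect_true(all(keys %in% co$truth[[pid]]$variants$key), info = pid)
  }
})

test_that("clone trees nest and trajectories obey crossing and sum-up exactly", {
  for (seed in 1:100) {
    set.seed(seed)
    K <- sample(1:5, 1)
    tree <- simulate_clone_tree(K)
    if (K >= 2) expect_true(all(tree$parent[-1] < (2:K)))
    arch <- sample(c("responder", "stable", "progressor", "relapse"), 1)
    if (arch == "relapse") K <- max(K, 2)
    tree <- simulate_clone_tree(K)
    days <- as.integer(cumsum(c(0, round(runif(4, 14, 35)))))
    phi <- simulate_trajectories(tree, arch, days,
                                 emergence_day = if (arch == "relapse") 40)
    expect_true(all(phi >= 0 & phi <= 1))
    for (k in which(!is.na(tree$parent)))
      expect_true(all(phi[k, ] <= phi[tree$parent[k], ] + 1e-12))
    for (p in seq_len(K)) {
      kids <- which(tree$parent == p)
      if (length(kids))
        expect_true(all(colSums(phi[kids, , drop = FALSE]) <=
                          phi[p, ] + 1e-12))
    }
  }
  expect_error(simulate_clone_tree(0), ">= 1")
})

test_that("archetypes shape the founder trajectory as designed", {
  set.seed(2)
  days <- c(0, 30, 60, 90, 120)
  resp <- simulate_trajectories(simulate_clone_tree(1), "responder", days)
  expect_true(all(diff(resp[1, ]) < 0))
  rel <- simulate_trajectories(simulate_clone_tree(3), "relapse", days,
                               emergence_day = 35)
  r <- rel[attr(rel, "resistance_clone"), ]
  expect_true(any(diff(r) > 0 & r[-1] > 0.01))  # a rising detectable clone
  expect_error(simulate_trajectories(simulate_clone_tree(2), "relapse",
                                     days), "emergence_day")
})

test_that("read simulation respects the planted binomial model", {
  variants <- data.frame(chrom = "chr1", pos = 1:2, ref = "A", alt = "T",
                         gene = "G", effect = "nonsynonymous", logr = 0,
                         origin = "somatic", clone = c(1L, 2L),
                         true_vaf_fixed = NA_real_, stringsAsFactors = FALSE)
  phi <- rbind(c(0.3), c(0))   # second clone extinct at this day
  set.seed(4)
  vafs <- vapply(1:100, function(i) {
    tab <- simulate_reads(variants, phi, days = 0, depth_mean = 3000)[[1]]
    expect_false("chr1:2:A:T" %in% variant_key(tab))  # phi 0 never emitted
    tab$vaf[variant_key(tab) == "chr1:1:A:T"]
  }, numeric(1))
  expect_lt(abs(mean(vafs) - 0.15), 0.01)
})

test_that("germline SNPs land in the population DB at VAF ~ 0.5 every day", {
  co <- simulate_cohort(sim_config(n_patients = 2), seed = 8)
  for (pid in names(co$series)) {
    tr <- co$truth[[pid]]
    gl <- tr$variants$key[tr$variants$origin == "common_germline"]
    expect_true(all(gl %in% co$popdb$key))
    expect_true(all(co$popdb$pop_af >= 0.001))
    v <- co$series[[pid]]$variants
    gv <- v[variant_key(v) %in% gl, ]
    expect_equal(nrow(gv), length(gl) * length(tr$days))
    expect_true(all(abs(gv$vaf - 0.5) < 0.05))
    # CHIP variants carry WBC evidence above the filter cutoff
    chip <- tr$variants$key[tr$variants$origin == "chip"]
    wbc <- co$normal_evidence$wbc_alt_reads[
      match(chip, co$normal_evidence$key)]
    expect_true(all(wbc > 2))
  }
})

test_that("clinical labels follow the diameter threshold rules", {
  days <- c(0, 30, 60, 90)
  # steady 60% diameter decrease: best response PR, censored at last visit
  resp <- simulate_clinical(days, tumor_fraction = c(0.5, 0.2, 0.08, 0.03),
                            archetype = "responder", baseline_cm = 10,
                            noise_sd = 0)
  expect_equal(resp$best_response, "PR")
  expect_false(resp$event)
  expect_equal(resp$pfs_days, 90)

  flat <- simulate_clinical(days, tumor_fraction = rep(0.2, 4),
                            archetype = "stable", baseline_cm = 8,
                            noise_sd = 0)
  expect_equal(flat$best_response, "SD")
  expect_false(flat$event)

  prog <- simulate_clinical(days, tumor_fraction = c(0.1, 0.2, 0.4, 0.8),
                            archetype = "progressor", baseline_cm = 6,
                            noise_sd = 0)
  expect_equal(prog$best_response, "PD")  # grows throughout: PD only
  expect_true(prog$event)
  expect_equal(prog$pfs_days, prog$pd_day)
})

test_that("relapse patients plant a PD scan and a pre-PD rising clone", {
  cfg <- sim_config(n_patients = 3, archetypes = rep("relapse", 3))
  co <- simulate_cohort(cfg, seed = 10)
  for (pid in names(co$series)) {
    tr <- co$truth[[pid]]
    expect_false(is.na(tr$pd_day))
    lead <- tr$pd_planned - tr$emergence_day
    expect_gte(lead, 60); expect_lte(lead, 120)
    expect_gte(tr$pd_day, tr$pd_planned)  # first PD scan at/after the plant
    clin <- co$clinical[co$clinical$patient_id == pid, ]
    expect_true(clin$event)
    expect_equal(clin$pfs_days, tr$pd_day)
  }
})

test_that("planted identifiable trees satisfy their own constraints", {
  set.seed(31)
  for (i in 1:10) {
    days <- as.integer(cumsum(c(0, round(runif(5, 14, 35)))))
    g <- simulate_planted_tree(sample(3:5, 1), days)
    for (k in which(!is.na(g$tree$parent)))
      expect_true(all(g$phi[k, ] <= g$phi[g$tree$parent[k], ] + 1e-12))
    # non-nested lineages mutually cross by more than 2 * epsilon
    K <- nrow(g$phi)
    for (a in seq_len(K)) for (b in seq_len(K)) {
      if (a >= b) next
      anc <- function(x, y) {
        while (!is.na(y)) { if (y == x) return(TRUE); y <- g$tree$parent[y] }
        FALSE
      }
      if (anc(a, b) || anc(b, a)) next
      expect_true(any(g$phi[a, ] > g$phi[b, ] + 0.04))
      expect_true(any(g$phi[b, ] > g$phi[a, ] + 0.04))
    }
  }
})
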