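# Sampler settings kept small for test speed; accuracy checks below confirm
# they suffice at these problem sizes.
fast_control <- dp_control(iterations = 1500, burnin = 400, thin = 2)

test_that("two planted clusters with crossing trajectories are recovered", {
  phi_true <- rbind(c(0.40, 0.10, 0.05), c(0.02, 0.10, 0.30))
  pc <- planted_counts(phi_true, n_per = c(10, 10), seed = 7)
  fit <- dp_cluster(pc$alt, pc$depth, pc$cn, days = c(0, 30, 60),
                    control = fast_control, seed = 7)
  expect_equal(fit$n_clusters, 2)
  # label-invariant pairwise co-clustering: at least 18/20 mutations placed
  # with their planted partners
  co_true <- outer(pc$z, pc$z, `==`)
  co_fit <- outer(fit$assignments, fit$assignments, `==`)
  miscl <- sum(rowSums(co_true != co_fit) > 0)
  expect_lte(miscl, 2)
  # prevalence recovery within 0.05 at every time point
  map_row <- vapply(1:2, function(k)
    fit$assignments[which(pc$z == k)[1]], integer(1))
  expect_true(all(abs(fit$phi[map_row, ] - phi_true) < 0.05))
})

test_that("exchangeable mutations collapse to one cluster; singletons work", {
  pc <- planted_counts(matrix(0.3, 1, 3), n_per = 8, seed = 5)
  fit <- dp_cluster(pc$alt, pc$depth, pc$cn, days = c(0, 20, 40),
                    control = fast_control, seed = 5)
  expect_equal(fit$n_clusters, 1)

  one <- planted_counts(rbind(c(0.2, 0.4)), n_per = 1, seed = 2)
  fit1 <- dp_cluster(one$alt, one$depth, one$cn, days = c(0, 30),
                     control = fast_control, seed = 2)
  expect_equal(fit1$n_clusters, 1)
  vaf <- one$alt / one$depth
  se <- sqrt(vaf * (1 - vaf) / one$depth)
  expect_true(all(abs(fit1$phi - 2 * vaf) <= 2 * 3 * se + 0.01))
})

test_that("identical seed and input give identical fits", {
  pc <- planted_counts(rbind(c(0.3, 0.1), c(0.05, 0.2)), n_per = c(5, 5),
                       seed = 9)
  f1 <- dp_cluster(pc$alt, pc$depth, pc$cn, days = c(0, 30),
                   control = fast_control, seed = 123)
  f2 <- dp_cluster(pc$alt, pc$depth, pc$cn, days = c(0, 30),
                   control = fast_control, seed = 123)
  expect_identical(f1$assignments, f2$assignments)
  expect_identical(f1$phi, f2$phi)
})

test_that("undetected time points enter as zero alt reads, not dropped", {
  v0 <- rbind(vt(pos = 1, alt_reads = 300, ref_reads = 2700),
              vt(pos = 2, alt_reads = 290, ref_reads = 2710))
  v1 <- rbind(vt(pos = 1, alt_reads = 150, ref_reads = 2850),
              vt(pos = 2, alt_reads = 160, ref_reads = 2840))
  v2 <- vt(pos = 1, alt_reads = 30, ref_reads = 2970) # pos 2 undetected
  s <- patient_series("P1", c(0, 30, 60), list(v0, v1, v2))
  fit <- cluster_series(s, control = fast_control, seed = 4)
  expect_length(fit$assignments, 2)
  expect_equal(ncol(fit$phi), 3)
})

test_that("series clustering enforces the three-time-point eligibility rule", {
  s <- series_with_vafs(c(0.1, 0.12))
  expect_error(cluster_series(s, seed = 1), "3 required")
  pc <- planted_counts(rbind(c(0.3, 0.1)), n_per = 3, seed = 1)
  expect_error(dp_cluster(pc$alt, pc$depth, pc$cn, days = c(0, 30)),
               "seed")
})

test_that("trajectory table is tidy: one row per cluster and day", {
  pc <- planted_counts(rbind(c(0.4, 0.1, 0.05, 0.02),
                             c(0.02, 0.1, 0.2, 0.3)),
                       n_per = c(6, 6), seed = 13)
  fit <- dp_cluster(pc$alt, pc$depth, pc$cn, days = c(0, 30, 60, 90),
                    control = fast_control, seed = 13)
  tr <- summarize_trajectories(fit)
  expect_equal(nrow(tr), fit$n_clusters * 4)
  expect_true(all(tr$phi >= 0 & tr$phi <= 1))
  expect_true(all(tr$phi_lower <= tr$phi & tr$phi <= tr$phi_upper))
  expect_equal(sum(tr$n_mutations[tr$day == 0]), 12)
})

test_that("Gibbs consensus agrees with the exhaustive MAP partition on small instances", {
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed + 100)
    K <- sample(1:3, 1)
    phi_true <- matrix(runif(K * 2, 0.05, 0.6), K, 2)
    z_true <- sort(sample(seq_len(K), 6, replace = TRUE))
    alt <- t(vapply(z_true, function(k) rbinom(2, 3000, phi_true[k, ] / 2),
                    integer(2)))
    dep <- matrix(3000, 6, 2)
    fit <- dp_cluster(alt, dep, rep(2L, 6), days = c(0, 30), seed = seed,
                      control = fast_control)
    mp <- map_partition(alt, dep, rep(2L, 6))
    hits <- hits + identical(
      match(unname(fit$assignments), unique(unname(fit$assignments))),
      match(mp$partition, unique(mp$partition)))
  }
  expect_gte(hits, 9)
})

test_that("prevalence recovery error stays below 0.05 across replicates", {
  maes <- vapply(1:20, function(r) {
    set.seed(r + 500)
    phi_true <- rbind(runif(3, 0.2, 0.7), runif(3, 0.01, 0.15))
    z_true <- rep(1:2, c(6, 5))
    alt <- t(vapply(z_true, function(k)
      rbinom(3, 3000, phi_true[k, ] / 2), integer(3)))
    dep <- matrix(3000, 11, 3)
    fit <- dp_cluster(alt, dep, rep(2L, 11), days = c(0, 30, 60), seed = r,
                      control = fast_control)
    mean(vapply(seq_along(z_true), function(i)
      mean(abs(fit$phi[fit$assignments[i], ] - phi_true[z_true[i], ])),
      numeric(1)))
  }, numeric(1))
  expect_lte(mean(maes), 0.05)
})

test_that("copy number scales the emission: amplified loci recover the same clone", {
  set.seed(21)
  # same clone at prevalence 0.4; loci at CN 1, 2, 3 have VAF 0.4, 0.2, 0.133
  cn <- c(2L, 2L, 2L, 1L, 3L)
  phi_t <- c(0.4, 0.25)
  alt <- t(vapply(cn, function(c) rbinom(2, 3000, phi_t / c), integer(2)))
  fit <- dp_cluster(alt, matrix(3000, 5, 2), cn, days = c(0, 30),
                    control = fast_control, seed = 21)
  expect_equal(fit$n_clusters, 1)
  expect_true(all(abs(fit$phi[1, ] - phi_t) < 0.05))
})
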