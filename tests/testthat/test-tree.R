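test_that("trend splitting partitions by sign of the windowed VAF change", {
  days <- c(0, 50, 100)
  vaf <- rbind("chr1:1:A:T" = c(0.05, 0.06, 0.09),
               "chr1:2:A:T" = c(0.05, 0.055, 0.07),
               "chr2:3:A:T" = c(0.08, 0.07, 0.05))
  out <- split_by_trend(vaf, days, window = c(50, 100))
  expect_length(out, 2)
  expect_setequal(lengths(out), c(2, 1))
  expect_error(split_by_trend(vaf, days, window = c(50, 120)),
               "outside sampled days")

  # all ascending and mutually correlated: one sub-cluster
  up <- rbind("chr1:1:A:T" = c(0.01, 0.05, 0.10),
              "chr1:2:A:T" = c(0.02, 0.06, 0.12))
  expect_length(split_by_trend(up, days, window = c(0, 100)), 1)
})

test_that("patient-8-like cluster splits into 4 ascending vs 3 descending mutations", {
  days <- c(0, 42, 86, 106, 149, 191)
  up_keys <- c("chr17:7578406:C:T",   # TP53-like
               "chr15:88576276:C:G",  # NTRK3-like
               "chr15:45003746:T:A",  # B2M-like
               "chr15:45003812:G:C")  # B2M-like, later
  down_keys <- c("chr7:140453136:A:T",  # BRAF-like
                 "chr6:117609901:G:A",  # ROS1-like
                 "chr4:55141055:A:G")   # PDGFRA-like
  base_up <- c(0.30, 0.12, 0.02, 0.01)
  vaf <- rbind(
    t(vapply(base_up, function(b) b * c(1, 0.5, 0.4, 0.35, 0.9, 1.4),
             numeric(6))),
    t(vapply(c(0.20, 0.10, 0.06),
             function(b) b * c(1, 0.6, 0.5, 0.55, 0.25, 0.1), numeric(6))))
  rownames(vaf) <- c(up_keys, down_keys)
  out <- split_by_trend(vaf, days, window = c(106, 149))
  expect_length(out, 2)
  sizes <- lengths(out)
  expect_setequal(sizes, c(4, 3))
  asc <- out[[which(sizes == 4)]]
  expect_setequal(asc, up_keys)
})

test_that("crossing rule compares child to parent pointwise with tolerance", {
  expect_true(check_crossing_rule(c(0.4, 0.3, 0.2), c(0.2, 0.1, 0.05)))
  expect_false(check_crossing_rule(c(0.4, 0.3, 0.2), c(0.5, 0.1, 0.05)))
  expect_true(check_crossing_rule(c(0.4, 0.3, 0.2), c(0.41, 0.1, 0.05),
                                  epsilon = 0.02))
  expect_error(check_crossing_rule(c(0.4, 0.3), c(0.2, 0.1, 0.05)),
               "mismatched")
})

test_that("nested trajectories build a chain; validator certifies it", {
  days <- c(0, 30, 60)
  phi <- rbind(A = c(0.8, 0.6, 0.5),
               B = c(0.5, 0.35, 0.3),
               C = c(0.2, 0.15, 0.1))
  tree <- build_tree(phi, days)
  expect_equal(tree$edges$parent[match(c("A", "B", "C"), tree$edges$child)],
               c("root", "A", "B"))
  expect_true(validate_clone_tree(tree))
  # determinism
  tree2 <- build_tree(phi, days)
  expect_identical(tree$edges, tree2$edges)
  expect_error(build_tree(phi[0, , drop = FALSE], days), "no clusters")
})

test_that("sum-up constraint forbids siblings that jointly exceed the parent", {
  days <- c(0, 30, 60)
  # B and C each fit under A, but B + C > A everywhere; C also crosses B,
  # so C cannot nest under B and must fall back to the root
  phi <- rbind(A = c(0.50, 0.50, 0.50),
               B = c(0.40, 0.30, 0.35),
               C = c(0.30, 0.40, 0.35))
  tree <- build_tree(phi, days)
  pa <- tree$edges$parent[match(c("B", "C"), tree$edges$child)]
  expect_false(all(pa == "A"))
  expect_true(validate_clone_tree(tree))
})

test_that("patient-8-like relapse topology is recovered from noisy prevalences", {
  set.seed(8)
  days <- c(0, 42, 86, 106, 149, 191)
  # truth: founder -> descending branch; founder -> rising -> late rising
  phi <- rbind(founder = c(0.50, 0.30, 0.22, 0.20, 0.28, 0.42),
               desc    = c(0.40, 0.22, 0.15, 0.10, 0.05, 0.02),
               rise1   = c(0.02, 0.05, 0.06, 0.09, 0.20, 0.30),
               rise2   = c(0.00, 0.00, 0.00, 0.02, 0.10, 0.20))
  phihat <- t(apply(phi, 1, function(p) {
    alt <- matrix(rbinom(8 * length(days), 3000, rep(p, each = 8) / 2), 8)
    2 * colMeans(alt / 3000)
  }))
  rownames(phihat) <- rownames(phi)
  tree <- build_tree(phihat, days)
  pa <- tree$edges$parent[match(c("desc", "rise1", "rise2"),
                                tree$edges$child)]
  expect_equal(pa, c("founder", "founder", "rise1"))
  expect_true(validate_clone_tree(tree))
  # later-emerging child: detection day ordering is exposed per edge
  fd <- tree$edges$child_first_detected
  expect_gt(fd[tree$edges$child == "rise2"],
            fd[tree$edges$child == "rise1"])
})

test_that("emergence detection needs the floor plus a sustained rise", {
  days <- c(0, 30, 60, 90, 120)
  expect_equal(detect_emergence(c(0, 0, 0.02, 0.05, 0.1), days), 60)
  expect_true(is.na(detect_emergence(c(0.3, 0.25, 0.2, 0.1, 0.05), days)))
  expect_true(is.na(detect_emergence(rep(0.005, 5), days)))
  # a rise of one interval only is not enough at rise_points = 2
  expect_true(is.na(detect_emergence(c(0, 0.05, 0.04, 0.03, 0.02), days)))
})

test_that("lead time is PD day minus emergence day, NA-safe", {
  expect_equal(compute_lead_time(86, 212), 126)
  expect_equal(compute_lead_time(212, 212), 0)
  expect_equal(compute_lead_time(250, 212), -38)
  expect_true(is.na(compute_lead_time(NA, 212)))
  expect_true(is.na(compute_lead_time(86, NA)))
})

test_that("lesion association reports sign agreement per cluster", {
  tr <- data.frame(patient_id = "P1",
                   cluster = rep(c("clone1", "clone2"), each = 3),
                   day = rep(c(0, 30, 60), 2),
                   phi = c(0.4, 0.3, 0.2, 0.01, 0.05, 0.10))
  scans <- data.frame(day = c(0, 30, 60),
                      diameter_sum_cm = c(10, 8, 6))
  out <- lesion_association(tr, scans)
  expect_equal(out$sign_agreement[out$cluster == "clone1"], 1)
  expect_equal(out$sign_agreement[out$cluster == "clone2"], 0)
})
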