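#' Simulation settings for a synthetic serial-ctDNA cohort
#'
#' Defaults emulate the study design the pipeline targets: about 12 patients
#' with 2-7 serial plasma samples drawn every 2-5 weeks, sequenced at about
#' 3000x deduplicated depth over a 329-gene / 637-kb panel, with 2-5 clones
#' per patient, germline heterozygous SNPs present in population databases,
#' CHIP variants detectable in white blood cells, rare private germline
#' variants that escape both, and lesion diameters positively coupled to the
#' circulating tumor fraction. Response archetypes follow the cohort mix
#' (PR 5 / SD 6 / PD 1 among 12), with relapse-after-response patients whose
#' resistance clone becomes molecularly detectable 60-120 days before the
#' radiological progression it causes.
#'
#' @param n_patients cohort size (default 12).
#' @param depth_mean mean deduplicated depth (default 3000).
#' @param panel_bp panel territory in bp (default 637000).
#' @param n_clones_range clones per patient (default 2:5).
#' @param founder_mut_mean,subclone_mut_mean Poisson means for mutation
#'   counts (founder: 2 + Pois; subclone: 1 + Pois); defaults 4 and 2 give
#'   about 13-14 somatic mutations per patient, matching a cohort-median
#'   bTMB near 21/Mb on the 637-kb panel.
#' @param n_germline common germline het SNPs per patient (default 5).
#' @param n_chip CHIP variants per patient (default 2).
#' @param n_private_germline germline variants that escape both the
#'   population database and the WBC evidence (default 1).
#' @param archetype_probs named probabilities over
#'   `responder`/`stable`/`progressor`/`relapse`.
#' @param timepoint_counts,timepoint_probs distribution of serial sample
#'   counts per patient.
#' @param interval_range days between consecutive samples (default 14-35).
#' @param lead_range days between resistance-clone detectability and the
#'   planted radiological progression (default 60-120).
#' @param min_alt_detect alt reads required for a call to be emitted
#'   (default 3).
#' @param cn_event_rate fraction of somatic mutations placed on a
#'   copy-number event (default 0.1).
#' @param chip_vaf_range plasma VAF range of CHIP variants.
#' @param diameter_noise_sd multiplicative lognormal-scale noise on lesion
#'   diameters (default 0.04).
#' @param timepoints_per_patient optional explicit vector of sample counts.
#' @param archetypes optional explicit vector of archetypes.
#' @return list of settings of class `sim_config`.
#' @export
sim_config <- function(n_patients = 12, depth_mean = 3000,
                       panel_bp = 637000, n_clones_range = 2:5,
                       founder_mut_mean = 4, subclone_mut_mean = 2,
                       n_germline = 5, n_chip = 2, n_private_germline = 1,
                       archetype_probs = c(responder = 3, stable = 6,
                                           progressor = 1, relapse = 2) / 12,
                       timepoint_counts = 2:7,
                       timepoint_probs = c(.55, .10, .10, .10, .10, .05),
                       interval_range = c(14, 35), lead_range = c(60, 120),
                       min_alt_detect = 3, cn_event_rate = 0.1,
                       chip_vaf_range = c(0.005, 0.03),
                       diameter_noise_sd = 0.04,
                       timepoints_per_patient = NULL, archetypes = NULL) {
  cfg <- as.list(environment())
  stopifnot(n_patients >= 1, depth_mean > 0, panel_bp > 0,
            all(n_clones_range >= 1))
  class(cfg) <- "sim_config"
  cfg
}

#' The bundled synthetic gene panel
#'
#' A 329-symbol list decorating simulated variants: a core of well-known
#' lung-cancer genes plus synthetic filler symbols (`PANX...`). It is a
#' synthetic stand-in, not any assay's real design.
#'
#' @return character vector of 329 gene symbols.
#' @export
panel_genes <- function() {
  read.delim(system.file("extdata", "panel_genes.tsv",
                         package = "ctdnaclone"),
             stringsAsFactors = FALSE)$gene
}

#' Simulate a random rooted clone tree
#'
#' Clone 1 is the founder; each later clone attaches uniformly to an earlier
#' one, so parent-child nesting is guaranteed by construction.
#'
#' @param n_clones number of clones (>= 1).
#' @param seed optional seed (set it for standalone reproducibility; inside
#'   [simulate_cohort()] the cohort seed governs).
#' @return list with `parent` (integer vector; `NA` for the founder).
#' @export
simulate_clone_tree <- function(n_clones, seed = NULL) {
  if (n_clones < 1) stop("n_clones must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  parent <- rep(NA_integer_, n_clones)
  if (n_clones >= 2)
    for (k in 2:n_clones)
      parent[k] <- if (k == 2) 1L else sample.int(k - 1L, 1L)
  list(parent = parent)
}

#' Simulate per-clone cellular-prevalence trajectories
#'
#' The founder follows the archetype: exponential decay (`responder`), mild
#' fluctuation (`stable`), exponential growth (`progressor`), or
#' decay-then-regrowth driven by a resistance clone (`relapse`; clone 2,
#' always a child of the founder, rises logistically and crosses the 1%
#' detectability floor at the planted emergence day). Every other clone
#' receives a time-varying fraction of its parent's divisible mass with
#' alternating trend directions for siblings; sibling fractions are capped
#' so that children sum to at most their parent everywhere, so the crossing
#' and sum-up constraints hold exactly by construction.
#'
#' @param tree from [simulate_clone_tree()].
#' @param archetype one of `responder`, `stable`, `progressor`, `relapse`.
#' @param days ordered sampling days.
#' @param emergence_day planted detectability day of the resistance clone
#'   (required for `relapse`).
#' @return matrix (clones x days) of prevalences, with attributes
#'   `tumor_fraction` (founder trajectory), `decay` (founder mass net of the
#'   resistance clone) and `resistance_clone`.
#' @export
simulate_trajectories <- function(tree, archetype, days,
                                  emergence_day = NULL) {
  stopifnot(!is.unsorted(days))
  K <- length(tree$parent); TT <- length(days)
  archetype <- match.arg(archetype,
                         c("responder", "stable", "progressor", "relapse"))
  phi <- matrix(0, K, TT, dimnames = list(paste0("clone", seq_len(K)), days))
  resistance <- NA_integer_

  if (archetype == "responder") {
    phi0 <- exp(runif(1, log(0.10), log(0.96)))
    h <- runif(1, 20, 40)
    founder <- phi0 * 2^(-days / h)
    decay <- founder
  } else if (archetype == "stable") {
    phi0 <- exp(runif(1, log(0.03), log(0.35)))
    founder <- phi0 * exp(runif(TT, -0.08, 0.08))
    decay <- founder
  } else if (archetype == "progressor") {
    phi0 <- exp(runif(1, log(0.03), log(0.30)))
    dbl <- runif(1, 40, 80)
    founder <- pmin(0.9, phi0 * 2^(days / dbl))
    decay <- founder
  } else {
    if (is.null(emergence_day))
      stop("relapse archetype needs an emergence_day")
    if (K < 2) stop("relapse archetype needs at least 2 clones")
    phi0 <- exp(runif(1, log(0.10), log(0.80)))
    h <- runif(1, 18, 30)
    R <- runif(1, 0.20, 0.50)
    s <- 12
    t50 <- emergence_day + s * log(R / 0.01 - 1)
    r <- R / (1 + exp(-(days - t50) / s))
    decay <- phi0 * 2^(-days / h)
    founder <- decay + r
    phi[2, ] <- r
    resistance <- 2L
  }
  phi[1, ] <- founder

  # divisible mass per node: what children other than a planted resistance
  # clone may share
  base <- vector("list", K)
  base[[1]] <- decay
  if (!is.na(resistance)) base[[resistance]] <- phi[resistance, ]
  span <- max(days) - min(days) + 1
  for (p in seq_len(K)) {
    kids <- which(tree$parent == p)
    if (!is.na(resistance)) kids <- setdiff(kids, resistance)
    if (!length(kids)) next
    w0 <- runif(length(kids), 0.20, 0.50)
    sl <- runif(length(kids), 0.5, 1.5) / span *
      rep_len(c(1, -1), length(kids))                # diverging siblings
    w <- vapply(seq_along(kids), function(j)
      w0[j] * exp(sl[j] * (days - days[1])), numeric(TT))
    w <- matrix(w, nrow = TT)
    cap <- pmin(1, 0.9 / rowSums(w))
    w <- w * cap
    for (j in seq_along(kids)) {
      phi[kids[j], ] <- w[, j] * base[[p]]
      base[[kids[j]]] <- phi[kids[j], ]
    }
  }
  attr(phi, "tumor_fraction") <- founder
  attr(phi, "decay") <- decay
  attr(phi, "resistance_clone") <- resistance
  phi
}

# is `a` an ancestor of `b` (or equal) in a parent-vector tree?
is_ancestor <- function(parent, a, b) {
  while (!is.na(b)) {
    if (b == a) return(TRUE)
    b <- parent[b]
  }
  FALSE
}

#' Simulate an identifiable planted clone tree with trajectories
#'
#' Draws a random rooted tree and prevalence trajectories constructed so the
#' crossing and sum-up rules can identify the topology from data: siblings
#' share their parent's mass with trends that meet mid-course and diverge
#' (so every sibling pair crosses), children of a node jointly take 85-95%
#' of its mass (so foreign clones cannot be inserted without violating the
#' sum-up rule), and draws are rejected until every pair of non-nested
#' lineages mutually crosses by more than `2 * epsilon`. Lineages closer
#' than the tolerance everywhere are not topologically identifiable by these
#' rules, so such instances are excluded by construction; this is the
#' regime the tree-recovery guarantees refer to.
#'
#' @param n_clones clones including the founder (>= 1).
#' @param days sampling days.
#' @param epsilon tree-builder tolerance the instance must clear
#'   (default 0.02).
#' @param max_tries rejection-sampling cap (default 200).
#' @return list with `tree` (parent vector), `phi` (clones x days) and
#'   `attempts`.
#' @export
simulate_planted_tree <- function(n_clones, days, epsilon = 0.02,
                                  max_tries = 200) {
  stopifnot(n_clones >= 1, length(days) >= 2)
  TT <- length(days); span <- max(days) - min(days)
  tree <- NULL; phi <- NULL
  for (att in seq_len(max_tries)) {
    tree <- simulate_clone_tree(n_clones)
    phi0 <- runif(1, 0.55, 0.9)
    founder <- pmin(0.95, phi0 * 2^(sample(c(-1, 1), 1) * days / 90))
    phi <- matrix(0, n_clones, TT,
                  dimnames = list(paste0("clone", seq_len(n_clones)), days))
    phi[1, ] <- founder
    for (p in seq_len(n_clones)) {
      kids <- which(tree$parent == p)
      if (!length(kids)) next
      m <- length(kids)
      s <- if (m == 1) runif(1, -1, 1) / span
        else (seq_len(m) - (m + 1) / 2) * runif(1, 2.4, 3.6) /
          max(1, m - 1) / span
      u <- exp(-s * span / 2)            # siblings meet at mid-course
      w <- vapply(seq_len(m), function(j)
        u[j] * exp(s[j] * (days - days[1])), numeric(TT))
      w <- matrix(w, nrow = TT)
      w <- w * (runif(1, 0.85, 0.95) / rowSums(w))
      for (j in seq_len(m)) phi[kids[j], ] <- w[, j] * phi[p, ]
    }
    identifiable <- TRUE
    for (a in seq_len(n_clones)) for (b in seq_len(n_clones)) {
      if (a >= b) next
      if (is_ancestor(tree$parent, a, b) ||
          is_ancestor(tree$parent, b, a)) next
      if (!(any(phi[a, ] > phi[b, ] + 2 * epsilon) &&
            any(phi[b, ] > phi[a, ] + 2 * epsilon)))
        identifiable <- FALSE
    }
    if (identifiable)
      return(list(tree = tree, phi = phi, attempts = att))
  }
  list(tree = tree, phi = phi, attempts = max_tries)
}

# Random loci over a synthetic panel coordinate space.
random_loci <- function(n, genes) {
  bases <- c("A", "C", "G", "T")
  chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
  pos <- sample.int(5e7, n)
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             gene = sample(genes, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Simulate read counts for planted variants over a sampling schedule
#'
#' Per variant and day: depth ~ Poisson(`depth_mean`), alt reads ~
#' Binomial(depth, p) with `p = phi * m / c` for somatic variants (m = 1,
#' total copy number from the planted logR), 0.5 for germline variants and
#' the fixed plasma VAF for CHIP variants. Calls with fewer than
#' `min_alt_detect` alt reads are not emitted (below the caller's detection
#' floor), except that variants with a true VAF of 0.5 (germline) are always
#' emitted.
#'
#' @param variants planted variant table with columns `chrom`, `pos`, `ref`,
#'   `alt`, `gene`, `effect`, `logr`, `origin`, `clone`, `true_vaf_fixed`
#'   (NA for somatic).
#' @param phi clone-prevalence matrix (clones x days).
#' @param days sampling days.
#' @param depth_mean mean depth.
#' @param min_alt_detect emission threshold on alt reads.
#' @return list of per-day variant tables (calls actually emitted).
#' @export
simulate_reads <- function(variants, phi, days, depth_mean = 3000,
                           min_alt_detect = 3) {
  cn <- discretize_copy_number(variants$logr)
  lapply(seq_along(days), function(t) {
    p <- ifelse(is.na(variants$clone),
                variants$true_vaf_fixed,
                phi[cbind(variants$clone, t)] / cn)
    depth <- rpois(nrow(variants), depth_mean)
    depth[depth == 0] <- 1L
    alt <- rbinom(nrow(variants), depth, p)
    keep <- alt >= min_alt_detect
    data.frame(chrom = variants$chrom[keep], pos = variants$pos[keep],
               ref = variants$ref[keep], alt = variants$alt[keep],
               alt_reads = alt[keep], ref_reads = (depth - alt)[keep],
               vaf = (alt / depth)[keep], gene = variants$gene[keep],
               effect = variants$effect[keep], logr = variants$logr[keep],
               filter_status = "PASS", review_flag = FALSE,
               stringsAsFactors = FALSE)
  })
}

# Scan response labels from lesion-diameter sums. `diameters` includes the
# baseline (day 0) first. PR: >= 30% decrease from baseline; PD: >= 20%
# increase from the nadir so far (baseline included); PD wins when both
# hold; otherwise SD. Returns labels for the on-treatment scans.
response_labels <- function(diameters) {
  base <- diameters[1]
  labels <- character(length(diameters) - 1)
  nadir <- base
  for (i in seq_along(labels)) {
    d <- diameters[i + 1]
    labels[i] <- if (d >= 1.2 * nadir) "PD"
      else if (d <= 0.7 * base) "PR" else "SD"
    nadir <- min(nadir, d)
  }
  labels
}

#' Simulate the clinical course of one patient from its trajectories
#'
#' Lesion diameters are positively coupled to the tumor fraction with a
#' radiological delay: the CT-visible burden at day `t` reflects the
#' molecular shrinkage about three weeks earlier, and for relapse patients
#' the regrowth caused by the resistance clone becomes measurable only at
#' the planted progression day (the planted lead time after the clone's
#' molecular emergence). Response labels follow thresholded
#' response-criteria rules: PR at a 30% diameter decrease from baseline, PD
#' at a 20% increase from the nadir, SD otherwise.
#'
#' @param days scan days (same visits as the blood draws; day 0 = baseline).
#' @param tumor_fraction founder-prevalence trajectory over `days`.
#' @param archetype patient archetype.
#' @param baseline_cm baseline diameter sum.
#' @param pd_planned planted radiological progression day (relapse only).
#' @param noise_sd multiplicative diameter noise.
#' @param decay founder trajectory net of the resistance clone (relapse
#'   only; the CT-visible shrinkage component). Defaults to
#'   `tumor_fraction`.
#' @return list with `scans` (data.frame `day`, `diameter_sum_cm`,
#'   `response`; baseline row has `NA` response), `best_response`,
#'   `pfs_days`, `event`, `pd_day`.
#' @export
simulate_clinical <- function(days, tumor_fraction, archetype, baseline_cm,
                              pd_planned = NA, noise_sd = 0.04,
                              decay = tumor_fraction) {
  tf0 <- tumor_fraction[1]
  lag <- 21
  if (archetype == "relapse" && !is.na(pd_planned)) {
    # CT sees only the shrinking disease until the planted progression day,
    # when the resistance clone's regrowth becomes measurable
    d_lagged <- stats::approx(days, decay, pmax(0, days - lag), rule = 2)$y
    growth <- ifelse(days >= pd_planned,
                     0.15 + 0.012 * (days - pd_planned), 0)
    ratio <- 0.3 + 0.7 * d_lagged / tf0 + growth
  } else {
    tf_lagged <- stats::approx(days, tumor_fraction, pmax(0, days - lag),
                               rule = 2)$y
    ratio <- 0.3 + 0.7 * tf_lagged / tf0
  }
  diam <- baseline_cm * ratio * exp(rnorm(length(days), 0, noise_sd))
  diam[1] <- baseline_cm
  labels <- response_labels(diam)
  pd_day <- if (any(labels == "PD"))
    days[-1][which(labels == "PD")[1]] else NA_integer_
  event <- !is.na(pd_day)
  scans <- data.frame(day = days, diameter_sum_cm = round(diam, 2),
                      response = c(NA, labels), stringsAsFactors = FALSE)
  list(scans = scans, best_response = best_response(labels),
       pfs_days = if (event) pd_day else max(days), event = event,
       pd_day = pd_day)
}

#' Simulate a complete synthetic serial-ctDNA cohort with ground truth
#'
#' Draws, per patient: a response archetype, a sampling schedule, a clone
#' tree with prevalence trajectories, planted somatic mutations (with
#' occasional copy-number events), common germline SNPs (entered into the
#' population database), CHIP variants (entered into the white-blood-cell
#' evidence), private germline variants (escaping both), ultra-deep read
#' counts, and a clinical course coupled to the tumor fraction. The same
#' config and seed give identical output.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (mandatory).
#' @return object of class `ctdna_cohort`: list with `series` (named list of
#'   [patient_series]), `popdb`, `normal_evidence`, `clinical`, `scans`,
#'   `truth` (per-patient ground truth), `config`, `seed`.
#' @export
simulate_cohort <- function(config = sim_config(), seed) {
  if (missing(seed)) stop("simulate_cohort requires a seed")
  set.seed(seed)
  genes <- panel_genes()
  drivers <- c("TP53", "CDKN2A")
  effects_p <- c(nonsynonymous = .55, synonymous = .20, frameshift = .05,
                 inframe_indel = .03, intronic = .12, other = .05)

  series <- list(); truth <- list()
  popdb_rows <- list(); normal_rows <- list()
  clin_rows <- list(); scan_rows <- list()

  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", i)
    archetype <- if (!is.null(config$archetypes)) config$archetypes[i]
      else sample(names(config$archetype_probs), 1,
                  prob = config$archetype_probs)

    # schedule
    n_tp <- if (!is.null(config$timepoints_per_patient))
      config$timepoints_per_patient[i]
      else sample(config$timepoint_counts, 1, prob = config$timepoint_probs)
    if (archetype == "relapse") n_tp <- max(n_tp, 5L)
    intervals <- round(runif(n_tp - 1, config$interval_range[1],
                             config$interval_range[2]))
    days <- as.integer(cumsum(c(0, intervals)))
    emergence <- pd_planned <- NA_integer_
    if (archetype == "relapse") {
      emergence <- round(runif(1, 25, 70))
      lead <- round(runif(1, config$lead_range[1], config$lead_range[2]))
      pd_planned <- emergence + lead
      while (max(days) < pd_planned + 14) {
        days <- c(days, max(days) +
                    round(runif(1, config$interval_range[1],
                                config$interval_range[2])))
      }
      days <- as.integer(days)
      n_tp <- length(days)
    }

    # clones, trajectories, mutations
    n_clones <- sample(config$n_clones_range, 1)
    if (archetype == "relapse") n_clones <- max(n_clones, 2L)
    tree <- simulate_clone_tree(n_clones)
    phi <- simulate_trajectories(tree, archetype, days,
                                 emergence_day = emergence)
    n_mut <- c(2 + rpois(1, config$founder_mut_mean),
               1 + rpois(max(0, n_clones - 1), config$subclone_mut_mean))
    clone_of <- rep(seq_len(n_clones), n_mut)
    som <- random_loci(sum(n_mut), genes)
    som$gene[1:2] <- drivers                    # founder carries drivers
    som$effect <- sample(names(effects_p), nrow(som), replace = TRUE,
                         prob = effects_p)
    cn_state <- sample(c(1L, 2L, 3L), nrow(som), replace = TRUE,
                       prob = c(config$cn_event_rate / 2,
                                1 - config$cn_event_rate,
                                config$cn_event_rate / 2))
    som$logr <- ifelse(cn_state == 1L, rnorm(nrow(som), -0.5, 0.05),
                ifelse(cn_state == 3L, rnorm(nrow(som), 0.5, 0.05),
                       rnorm(nrow(som), 0, 0.05)))
    som$origin <- "somatic"; som$clone <- clone_of
    som$true_vaf_fixed <- NA_real_

    gl <- random_loci(config$n_germline, genes)
    gl$effect <- sample(names(effects_p), nrow(gl), replace = TRUE,
                        prob = effects_p)
    gl$logr <- rnorm(nrow(gl), 0, 0.05)
    gl$origin <- "common_germline"; gl$clone <- NA_integer_
    gl$true_vaf_fixed <- 0.5

    chip <- random_loci(config$n_chip, genes)
    chip$effect <- "nonsynonymous"
    chip$logr <- rnorm(nrow(chip), 0, 0.05)
    chip$origin <- "chip"; chip$clone <- NA_integer_
    chip$true_vaf_fixed <- runif(config$n_chip, config$chip_vaf_range[1],
                                 config$chip_vaf_range[2])

    pg <- random_loci(config$n_private_germline, genes)
    pg$effect <- sample(names(effects_p), nrow(pg), replace = TRUE,
                        prob = effects_p)
    pg$logr <- rnorm(nrow(pg), 0, 0.05)
    pg$origin <- "private_germline"; pg$clone <- NA_integer_
    pg$true_vaf_fixed <- 0.5

    planted <- rbind(som, gl, chip, pg)
    planted <- planted[!duplicated(variant_key(planted)), , drop = FALSE]
    tabs <- simulate_reads(planted, phi, days, config$depth_mean,
                           config$min_alt_detect)
    series[[pid]] <- patient_series(pid, days, tabs)

    popdb_rows[[pid]] <- data.frame(
      gl[c("chrom", "pos", "ref", "alt")],
      pop_af = pmin(0.5, 10^runif(nrow(gl), -3, -0.3)),
      stringsAsFactors = FALSE)
    normal_rows[[pid]] <- rbind(
      data.frame(chip[c("chrom", "pos", "ref", "alt")],
                 wbc_alt_reads = 3L + rpois(nrow(chip), 8),
                 stringsAsFactors = FALSE),
      data.frame(gl[c("chrom", "pos", "ref", "alt")],
                 wbc_alt_reads = 10L + rpois(nrow(gl), 30),
                 stringsAsFactors = FALSE))

    # clinical course
    tf <- attr(phi, "tumor_fraction")
    baseline_cm <- round((2.5 + 20 * tf[1]) * exp(rnorm(1, 0, 0.15)), 1)
    clin <- simulate_clinical(days, tf, archetype, baseline_cm,
                              pd_planned, config$diameter_noise_sd,
                              decay = attr(phi, "decay"))
    smoking <- if (runif(1) < 0.25) 0L else
      as.integer(round(runif(1, 400, 1500) / 50) * 50)
    clin_rows[[pid]] <- data.frame(
      patient_id = pid,
      stage = sample(c("IV", "III"), 1, prob = c(11, 1)),
      smoking_index = smoking,
      diameter_sum_cm = baseline_cm,
      best_response = clin$best_response,
      pfs_days = clin$pfs_days, event = clin$event,
      stringsAsFactors = FALSE)
    sc <- clin$scans; sc$patient_id <- pid
    scan_rows[[pid]] <- sc[c("patient_id", "day", "diameter_sum_cm",
                             "response")]

    truth[[pid]] <- list(
      archetype = archetype, parent = tree$parent, phi = phi, days = days,
      variants = data.frame(key = variant_key(planted),
                            origin = planted$origin, clone = planted$clone,
                            logr = planted$logr,
                            stringsAsFactors = FALSE),
      emergence_day = emergence, pd_planned = pd_planned,
      pd_day = clin$pd_day)
  }

  popdb <- do.call(rbind, popdb_rows)
  popdb$key <- variant_key(popdb)
  normal <- do.call(rbind, normal_rows)
  normal$key <- variant_key(normal)
  rownames(popdb) <- rownames(normal) <- NULL
  clinical <- do.call(rbind, clin_rows); rownames(clinical) <- NULL
  scans <- do.call(rbind, scan_rows); rownames(scans) <- NULL

  structure(list(series = series, popdb = popdb, normal_evidence = normal,
                 clinical = clinical, scans = scans, truth = truth,
                 config = config, seed = seed),
            class = "ctdna_cohort")
}

#' @export
print.ctdna_cohort <- function(x, ...) {
  n_samp <- sum(vapply(x$series, function(s) length(s$days), integer(1)))
  cat("<ctdna_cohort> ", length(x$series), " patients, ", n_samp,
      " samples (seed ", x$seed, ")\n", sep = "")
  cat("archetypes: ", paste(vapply(x$truth, `[[`, "", "archetype"),
                            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Emits one plain-text VCF per sample, the sample sheet, the population-DB
#' and WBC-evidence tables, the clinical and per-scan tables, and the
#' ground-truth JSON.
#'
#' @param cohort a `ctdna_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "vcf"), showWarnings = FALSE)
  sheet <- list()
  for (pid in names(cohort$series)) {
    s <- cohort$series[[pid]]
    for (d in s$days) {
      v <- s$variants[s$variants$day == d, , drop = FALSE]
      path <- file.path("vcf", sprintf("%s_day%03d.vcf", pid, d))
      write_vcf(v, file.path(dir, path), sample_id = pid)
      sheet[[length(sheet) + 1L]] <- data.frame(
        patient_id = pid, day = d, vcf_path = path,
        stringsAsFactors = FALSE)
    }
  }
  wt <- function(df, name) write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(do.call(rbind, sheet), "sample_sheet.tsv")
  wt(cohort$popdb[setdiff(names(cohort$popdb), "key")], "popdb.tsv")
  wt(cohort$normal_evidence[setdiff(names(cohort$normal_evidence), "key")],
     "normal_evidence.tsv")
  wt(cohort$clinical, "clinical.tsv")
  wt(cohort$scans, "scans.tsv")
  truth <- lapply(cohort$truth, function(tr) {
    tr$phi <- as.data.frame(tr$phi)
    tr
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' Planted null band for a patient's per-sample MSAF
#'
#' MSAF is a maximum over the passing calls of a sample, taken after a
#' filter that itself depends on the read draws, so its sampling
#' distribution under the planted model is wider and upward-shifted relative
#' to a single binomial draw at the top clone's expected VAF. This function
#' simulates that null exactly: for each Monte-Carlo replicate it draws alt
#' reads for every planted somatic variant at its expected VAF
#' (`phi * m / c`), applies the detection floor and the patient-combined
#' "VAF above 20% at every time point" removal, and records the per-day
#' maximum VAF. Germline and CHIP variants are excluded (the population-DB
#' and WBC filters remove them deterministically).
#'
#' @param truth one patient's entry of a `ctdna_cohort`'s `truth` list.
#' @param depth_mean sequencing depth used for the draws (default 3000).
#' @param n_rep Monte-Carlo replicates (default 4000).
#' @param level two-sided tail mass cut at each side, default
#'   `pnorm(-3)` (the 3-sigma equivalent).
#' @param min_alt_detect detection floor on alt reads (default 3).
#' @param vaf_threshold combined-VAF removal threshold (default 0.20).
#' @return matrix with one row per day and columns `lower`, `upper`.
#' @export
planted_msaf_band <- function(truth, depth_mean = 3000, n_rep = 4000,
                              level = stats::pnorm(-3), min_alt_detect = 3,
                              vaf_threshold = 0.20) {
  som <- truth$variants[truth$variants$origin == "somatic", , drop = FALSE]
  TT <- length(truth$days)
  if (nrow(som) == 0)
    return(matrix(0, TT, 2, dimnames = list(truth$days,
                                            c("lower", "upper"))))
  cn <- discretize_copy_number(som$logr)
  p <- truth$phi[som$clone, , drop = FALSE] / cn   # expected VAF, var x day
  k <- nrow(som)
  msaf_null <- matrix(0, n_rep, TT)
  for (r in seq_len(n_rep)) {
    alt <- matrix(rbinom(k * TT, depth_mean, p), k, TT)
    vaf <- alt / depth_mean
    det <- alt >= min_alt_detect
    removed <- rowSums(det & vaf > vaf_threshold) == TT
    use <- det & !removed
    vaf[!use] <- 0
    msaf_null[r, ] <- apply(vaf, 2, max)
  }
  band <- t(apply(msaf_null, 2, stats::quantile,
                  probs = c(level, 1 - level), names = FALSE))
  dimnames(band) <- list(truth$days, c("lower", "upper"))
  band
}
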