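#' Sampler settings for the Dirichlet-process binomial mixture
#'
#' @param alpha Chinese-restaurant-process concentration (default 1).
#' @param iterations total Gibbs sweeps (default 5000).
#' @param burnin sweeps discarded before recording (default 1000).
#' @param thin record every `thin`-th sweep after burn-in (default 5).
#' @param grid_size number of grid points used for the cellular-prevalence
#'   conditional draws and marginal integrals (default 512; resolution
#'   ~0.002, below the binomial noise floor at 3000x depth).
#' @param consensus_cut similarity level at which the average-linkage
#'   consensus dendrogram is cut (default 0.5).
#' @return list of settings.
#' @export
dp_control <- function(alpha = 1, iterations = 5000, burnin = 1000,
                       thin = 5, grid_size = 512, consensus_cut = 0.5) {
  stopifnot(alpha > 0, iterations > burnin, thin >= 1, grid_size >= 16)
  list(alpha = alpha, iterations = as.integer(iterations),
       burnin = as.integer(burnin), thin = as.integer(thin),
       grid_size = as.integer(grid_size), consensus_cut = consensus_cut)
}

# Per-time-point log-likelihood grids: list over t of n x G matrices with
# entry [i, g] = log Binom(a_it | n_it, phi_g * m_i / c_i), dropping the
# binomial coefficient (it cancels in every comparison made with these).
loglik_grids <- function(alt, depth, cn, multiplicity, grid) {
  n <- nrow(alt); TT <- ncol(alt)
  lapply(seq_len(TT), function(t) {
    p <- outer(multiplicity / cn, grid)          # n x G success probs
    alt[, t] * log(p) + (depth[, t] - alt[, t]) * log1p(-p)
  })
}

#' Cluster mutations into clones with a Dirichlet-process binomial mixture
#'
#' Fits the model: mutation `i` in cluster `k` at time point `t` has
#' `alt[i,t] ~ Binomial(depth[i,t], phi[k,t] * m_i / c_i)` where `phi[k,t]`
#' is the cluster's cellular prevalence with a Uniform(0,1) prior and the
#' partition follows a Chinese-restaurant process with concentration
#' `alpha`. Inference is by Gibbs sampling (prevalences drawn from a
#' discretized conditional on a fixed grid; partition updated one mutation
#' at a time, integrating the prevalence out on the same grid for new
#' clusters). The reported partition is the consensus from the posterior
#' similarity matrix (average linkage, dendrogram cut at similarity
#' `consensus_cut`), and the reported prevalences are posterior means given
#' the consensus partition. Identical seed and inputs give identical output.
#'
#' @param alt integer matrix (mutations x time points) of alt read counts; a
#'   mutation undetected at a time point contributes 0 there.
#' @param depth matrix of total read counts (same shape).
#' @param cn integer vector of total copy numbers per mutation (1, 2 or 3).
#' @param days integer vector of sampling days (column labels).
#' @param control sampler settings from [dp_control()].
#' @param seed RNG seed (required: the fit must be reproducible).
#' @param multiplicity mutated-copy count per mutation (default 1).
#' @param keys optional mutation identifiers (rownames used if absent).
#' @return object of class `clone_fit` with elements `assignments` (named
#'   integer vector), `phi` (clusters x time points posterior means),
#'   `phi_lower`/`phi_upper` (95% credible bounds), `n_clusters`, `psm`,
#'   `diagnostics`, `days`, and the model inputs.
#' @export
dp_cluster <- function(alt, depth, cn, days, control = dp_control(),
                       seed, multiplicity = 1, keys = NULL) {
  alt <- as.matrix(alt); depth <- as.matrix(depth)
  n <- nrow(alt); TT <- ncol(alt)
  stopifnot(n >= 1, TT >= 1, all(dim(depth) == dim(alt)),
            length(cn) == n, all(cn %in% 1:3), length(days) == TT)
  if (missing(seed)) stop("dp_cluster requires an explicit seed")
  if (any(alt > depth)) stop("alt reads exceed depth")
  if (length(multiplicity) == 1) multiplicity <- rep(multiplicity, n)
  if (any(multiplicity > cn)) stop("multiplicity exceeds total copy number")
  if (is.null(keys)) keys <- rownames(alt)
  if (is.null(keys)) keys <- paste0("mut", seq_len(n))

  set.seed(seed)
  G <- control$grid_size
  grid <- (seq_len(G) - 0.5) / G
  Lg <- loglik_grids(alt, depth, cn, multiplicity, grid)
  # marginal log-likelihood of a singleton cluster, phi integrated out per t
  logM <- vapply(seq_len(n), function(i) {
    sum(vapply(Lg, function(L) logmeanexp(L[i, ]), numeric(1)))
  }, numeric(1))

  draw_phi <- function(members) {
    # one draw of phi_t | members, per time point, from the grid posterior
    vapply(Lg, function(L) {
      lw <- if (length(members) == 1) L[members, ] else colSums(L[members, ])
      grid[sample.int(G, 1L, prob = exp(lw - max(lw)))]
    }, numeric(1))
  }

  # init: every mutation in one cluster
  z <- rep(1L, n)
  phi <- matrix(draw_phi(seq_len(n)), nrow = 1)
  la <- log(control$alpha)

  keep <- seq(control$burnin + 1L, control$iterations, by = control$thin)
  Z <- matrix(0L, nrow = length(keep), ncol = n)
  k_trace <- integer(length(keep))
  rec <- 0L

  for (it in seq_len(control$iterations)) {
    for (i in seq_len(n)) {
      # detach mutation i
      sizes <- tabulate(z, nbins = max(z))
      sizes[z[i]] <- sizes[z[i]] - 1L
      if (sizes[z[i]] == 0L) {        # drop the emptied cluster
        gone <- z[i]
        phi <- phi[-gone, , drop = FALSE]
        z[z > gone] <- z[z > gone] - 1L
        sizes <- sizes[-gone]
      }
      z[i] <- NA_integer_
      K <- nrow(phi)
      if (K > 0L) {
        p <- phi * (multiplicity[i] / cn[i])     # K x T
        ll <- as.vector(log(p) %*% alt[i, ] +
                          log1p(-p) %*% (depth[i, ] - alt[i, ]))
        logw <- c(log(sizes) + ll, la + logM[i])
      } else {
        logw <- la + logM[i]
      }
      pick <- sample.int(K + 1L, 1L, prob = exp(logw - max(logw)))
      if (pick > K) {
        z[i] <- K + 1L
        phi <- rbind(phi, draw_phi(i))
      } else z[i] <- pick
    }
    # refresh cluster prevalences
    for (k in seq_len(max(z))) phi[k, ] <- draw_phi(which(z == k))
    if (it > control$burnin && (it - control$burnin - 1L) %% control$thin == 0L) {
      rec <- rec + 1L
      Z[rec, ] <- z
      k_trace[rec] <- max(z)
    }
  }
  Z <- Z[seq_len(rec), , drop = FALSE]
  k_trace <- k_trace[seq_len(rec)]

  # posterior similarity and consensus partition
  psm <- Reduce(`+`, lapply(seq_len(rec), function(s) {
    outer(Z[s, ], Z[s, ], `==`) * 1
  })) / rec
  dimnames(psm) <- list(keys, keys)
  if (n == 1) {
    consensus <- 1L
  } else {
    hc <- stats::hclust(stats::as.dist(1 - psm), method = "average")
    consensus <- stats::cutree(hc, h = 1 - control$consensus_cut)
  }
  # relabel clusters by decreasing mean prevalence
  post <- cluster_phi_posterior(Lg, consensus, grid)
  ord <- order(-rowMeans(post$mean))
  relab <- match(consensus, ord)
  post$mean <- post$mean[ord, , drop = FALSE]
  post$lower <- post$lower[ord, , drop = FALSE]
  post$upper <- post$upper[ord, , drop = FALSE]
  K <- nrow(post$mean)
  dimnames(post$mean) <- dimnames(post$lower) <- dimnames(post$upper) <-
    list(paste0("clone", seq_len(K)), days)

  structure(list(
    assignments = stats::setNames(relab, keys),
    phi = post$mean, phi_lower = post$lower, phi_upper = post$upper,
    n_clusters = K, psm = psm,
    diagnostics = list(k_trace = k_trace, k_table = table(k_trace),
                       n_samples = rec),
    days = as.integer(days), alt = alt, depth = depth, cn = cn,
    multiplicity = multiplicity, control = control, seed = seed),
    class = "clone_fit")
}

# Posterior mean and 95% interval of phi per cluster and time point, given a
# fixed partition, computed by numeric integration on the grid.
cluster_phi_posterior <- function(Lg, z, grid) {
  K <- max(z); TT <- length(Lg); G <- length(grid)
  m <- lo <- hi <- matrix(NA_real_, K, TT)
  for (k in seq_len(K)) {
    members <- which(z == k)
    for (t in seq_len(TT)) {
      lw <- if (length(members) == 1) Lg[[t]][members, ] else
        colSums(Lg[[t]][members, ])
      w <- exp(lw - max(lw)); w <- w / sum(w)
      m[k, t] <- sum(grid * w)
      cw <- cumsum(w)
      lo[k, t] <- grid[which(cw >= 0.025)[1]]
      hi[k, t] <- grid[which(cw >= 0.975)[1]]
    }
  }
  list(mean = m, lower = lo, upper = hi)
}

#' Cluster a patient's serial samples into clones
#'
#' Builds the alt/depth count matrices from a filtered [patient_series]
#' (passing variants only) and runs [dp_cluster()]. A variant absent from a
#' sample's calls contributes 0 alt reads with that sample's median depth as
#' the trial count. Total copy number per variant comes from its logR
#' annotation via [discretize_copy_number()]. Patients with fewer than
#' `min_timepoints` samples are rejected: serial information is what
#' identifies the clusters.
#'
#' @param series filtered [patient_series].
#' @param control sampler settings from [dp_control()].
#' @param seed RNG seed.
#' @param min_timepoints minimum number of samples (default 3).
#' @return a `clone_fit` (see [dp_cluster()]).
#' @export
cluster_series <- function(series, control = dp_control(), seed,
                           min_timepoints = 3) {
  stopifnot(inherits(series, "patient_series"))
  if (length(series$days) < min_timepoints)
    stop("patient ", series$patient_id, " has ", length(series$days),
         " time points; ", min_timepoints, " required")
  inp <- series_count_matrices(series)
  if (nrow(inp$alt) == 0)
    stop("patient ", series$patient_id, " has no passing variants")
  fit <- dp_cluster(inp$alt, inp$depth, inp$cn, series$days,
                    control = control, seed = seed, keys = inp$keys)
  fit$patient_id <- series$patient_id
  fit
}

# Passing-variant count matrices (variant x day) for one patient.
series_count_matrices <- function(series) {
  v <- series$variants[series$variants$filter_status == "PASS", ,
                       drop = FALSE]
  keys <- sort(unique(variant_key(v)))
  days <- series$days
  alt <- depth <- matrix(0L, length(keys), length(days),
                         dimnames = list(keys, days))
  med_depth <- vapply(days, function(d) {
    w <- v$day == d
    if (any(w)) as.integer(median(v$alt_reads[w] + v$ref_reads[w]))
    else 1000L
  }, integer(1))
  for (t in seq_along(days)) depth[, t] <- med_depth[t]
  key_all <- variant_key(v)
  for (r in seq_len(nrow(v))) {
    i <- match(key_all[r], keys); t <- match(v$day[r], days)
    alt[i, t] <- v$alt_reads[r]
    depth[i, t] <- v$alt_reads[r] + v$ref_reads[r]
  }
  logr <- vapply(keys, function(k) {
    x <- v$logr[key_all == k]
    x <- x[!is.na(x)]
    if (length(x)) x[1] else NA_real_
  }, numeric(1))
  list(alt = alt, depth = depth, cn = discretize_copy_number(logr),
       keys = keys)
}

#' Exhaustive MAP partition for small instances
#'
#' Enumerates every set partition of the mutations (feasible for n <= 8;
#' Bell(8) = 4140) and returns the maximum a posteriori partition under the
#' same likelihood as [dp_cluster()]: a Chinese-restaurant prior with
#' concentration `alpha` and, per block and time point, the binomial
#' likelihood with the cellular prevalence integrated over its Uniform(0,1)
#' prior on the grid. Serves as the small-instance reference for the Gibbs
#' consensus.
#'
#' @inheritParams dp_cluster
#' @param alpha concentration parameter (default 1).
#' @param grid_size integration grid size (default 512).
#' @return list with `partition` (canonical labels) and `log_post`.
#' @export
map_partition <- function(alt, depth, cn, alpha = 1, grid_size = 512,
                          multiplicity = 1) {
  alt <- as.matrix(alt); depth <- as.matrix(depth)
  n <- nrow(alt)
  if (n > 8) stop("exhaustive enumeration limited to n <= 8 mutations")
  if (length(multiplicity) == 1) multiplicity <- rep(multiplicity, n)
  grid <- (seq_len(grid_size) - 0.5) / grid_size
  Lg <- loglik_grids(alt, depth, cn, multiplicity, grid)
  block_ll <- function(members) {
    sum(vapply(Lg, function(L) {
      lw <- if (length(members) == 1) L[members, ] else colSums(L[members, ])
      logmeanexp(lw)
    }, numeric(1)))
  }
  best <- NULL; best_lp <- -Inf
  for (z in set_partitions(n)) {
    blocks <- split(seq_len(n), z)
    lp <- length(blocks) * log(alpha) +
      sum(vapply(blocks, function(b) lgamma(length(b)) + block_ll(b),
                 numeric(1)))
    if (lp > best_lp) { best_lp <- lp; best <- z }
  }
  list(partition = canonical_partition(best), log_post = best_lp)
}

#' @export
print.clone_fit <- function(x, ...) {
  cat("<clone_fit>", if (!is.null(x$patient_id)) x$patient_id else "",
      ": ", length(x$assignments), " mutations, ", x$n_clusters,
      " consensus clones over ", length(x$days), " time points\n", sep = "")
  cat("cellular prevalence (posterior mean):\n")
  print(round(x$phi, 3))
  invisible(x)
}

#' @export
summary.clone_fit <- function(object, ...) {
  sizes <- table(object$assignments)
  cat("Dirichlet-process binomial mixture fit\n")
  cat("  mutations:      ", length(object$assignments), "\n")
  cat("  time points:    ", paste(object$days, collapse = ", "), "\n")
  cat("  consensus clones:", object$n_clusters,
      " (sizes ", paste(as.integer(sizes), collapse = ", "), ")\n", sep = "")
  cat("  posterior K:    ")
  print(object$diagnostics$k_table)
  cat("  samples kept:   ", object$diagnostics$n_samples,
      " (iterations ", object$control$iterations, ", burn-in ",
      object$control$burnin, ", thin ", object$control$thin, ")\n", sep = "")
  invisible(object)
}

#' @export
coef.clone_fit <- function(object, ...) object$phi

#' @export
plot.clone_fit <- function(x, ...) {
  cols <- hcl.colors(max(3, x$n_clusters), "Dark 3")
  matplot(x$days, t(x$phi), type = "b", pch = 16, lty = 1,
          col = cols[seq_len(x$n_clusters)],
          xlab = "day", ylab = "cellular prevalence", ylim = c(0, 1), ...)
  legend("topright", legend = rownames(x$phi), bty = "n",
         col = cols[seq_len(x$n_clusters)], lty = 1, pch = 16)
  invisible(x)
}

#' Tidy per-cluster trajectory table from a clone fit
#'
#' @param fit a `clone_fit`.
#' @return data.frame with `patient_id`, `cluster`, `day`, `phi`,
#'   `phi_lower`, `phi_upper`, `n_mutations` (one row per cluster and day).
#' @export
summarize_trajectories <- function(fit) {
  stopifnot(inherits(fit, "clone_fit"))
  if (fit$n_clusters == 0)
    return(data.frame(patient_id = character(), cluster = character(),
                      day = integer(), phi = numeric(),
                      phi_lower = numeric(), phi_upper = numeric(),
                      n_mutations = integer()))
  sizes <- tabulate(fit$assignments, nbins = fit$n_clusters)
  out <- expand.grid(cluster = rownames(fit$phi), day = fit$days,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$patient_id <- if (!is.null(fit$patient_id)) fit$patient_id else NA
  out$phi <- fit$phi[cbind(match(out$cluster, rownames(fit$phi)),
                           match(out$day, fit$days))]
  out$phi_lower <- fit$phi_lower[cbind(match(out$cluster, rownames(fit$phi)),
                                       match(out$day, fit$days))]
  out$phi_upper <- fit$phi_upper[cbind(match(out$cluster, rownames(fit$phi)),
                                       match(out$day, fit$days))]
  out$n_mutations <- sizes[match(out$cluster, rownames(fit$phi))]
  out[order(out$cluster, out$day),
      c("patient_id", "cluster", "day", "phi", "phi_lower", "phi_upper",
        "n_mutations")]
}
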