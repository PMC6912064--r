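#' Split a cluster's mutations by VAF trend over a time window
#'
#' Mutations are first partitioned by the sign of their VAF change across
#' the window (ascending: positive change; descending: negative; flat: zero).
#' Within each sign group, mutations whose full trajectories disagree are
#' separated further: mutations stay together only if connected by pairwise
#' Pearson trajectory correlations of at least `min_corr` (single linkage
#' over the correlation graph). The result is deterministic: mutations are
#' processed in genomic-coordinate order and sub-cluster ids follow that
#' order.
#'
#' @param vaf matrix (mutations x days) of VAFs; rownames are variant keys
#'   in `chrom:pos:ref:alt` form (used for coordinate ordering).
#' @param days integer vector of sampling days (columns of `vaf`).
#' @param window length-2 vector of days delimiting the trend window; both
#'   must be sampled days.
#' @param min_corr minimum pairwise trajectory correlation to stay in one
#'   sub-cluster (default 0).
#' @return list of character vectors of variant keys, one per sub-cluster.
#' @export
split_by_trend <- function(vaf, days, window, min_corr = 0) {
  vaf <- as.matrix(vaf)
  stopifnot(ncol(vaf) == length(days), nrow(vaf) >= 1)
  if (!all(window %in% days))
    stop("trend window (", paste(window, collapse = "-"),
         ") outside sampled days")
  keys <- rownames(vaf)
  if (is.null(keys)) keys <- paste0("mut", seq_len(nrow(vaf)))
  # genomic-coordinate order for determinism
  parts <- strsplit(keys, ":", fixed = TRUE)
  chrom <- vapply(parts, `[`, character(1), 1)
  pos <- suppressWarnings(as.integer(vapply(parts, function(p)
    if (length(p) >= 2) p[2] else NA_character_, character(1))))
  ord <- order(chrom, pos, keys)
  vaf <- vaf[ord, , drop = FALSE]; keys <- keys[ord]

  i1 <- match(window[1], days); i2 <- match(window[2], days)
  delta <- vaf[, i2] - vaf[, i1]
  sign_group <- sign(delta)
  out <- list()
  for (s in unique(sign_group)) {
    idx <- which(sign_group == s)
    if (length(idx) == 1) { out[[length(out) + 1L]] <- keys[idx]; next }
    # single-linkage components over the correlation graph
    cc <- suppressWarnings(stats::cor(t(vaf[idx, , drop = FALSE])))
    cc[is.na(cc)] <- 1  # flat trajectories agree with everything
    adj <- cc >= min_corr
    comp <- rep(0L, length(idx)); cid <- 0L
    for (v in seq_along(idx)) {
      if (comp[v] > 0L) next
      cid <- cid + 1L
      queue <- v
      while (length(queue)) {
        u <- queue[1]; queue <- queue[-1]
        if (comp[u] > 0L) next
        comp[u] <- cid
        queue <- c(queue, which(adj[u, ] & comp == 0L))
      }
    }
    for (g in seq_len(cid))
      out[[length(out) + 1L]] <- keys[idx[comp == g]]
  }
  out
}

#' Does a parent-child pair of trajectories satisfy the crossing rule?
#'
#' The crossing rule: a descendant clone's cellular prevalence may never
#' exceed its ancestor's at any time point. A tolerance `epsilon` absorbs
#' binomial sampling noise at ultra-deep coverage.
#'
#' @param parent_traj,child_traj prevalence vectors on the same day grid.
#' @param epsilon slack per time point (default 0.02).
#' @return TRUE iff `child <= parent + epsilon` at every time point.
#' @export
check_crossing_rule <- function(parent_traj, child_traj, epsilon = 0.02) {
  if (length(parent_traj) != length(child_traj))
    stop("mismatched day grids")
  all(child_traj <= parent_traj + epsilon)
}

#' Assemble a rooted clone tree under the crossing and sum-up rules
#'
#' Deterministic greedy construction encoding the manual reasoning used to
#' order clusters into an evolutionary tree: clusters are placed in order of
#' decreasing mean prevalence; each is attached to the already-placed
#' candidate parent with the smallest mean prevalence that satisfies both
#' (a) the crossing rule (child prevalence at most parent prevalence plus
#' `epsilon` at every time point) and (b) the sum-up constraint (the
#' prevalences of the parent's children, including the candidate, sum to at
#' most the parent's prevalence plus `epsilon` at every time point). Among
#' otherwise equally specific parents, one whose first detection day
#' precedes the child's is preferred (a clone cannot appear before its
#' ancestor). Clusters with no valid parent attach to the germline root,
#' whose prevalence is taken as 1 everywhere.
#'
#' @param phi matrix (clusters x time points) of cellular prevalences;
#'   rownames are cluster ids.
#' @param days integer vector of sampling days.
#' @param epsilon per-time-point slack (default 0.02).
#' @param detection_threshold prevalence above which a clone counts as
#'   detected (default 0.01), used for the per-edge first-detection day.
#' @return object of class `clone_tree`: list with `nodes`, `edges`
#'   (data.frame `parent`, `child`, `child_first_detected`), `phi`, `days`,
#'   `epsilon`.
#' @export
build_tree <- function(phi, days, epsilon = 0.02,
                       detection_threshold = 0.01) {
  phi <- as.matrix(phi)
  if (nrow(phi) == 0) stop("build_tree: no clusters")
  stopifnot(ncol(phi) == length(days))
  ids <- rownames(phi)
  if (is.null(ids)) ids <- paste0("clone", seq_len(nrow(phi)))
  rownames(phi) <- ids
  first_detect <- apply(phi, 1, function(p) {
    w <- which(p > detection_threshold)
    if (length(w)) days[w[1]] else NA_integer_
  })

  ord <- order(-rowMeans(phi))
  parent <- stats::setNames(rep(NA_character_, nrow(phi)), ids)
  placed <- character()
  children <- list(root = character())
  for (cid in ids[ord]) {
    cand <- placed
    ok <- vapply(cand, function(p) {
      if (!check_crossing_rule(phi[p, ], phi[cid, ], epsilon)) return(FALSE)
      sibs <- children[[p]]
      all(colSums(phi[c(sibs, cid), , drop = FALSE]) <= phi[p, ] + epsilon)
    }, logical(1))
    cand <- cand[ok]
    if (length(cand)) {
      mphi <- rowMeans(phi[cand, , drop = FALSE])
      # most specific parent; detection-day precedence breaks near-ties
      best <- min(mphi)
      near <- cand[mphi <= best + epsilon]
      earlier <- near[!is.na(first_detect[near]) & !is.na(first_detect[cid]) &
                        first_detect[near] <= first_detect[cid]]
      pick <- if (length(earlier)) earlier[which.min(mphi[match(earlier, cand)])]
              else cand[which.min(mphi)]
      parent[cid] <- pick
      children[[pick]] <- c(children[[pick]], cid)
    } else {
      parent[cid] <- "root"
      children$root <- c(children$root, cid)
    }
    children[[cid]] <- character()
    placed <- c(placed, cid)
  }
  edges <- data.frame(parent = unname(parent), child = ids,
                      child_first_detected = unname(first_detect[ids]),
                      stringsAsFactors = FALSE)
  structure(list(nodes = c("root", ids), edges = edges, phi = phi,
                 days = as.integer(days), epsilon = epsilon,
                 detection_threshold = detection_threshold),
            class = "clone_tree")
}

#' Validate a clone tree against the crossing and sum-up rules
#'
#' Re-checks every edge (crossing rule) and every internal node (children's
#' prevalences summing to at most the parent's, plus `epsilon`), treating
#' the germline root as prevalence 1. Run after every construction.
#'
#' @param tree a `clone_tree`.
#' @param epsilon slack; defaults to the tree's own.
#' @return TRUE if valid, otherwise FALSE with attribute `violations`.
#' @export
validate_clone_tree <- function(tree, epsilon = tree$epsilon) {
  stopifnot(inherits(tree, "clone_tree"))
  phi_of <- function(id) if (id == "root") rep(1, length(tree$days))
                         else tree$phi[id, ]
  bad <- character()
  for (r in seq_len(nrow(tree$edges))) {
    p <- tree$edges$parent[r]; ch <- tree$edges$child[r]
    if (!check_crossing_rule(phi_of(p), phi_of(ch), epsilon))
      bad <- c(bad, paste0("crossing:", p, "->", ch))
  }
  for (p in unique(tree$edges$parent)) {
    kids <- tree$edges$child[tree$edges$parent == p]
    tot <- colSums(tree$phi[kids, , drop = FALSE])
    if (!all(tot <= phi_of(p) + epsilon))
      bad <- c(bad, paste0("sum:", p))
  }
  out <- length(bad) == 0
  attr(out, "violations") <- bad
  out
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("<clone_tree> ", nrow(x$phi), " clones + germline root, days ",
      paste(x$days, collapse = ", "), "\n", sep = "")
  show <- function(node, indent) {
    kids <- x$edges$child[x$edges$parent == node]
    for (k in kids) {
      cat(strrep("  ", indent), "- ", k,
          " (mean phi ", sprintf("%.3f", mean(x$phi[k, ])), ")\n", sep = "")
      show(k, indent + 1)
    }
  }
  cat("root\n"); show("root", 1)
  invisible(x)
}

#' @export
plot.clone_tree <- function(x, ...) {
  # simple layered layout: depth = generation, siblings spread horizontally
  depth <- stats::setNames(0, "root")
  ord <- "root"
  while (length(ord)) {
    node <- ord[1]; ord <- ord[-1]
    kids <- x$edges$child[x$edges$parent == node]
    for (k in kids) depth[k] <- depth[node] + 1
    ord <- c(ord, kids)
  }
  nodes <- names(depth)
  xs <- stats::setNames(rep(0, length(nodes)), nodes)
  for (d in sort(unique(depth))) {
    at <- nodes[depth == d]
    xs[at] <- seq_along(at) - (length(at) + 1) / 2
  }
  plot(NA, xlim = range(xs) + c(-0.5, 0.5), ylim = c(max(depth), -0.5),
       axes = FALSE, xlab = "", ylab = "", ...)
  for (r in seq_len(nrow(x$edges)))
    segments(xs[x$edges$parent[r]], depth[x$edges$parent[r]],
             xs[x$edges$child[r]], depth[x$edges$child[r]], col = "grey50")
  points(xs, depth[nodes], pch = 21, bg = "white", cex = 3)
  text(xs, depth[nodes], labels = sub("clone", "", nodes), cex = 0.8)
  invisible(x)
}

#' Detect the emergence day of a rising clone
#'
#' The emergence day is the earliest sampled day `d` at which the clone's
#' prevalence exceeds `phi_min` and the trajectory shows `rise_points`
#' consecutive increasing sampled intervals ending at or after `d`. Returns
#' `NA` for clones that never emerge (flat, falling, or below the detection
#' floor).
#'
#' @param traj prevalence vector over the day grid.
#' @param days integer vector of sampling days.
#' @param phi_min detection floor (default 0.01).
#' @param rise_points required consecutive increasing intervals (default 2).
#' @return emergence day, or `NA_integer_`.
#' @export
detect_emergence <- function(traj, days, phi_min = 0.01, rise_points = 2) {
  stopifnot(length(traj) == length(days))
  if (length(traj) < rise_points + 1) return(NA_integer_)
  rising <- diff(traj) > 0
  run_end_days <- integer()
  run <- 0L
  for (j in seq_along(rising)) {
    run <- if (rising[j]) run + 1L else 0L
    if (run >= rise_points) run_end_days <- c(run_end_days, days[j + 1L])
  }
  if (!length(run_end_days)) return(NA_integer_)
  cand <- which(traj > phi_min & days <= max(run_end_days))
  if (!length(cand)) return(NA_integer_)
  as.integer(days[cand[1]])
}

#' Lead time of molecular emergence over radiological progression
#'
#' @param emergence_day day the clone was first detected rising
#'   ([detect_emergence()]); `NA` gives `NA`.
#' @param pd_day day of the first progressive-disease scan; `NA` (no PD
#'   observed) gives `NA`.
#' @return `pd_day - emergence_day` in days (negative if molecular detection
#'   trailed the scan; reported as-is).
#' @export
compute_lead_time <- function(emergence_day, pd_day) {
  if (is.na(emergence_day) || is.na(pd_day)) return(NA_integer_)
  as.integer(pd_day) - as.integer(emergence_day)
}

#' Emergence and lead-time calls for every cluster of a fit
#'
#' @param fit a `clone_fit`.
#' @param pd_day first progressive-disease scan day for the patient (`NA` if
#'   none).
#' @param phi_min,rise_points forwarded to [detect_emergence()].
#' @return data.frame with `cluster`, `emergence_day`, `lead_time_days`.
#' @export
emergence_calls <- function(fit, pd_day = NA, phi_min = 0.01,
                            rise_points = 2) {
  stopifnot(inherits(fit, "clone_fit"))
  em <- apply(fit$phi, 1, detect_emergence, days = fit$days,
              phi_min = phi_min, rise_points = rise_points)
  data.frame(cluster = rownames(fit$phi),
             emergence_day = as.integer(em),
             lead_time_days = vapply(em, compute_lead_time,
                                     integer(1), pd_day = pd_day),
             stringsAsFactors = FALSE)
}

#' Sign-agreement table between cluster dynamics and lesion diameters
#'
#' For each cluster, compares the sign of its prevalence change against the
#' sign of the diameter-sum change over each interval between consecutive
#' scans that coincide with sampling days. This is a descriptive association
#' report, not a causal assignment of clones to lesions.
#'
#' @param trajectories table from [summarize_trajectories()].
#' @param scans per-scan data.frame with `day` and `diameter_sum_cm` for one
#'   patient.
#' @return data.frame with `cluster`, `n_intervals`, `sign_agreement`
#'   (fraction of intervals where the signs agree).
#' @export
lesion_association <- function(trajectories, scans) {
  days <- sort(intersect(unique(trajectories$day), scans$day))
  if (length(days) < 2)
    return(data.frame(cluster = character(), n_intervals = integer(),
                      sign_agreement = numeric()))
  dd <- diff(scans$diameter_sum_cm[match(days, scans$day)])
  out <- lapply(split(trajectories, trajectories$cluster), function(tr) {
    dphi <- diff(tr$phi[match(days, tr$day)])
    data.frame(cluster = tr$cluster[1], n_intervals = length(dd),
               sign_agreement = mean(sign(dphi) == sign(dd)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
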