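#' Mann-Whitney U test with exact enumeration for small samples
#'
#' Computes the Mann-Whitney U statistic for the first group (rank-sum form,
#' with ties contributing 1/2). For combined sample sizes up to
#' `exact_limit` the p-value is exact: every assignment of the pooled
#' observations to the two groups is enumerated, so ties are handled without
#' approximation. Larger samples use the normal approximation with the tie
#' correction (no continuity correction). Two-sided p-values are
#' `P(|U - n1*n2/2| >= |u - n1*n2/2|)` under the exact null, which reduces
#' to the usual tail doubling for symmetric cases.
#'
#' @param group_a,group_b numeric vectors (both non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   referring to the location of `group_a` relative to `group_b`.
#' @param exact_limit largest combined n for exact enumeration (default 20).
#' @return list with `U` (statistic for `group_a`), `p`, `method`.
#' @export
mann_whitney_u <- function(group_a, group_b,
                           alternative = c("two.sided", "less", "greater"),
                           exact_limit = 20) {
  alternative <- match.arg(alternative)
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("mann_whitney_u: empty group")
  n1 <- length(group_a); n2 <- length(group_b)
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  if (n1 + n2 <= exact_limit) {
    idx <- utils::combn(n1 + n2, n1)
    rs <- colSums(matrix(r[idx], nrow = n1))
    u_all <- rs - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- switch(alternative,
      two.sided = mean(abs(u_all - mu) >= abs(u_obs - mu) - eps),
      less = mean(u_all <= u_obs + eps),
      greater = mean(u_all >= u_obs - eps))
    return(list(U = u_obs, p = p, method = "exact enumeration"))
  }
  # normal approximation with tie correction
  ties <- table(pooled)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (u_obs - mu) / sqrt(sigma2)
  p <- switch(alternative,
    two.sided = 2 * stats::pnorm(-abs(z)),
    less = stats::pnorm(z),
    greater = stats::pnorm(-z))
  list(U = u_obs, p = min(1, p), method = "normal approximation")
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Rank correlation using average ranks for ties; the p-value uses the
#' t-distribution approximation (as `stats::cor.test` does for tied data).
#'
#' @param x,y numeric vectors of equal length (>= 3); constant vectors are
#'   rejected (rho undefined).
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("constant input vector: rho undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate; censored observations leave the risk set without
#' producing a step. Backed by `survival::survfit`.
#'
#' @param times positive follow-up times.
#' @param events event indicator (1/TRUE = event, 0/FALSE = censored).
#' @return data.frame step table with `time`, `n_risk`, `n_event`,
#'   `surv` (survival probability just after `time`).
#' @export
km_curve <- function(times, events) {
  if (any(times <= 0)) stop("times must be positive")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Median-split log-rank comparison of progression-free survival
#'
#' Splits patients at the cohort median of a biomarker (values equal to the
#' median go to the low group), then compares PFS between the groups with
#' the standard log-rank test (1 df) and returns the per-group Kaplan-Meier
#' step curves. Backed by `survival::survdiff` / `survival::survfit`.
#'
#' @param pfs_days positive follow-up times.
#' @param event progression indicator.
#' @param biomarker numeric biomarker (e.g. baseline bTMB) per patient.
#' @return list with `group` (factor `low`/`high`), `median` (split value),
#'   `chisq`, `p`, and `km` (list of step tables per group).
#' @export
median_split_logrank <- function(pfs_days, event, biomarker) {
  stopifnot(length(pfs_days) == length(event),
            length(event) == length(biomarker))
  med <- stats::median(biomarker)
  group <- factor(ifelse(biomarker <= med, "low", "high"),
                  levels = c("low", "high"))
  if (any(table(group) < 2))
    stop("degenerate median split: fewer than 2 patients on one side")
  sd <- survival::survdiff(
    survival::Surv(pfs_days, as.integer(event)) ~ group)
  chisq <- sd$chisq
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  km <- lapply(split(seq_along(pfs_days), group), function(i)
    km_curve(pfs_days[i], event[i]))
  list(group = group, median = med, chisq = chisq, p = p, km = km)
}

#' Label on-treatment samples by the response of their scan interval
#'
#' Each on-treatment sample (day > 0) is labeled with the response
#' assessment whose scan day is nearest in time (ties to the earlier scan),
#' then grouped PR versus SD/PD for the sample-level MSAF comparison.
#' Baseline samples carry no response label and are excluded.
#'
#' @param metrics per-sample metrics table (from [burden_metrics()], rows
#'   for several patients allowed).
#' @param scans per-scan data.frame with `patient_id`, `day`, `response`.
#' @return `metrics` restricted to labeled samples, with `response` and
#'   `response_group` (`PR` / `SD/PD`) columns added.
#' @export
msaf_response_groups <- function(metrics, scans) {
  on_tx <- metrics[metrics$day > 0, , drop = FALSE]
  rows <- lapply(seq_len(nrow(on_tx)), function(i) {
    s <- scans[scans$patient_id == on_tx$patient_id[i] & scans$day > 0, ,
               drop = FALSE]
    if (nrow(s) == 0) return(NULL)
    j <- which.min(abs(s$day - on_tx$day[i]))
    out <- on_tx[i, , drop = FALSE]
    out$response <- s$response[j]
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- on_tx[0, , drop = FALSE]
    out$response <- character(0); out$response_group <- character(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$response_group <- ifelse(out$response == "PR", "PR", "SD/PD")
  rownames(out) <- NULL
  out
}
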