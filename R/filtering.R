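#' Step 1: remove common germline variants by population allele frequency
#'
#' A variant present in the population database with a maximum population
#' allele frequency at or above `af_threshold` is labeled `common_germline`
#' and removed. Variants absent from the database, or below the threshold,
#' are kept. The threshold is inclusive.
#'
#' @param variants variant table.
#' @param popdb population DB from [read_popdb()].
#' @param af_threshold population AF cutoff (default 0.001, i.e. 0.1%).
#' @return list with `kept` and `removed` variant tables; removed rows carry
#'   `filter_status = "common_germline"`.
#' @export
filter_common_germline <- function(variants, popdb, af_threshold = 0.001) {
  variants <- as_variant_table(variants)
  if (nrow(variants) == 0) return(list(kept = variants, removed = variants))
  af <- popdb$pop_af[match(variant_key(variants), popdb$key)]
  hit <- !is.na(af) & af >= af_threshold
  removed <- variants[hit, , drop = FALSE]
  if (nrow(removed)) removed$filter_status <- "common_germline"
  list(kept = variants[!hit, , drop = FALSE], removed = removed)
}

#' Step 2: remove variants seen in the matched white-blood-cell library
#'
#' A variant with more than `max_normal_reads` alt reads in the matched
#' white-blood-cell sequencing is removed as `matched_normal`. This step
#' absorbs both residual germline variants and clonal hematopoiesis (CHIP):
#' no separate CHIP classifier exists. Variants without an evidence row, or
#' at or below the read cutoff, are kept.
#'
#' @param variants variant table.
#' @param normal_evidence table from [read_normal_evidence()].
#' @param max_normal_reads highest tolerated WBC alt-read count (default 2:
#'   "more than two reads" removes).
#' @return list with `kept` and `removed` variant tables.
#' @export
filter_matched_normal <- function(variants, normal_evidence,
                                  max_normal_reads = 2) {
  variants <- as_variant_table(variants)
  if (nrow(variants) == 0) return(list(kept = variants, removed = variants))
  n <- normal_evidence$wbc_alt_reads[match(variant_key(variants),
                                           normal_evidence$key)]
  hit <- !is.na(n) & n > max_normal_reads
  removed <- variants[hit, , drop = FALSE]
  if (nrow(removed)) removed$filter_status <- "matched_normal"
  list(kept = variants[!hit, , drop = FALSE], removed = removed)
}

#' Step 3: remove private germline variants by the patient-combined VAF rule
#'
#' A variant key is removed from every sample of the patient if and only if
#' it is detected (alt reads > 0) at every sampled time point and its VAF
#' exceeds `vaf_threshold` (strictly) at every time point. Absence, or VAF at
#' or below the threshold, at any single time point vetoes removal: a variant
#' that disappears cannot be germline. With a single time point the rule
#' still applies (one VAF above threshold removes) and a caution is logged.
#'
#' @param series [patient_series] (after steps 1-2).
#' @param vaf_threshold VAF cutoff (default 0.20, strict `>` as printed).
#' @return list with `series` (kept calls) and `removed` (long variant table
#'   labeled `private_germline`).
#' @export
filter_private_germline <- function(series, vaf_threshold = 0.20) {
  stopifnot(inherits(series, "patient_series"))
  v <- series$variants
  n_days <- length(series$days)
  if (n_days == 1)
    message("patient ", series$patient_id,
            ": private-germline rule applied to a single time point")
  if (nrow(v) == 0)
    return(list(series = series, removed = v))
  key <- variant_key(v)
  detected <- v$alt_reads > 0
  high <- v$vaf > vaf_threshold
  by_key <- split(seq_len(nrow(v)), key)
  remove_keys <- names(by_key)[vapply(by_key, function(i) {
    length(i) == n_days && all(detected[i]) && all(high[i])
  }, logical(1))]
  hit <- key %in% remove_keys
  removed <- v[hit, , drop = FALSE]
  if (nrow(removed)) removed$filter_status <- "private_germline"
  series$variants <- v[!hit, , drop = FALSE]
  list(series = series, removed = removed)
}

#' Step 4: flag variants with a large VAF swing for review
#'
#' Marks variant keys whose VAF range (max minus min) across the patient's
#' time points exceeds `delta_threshold`. A key absent from a sample's calls
#' contributes VAF 0 at that time point, so a mutation appearing de novo at
#' 4% is flagged. Nothing is removed: the flag replaces the manual IGV check
#' of the original workflow.
#'
#' @param series [patient_series] of passing variants.
#' @param delta_threshold VAF-range cutoff (default 0.02, i.e. 2%).
#' @return the series with `review_flag` set on flagged calls; the flagged
#'   keys are in attribute `flagged_keys`.
#' @export
flag_for_review <- function(series, delta_threshold = 0.02) {
  stopifnot(inherits(series, "patient_series"))
  v <- series$variants
  if (nrow(v) == 0) {
    attr(series, "flagged_keys") <- character()
    return(series)
  }
  key <- variant_key(v)
  n_days <- length(series$days)
  rng <- vapply(split(v$vaf, key), function(vaf) {
    if (length(vaf) < n_days) vaf <- c(vaf, 0) # undetected time points
    max(vaf) - min(vaf)
  }, numeric(1))
  flagged <- names(rng)[rng > delta_threshold]
  v$review_flag <- v$review_flag | key %in% flagged
  series$variants <- v
  attr(series, "flagged_keys") <- flagged
  series
}

#' Run the full four-step germline/artifact filter cascade on one patient
#'
#' Applies, in order: (1) the population-database common-germline filter,
#' (2) the matched white-blood-cell filter, (3) the patient-combined private
#' germline VAF rule, and (4) the review flag for large VAF swings. Each
#' removed call keeps only its first-failing label, so a variant found both
#' in the population database and in the WBC evidence is `common_germline`.
#' Per-sample counts satisfy
#' `input == common_germline + matched_normal + private_germline + passing`
#' (the review flag removes nothing).
#'
#' @param series [patient_series] of unfiltered calls.
#' @param popdb population DB from [read_popdb()].
#' @param normal_evidence table from [read_normal_evidence()].
#' @param af_threshold,max_normal_reads,vaf_threshold,delta_threshold
#'   thresholds of steps 1-4 (defaults 0.001, 2, 0.20, 0.02).
#' @return list with `series` (passing calls, review flags set), `removed`
#'   (long table of removed calls with their labels) and `report` (per-sample
#'   count data.frame of class `filter_report`).
#' @export
apply_filter_cascade <- function(series, popdb, normal_evidence,
                                 af_threshold = 0.001, max_normal_reads = 2,
                                 vaf_threshold = 0.20,
                                 delta_threshold = 0.02) {
  stopifnot(inherits(series, "patient_series"))
  v <- series$variants
  input_by_day <- table(factor(v$day, levels = series$days))

  s1 <- filter_common_germline(v, popdb, af_threshold)
  s2 <- filter_matched_normal(s1$kept, normal_evidence, max_normal_reads)
  series$variants <- s2$kept
  s3 <- filter_private_germline(series, vaf_threshold)
  series <- flag_for_review(s3$series, delta_threshold)

  removed <- rbind(s1$removed, s2$removed, s3$removed)
  cnt <- function(df) as.integer(table(factor(df$day, levels = series$days)))
  report <- data.frame(
    patient_id = series$patient_id,
    day = series$days,
    input = as.integer(input_by_day),
    removed_common_germline = cnt(s1$removed),
    removed_matched_normal = cnt(s2$removed),
    removed_private_germline = cnt(s3$removed),
    flagged_for_review = cnt(series$variants[series$variants$review_flag, ,
                                             drop = FALSE]),
    passing = cnt(series$variants),
    stringsAsFactors = FALSE)
  class(report) <- c("filter_report", "data.frame")
  stopifnot(all(report$input == report$removed_common_germline +
                  report$removed_matched_normal +
                  report$removed_private_germline + report$passing))
  list(series = series, removed = removed, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> patient ", x$patient_id[1], "\n", sep = "")
  print.data.frame(x)
  invisible(x)
}
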