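#' Maximum somatic allele frequency (MSAF) of one sample
#'
#' MSAF is the maximum VAF among passing somatic variants and serves as a
#' proxy for the circulating tumor fraction. All effect classes, including
#' synonymous changes, are counted by default. Cross-sample capping of
#' aneuploid outliers is already handled by the patient-combined private
#' germline rule (filter step 3), so no additional per-sample VAF cap is
#' applied here. An empty passing set yields 0.
#'
#' @param variants passing variant table of one sample.
#' @param include_classes effect classes to include (default all).
#' @return MSAF in `[0, 1]`.
#' @export
compute_msaf <- function(variants, include_classes = .EFFECT_LEVELS) {
  v <- variants[variants$filter_status == "PASS" &
                  variants$effect %in% include_classes, , drop = FALSE]
  if (nrow(v) == 0) return(0)
  max(v$vaf)
}

#' Blood tumor mutational burden (bTMB) of one sample
#'
#' Passing somatic variant count (SNVs and indels; synonymous included by
#' default, mirroring the MSAF inclusion rule) divided by the panel size in
#' megabases.
#'
#' @param variants passing variant table of one sample.
#' @param panel_bp panel territory in base pairs (default 637000).
#' @param include_synonymous count synonymous variants (default TRUE).
#' @return mutations per megabase.
#' @export
compute_btmb <- function(variants, panel_bp = 637000,
                         include_synonymous = TRUE) {
  if (panel_bp <= 0) stop("panel_bp must be positive")
  v <- variants[variants$filter_status == "PASS", , drop = FALSE]
  if (!include_synonymous)
    v <- v[v$effect != "synonymous", , drop = FALSE]
  nrow(v) / (panel_bp / 1e6)
}

#' Mean MSAF over a patient's samples
#'
#' @param msaf numeric vector of per-sample MSAF values for one patient
#'   (at least one sample).
#' @return arithmetic mean.
#' @export
mean_msaf <- function(msaf) {
  if (length(msaf) == 0) stop("mean_msaf: empty series")
  mean(msaf)
}

#' Per-sample burden metrics for a filtered patient series
#'
#' @param series [patient_series] after the filter cascade (passing calls).
#' @param panel_bp panel size in base pairs (default 637000).
#' @param include_synonymous forwarded to [compute_btmb()].
#' @return data.frame with `patient_id`, `day`, `msaf`, `btmb`, `n_passing`.
#' @export
burden_metrics <- function(series, panel_bp = 637000,
                           include_synonymous = TRUE) {
  stopifnot(inherits(series, "patient_series"))
  rows <- lapply(series$days, function(d) {
    v <- series$variants[series$variants$day == d, , drop = FALSE]
    data.frame(patient_id = series$patient_id, day = d,
               msaf = compute_msaf(v),
               btmb = compute_btmb(v, panel_bp, include_synonymous),
               n_passing = sum(v$filter_status == "PASS"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
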