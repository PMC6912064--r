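#' Discretize a copy-number log ratio into a total copy number
#'
#' Total copy number is 1 for logR below -0.25, 3 for logR above 0.25, and 2
#' in between; both boundaries (exactly +/-0.25) and an absent logR map to 2.
#'
#' @param logr numeric vector of log2 depth ratios; `NA` allowed (treated as
#'   neutral).
#' @return integer vector of total copy numbers in `{1, 2, 3}`.
#' @export
discretize_copy_number <- function(logr) {
  if (any(!is.na(logr) & !is.finite(logr)))
    stop("non-finite logR value")
  cn <- rep(2L, length(logr))
  cn[!is.na(logr) & logr < -0.25] <- 1L
  cn[!is.na(logr) & logr > 0.25] <- 3L
  cn
}

#' Point estimate of cellular prevalence from a VAF
#'
#' Under the binomial read-count model, a mutation present at multiplicity
#' `m` of `cn_total` copies in a clone of cellular prevalence `phi` has
#' expected VAF `phi * m / cn_total`, so the inverse transform
#' `min(1, vaf * cn_total / m)` is used for initialization and reporting.
#'
#' @param vaf variant allele frequency in `[0, 1]`.
#' @param cn_total total copy number at the locus.
#' @param multiplicity mutated copies `m` in `1..cn_total` (default 1).
#' @return estimated cellular prevalence, clipped to `[0, 1]`.
#' @export
prevalence_of_vaf <- function(vaf, cn_total, multiplicity = 1) {
  if (any(multiplicity > cn_total))
    stop("multiplicity exceeds total copy number")
  if (any(multiplicity < 1)) stop("multiplicity must be >= 1")
  pmin(1, vaf * cn_total / multiplicity)
}
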