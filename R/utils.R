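#' Variant key
#'
#' Canonical `chrom:pos:ref:alt` key used to match variants across samples,
#' the population database and the white-blood-cell evidence table.
#'
#' @param x data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return character vector of keys.
#' @export
variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(mean(exp(x)))
logmeanexp <- function(x) logsumexp(x) - log(length(x))

#' Enumerate all set partitions of n items
#'
#' Partitions are generated as restricted growth strings, so the first item is
#' always in block 1 and block labels are canonical. Used by the exhaustive
#' small-instance MAP estimator ([map_partition()]) that serves as a reference
#' for the Gibbs sampler on tiny inputs.
#'
#' @param n number of items (kept small; the Bell number grows fast).
#' @return list of integer vectors, each a block-label assignment of length n.
#' @export
set_partitions <- function(n) {
  stopifnot(n >= 1, n <= 10)
  out <- list()
  grow <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L)) {
      grow(c(prefix, lab), max(maxlab, lab))
    }
  }
  grow(1L, 1L)
  out
}

# Canonical form of a partition label vector (first appearance order).
canonical_partition <- function(z) {
  match(z, unique(z))
}

# Do two label vectors describe the same partition?
same_partition <- function(a, b) {
  identical(canonical_partition(a), canonical_partition(b))
}

# Empty variant table with the canonical columns.
empty_variants <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), alt_reads = integer(), ref_reads = integer(),
             vaf = numeric(), gene = character(), effect = character(),
             logr = numeric(), filter_status = character(),
             review_flag = logical(), stringsAsFactors = FALSE)
}

# Validate/complete a variant table in place.
as_variant_table <- function(df) {
  if (nrow(df) == 0) return(empty_variants())
  need <- c("chrom", "pos", "ref", "alt", "alt_reads", "ref_reads")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("variant table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$alt_reads < 0) || any(df$ref_reads < 0))
    stop("negative read counts in variant table")
  tot <- df$alt_reads + df$ref_reads
  if (any(tot == 0)) stop("variant with zero total depth at ",
                          variant_key(df)[which(tot == 0)[1]])
  df$vaf <- df$alt_reads / tot
  if (is.null(df$gene)) df$gene <- NA_character_
  if (is.null(df$effect)) df$effect <- "other"
  if (is.null(df$logr)) df$logr <- NA_real_
  if (is.null(df$filter_status)) df$filter_status <- "PASS"
  if (is.null(df$review_flag)) df$review_flag <- FALSE
  bad <- !df$filter_status %in% .FILTER_LEVELS
  if (any(bad)) stop("unknown filter_status: ", df$filter_status[bad][1])
  rownames(df) <- NULL
  df
}
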