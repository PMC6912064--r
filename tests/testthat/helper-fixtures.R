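# Shared fixtures, built in code at test time.

# Write a minimal VCF v4.2 by hand (independent of write_vcf) so the reader
# is tested against raw text, not against the package's own writer.
write_raw_vcf <- function(records, path = tempfile(fileext = ".vcf"),
                          format = "AD:DP") {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=LOGR,Number=1,Type=Float,Description=\"logR\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "S1", sep = "\t"))
  writeLines(c(hdr, records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, ad, info = ".",
                       format = "AD:DP", sample = NULL) {
  if (is.null(sample)) {
    depths <- as.integer(strsplit(ad, ",")[[1]])
    sample <- paste0(ad, ":", sum(depths))
  }
  paste(chrom, pos, ".", ref, alt, ".", "PASS", info, format, sample,
        sep = "\t")
}

# Variant table row(s) with defaults.
vt <- function(chrom = "chr1", pos = 100, ref = "A", alt = "T",
               alt_reads = 30, ref_reads = 70, gene = NA_character_,
               effect = "nonsynonymous", logr = NA_real_,
               filter_status = "PASS", review_flag = FALSE,
               day = NULL) {
  df <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   alt_reads = alt_reads, ref_reads = ref_reads,
                   vaf = alt_reads / (alt_reads + ref_reads),
                   gene = gene, effect = effect, logr = logr,
                   filter_status = filter_status, review_flag = review_flag,
                   stringsAsFactors = FALSE)
  if (!is.null(day)) df$day <- day
  df
}

# A series holding one variant key observed at given VAFs across days
# (NA vaf = absent from that day's calls), at fixed depth.
series_with_vafs <- function(vafs, days = seq(0, by = 30,
                                              length.out = length(vafs)),
                             depth = 1000, patient_id = "P1",
                             chrom = "chr1", pos = 100) {
  tabs <- lapply(vafs, function(v) {
    if (is.na(v)) return(vt()[0, ])
    vt(chrom = chrom, pos = pos, alt_reads = round(v * depth),
       ref_reads = depth - round(v * depth))
  })
  patient_series(patient_id, days, tabs)
}

empty_popdb <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), pop_af = numeric(), key = character(),
             stringsAsFactors = FALSE)
}

popdb_for <- function(variants, pop_af) {
  db <- variants[c("chrom", "pos", "ref", "alt")]
  db$pop_af <- pop_af
  db$key <- variant_key(db)
  db
}

normal_for <- function(variants, wbc_alt_reads) {
  ev <- variants[c("chrom", "pos", "ref", "alt")]
  ev$wbc_alt_reads <- wbc_alt_reads
  ev$key <- variant_key(ev)
  ev
}

# Independent Mann-Whitney oracle: U from the pair-counting definition, the
# null distribution by enumerating every subset assignment of the pooled
# values with utils::combn, two-sided p by symmetric distance from the mean.
mw_oracle <- function(a, b) {
  u_of <- function(x, y) {
    sum(vapply(x, function(xi) sum(xi > y) + 0.5 * sum(xi == y), numeric(1)))
  }
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  u_all <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  u_obs <- u_of(a, b)
  mu <- n1 * length(b) / 2
  list(U = u_obs,
       p = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
}

# Small deterministic counts for clustering tests: two clusters with the
# given prevalence trajectories, n mutations each, CN 2, fixed depth.
planted_counts <- function(phi_rows, n_per, depth = 3000, seed = 1) {
  set.seed(seed)
  z <- rep(seq_len(nrow(phi_rows)), n_per)
  alt <- t(vapply(z, function(k)
    rbinom(ncol(phi_rows), depth, phi_rows[k, ] / 2),
    integer(ncol(phi_rows))))
  list(alt = alt, depth = matrix(depth, nrow(alt), ncol(alt)),
       cn = rep(2L, nrow(alt)), z = z)
}
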