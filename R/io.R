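#' Read somatic variant calls from a VCF file
#'
#' Parses a single-sample VCF v4.2 and returns one call per ALT allele per
#' record. Allelic depths are taken from the per-sample `AD` field (matched
#' positionally for multi-allelic records); the VAF is always recomputed as
#' `alt / (ref + alt)` and never read from an `AF` field. Records whose total
#' depth falls below `min_total_depth` are dropped and counted in the
#' `n_dropped` attribute of the result.
#'
#' Optional INFO keys are carried through: the copy-number log-ratio
#' (`logr_key`, default `"LOGR"`; absent values mean total copy number 2
#' downstream), `GENE` and `EFFECT` annotations, and a `REVIEW` flag.
#'
#' @param path path to a VCF v4.2 file (plain text or gzipped).
#' @param min_total_depth minimum ref+alt depth for a call to be kept
#'   (default 100, an ultra-deep panel setting).
#' @param logr_key INFO key holding the copy-number logR (default `"LOGR"`).
#' @return data.frame of variant calls (columns `chrom`, `pos`, `ref`, `alt`,
#'   `alt_reads`, `ref_reads`, `vaf`, `gene`, `effect`, `logr`,
#'   `filter_status`, `review_flag`) with attribute `n_dropped`.
#' @export
read_vcf <- function(path, min_total_depth = 100, logr_key = "LOGR") {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- try(vcfR::read.vcfR(path, verbose = FALSE), silent = TRUE)
  if (inherits(v, "try-error"))
    stop("malformed VCF ", path, ": ", attr(v, "condition")$message)
  fix <- vcfR::getFIX(v)
  if (!is.null(fix) && is.null(dim(fix)))   # single-record files
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (is.null(fix) || nrow(fix) == 0) {
    out <- empty_variants()
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  if (ncol(v@gt) < 2)
    stop("VCF has no sample genotype columns: ", path)
  fmt <- v@gt[, 1]
  has_ad <- vapply(strsplit(fmt, ":"), function(f) "AD" %in% f, logical(1))
  if (any(!has_ad)) {
    i <- which(!has_ad)[1]
    stop("record without AD field in ", path, " at ",
         fix[i, "CHROM"], ":", fix[i, "POS"])
  }
  ad <- vcfR::extract.gt(v, element = "AD")[, 1]
  logr <- suppressWarnings(
    vcfR::extract.info(v, element = logr_key, as.numeric = TRUE))
  gene <- vcfR::extract.info(v, element = "GENE")
  eff <- vcfR::extract.info(v, element = "EFFECT")
  review <- vcfR::extract.info(v, element = "REVIEW")
  if (is.null(logr)) logr <- rep(NA_real_, nrow(fix))
  if (is.null(gene)) gene <- rep(NA_character_, nrow(fix))
  if (is.null(eff)) eff <- rep(NA_character_, nrow(fix))

  rows <- vector("list", nrow(fix))
  n_dropped <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    depths <- suppressWarnings(
      as.integer(strsplit(ad[i], ",", fixed = TRUE)[[1]]))
    if (anyNA(depths) || length(depths) != length(alts) + 1L)
      stop("unparseable AD '", ad[i], "' at ",
           fix[i, "CHROM"], ":", fix[i, "POS"], " in ", path)
    ref_reads <- depths[1]
    for (j in seq_along(alts)) {
      alt_reads <- depths[j + 1L]
      tot <- ref_reads + alt_reads
      if (tot == 0)
        stop("zero total depth at ", fix[i, "CHROM"], ":", fix[i, "POS"],
             " in ", path)
      if (tot < min_total_depth) { n_dropped <- n_dropped + 1L; next }
      filt <- fix[i, "FILTER"]
      if (is.na(filt) || filt %in% c(".", "")) filt <- "PASS"
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[j],
        alt_reads = alt_reads, ref_reads = ref_reads,
        vaf = alt_reads / tot,
        gene = gene[i],
        effect = if (is.na(eff[i])) "other" else eff[i],
        logr = logr[i],
        filter_status = if (filt %in% .FILTER_LEVELS) filt else "PASS",
        review_flag = !is.null(review) && !is.na(review[i]) &&
          review[i] %in% c("1", "TRUE"),
        stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty_variants()
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write variant calls to a plain-text VCF v4.2 file
#'
#' Emits one record per call with allelic depths in the per-sample `AD` field,
#' the filter label in `FILTER`, and `LOGR`/`GENE`/`EFFECT`/`REVIEW` INFO keys
#' where defined. Multi-allelic sites are written as separate records (one per
#' ALT), mirroring how [read_vcf()] splits them.
#'
#' @param variants variant table as returned by [read_vcf()].
#' @param path output path.
#' @param sample_id sample column name in the VCF header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, sample_id = "SAMPLE") {
  variants <- as_variant_table(variants)
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=ctdnaclone",
    "##INFO=<ID=LOGR,Number=1,Type=Float,Description=\"Copy-number log ratio\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Coding effect class\">",
    "##INFO=<ID=REVIEW,Number=0,Type=Flag,Description=\"Flagged for manual review (max VAF change rule)\">",
    "##FILTER=<ID=common_germline,Description=\"Population database AF above threshold\">",
    "##FILTER=<ID=matched_normal,Description=\"Present in matched white-blood-cell reads\">",
    "##FILTER=<ID=private_germline,Description=\"VAF above 20% at all time points\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t"))
  writeLines(hdr, con)
  if (nrow(variants)) {
    ord <- order(variants$chrom, variants$pos, variants$ref, variants$alt)
    variants <- variants[ord, , drop = FALSE]
    info <- vapply(seq_len(nrow(variants)), function(i) {
      parts <- character()
      if (!is.na(variants$logr[i]))
        parts <- c(parts, sprintf("LOGR=%.4f", variants$logr[i]))
      if (!is.na(variants$gene[i]))
        parts <- c(parts, paste0("GENE=", variants$gene[i]))
      if (!is.na(variants$effect[i]))
        parts <- c(parts, paste0("EFFECT=", variants$effect[i]))
      if (isTRUE(variants$review_flag[i])) parts <- c(parts, "REVIEW")
      if (!length(parts)) "." else paste(parts, collapse = ";")
    }, character(1))
    writeLines(paste(variants$chrom, variants$pos, ".", variants$ref,
                     variants$alt, ".", variants$filter_status, info,
                     "AD:DP",
                     paste0(variants$ref_reads, ",", variants$alt_reads, ":",
                            variants$ref_reads + variants$alt_reads),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a sample sheet linking patients to serial VCFs
#'
#' @param path TSV with header `patient_id`, `day`, `vcf_path`. `day` is the
#'   number of days since treatment start (baseline = 0).
#' @return named list: one data.frame per patient (`day`, `vcf_path`), sorted
#'   by day. Duplicate (patient, day) pairs are rejected.
#' @export
read_sample_sheet <- function(path) {
  sheet <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "day", "vcf_path")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  sheet$day <- as.integer(sheet$day)
  if (any(sheet$day < 0)) stop("negative day in sample sheet")
  out <- split(sheet[c("day", "vcf_path")], sheet$patient_id)
  out <- Map(function(d, p) {
    if (anyDuplicated(d$day)) stop("duplicate day for patient ", p)
    d <- d[order(d$day), , drop = FALSE]
    rownames(d) <- NULL
    d
  }, out, names(out))
  out
}

#' Read the population allele-frequency table
#'
#' One row per variant with the maximum allele frequency observed across the
#' population databases consulted (ESP6500 / 1000 Genomes / gnomAD / ExAC
#' style resources), keyed by `chrom:pos:ref:alt`.
#'
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt`, `pop_af`.
#' @return data.frame with an extra `key` column.
#' @export
read_popdb <- function(path) {
  db <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "pop_af")
  if (!all(need %in% names(db)))
    stop("population DB must have columns: ", paste(need, collapse = ", "))
  if (any(db$pop_af < 0 | db$pop_af > 1)) stop("pop_af outside [0,1]")
  db$key <- variant_key(db)
  db
}

#' Read the matched white-blood-cell evidence table
#'
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt`,
#'   `wbc_alt_reads` (non-negative integer alt-read count in the matched
#'   white-blood-cell library).
#' @return data.frame with an extra `key` column.
#' @export
read_normal_evidence <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "wbc_alt_reads")
  if (!all(need %in% names(ev)))
    stop("normal evidence must have columns: ", paste(need, collapse = ", "))
  if (any(ev$wbc_alt_reads < 0)) stop("negative wbc_alt_reads")
  ev$key <- variant_key(ev)
  ev
}

#' Read the clinical table (and optional per-scan responses)
#'
#' The clinical TSV carries one row per patient with at least `patient_id`,
#' `stage` (III or IV), `smoking_index` (cigarettes/day times years smoked),
#' `diameter_sum_cm` (baseline sum of longest target-lesion diameters) and
#' `best_response` (PR/SD/PD); `pfs_days` and `event` are optional. When a
#' per-scan table (`patient_id`, `day`, `response`, optionally
#' `diameter_sum_cm`) is supplied, the best response is recomputed from the
#' scan labels under the ordering PR > SD > PD and cross-checked against the
#' stated column (mismatches warn and the recomputed label wins).
#'
#' @param path clinical TSV path.
#' @param scans_path optional per-scan TSV path.
#' @return list with `patients` (data.frame) and `scans` (data.frame or NULL).
#' @export
read_clinical_table <- function(path, scans_path = NULL) {
  clin <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(clin) == 0) {
    warning("empty clinical table: ", path)
    return(list(patients = clin, scans = NULL))
  }
  need <- c("patient_id", "stage", "smoking_index", "diameter_sum_cm",
            "best_response")
  miss <- setdiff(need, names(clin))
  if (length(miss))
    stop("clinical table missing columns: ", paste(miss, collapse = ", "))
  clin$patient_id <- as.character(clin$patient_id)
  if (!all(clin$stage %in% c("III", "IV")))
    stop("unknown stage label: ",
         paste(setdiff(clin$stage, c("III", "IV")), collapse = ", "))
  if (any(clin$smoking_index < 0)) stop("negative smoking_index")
  if (!all(clin$best_response %in% .RESPONSE_LEVELS))
    stop("unknown response label: ",
         paste(setdiff(clin$best_response, .RESPONSE_LEVELS), collapse = ", "))
  if (is.null(clin$pfs_days)) clin$pfs_days <- NA_integer_
  if (is.null(clin$event)) clin$event <- NA
  if (any(!is.na(clin$pfs_days) & clin$pfs_days <= 0))
    stop("pfs_days must be positive")

  scans <- NULL
  if (!is.null(scans_path)) {
    scans <- read.delim(scans_path, stringsAsFactors = FALSE)
    if (!all(c("patient_id", "day", "response") %in% names(scans)))
      stop("scan table must have columns patient_id, day, response")
    scans$patient_id <- as.character(scans$patient_id)
    lab <- scans$response[!is.na(scans$response)]  # baseline rows carry NA
    if (!all(lab %in% .RESPONSE_LEVELS))
      stop("unknown response label: ",
           paste(setdiff(lab, .RESPONSE_LEVELS), collapse = ", "))
    best <- vapply(split(scans$response, scans$patient_id), function(r) {
      r <- r[!is.na(r)]
      if (!length(r)) NA_character_ else best_response(r)
    }, character(1))
    idx <- match(clin$patient_id, names(best))
    recomputed <- best[idx]
    cmp <- !is.na(recomputed) & recomputed != clin$best_response
    if (any(cmp))
      warning("best_response mismatch for patient(s) ",
              paste(clin$patient_id[cmp], collapse = ", "),
              "; using labels recomputed from scans")
    clin$best_response <- ifelse(is.na(recomputed), clin$best_response,
                                 recomputed)
  }
  list(patients = clin, scans = scans)
}

#' Best response across scan labels
#'
#' @param labels character vector of `PR`/`SD`/`PD` labels.
#' @return the best label attained, under the ordering PR > SD > PD.
#' @export
best_response <- function(labels) {
  stopifnot(all(labels %in% .RESPONSE_LEVELS))
  .RESPONSE_LEVELS[min(match(labels, .RESPONSE_LEVELS))]
}

#' Cohort summary statistics from the clinical table
#'
#' @param patients clinical data.frame as returned by [read_clinical_table()].
#' @param heavy_smoker_index smoking-index cutoff for "heavy smoker"
#'   (default 400).
#' @return list with `n`, `n_stage_iv`, `n_heavy_smoker`, `n_pr`,
#'   `pr_fraction`.
#' @export
summarize_clinical <- function(patients, heavy_smoker_index = 400) {
  list(n = nrow(patients),
       n_stage_iv = sum(patients$stage == "IV"),
       n_heavy_smoker = sum(patients$smoking_index >= heavy_smoker_index),
       n_pr = sum(patients$best_response == "PR"),
       pr_fraction = mean(patients$best_response == "PR"))
}

#' Assemble a patient's serial samples into one series object
#'
#' @param patient_id patient identifier.
#' @param days integer vector of sampling days (strictly increasing, >= 0).
#' @param tables list of variant tables, one per day, aligned with `days`.
#' @return object of class `patient_series`: a list with `patient_id`, `days`
#'   and `variants`, the latter a long data.frame with a `day` column.
#' @export
patient_series <- function(patient_id, days, tables) {
  days <- as.integer(days)
  stopifnot(length(days) == length(tables))
  if (any(days < 0)) stop("negative sampling day for patient ", patient_id)
  if (is.unsorted(days, strictly = TRUE))
    stop("days must be strictly increasing for patient ", patient_id)
  tabs <- lapply(seq_along(tables), function(i) {
    t <- as_variant_table(tables[[i]])
    if (nrow(t)) t$day <- days[i] else t$day <- integer(0)
    t
  })
  variants <- do.call(rbind, tabs)
  if (is.null(variants)) {
    variants <- empty_variants()
    variants$day <- integer(0)
  }
  structure(list(patient_id = patient_id, days = days, variants = variants),
            class = "patient_series")
}

#' @export
print.patient_series <- function(x, ...) {
  cat("<patient_series> ", x$patient_id, ": ", length(x$days),
      " samples (days ", paste(x$days, collapse = ", "), "), ",
      nrow(x$variants), " variant calls\n", sep = "")
  invisible(x)
}

#' Read a whole cohort from a sample sheet
#'
#' @param sheet_path sample-sheet TSV (see [read_sample_sheet()]).
#' @param min_total_depth per-call depth threshold passed to [read_vcf()].
#' @param logr_key INFO key for the copy-number logR.
#' @return named list of [patient_series] objects.
#' @export
read_cohort <- function(sheet_path, min_total_depth = 100,
                        logr_key = "LOGR") {
  sheet <- read_sample_sheet(sheet_path)
  base <- dirname(sheet_path)
  lapply(stats::setNames(names(sheet), names(sheet)), function(p) {
    d <- sheet[[p]]
    paths <- ifelse(file.exists(d$vcf_path), d$vcf_path,
                    file.path(base, d$vcf_path))
    missing <- !file.exists(paths)
    if (any(missing)) stop("VCF not found: ", paths[missing][1])
    tabs <- lapply(paths, read_vcf, min_total_depth = min_total_depth,
                   logr_key = logr_key)
    patient_series(p, d$day, tabs)
  })
}
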