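## Input layer: VCFs + annotation table, clinical table, panel BED.
## VCF positions stay 1-based; BED intervals stay 0-based half-open.

#' Read a cohort of VCFs into a variant record table
#'
#' Each VCF holds one or more samples; every sample becomes one
#' patient-sample in the cohort table.  VAF is recomputed from the AD
#' (allelic depth) genotype field rather than trusting a caller AF tag, so
#' that the minimum-read guard used downstream is checkable.  Multi-allelic
#' sites are split into one record per alternate allele; the per-allele VAF
#' uses the site's total depth as denominator (equivalently, all non-allele
#' reads are counted as reference for that allele).
#'
#' @param paths Character vector of VCF file paths.
#' @param annotation_table Path to a tab-separated annotation table keyed on
#'   `chrom`, `pos`, `ref`, `alt` with columns `gene`, `consequence`,
#'   `pop_af`, `cosmic_flag`, `clinvar_flag`.  Records without an annotation
#'   row get `consequence = "other"` and missing `pop_af`.
#' @param patient_ids Optional character vector, one per sample across all
#'   files, overriding the VCF sample names.
#' @param sample_times Integer vector of sampling indices (0 = diagnosis),
#'   recycled across samples.
#' @return Data frame of variant records sorted by patient then locus.
#' @export
read_cohort_vcf <- function(paths, annotation_table = NULL,
                            patient_ids = NULL, sample_times = 0L) {
  for (p in paths)
    if (!file.exists(p)) stop("cannot read VCF file: ", p)
  ann <- if (!is.null(annotation_table)) read_annotation(annotation_table)
  recs <- list()
  sample_counter <- 0L
  for (p in paths) {
    vcf <- vcfR::read.vcfR(p, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    ad <- vcfR::extract.gt(vcf, element = "AD")
    if (is.null(ad)) stop("VCF lacks the AD genotype field: ", p)
    for (s in seq_len(ncol(ad))) {
      sample_counter <- sample_counter + 1L
      pid <- if (!is.null(patient_ids)) patient_ids[sample_counter] else
        colnames(ad)[s]
      stime <- rep_len(as.integer(sample_times), sample_counter)[sample_counter]
      for (i in seq_len(nrow(fix))) {
        alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
        depths <- suppressWarnings(
          as.integer(strsplit(ad[i, s], ",", fixed = TRUE)[[1]]))
        total <- sum(depths, na.rm = TRUE)
        if (is.na(total) || total <= 0) {
          warning(sprintf("rejected %s:%s in %s: zero total depth",
                          fix[i, "CHROM"], fix[i, "POS"], pid))
          next
        }
        for (a in seq_along(alts)) {
          alt_d <- depths[a + 1L]
          if (is.na(alt_d)) next
          recs[[length(recs) + 1L]] <- data.frame(
            patient_id = pid, sample_time = stime,
            chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
            ref = fix[i, "REF"], alt = alts[a],
            ref_depth = total - alt_d, alt_depth = alt_d,
            vaf = 100 * alt_d / total,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(recs))
    return(validate_records(annotate_records(
      data.frame(patient_id = character(), sample_time = integer(),
                 chrom = character(), pos = integer(), ref = character(),
                 alt = character(), ref_depth = integer(),
                 alt_depth = integer(), vaf = numeric()), ann)))
  out <- do.call(rbind, recs)
  out <- annotate_records(out, ann)
  validate_records(out)
  out <- .order_records(out)
  rownames(out) <- NULL
  out
}

read_annotation <- function(path) {
  if (!file.exists(path)) stop("cannot read annotation table: ", path)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character",
                                          ref = "character",
                                          alt = "character",
                                          gene = "character",
                                          consequence = "character"))
  need <- c("chrom", "pos", "ref", "alt")
  missing <- setdiff(need, names(ann))
  if (length(missing))
    stop("annotation table lacks key columns: ",
         paste(missing, collapse = ", "))
  ann
}

## join caller output with the upstream annotation table
annotate_records <- function(df, ann) {
  n <- nrow(df)
  df$gene <- rep(NA_character_, n)
  df$consequence <- rep("other", n)
  df$pop_af <- rep(NA_real_, n)
  df$cosmic_flag <- rep("absent", n)
  df$clinvar_flag <- rep(FALSE, n)
  if (!is.null(ann) && n) {
    key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
    akey <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
    idx <- match(key, akey)
    hit <- !is.na(idx)
    if ("gene" %in% names(ann)) df$gene[hit] <- ann$gene[idx[hit]]
    if ("consequence" %in% names(ann))
      df$consequence[hit] <- ann$consequence[idx[hit]]
    if ("pop_af" %in% names(ann)) df$pop_af[hit] <- ann$pop_af[idx[hit]]
    if ("cosmic_flag" %in% names(ann))
      df$cosmic_flag[hit] <- ann$cosmic_flag[idx[hit]]
    if ("clinvar_flag" %in% names(ann))
      df$clinvar_flag[hit] <- as.logical(ann$clinvar_flag[idx[hit]])
  }
  df[, .record_columns, drop = FALSE]
}

#' Read a cohort variant table from TSV
#'
#' The tab-separated counterpart of [read_cohort_vcf()]; this is the format
#' [write_cohort_tsv()] and the synthetic generator emit.
#'
#' @param path File path.
#' @return Validated record data frame.
#' @export
read_cohort_tsv <- function(path) {
  if (!file.exists(path)) stop("cannot read cohort table: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(patient_id = "character",
                                         chrom = "character",
                                         ref = "character",
                                         alt = "character",
                                         gene = "character",
                                         consequence = "character",
                                         cosmic_flag = "character",
                                         vaf = "numeric",
                                         pop_af = "numeric"))
  validate_records(df)
  .order_records(df[, .record_columns, drop = FALSE])
}

#' Write a cohort variant table as TSV
#'
#' @param records Record data frame.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_cohort_tsv <- function(records, path) {
  df <- records[, .record_columns, drop = FALSE]
  df$vaf <- .fmt_num(df$vaf)
  df$pop_af <- .fmt_num(df$pop_af)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read the clinical table
#'
#' Expects a tab-separated file with header columns `patient_id`, `age`,
#' `ipssr_category` (one of low / intermediate / high / very_high, spaces
#' tolerated), `blasts_pct`, `hemoglobin`, `neutrophils`, `platelets`,
#' `hsct`, `followup_time` (months), `event`.  The ordinal IPSS-R score
#' `ipssr_numeric` in 1..4 is derived from the category.
#'
#' @param path File path.
#' @return Data frame of clinical records, one row per patient.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("cannot read clinical table: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(patient_id = "character",
                                         ipssr_category = "character"))
  need <- c("patient_id", "ipssr_category", "followup_time", "event")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("clinical table lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id in clinical table")
  if (any(df$followup_time < 0))
    stop("negative follow-up time in clinical table")
  df$ipssr_numeric <- ipssr_to_numeric(df$ipssr_category)
  df$event <- as.logical(df$event)
  if ("hsct" %in% names(df)) df$hsct <- as.logical(df$hsct)
  df
}

#' Map IPSS-R risk categories to the ordinal score 1..4
#'
#' @param x Character vector of categories.
#' @return Integer vector in 1..4.
#' @export
ipssr_to_numeric <- function(x) {
  key <- gsub("[ -]", "_", tolower(trimws(x)))
  map <- c(low = 1L, intermediate = 2L, high = 3L, very_high = 4L)
  out <- map[key]
  if (any(is.na(out)))
    stop("unknown IPSS-R category: ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Read a BED3 panel file into merged regions
#'
#' Intervals are kept 0-based half-open as in BED and merged per chromosome
#' before the total target size is computed.
#'
#' @param path BED file path.
#' @return Object of class `panel_regions`: a list with the merged interval
#'   data frame and `total_size_bp`.
#' @export
read_panel_bed <- function(path) {
  if (!file.exists(path)) stop("cannot read BED file: ", path)
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty BED file: ", path)
  names(df)[1:3] <- c("chrom", "start", "end")
  panel_regions(df[, 1:3])
}

#' Construct panel regions from a chrom/start/end table
#'
#' @param df Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return Object of class `panel_regions` with merged intervals.
#' @export
panel_regions <- function(df) {
  if (!nrow(df)) stop("panel must contain at least one interval")
  merged <- do.call(rbind, lapply(split(df, df$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    data.frame(chrom = d$chrom[1], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  }))
  merged <- merged[order(merged$chrom, merged$start), , drop = FALSE]
  rownames(merged) <- NULL
  structure(list(intervals = merged,
                 total_size_bp = sum(merged$end - merged$start)),
            class = "panel_regions")
}

#' Panel target size in megabases
#'
#' @param regions A `panel_regions` object.
#' @return Merged target size / 1e6.
#' @export
panel_size_mb <- function(regions) {
  stopifnot(inherits(regions, "panel_regions"))
  if (!nrow(regions$intervals)) stop("panel has no intervals")
  regions$total_size_bp / 1e6
}

#' Write panel regions as BED3
#'
#' @param regions A `panel_regions` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_panel_bed <- function(regions, path) {
  utils::write.table(regions$intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a numeric matrix as TSV with exact round-trip
#'
#' Values are serialised with 17 significant digits so that reading the file
#' back reproduces the doubles bit-exactly.
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @param index_name Header for the row-name column.
#' @return The path, invisibly.
#' @export
write_matrix_tsv <- function(m, path, index_name = "id") {
  df <- as.data.frame(matrix(.fmt_num(m), nrow = nrow(m),
                             dimnames = dimnames(m)), check.names = FALSE)
  df <- cbind(stats::setNames(data.frame(rownames(m)), index_name), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a numeric matrix written by [write_matrix_tsv()]
#'
#' @param path File path.
#' @return Numeric matrix with dimnames restored.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}
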