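#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Consequence classes recognised by the pipeline
#'
#' @return Character vector of the consequence vocabulary.
#' @export
consequence_levels <- function() {
  c("missense", "nonsense", "frameshift", "inframe_indel", "splice",
    "synonymous", "utr5", "utr3", "intronic", "intergenic", "other")
}

#' The default 18-gene myeloid panel
#'
#' Common MDS driver genes plus the immune-checkpoint and micro-RNA
#' processing genes the method was designed around.
#'
#' @return Character vector of gene symbols.
#' @export
mds_panel_genes <- function() {
  c("ASXL1", "CD274", "CD276", "DICER1", "DNMT3A", "DROSHA", "EZH2",
    "IDH1", "IDH2", "LAG3", "MFSD11", "PDCD1", "PIKFYVE", "RUNX1",
    "SF3B1", "SRSF2", "TET2", "TP53")
}

#' Checkpoint and micro-RNA processing genes
#'
#' Genes for which UTR variants are retained by the functional filter, since
#' regulatory-region variation can modify expression of immune-checkpoint
#' receptors/ligands and of the micro-RNA processing machinery.
#'
#' @return Character vector of gene symbols.
#' @export
checkpoint_mirna_genes <- function() {
  c("CD274", "CD276", "CTLA4", "LAG3", "PDCD1", "DICER1", "DROSHA")
}

#' Variant key from locus and alleles
#'
#' @param chrom,pos,ref,alt Vectors describing one alternate allele each.
#' @return Character key `chrom:pos:ref:alt`.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

## canonical record ordering: patient, then locus
.order_records <- function(df) {
  df[order(df$patient_id, df$chrom, df$pos, df$ref, df$alt,
           df$sample_time, method = "radix"), , drop = FALSE]
}

.record_columns <- c("patient_id", "sample_time", "chrom", "pos", "ref",
                     "alt", "gene", "consequence", "ref_depth", "alt_depth",
                     "vaf", "pop_af", "cosmic_flag", "clinvar_flag")

#' Validate a cohort variant table
#'
#' Checks the invariants of the record table: required columns, positive
#' total depth, VAF consistent with allelic depths, consequence vocabulary.
#'
#' @param records Data frame of variant records.
#' @return The validated records, invisibly reordered columns.
#' @export
validate_records <- function(records) {
  missing <- setdiff(.record_columns, names(records))
  if (length(missing))
    stop("record table lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(records)) {
    tot <- records$ref_depth + records$alt_depth
    if (any(!is.na(tot) & tot <= 0))
      stop("records with zero total depth are not valid")
    have <- !is.na(records$ref_depth) & !is.na(records$alt_depth)
    if (any(have)) {
      expect <- 100 * records$alt_depth[have] / tot[have]
      if (any(abs(expect - records$vaf[have]) > 1e-9))
        stop("vaf inconsistent with allelic depths")
    }
    bad <- setdiff(unique(records$consequence), consequence_levels())
    if (length(bad))
      stop("unknown consequence class: ", paste(bad, collapse = ", "))
  }
  invisible(records[, .record_columns, drop = FALSE])
}

## Mann-Whitney U with the policy used throughout: exact permutation null
## (full enumeration over group assignments, midranks for ties) when the
## combined sample size is at most `exact_max`, otherwise the normal
## approximation with continuity correction via wilcox.test.  Fully tied
## data carry no information -> p = 1.  The exact two-sided p is the
## probability of a U at least as far from its null mean mn/2 as observed;
## for untied data this coincides with the classical exact test.
.mann_whitney <- function(x, y, exact_max = 20L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  m <- length(x); n <- length(y)
  if (m == 0L || n == 0L) stop("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1L) {
    warning("all values tied across groups; p set to 1")
    return(list(statistic = m * n / 2, p = 1))
  }
  r <- rank(c(x, y))                    # midranks
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if ((m + n) <= exact_max) {
    sel <- utils::combn(m + n, m)
    u_all <- colSums(matrix(r[sel], nrow = m)) - m * (m + 1) / 2
    dev <- abs(u_obs - m * n / 2)
    p <- mean(abs(u_all - m * n / 2) >= dev - 1e-9)
    return(list(statistic = u_obs, p = p))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p = unname(wt$p.value))
}

## full-precision numeric formatting so that written matrices round-trip
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}
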