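## Filter cascade: consequence class -> population frequency -> detection
## (VAF + read support) -> cohort prevalence / singleton pruning.
## Every filter is a contraction of the record set and idempotent, and the
## three per-record filters commute (they act on disjoint record fields).

#' Filter configuration
#'
#' Bundles the thresholds of the filter cascade.  Two threshold regimes are
#' used in practice: a 5\% VAF threshold restricted to exonic pathogenic
#' classes for reporting common MDS driver mutations, and a 1\% threshold
#' including UTRs of checkpoint / micro-RNA-processing genes for the general
#' analysis and for clustering (minor subpopulations, e.g. bone-marrow niche
#' cells, can carry low-VAF variants).  At panel depths of roughly 1000x the
#' 1\% threshold together with `min_alt_reads = 10` guards against false
#' positives.
#'
#' @param vaf_threshold_pct Minimum VAF in percent (default 1).
#' @param min_alt_reads Minimum alternate-allele reads (default 10).
#' @param pop_af_max Maximum population (gnomAD-style) allele frequency as a
#'   fraction; variants above it are treated as common polymorphisms and
#'   removed (default 0.01).  Missing population frequency is retained:
#'   absence from the database implies the variant is rare.
#' @param drop_consequences Consequence classes removed by the functional
#'   filter (default synonymous, intronic, intergenic).
#' @param keep_utr_genes Genes whose `utr5`/`utr3` records survive the
#'   functional filter even when UTR classes are in `drop_consequences`
#'   (default the checkpoint + micro-RNA processing genes).
#' @param prevalence_cap Cohort prevalence above which a variant is treated
#'   as an unfiltered common polymorphism: excluded from tallies, kept for
#'   display (default 0.5).
#' @param drop_singletons Whether clustering input excludes variants seen in
#'   a single patient (default TRUE).
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(vaf_threshold_pct = 1,
                          min_alt_reads = 10L,
                          pop_af_max = 0.01,
                          drop_consequences = c("synonymous", "intronic",
                                                "intergenic"),
                          keep_utr_genes = checkpoint_mirna_genes(),
                          prevalence_cap = 0.5,
                          drop_singletons = TRUE) {
  if (!(vaf_threshold_pct > 0 && vaf_threshold_pct <= 100))
    stop("vaf_threshold_pct must be in (0, 100]")
  if (pop_af_max < 0 || pop_af_max > 1)
    stop("pop_af_max must be in [0, 1]")
  bad <- setdiff(drop_consequences, consequence_levels())
  if (length(bad))
    stop("unknown consequence class: ", paste(bad, collapse = ", "))
  structure(list(vaf_threshold_pct = vaf_threshold_pct,
                 min_alt_reads = as.integer(min_alt_reads),
                 pop_af_max = pop_af_max,
                 drop_consequences = drop_consequences,
                 keep_utr_genes = keep_utr_genes,
                 prevalence_cap = prevalence_cap,
                 drop_singletons = isTRUE(drop_singletons)),
            class = "filter_config")
}

#' Reporting configuration for common driver mutations
#'
#' The 5\% VAF regime restricted to exonic pathogenic classes (missense,
#' nonsense, frameshift, in-frame indel, splice).
#'
#' @param vaf_threshold_pct Minimum VAF in percent (default 5).
#' @param ... Passed to [filter_config()].
#' @return Object of class `filter_config`.
#' @export
reporting_config <- function(vaf_threshold_pct = 5, ...) {
  filter_config(vaf_threshold_pct = vaf_threshold_pct,
                drop_consequences = c("synonymous", "intronic", "intergenic",
                                      "utr5", "utr3", "other"),
                keep_utr_genes = character(0), ...)
}

#' Remove non-functional consequence classes
#'
#' Drops records whose consequence class is in `config$drop_consequences`,
#' except that UTR records of genes in `config$keep_utr_genes` are always
#' retained (all mutations, exonic and UTR, are of interest in the
#' checkpoint / micro-RNA genes whose clinical relevance is undetermined).
#'
#' @param records Record data frame.
#' @param config A [filter_config()].
#' @return Subset of `records`.
#' @export
filter_functional <- function(records, config = filter_config()) {
  if (!nrow(records)) return(records)
  drop <- records$consequence %in% config$drop_consequences
  utr_keep <- records$consequence %in% c("utr5", "utr3") &
    records$gene %in% config$keep_utr_genes
  out <- records[!drop | utr_keep, , drop = FALSE]
  if (!nrow(out)) message("functional filter removed all records")
  out
}

#' Remove common population polymorphisms
#'
#' Drops records whose annotated population allele frequency exceeds
#' `config$pop_af_max`; records with missing population frequency are kept.
#'
#' @inheritParams filter_functional
#' @return Subset of `records`.
#' @export
filter_population <- function(records, config = filter_config()) {
  if (!nrow(records)) return(records)
  drop <- !is.na(records$pop_af) & records$pop_af > config$pop_af_max
  records[!drop, , drop = FALSE]
}

#' Apply the VAF threshold and minimum-read guard
#'
#' Keeps records with `vaf >= vaf_threshold_pct` and
#' `alt_depth >= min_alt_reads`.
#'
#' @inheritParams filter_functional
#' @return Subset of `records`.
#' @export
filter_detection <- function(records, config = filter_config()) {
  if (!nrow(records)) return(records)
  keep <- records$vaf >= config$vaf_threshold_pct &
    records$alt_depth >= config$min_alt_reads
  records[keep, , drop = FALSE]
}

## patients carrying each variant key (diagnosis and later samples count once)
.patients_per_variant <- function(records) {
  key <- variant_key(records$chrom, records$pos, records$ref, records$alt)
  tapply(records$patient_id, key, function(p) length(unique(p)))
}

#' Split off variants above the cohort prevalence cap
#'
#' Variants detected in more than `prevalence_cap * n_patients` patients are
#' treated as ubiquitous polymorphisms: excluded from prevalence tallies but
#' returned separately so reports can still display them.
#'
#' @inheritParams filter_functional
#' @param n_patients Cohort size used as the prevalence denominator.
#' @return List with elements `kept` and `display_only`, both record data
#'   frames.
#' @export
filter_cohort_prevalence <- function(records, n_patients,
                                     config = filter_config()) {
  stopifnot(n_patients >= 1)
  if (!nrow(records))
    return(list(kept = records, display_only = records))
  counts <- .patients_per_variant(records)
  key <- variant_key(records$chrom, records$pos, records$ref, records$alt)
  common <- counts[key] > config$prevalence_cap * n_patients
  list(kept = records[!common, , drop = FALSE],
       display_only = records[common, , drop = FALSE])
}

#' Exclude variants detected in only one patient
#'
#' Singleton variants carry no between-patient contrast and would only add
#' noise to the shift matrix, so they are removed before clustering.
#'
#' @param records Record data frame.
#' @return Subset of `records`.
#' @export
drop_singletons <- function(records) {
  if (!nrow(records)) return(records)
  counts <- .patients_per_variant(records)
  key <- variant_key(records$chrom, records$pos, records$ref, records$alt)
  out <- records[counts[key] > 1L, , drop = FALSE]
  if (!nrow(out))
    warning("all variants are singletons; nothing left for clustering")
  out
}

#' The full clustering input cascade
#'
#' Functional filter, population filter, detection at the configured (1\%)
#' threshold, then singleton exclusion.
#'
#' @inheritParams filter_functional
#' @return Subset of `records` forming the clustering input set.
#' @export
clustering_set <- function(records, config = filter_config()) {
  out <- filter_functional(records, config)
  out <- filter_population(out, config)
  out <- filter_detection(out, config)
  if (config$drop_singletons) out <- drop_singletons(out)
  out
}

#' The reporting cascade
#'
#' Functional, population and detection filters under a reporting
#' configuration; no singleton exclusion.
#'
#' @inheritParams filter_functional
#' @return Subset of `records`.
#' @export
reporting_set <- function(records, config = reporting_config()) {
  out <- filter_functional(records, config)
  out <- filter_population(out, config)
  filter_detection(out, config)
}
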