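## Cohort-level descriptive statistics and cluster-vs-clinical comparisons.

#' Per-gene mutation prevalence
#'
#' Counts, per gene, the number of patients carrying at least one qualifying
#' variant at diagnosis; a patient counts once per gene however many
#' variants they carry.  The denominator is the full enrolled cohort, not
#' only patients with any mutation.
#'
#' @param records Record data frame, already filtered by the reporting
#'   cascade appropriate to `gene_set`.
#' @param patients Character vector of all enrolled patient ids.
#' @param gene_set Genes to tabulate (default: genes present in `records`);
#'   genes with no mutated patient get a zero row.
#' @return Data frame with columns `gene`, `n_mutated`, `fraction` (exact
#'   percentage) and `percent` (rounded to integer, as reported).
#' @export
gene_prevalence <- function(records, patients, gene_set = NULL) {
  n <- length(patients)
  if (n == 0L) stop("empty cohort")
  recs <- records[records$sample_time == 0L & !is.na(records$gene), ,
                  drop = FALSE]
  gene_set <- gene_set %||% sort(unique(recs$gene), method = "radix")
  counts <- vapply(gene_set, function(g) {
    length(unique(recs$patient_id[recs$gene == g]))
  }, integer(1))
  out <- data.frame(gene = gene_set, n_mutated = unname(counts),
                    fraction = unname(100 * counts / n),
                    stringsAsFactors = FALSE)
  out$percent <- round(out$fraction)
  rownames(out) <- NULL
  out
}

#' Mutation burden per megabase
#'
#' Number of qualifying diagnosis variants per patient, normalised by the
#' merged panel target size in megabases.
#'
#' @param records Filtered record data frame.
#' @param regions A `panel_regions` object.
#' @param patients Cohort patient ids (patients without variants get burden
#'   0); defaults to patients present in `records`.
#' @return Data frame with columns `patient_id`, `n_variants`, `per_mb`.
#' @export
mutation_burden <- function(records, regions, patients = NULL) {
  mb <- panel_size_mb(regions)
  recs <- records[records$sample_time == 0L, , drop = FALSE]
  patients <- patients %||% sort(unique(recs$patient_id), method = "radix")
  counts <- vapply(patients, function(p) sum(recs$patient_id == p),
                   integer(1))
  data.frame(patient_id = patients, n_variants = unname(counts),
             per_mb = unname(counts / mb), stringsAsFactors = FALSE)
}

#' Compare a quantitative clinical field between the two clusters
#'
#' Two-sided Mann-Whitney U test; the null distribution is the exact
#' permutation null (full enumeration, midranks for ties) when the combined
#' sample size is at most 20, otherwise the normal approximation with
#' continuity correction is used.
#'
#' @param clinical Clinical data frame (from [read_clinical()]).
#' @param labels Named cluster labels (patient id -> 1/2).
#' @param field Name of a numeric column of `clinical`.
#' @return List with `field`, `statistic` (U), `p`, `median_1`, `median_2`,
#'   `n_1`, `n_2`.
#' @export
compare_clusters_quantitative <- function(clinical, labels, field) {
  if (is.list(labels) && !is.null(labels$labels)) labels <- labels$labels
  lab <- labels[clinical$patient_id]
  if (anyNA(lab)) stop("labels missing for some patients")
  v <- clinical[[field]]
  if (!is.numeric(v)) stop("field '", field, "' is not numeric")
  x <- v[lab == 1L]; y <- v[lab == 2L]
  if (!length(x) || !length(y)) stop("both clusters must be non-empty")
  mw <- .mann_whitney(x, y)
  list(field = field, statistic = mw$statistic, p = mw$p,
       median_1 = stats::median(x, na.rm = TRUE),
       median_2 = stats::median(y, na.rm = TRUE),
       n_1 = length(x), n_2 = length(y))
}

#' Compare a binary clinical field between the two clusters
#'
#' Two-sided Fisher exact test on the 2x2 cluster-by-field table.  The
#' reported odds ratio is the sample cross-product ratio, with the Haldane
#' half-count correction applied when any cell is zero; the p-value comes
#' from the exact conditional (hypergeometric) null.
#'
#' @inheritParams compare_clusters_quantitative
#' @param field Name of a logical (or 0/1) column of `clinical`.
#' @return List with `field`, `table`, `odds_ratio`, `p`, `rate_1`,
#'   `rate_2`.
#' @export
compare_clusters_categorical <- function(clinical, labels, field) {
  if (is.list(labels) && !is.null(labels$labels)) labels <- labels$labels
  lab <- labels[clinical$patient_id]
  if (anyNA(lab)) stop("labels missing for some patients")
  v <- as.logical(clinical[[field]])
  tab <- matrix(c(sum(v[lab == 1L]), sum(!v[lab == 1L]),
                  sum(v[lab == 2L]), sum(!v[lab == 2L])),
                nrow = 2, byrow = TRUE,
                dimnames = list(cluster = c("1", "2"),
                                field = c("yes", "no")))
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 table (zero margin); p set to 1")
    return(list(field = field, table = tab, odds_ratio = NA_real_, p = 1,
                rate_1 = a / max(a + b, 1), rate_2 = c_ / max(c_ + d, 1)))
  }
  or <- if (any(tab == 0))
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  else (a * d) / (b * c_)
  p <- stats::fisher.test(tab)$p.value
  list(field = field, table = tab, odds_ratio = or, p = p,
       rate_1 = a / (a + b), rate_2 = c_ / (c_ + d))
}

#' Longitudinal VAF trajectories for one patient
#'
#' For every variant detected at any time point of the patient, returns the
#' VAF series over all of the patient's time points (0 where undetected) and
#' classifies the trajectory: `emerging` (absent at diagnosis, at or above
#' `emerge_threshold_pct` later), `expanding` / `contracting` (net VAF
#' change of at least `change_pct` points), otherwise `stable`.
#'
#' @param records Record data frame with `sample_time` indices.
#' @param patient_id Patient to trace.
#' @param change_pct Net VAF change (percentage points) separating
#'   expanding/contracting from stable (default 10).
#' @param emerge_threshold_pct Detection level a variant absent at diagnosis
#'   must reach later to be called emerging (default 1).
#' @return List with `trajectories` (long data frame: `variant`, `gene`,
#'   `sample_time`, `vaf`) and `classification` (data frame: `variant`,
#'   `gene`, `delta`, `class`).
#' @export
longitudinal_trajectories <- function(records, patient_id, change_pct = 10,
                                      emerge_threshold_pct = 1) {
  recs <- records[records$patient_id == patient_id, , drop = FALSE]
  times <- sort(unique(recs$sample_time))
  if (length(times) < 2L)
    stop("patient ", patient_id, " has fewer than two time points")
  key <- variant_key(recs$chrom, recs$pos, recs$ref, recs$alt)
  variants <- unique(key[order(recs$chrom, recs$pos, recs$ref,
                               recs$alt, method = "radix")])
  gene_of <- recs$gene[match(variants, key)]
  grid <- expand.grid(variant = variants, sample_time = times,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- match(paste(grid$variant, grid$sample_time),
               paste(key, recs$sample_time))
  grid$vaf <- ifelse(is.na(idx), 0, recs$vaf[idx])
  grid$gene <- gene_of[match(grid$variant, variants)]
  cls <- vapply(variants, function(v) {
    tv <- grid$vaf[grid$variant == v]
    delta <- tv[length(tv)] - tv[1]
    if (tv[1] == 0 && max(tv[-1]) >= emerge_threshold_pct) "emerging"
    else if (delta >= change_pct) "expanding"
    else if (delta <= -change_pct) "contracting"
    else "stable"
  }, character(1))
  delta <- vapply(variants, function(v) {
    tv <- grid$vaf[grid$variant == v]
    tv[length(tv)] - tv[1]
  }, numeric(1))
  list(trajectories = grid[, c("variant", "gene", "sample_time", "vaf")],
       classification = data.frame(variant = variants, gene = gene_of,
                                   delta = unname(delta),
                                   class = unname(cls),
                                   stringsAsFactors = FALSE))
}

#' Pairwise gene co-occurrence counts
#'
#' Number of patients mutated in both genes of each pair, the machine
#' counterpart of a circos association plot.
#'
#' @param records Filtered record data frame.
#' @param gene_set Genes to include (default: genes present).
#' @return Symmetric integer matrix; the diagonal holds per-gene patient
#'   counts.
#' @export
gene_cooccurrence <- function(records, gene_set = NULL) {
  recs <- records[records$sample_time == 0L & !is.na(records$gene), ,
                  drop = FALSE]
  gene_set <- gene_set %||% sort(unique(recs$gene), method = "radix")
  pats <- sort(unique(recs$patient_id))
  ind <- vapply(gene_set, function(g)
    pats %in% recs$patient_id[recs$gene == g], logical(length(pats)))
  if (is.null(dim(ind))) ind <- matrix(ind, nrow = length(pats))
  m <- t(ind) %*% ind
  storage.mode(m) <- "integer"
  dimnames(m) <- list(gene_set, gene_set)
  m
}
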