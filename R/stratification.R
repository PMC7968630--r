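## Median-anchored frequency-shift matrix and two-cluster patient
## stratification.  The anchor of a variant is the member of {0, 50, 100}%
## nearest its cohort median VAF (ties toward the lower anchor); subtracting
## it jointly exposes abnormal polymorphisms (genotype contrasts around
## 50/100%) and somatic clones (shifts above an anchor of 0) without a
## matched germline control.

#' Build the patients-by-variants VAF matrix
#'
#' One row per unique variant key, one column per patient (patients with no
#' surviving variants keep an all-zero column); cells hold VAF in percent, 0
#' where the variant was not detected in that patient.
#'
#' @param records Pre-filtered record data frame (diagnosis samples).
#' @param patients Character vector fixing the cohort and column order;
#'   defaults to the patients present in `records`.
#' @return Numeric matrix, rows = variant keys, columns = patients.
#' @export
build_vaf_matrix <- function(records, patients = NULL) {
  if (!nrow(records)) stop("nothing to cluster: no records")
  patients <- patients %||% sort(unique(records$patient_id), method = "radix")
  key <- variant_key(records$chrom, records$pos, records$ref, records$alt)
  ord <- order(records$chrom, records$pos, records$ref, records$alt,
               method = "radix")
  variants <- unique(key[ord])
  m <- matrix(0, nrow = length(variants), ncol = length(patients),
              dimnames = list(variants, patients))
  ri <- match(key, variants)
  ci <- match(records$patient_id, patients)
  if (anyNA(ci))
    stop("records contain patients outside the supplied cohort: ",
         paste(unique(records$patient_id[is.na(ci)]), collapse = ", "))
  dup <- duplicated(cbind(ri, ci))
  if (any(dup)) {
    warning("duplicate (patient, variant) records; keeping the first")
    ri <- ri[!dup]; ci <- ci[!dup]
    m[cbind(ri, ci)] <- records$vaf[!dup]
  } else {
    m[cbind(ri, ci)] <- records$vaf
  }
  if (any(m < 0 | m > 100)) stop("VAF values outside [0, 100]")
  m
}

#' Anchor of one variant: the {0, 50, 100}\% value nearest the median VAF
#'
#' Zeros for non-detections are part of the median.  When the median is
#' equidistant from two anchors (exactly 25 or 75) the lower anchor is
#' chosen.
#'
#' @param vafs Numeric vector of VAF percentages across all patients.
#' @return One of 0, 50, 100.
#' @export
compute_anchor <- function(vafs) {
  if (!length(vafs)) stop("empty VAF vector")
  anchors <- c(0, 50, 100)
  med <- stats::median(vafs)
  anchors[which.min(abs(anchors - med))]
}

#' Per-variant anchors for a VAF matrix
#'
#' @param m VAF matrix from [build_vaf_matrix()].
#' @return Named numeric vector of anchors, one per variant row.
#' @export
compute_anchors <- function(m) {
  apply(m, 1, compute_anchor)
}

#' Frequency-shift matrix
#'
#' Subtracts each variant's anchor from every patient's VAF, producing
#' shifts bounded in [-100, +100].
#'
#' @param m VAF matrix from [build_vaf_matrix()].
#' @return Object of class `shift_matrix`: list with `values` (same
#'   dimnames as `m`) and `anchors`.
#' @export
compute_shift_matrix <- function(m) {
  anchors <- compute_anchors(m)
  values <- m - anchors
  stopifnot(all(values >= -100), all(values <= 100))
  structure(list(values = values, anchors = anchors),
            class = "shift_matrix")
}

#' @export
print.shift_matrix <- function(x, ...) {
  cat(sprintf("Frequency-shift matrix: %d variants x %d patients\n",
              nrow(x$values), ncol(x$values)))
  cat("Anchors:", paste(sprintf("%d%%: %d", c(0, 50, 100),
                                tabulate(factor(x$anchors,
                                                c(0, 50, 100)), 3)),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Cluster patients on the shift matrix
#'
#' Agglomerative clustering of patient columns under Euclidean distance,
#' cut to the top `k` clusters.  Ward's criterion (`ward.D2`, the form
#' consistent with raw Euclidean distances) is the default linkage;
#' `complete` and `average` are supported alternatives.  Labels are made
#' deterministic by assigning label 1 to the cluster containing the
#' lexicographically smallest patient id (and so on for k > 2).
#'
#' @param s A `shift_matrix`.
#' @param k Number of clusters (default 2).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return Object of class `cluster_assignment`: list with `labels` (named
#'   integer vector), `tree` (the `hclust` object), `linkage_name`, `k`.
#' @export
cluster_patients <- function(s, k = 2L, linkage = "ward.D2") {
  stopifnot(inherits(s, "shift_matrix"))
  n <- ncol(s$values)
  if (n < k) stop("fewer patients (", n, ") than clusters (", k, ")")
  d <- stats::dist(t(s$values), method = "euclidean")
  hc <- stats::hclust(d, method = linkage)
  raw <- stats::cutree(hc, k = k)
  ## relabel deterministically by each cluster's smallest patient id
  ## (radix order keeps label assignment independent of the locale)
  smallest <- tapply(names(raw), raw, function(x)
    sort(x, method = "radix")[1])
  newlab <- integer(k)
  newlab[order(smallest, method = "radix")] <- seq_len(k)
  labels <- stats::setNames(newlab[raw], names(raw))
  structure(list(labels = labels, tree = hc,
                 linkage_name = linkage, k = as.integer(k)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Patient clustering (%s linkage, Euclidean distance)\n",
              x$linkage_name))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Row (variant) dendrogram leaf order
#'
#' Clusters the variant rows of the shift matrix the same way patients are
#' clustered and returns the dendrogram leaf order, for heatmap export.
#'
#' @param s A `shift_matrix`.
#' @param linkage Agglomeration method.
#' @return Character vector of variant keys in leaf order.
#' @export
cluster_variants <- function(s, linkage = "ward.D2") {
  stopifnot(inherits(s, "shift_matrix"))
  if (nrow(s$values) < 2L) return(rownames(s$values))
  hc <- stats::hclust(stats::dist(s$values, method = "euclidean"),
                      method = linkage)
  rownames(s$values)[hc$order]
}

#' Rank variants by how strongly they separate the two clusters
#'
#' Per variant, a two-sided Mann-Whitney test compares shift values between
#' the clusters; raw p-values are Benjamini-Hochberg adjusted.  The table is
#' sorted by ascending raw p (descending significance), ties broken by
#' variant key.
#'
#' @param s A `shift_matrix`.
#' @param labels Named integer vector of cluster labels (1/2) as produced by
#'   [cluster_patients()].
#' @return Data frame with columns `variant`, `statistic`, `p`,
#'   `p_adjusted`.
#' @export
rank_discriminant_variants <- function(s, labels) {
  stopifnot(inherits(s, "shift_matrix"))
  if (is.list(labels) && !is.null(labels$labels)) labels <- labels$labels
  labels <- labels[colnames(s$values)]
  if (anyNA(labels)) stop("labels missing for some patients")
  g1 <- labels == 1L; g2 <- labels == 2L
  if (!any(g1) || !any(g2)) stop("both clusters must be non-empty")
  res <- suppressWarnings(apply(s$values, 1, function(v) {
    mw <- .mann_whitney(v[g1], v[g2])
    c(mw$statistic, mw$p)
  }))
  out <- data.frame(variant = rownames(s$values),
                    statistic = res[1, ], p = res[2, ],
                    stringsAsFactors = FALSE)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$variant, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a clustering merge tree in Newick format
#'
#' @param assignment A `cluster_assignment` (or bare `hclust`).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_newick <- function(assignment, path) {
  hc <- if (inherits(assignment, "cluster_assignment")) assignment$tree
  else assignment
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
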