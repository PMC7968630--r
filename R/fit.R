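## The front-door model fit: filter cascade -> VAF matrix -> anchored
## frequency-shift matrix -> two-cluster patient stratification -> cluster
## comparisons and survival inference.

#' Fit the frequency-shift stratification model to a cohort
#'
#' Runs the complete germline-control-free analysis on a cohort variant
#' table: the clustering cascade (functional, population and detection
#' filters at the general 1\% threshold, then singleton exclusion) on
#' diagnosis samples, the median-anchored frequency-shift matrix,
#' agglomerative two-cluster patient stratification, Mann-Whitney ranking
#' of cluster-discriminant variants, per-gene prevalence under both
#' reporting regimes, mutation burden per megabase (when a panel is given),
#' cluster-vs-clinical comparisons and Kaplan-Meier / log-rank / Cox
#' survival inference (when a clinical table is given).
#'
#' @param records Cohort variant table ([read_cohort_vcf()],
#'   [read_cohort_tsv()] or [generate_cohort()]).
#' @param clinical Optional clinical data frame ([read_clinical()]).
#' @param panel Optional `panel_regions` for burden normalisation.
#' @param config [filter_config()] for the clustering cascade.
#' @param report_config [reporting_config()] for the common-driver report.
#' @param linkage Linkage method for [cluster_patients()].
#' @param k Number of patient clusters (default 2).
#' @param ties Cox tie handling, `"breslow"` or `"efron"`.
#' @param horizon Survival evaluation horizon in months (default 60,
#'   i.e. five-year overall survival).
#' @param quantitative_fields,categorical_fields Clinical columns compared
#'   between clusters (defaults cover the usual blood counts and HSCT).
#' @return Object of class `mds_fit`.
#' @export
mds_fit <- function(records, clinical = NULL, panel = NULL,
                    config = filter_config(),
                    report_config = reporting_config(),
                    linkage = "ward.D2", k = 2L,
                    ties = "breslow", horizon = 60,
                    quantitative_fields = c("age", "blasts_pct",
                                            "hemoglobin", "neutrophils",
                                            "platelets", "ipssr_numeric"),
                    categorical_fields = "hsct") {
  validate_records(records)
  diagnosis <- records[records$sample_time == 0L, , drop = FALSE]
  patients <- if (!is.null(clinical)) clinical$patient_id else
    sort(unique(diagnosis$patient_id), method = "radix")

  cl_set <- clustering_set(diagnosis, config)
  if (!nrow(cl_set)) stop("nothing to cluster after filtering")
  vaf <- build_vaf_matrix(cl_set, patients)
  shift <- compute_shift_matrix(vaf)
  assignment <- cluster_patients(shift, k = k, linkage = linkage)
  variant_order <- cluster_variants(shift, linkage = linkage)
  discriminant <- if (k == 2L)
    rank_discriminant_variants(shift, assignment$labels)

  rep_set <- reporting_set(diagnosis, report_config)
  gen_set <- clustering_set(diagnosis,
                            filter_config(
                              vaf_threshold_pct = config$vaf_threshold_pct,
                              min_alt_reads = config$min_alt_reads,
                              pop_af_max = config$pop_af_max,
                              drop_singletons = FALSE))
  prev <- filter_cohort_prevalence(gen_set, length(patients), config)
  prevalence <- list(
    common = gene_prevalence(rep_set, patients),
    general = gene_prevalence(prev$kept, patients),
    display_only = prev$display_only)
  burden <- if (!is.null(panel))
    mutation_burden(prev$kept, panel, patients)

  comparisons <- survival <- NULL
  if (!is.null(clinical) && k == 2L) {
    lab <- assignment$labels
    comp <- list()
    for (f in intersect(quantitative_fields, names(clinical)))
      comp[[f]] <- c(compare_clusters_quantitative(clinical, lab, f),
                     type = "mann_whitney")
    for (f in intersect(categorical_fields, names(clinical)))
      comp[[f]] <- c(compare_clusters_categorical(clinical, lab, f),
                     type = "fisher")
    comparisons <- comp
    if (all(c("followup_time", "event") %in% names(clinical)) &&
        any(clinical$event)) {
      lab_p <- lab[clinical$patient_id]
      km <- lapply(1:2, function(cl)
        km_estimate(clinical$followup_time[lab_p == cl],
                    clinical$event[lab_p == cl]))
      names(km) <- c("cluster1", "cluster2")
      os <- lapply(km, function(cv)
        suppressWarnings(survival_at(cv, horizon)))
      lr <- logrank_test(clinical$followup_time, clinical$event, lab_p)
      cox <- NULL
      if (sum(clinical$event) >= 2L) {
        covs <- cbind(cluster2 = as.numeric(lab_p == 2L))
        if ("ipssr_numeric" %in% names(clinical))
          covs <- cbind(covs, ipssr = clinical$ipssr_numeric)
        cox <- tryCatch(
          suppressWarnings(cox_fit(clinical$followup_time, clinical$event,
                                   covs, ties = ties)),
          error = function(e) NULL)
      }
      survival <- list(km = km, os_at_horizon = os, horizon = horizon,
                       logrank = lr, cox = cox)
    }
  }

  structure(list(patients = patients, n_variants = nrow(vaf),
                 records = records, clustering_records = cl_set,
                 vaf_matrix = vaf, shift = shift,
                 assignment = assignment, variant_order = variant_order,
                 discriminant = discriminant, prevalence = prevalence,
                 burden = burden, comparisons = comparisons,
                 survival = survival, clinical = clinical, panel = panel,
                 config = config, linkage = linkage, k = as.integer(k)),
            class = "mds_fit")
}

#' @export
print.mds_fit <- function(x, ...) {
  cat("Frequency-shift cohort stratification\n")
  cat(sprintf("  %d patients, %d clustering variants (%s linkage)\n",
              length(x$patients), x$n_variants, x$linkage))
  sizes <- table(x$assignment$labels)
  cat("  cluster sizes:",
      paste(sprintf("%s: %d", names(sizes), sizes), collapse = ", "), "\n")
  if (!is.null(x$survival)) {
    cat(sprintf("  log-rank chi^2 = %.3f, p = %.4g\n",
                x$survival$logrank$chi_square, x$survival$logrank$p))
    if (!is.null(x$survival$cox)) {
      hr <- x$survival$cox$table["cluster2", ]
      cat(sprintf("  Cox cluster-2 HR = %.2f (95%% CI %.2f-%.2f), p = %.4g\n",
                  hr$hr, hr$lower, hr$upper, hr$p))
    }
  }
  invisible(x)
}

#' @export
summary.mds_fit <- function(object, n_top = 15L, ...) {
  out <- list(
    n_patients = length(object$patients),
    n_variants = object$n_variants,
    cluster_sizes = table(object$assignment$labels),
    anchors = table(factor(object$shift$anchors, c(0, 50, 100))),
    top_discriminant = if (!is.null(object$discriminant))
      utils::head(object$discriminant, n_top),
    prevalence = object$prevalence$general,
    comparisons = object$comparisons,
    survival = object$survival)
  class(out) <- "summary.mds_fit"
  out
}

#' @export
print.summary.mds_fit <- function(x, ...) {
  cat(sprintf("Cohort: %d patients, %d clustering variants\n",
              x$n_patients, x$n_variants))
  cat("Cluster sizes:\n"); print(x$cluster_sizes)
  cat("Variant anchors (0/50/100%):\n"); print(x$anchors)
  if (!is.null(x$top_discriminant)) {
    cat("Most cluster-discriminant variants:\n")
    print(x$top_discriminant, digits = 3)
  }
  if (!is.null(x$comparisons)) {
    cat("Cluster comparisons (field: p):\n")
    for (cmp in x$comparisons)
      cat(sprintf("  %s: p = %.4g\n", cmp$field, cmp$p))
  }
  if (!is.null(x$survival)) {
    os <- x$survival$os_at_horizon
    cat(sprintf("OS at %g months: cluster 1 %.0f%% (%.0f-%.0f), cluster 2 %.0f%% (%.0f-%.0f)\n",
                x$survival$horizon,
                100 * os$cluster1$estimate, 100 * os$cluster1$lower,
                100 * os$cluster1$upper,
                100 * os$cluster2$estimate, 100 * os$cluster2$lower,
                100 * os$cluster2$upper))
    cat(sprintf("Log-rank p = %.4g\n", x$survival$logrank$p))
    if (!is.null(x$survival$cox)) print(x$survival$cox)
  }
  invisible(x)
}

#' @export
coef.mds_fit <- function(object, ...) {
  if (is.null(object$survival$cox))
    stop("fit has no Cox model (no clinical data or too few events)")
  coef(object$survival$cox)
}

#' Cluster labels of a fit
#'
#' @param object An `mds_fit`.
#' @param ... Unused.
#' @return Named integer vector patient -> cluster.
#' @export
labels.mds_fit <- function(object, ...) object$assignment$labels

#' Assign new patients to the fitted clusters
#'
#' New VAF profiles are anchored with the fitted per-variant anchors and
#' assigned to the cluster with the nearest mean shift profile (Euclidean
#' nearest centroid).  Variants absent from the fit are ignored; fitted
#' variants missing from `newdata` are taken as VAF 0.
#'
#' @param object An `mds_fit`.
#' @param newdata Numeric matrix of VAF percentages, rows = variant keys,
#'   columns = new patients.
#' @param ... Unused.
#' @return Named integer vector of predicted cluster labels.
#' @export
predict.mds_fit <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  vars <- rownames(object$shift$values)
  m <- matrix(0, length(vars), ncol(newdata),
              dimnames = list(vars, colnames(newdata)))
  shared <- intersect(vars, rownames(newdata))
  m[shared, ] <- newdata[shared, , drop = FALSE]
  shifts <- m - object$shift$anchors
  centroids <- vapply(sort(unique(object$assignment$labels)), function(cl)
    rowMeans(object$shift$values[, object$assignment$labels == cl,
                                 drop = FALSE]),
    numeric(length(vars)))
  d <- vapply(seq_len(ncol(centroids)), function(j)
    colSums((shifts - centroids[, j])^2), numeric(ncol(m)))
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  stats::setNames(max.col(-d, ties.method = "first"), colnames(newdata))
}

#' Plot a fitted stratification
#'
#' Draws the patient dendrogram (annotated with cluster labels) and a
#' heatmap of the frequency-shift matrix in dendrogram order.
#'
#' @param x An `mds_fit`.
#' @param which `"dendrogram"`, `"heatmap"` or `"both"`.
#' @param ... Passed to [graphics::plot()] for the dendrogram.
#' @return `x`, invisibly.
#' @export
plot.mds_fit <- function(x, which = c("both", "dendrogram", "heatmap"),
                         ...) {
  which <- match.arg(which)
  if (which == "both") {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  if (which %in% c("both", "dendrogram"))
    graphics::plot(x$assignment$tree,
                   main = "Patient clustering (frequency shifts)",
                   xlab = "", sub = "", ...)
  if (which %in% c("both", "heatmap")) {
    ord_p <- x$assignment$tree$order
    vals <- x$shift$values[match(x$variant_order,
                                 rownames(x$shift$values)),
                           ord_p, drop = FALSE]
    pal <- grDevices::hcl.colors(51, "Blue-Red 3")
    graphics::image(t(vals), zlim = c(-100, 100), col = pal, axes = FALSE,
                    main = "Frequency-shift matrix")
    graphics::axis(1, at = seq(0, 1, length.out = ncol(vals)),
                   labels = colnames(vals), las = 2, cex.axis = 0.5)
  }
  invisible(x)
}
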