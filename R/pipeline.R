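## End-to-end orchestration: a single YAML/JSON config drives input
## reading, the filter cascade, stratification, cohort statistics and
## survival inference, and every intermediate matrix is written to a
## results bundle with a manifest.

.default_pipeline_config <- function() {
  list(cohort_tsv = NULL, vcf_paths = NULL, annotation_tsv = NULL,
       clinical_tsv = NULL, panel_bed = NULL,
       vaf_threshold_pct = 1, min_alt_reads = 10, pop_af_max = 0.01,
       prevalence_cap = 0.5, drop_singletons = TRUE,
       linkage = "ward.D2", k = 2, ties = "breslow", horizon = 60,
       skip_survival = FALSE, outdir = "results", seed = 1)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML or JSON configuration (or takes a list), fills defaults and
#' reports every violation at once rather than failing on the first.
#'
#' @param config Path to a YAML/JSON file, or a named list.
#' @param overrides Named list applied on top of the file values
#'   (CLI > file > defaults).
#' @return The normalised configuration list (class `pipeline_config`).
#' @export
validate_config <- function(config, overrides = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    parsed <- tryCatch({
      if (grepl("\\.json$", config, ignore.case = TRUE))
        jsonlite::read_json(config, simplifyVector = TRUE)
      else yaml::read_yaml(config)
    }, error = function(e)
      stop("malformed config ", config, ": ", conditionMessage(e)))
    config <- parsed
  }
  stopifnot(is.list(config))
  cfg <- .default_pipeline_config()
  known <- names(cfg)
  unknown <- setdiff(names(config), known)
  cfg[intersect(names(config), known)] <-
    config[intersect(names(config), known)]
  cfg[intersect(names(overrides), known)] <-
    overrides[intersect(names(overrides), known)]

  problems <- character(0)
  if (length(unknown))
    problems <- c(problems,
                  paste("unknown config fields:",
                        paste(unknown, collapse = ", ")))
  if (is.null(cfg$cohort_tsv) && is.null(cfg$vcf_paths))
    problems <- c(problems,
                  "one of cohort_tsv or vcf_paths must be supplied")
  for (f in c("cohort_tsv", "annotation_tsv", "clinical_tsv", "panel_bed"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      problems <- c(problems, paste0(f, " does not exist: ", cfg[[f]]))
  for (p in cfg$vcf_paths)
    if (!file.exists(p))
      problems <- c(problems, paste0("vcf path does not exist: ", p))
  if (!is.numeric(cfg$vaf_threshold_pct) || cfg$vaf_threshold_pct <= 0 ||
      cfg$vaf_threshold_pct > 100)
    problems <- c(problems, "vaf_threshold_pct must be in (0, 100]")
  if (!is.numeric(cfg$pop_af_max) || cfg$pop_af_max < 0 ||
      cfg$pop_af_max > 1)
    problems <- c(problems, "pop_af_max must be in [0, 1]")
  if (!cfg$linkage %in% c("ward.D2", "complete", "average", "single"))
    problems <- c(problems, paste("unsupported linkage:", cfg$linkage))
  if (!cfg$ties %in% c("breslow", "efron"))
    problems <- c(problems, paste("unsupported tie method:", cfg$ties))
  if (!is.numeric(cfg$k) || cfg$k < 2)
    problems <- c(problems, "k must be an integer >= 2")
  if (length(problems))
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline and write a results bundle
#'
#' Executes input reading, the filter cascade, stratification, cohort
#' statistics and (unless skipped) survival inference, writing every
#' intermediate matrix, table and a run manifest into `outdir`.  Outputs
#' contain no timestamps, so reruns with identical inputs and seed are
#' bit-identical.  On a stage failure the partial bundle is retained with a
#' `FAILED` marker file.
#'
#' @param config Path to a YAML/JSON config, or a (validated) config list.
#' @param overrides Named list of overriding values.
#' @return Invisibly, a list with the `mds_fit` object and the written file
#'   paths.
#' @export
run_pipeline <- function(config, overrides = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config, overrides)
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(outdir, "FAILED"))

  result <- tryCatch({
    set.seed(cfg$seed)
    records <- if (!is.null(cfg$cohort_tsv)) read_cohort_tsv(cfg$cohort_tsv)
    else read_cohort_vcf(cfg$vcf_paths, cfg$annotation_tsv)
    clinical <- if (!is.null(cfg$clinical_tsv) && !isTRUE(cfg$skip_survival))
      read_clinical(cfg$clinical_tsv)
    panel <- if (!is.null(cfg$panel_bed)) read_panel_bed(cfg$panel_bed)

    fconf <- filter_config(vaf_threshold_pct = cfg$vaf_threshold_pct,
                           min_alt_reads = cfg$min_alt_reads,
                           pop_af_max = cfg$pop_af_max,
                           prevalence_cap = cfg$prevalence_cap,
                           drop_singletons = cfg$drop_singletons)
    message(sprintf("read %d records from %d patients", nrow(records),
                    length(unique(records$patient_id))))
    fit <- mds_fit(records, clinical = clinical, panel = panel,
                   config = fconf, linkage = cfg$linkage, k = cfg$k,
                   ties = cfg$ties, horizon = cfg$horizon)
    message(sprintf("clustering set: %d records, %d variants",
                    nrow(fit$clustering_records), fit$n_variants))

    paths <- c(cohort = "cohort_table.tsv", vaf = "vaf_matrix.tsv",
               shift = "shift_matrix.tsv", anchors = "anchors.tsv",
               labels = "cluster_labels.tsv", tree = "patient_tree.nwk",
               discriminant = "discriminant_variants.tsv",
               prevalence_common = "prevalence_common.tsv",
               prevalence_general = "prevalence_general.tsv",
               cooccurrence = "gene_cooccurrence.tsv",
               manifest = "manifest.json")
    paths <- stats::setNames(file.path(outdir, paths), names(paths))
    write_cohort_tsv(records, paths["cohort"])
    write_matrix_tsv(fit$vaf_matrix, paths["vaf"], "variant")
    write_matrix_tsv(fit$shift$values, paths["shift"], "variant")
    utils::write.table(
      data.frame(variant = names(fit$shift$anchors),
                 anchor = fit$shift$anchors),
      paths["anchors"], sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(patient_id = names(fit$assignment$labels),
                 cluster = fit$assignment$labels),
      paths["labels"], sep = "\t", quote = FALSE, row.names = FALSE)
    export_newick(fit$assignment, paths["tree"])
    if (!is.null(fit$discriminant))
      utils::write.table(fit$discriminant, paths["discriminant"],
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fit$prevalence$common, paths["prevalence_common"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fit$prevalence$general, paths["prevalence_general"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix_tsv(
      gene_cooccurrence(clustering_set(
        records[records$sample_time == 0L, ], fconf)),
      paths["cooccurrence"], "gene")

    if (!is.null(fit$burden)) {
      p <- file.path(outdir, "mutation_burden.tsv")
      utils::write.table(fit$burden, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths["burden"] <- p
    }
    if (!is.null(fit$comparisons)) {
      cmp <- do.call(rbind, lapply(fit$comparisons, function(x)
        data.frame(field = x$field, type = x$type,
                   statistic = if (!is.null(x$statistic)) x$statistic
                   else x$odds_ratio,
                   p = x$p, stringsAsFactors = FALSE)))
      cmp$p_adjusted <- stats::p.adjust(cmp$p, "BH")
      p <- file.path(outdir, "cluster_comparisons.tsv")
      utils::write.table(cmp, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths["comparisons"] <- p
    }
    if (!is.null(fit$survival)) {
      for (cl in 1:2) {
        p <- file.path(outdir, sprintf("km_cluster%d.tsv", cl))
        utils::write.table(
          as.data.frame(fit$survival$km[[cl]]), p, sep = "\t",
          quote = FALSE, row.names = FALSE)
        paths[sprintf("km%d", cl)] <- p
      }
      surv_summary <- list(
        horizon = fit$survival$horizon,
        os = lapply(fit$survival$os_at_horizon, function(x)
          x[c("estimate", "lower", "upper")]),
        logrank = fit$survival$logrank[c("chi_square", "p")],
        cox = if (!is.null(fit$survival$cox))
          cbind(covariate = rownames(fit$survival$cox$table),
                fit$survival$cox$table))
      p <- file.path(outdir, "survival.json")
      jsonlite::write_json(surv_summary, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      paths["survival"] <- p
      message(sprintf("log-rank p = %.4g", fit$survival$logrank$p))
    }

    norm_cfg <- unclass(cfg)
    cfg_json <- jsonlite::toJSON(norm_cfg, auto_unbox = TRUE, null = "null",
                                 digits = NA)
    manifest <- list(
      config = norm_cfg,
      config_hash = unname(.hash_string(as.character(cfg_json))),
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("mdsshift")),
      n_patients = length(fit$patients),
      n_clustering_variants = fit$n_variants)
    jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    list(fit = fit, paths = paths)
  }, error = function(e) {
    writeLines(c("pipeline failed:", conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop(e)
  })
  invisible(result)
}

## md5 of a string via a temp file (tools:: only hashes files)
.hash_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  as.character(tools::md5sum(tf))
}
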