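## Seeded synthetic cohorts with the statistical structure the analysis
## assumes: a Hardy-Weinberg germline layer whose true allele fractions sit
## on {0, 50, 100}% with binomial sequencing noise, cluster-dependent
## somatic clones with right-skewed intermediate VAFs, clinical covariates
## independent of cluster, and exponential survival whose hazard differs
## between the two latent clusters.

#' Synthetic cohort configuration
#'
#' Defaults describe a 35-patient high-risk MDS cohort sequenced on the
#' 18-gene panel at 1000x: a dozen cohort-specific germline polymorphisms
#' (per-site alternate allele frequency 5\%, absent from the population
#' database), sixteen somatic sites split between two latent clusters with
#' disjoint gene preferences, somatic VAFs drawn as
#' `1 + 59 * Beta(2, 3)` percent (right-skewed clonal hierarchy), a
#' baseline hazard of 0.0055 events/month (about 72\% five-year survival)
#' and a cluster-2 hazard ratio of 4.2 with Uniform(6, 120) month censoring.
#'
#' @param n_patients Cohort size.
#' @param genes Panel gene symbols.
#' @param panel A `panel_regions` object (default: the built-in synthetic
#'   18-gene panel).
#' @param n_germline_sites Number of germline polymorphic sites.
#' @param germline_alt_freq Per-site population alternate-allele frequency
#'   used for Hardy-Weinberg genotype draws (scalar or per-site vector).
#' @param germline_pop_af Population-database annotation attached to
#'   germline sites; `NA` means absent from the database (retained by the
#'   population filter).
#' @param n_somatic_sites Number of somatic sites (split between clusters
#'   by `somatic_gene_weights`).
#' @param somatic_gene_weights Named list with elements `"1"` and `"2"`:
#'   per-cluster gene weight vectors.  A patient carries a somatic site
#'   with probability `somatic_detect_prob * w_cluster(gene) / max_c
#'   w_c(gene)`; disjoint weights give cluster-exclusive clones, equal
#'   weights remove any cluster dependence.
#' @param somatic_detect_prob Carriage probability of an own-cluster site.
#' @param somatic_vaf_beta Beta shape parameters of the somatic clone VAF.
#' @param somatic_vaf_range VAF interval (percent) the Beta is scaled to.
#' @param depth Sequencing depth per site.
#' @param cluster_fractions Latent cluster mixing proportions (sum to 1).
#' @param hazard_baseline Cluster-1 hazard, events per month.
#' @param hazard_ratio Cluster-2 / cluster-1 hazard ratio.
#' @param censoring_window Uniform censoring interval in months.
#' @param seed Integer seed; all sampling is reproducible from it.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 35L,
                             genes = mds_panel_genes(),
                             panel = NULL,
                             n_germline_sites = 12L,
                             germline_alt_freq = 0.05,
                             germline_pop_af = NA_real_,
                             n_somatic_sites = 16L,
                             somatic_gene_weights = list(
                               "1" = c(SF3B1 = 1, TET2 = 1, IDH1 = 1,
                                       DNMT3A = 1),
                               "2" = c(ASXL1 = 1, RUNX1 = 1, CD274 = 1,
                                       CD276 = 1)),
                             somatic_detect_prob = 0.85,
                             somatic_vaf_beta = c(2, 3),
                             somatic_vaf_range = c(1, 60),
                             depth = 1000L,
                             cluster_fractions = c(0.5, 0.5),
                             hazard_baseline = 0.0055,
                             hazard_ratio = 4.2,
                             censoring_window = c(6, 120),
                             seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), genes = genes,
              panel = panel %||% synthetic_panel(genes),
              n_germline_sites = as.integer(n_germline_sites),
              germline_alt_freq = germline_alt_freq,
              germline_pop_af = germline_pop_af,
              n_somatic_sites = as.integer(n_somatic_sites),
              somatic_gene_weights = somatic_gene_weights,
              somatic_detect_prob = somatic_detect_prob,
              somatic_vaf_beta = somatic_vaf_beta,
              somatic_vaf_range = somatic_vaf_range,
              depth = as.integer(depth),
              cluster_fractions = cluster_fractions,
              hazard_baseline = hazard_baseline,
              hazard_ratio = hazard_ratio,
              censoring_window = censoring_window,
              seed = as.integer(seed))
  if (cfg$n_patients < 1L) stop("n_patients must be >= 1")
  if (cfg$depth < 1L) stop("depth must be >= 1")
  if (abs(sum(cfg$cluster_fractions) - 1) > 1e-9)
    stop("cluster_fractions must sum to 1")
  if (cfg$hazard_ratio <= 0) stop("hazard_ratio must be positive")
  if (cfg$hazard_baseline <= 0) stop("hazard_baseline must be positive")
  if (any(cfg$germline_alt_freq < 0 | cfg$germline_alt_freq > 1))
    stop("germline_alt_freq must be in [0, 1]")
  if (!(cfg$somatic_detect_prob >= 0 && cfg$somatic_detect_prob <= 1))
    stop("somatic_detect_prob must be in [0, 1]")
  if (!all(c("1", "2") %in% names(cfg$somatic_gene_weights)))
    stop("somatic_gene_weights needs elements \"1\" and \"2\"")
  if (diff(cfg$somatic_vaf_range) <= 0 || cfg$somatic_vaf_range[1] < 0)
    stop("somatic_vaf_range must be an increasing non-negative interval")
  structure(cfg, class = "synthetic_config")
}

#' Built-in synthetic panel regions for a gene list
#'
#' One contiguous coding-footprint interval per gene (synthetic
#' coordinates, one chromosome per gene), sized like typical coding
#' footprints (1.5-7 kb).
#'
#' @param genes Gene symbols.
#' @return A `panel_regions` object.
#' @export
synthetic_panel <- function(genes = mds_panel_genes()) {
  sizes <- 1500 + (seq_along(genes) * 997L) %% 5500L  # 1.5-7 kb, fixed
  panel_regions(data.frame(chrom = paste0("chr", seq_along(genes)),
                           start = 1e6, end = 1e6 + sizes,
                           stringsAsFactors = FALSE))
}

## deterministic site table (positions, alleles) given a config
.site_table <- function(cfg) {
  genes <- cfg$genes
  iv <- cfg$panel$intervals
  gene_chrom <- stats::setNames(iv$chrom[seq_along(genes)], genes)
  gene_start <- stats::setNames(iv$start[seq_along(genes)], genes)
  bases <- c("A", "C", "G", "T")
  make_sites <- function(site_genes, offset) {
    k <- length(site_genes)
    if (!k) return(NULL)
    pos <- gene_start[site_genes] + offset + seq_len(k) * 37L
    data.frame(gene = site_genes,
               chrom = unname(gene_chrom[site_genes]),
               pos = as.integer(unname(pos)),
               ref = bases[1 + (seq_len(k) %% 4)],
               alt = bases[1 + ((seq_len(k) + 1) %% 4)],
               stringsAsFactors = FALSE)
  }
  g_genes <- rep_len(genes, cfg$n_germline_sites)
  germ <- make_sites(g_genes, offset = 100L)
  w1 <- cfg$somatic_gene_weights[["1"]]
  w2 <- cfg$somatic_gene_weights[["2"]]
  som_genes <- rep_len(unique(c(names(w1), names(w2))),
                       cfg$n_somatic_sites)
  som <- make_sites(som_genes, offset = 900L)
  list(germline = germ, somatic = som)
}

## carriage probability of a somatic site for each cluster
.somatic_site_prob <- function(cfg, gene) {
  w1 <- cfg$somatic_gene_weights[["1"]][gene] %||% 0
  w2 <- cfg$somatic_gene_weights[["2"]][gene] %||% 0
  w1 <- ifelse(is.na(w1), 0, w1); w2 <- ifelse(is.na(w2), 0, w2)
  top <- max(w1, w2)
  if (top == 0) c(0, 0) else cfg$somatic_detect_prob * c(w1, w2) / top
}

#' Generate a synthetic cohort
#'
#' Draws the germline layer from Hardy-Weinberg genotypes (true allele
#' fraction 0 / 50 / 100\%, observed depths binomial), the somatic layer
#' from cluster-weighted clone carriage with Beta-distributed clone VAFs,
#' exponential survival with a cluster-dependent hazard under uniform
#' censoring, and clinical covariates independent of cluster (so that any
#' survival signal flows only through the cluster structure).
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_cohort` with elements `records`
#'   (variant table), `clinical`, `panel` and `truth` (list with per-patient
#'   `patients` truth table and per-site `variants` truth table).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  n <- cfg$n_patients
  patients <- sprintf("P%03d", seq_len(n))
  cluster <- 1L + (stats::runif(n) > cfg$cluster_fractions[1])
  sites <- .site_table(cfg)
  consequences_germ <- c("missense", "utr3", "utr5", "synonymous",
                         "intronic")
  cw_germ <- c(0.35, 0.20, 0.10, 0.20, 0.15)
  consequences_som <- c("missense", "nonsense", "frameshift", "splice")
  cw_som <- c(0.6, 0.15, 0.15, 0.10)

  recs <- list()
  truth_var <- list()

  ## germline layer
  if (!is.null(sites$germline)) {
    q <- rep_len(cfg$germline_alt_freq, nrow(sites$germline))
    cons <- sample(consequences_germ, nrow(sites$germline), replace = TRUE,
                   prob = cw_germ)
    for (s in seq_len(nrow(sites$germline))) {
      st <- sites$germline[s, ]
      geno <- sample(0:2, n, replace = TRUE,
                     prob = c((1 - q[s])^2, 2 * q[s] * (1 - q[s]), q[s]^2))
      true_af <- geno * 50
      alt_d <- stats::rbinom(n, cfg$depth, true_af / 100)
      carrier <- geno > 0 & alt_d > 0
      truth_var[[length(truth_var) + 1L]] <- data.frame(
        variant = variant_key(st$chrom, st$pos, st$ref, st$alt),
        gene = st$gene, origin = "germline", alt_freq = q[s],
        stringsAsFactors = FALSE)
      if (!any(carrier)) next
      recs[[length(recs) + 1L]] <- data.frame(
        patient_id = patients[carrier], sample_time = 0L,
        chrom = st$chrom, pos = st$pos, ref = st$ref, alt = st$alt,
        gene = st$gene, consequence = cons[s],
        ref_depth = cfg$depth - alt_d[carrier],
        alt_depth = alt_d[carrier],
        vaf = 100 * alt_d[carrier] / cfg$depth,
        pop_af = cfg$germline_pop_af, cosmic_flag = "absent",
        clinvar_flag = FALSE, stringsAsFactors = FALSE)
    }
  }

  ## somatic layer
  if (!is.null(sites$somatic)) {
    cons <- sample(consequences_som, nrow(sites$somatic), replace = TRUE,
                   prob = cw_som)
    a <- cfg$somatic_vaf_beta[1]; b <- cfg$somatic_vaf_beta[2]
    lo <- cfg$somatic_vaf_range[1]; hi <- cfg$somatic_vaf_range[2]
    for (s in seq_len(nrow(sites$somatic))) {
      st <- sites$somatic[s, ]
      pr <- .somatic_site_prob(cfg, st$gene)
      carries <- stats::runif(n) < pr[cluster]
      clone_vaf <- lo + (hi - lo) * stats::rbeta(n, a, b)
      alt_d <- stats::rbinom(n, cfg$depth, clone_vaf / 100)
      carrier <- carries & alt_d > 0
      truth_var[[length(truth_var) + 1L]] <- data.frame(
        variant = variant_key(st$chrom, st$pos, st$ref, st$alt),
        gene = st$gene, origin = "somatic", alt_freq = NA_real_,
        stringsAsFactors = FALSE)
      if (!any(carrier)) next
      recs[[length(recs) + 1L]] <- data.frame(
        patient_id = patients[carrier], sample_time = 0L,
        chrom = st$chrom, pos = st$pos, ref = st$ref, alt = st$alt,
        gene = st$gene, consequence = cons[s],
        ref_depth = cfg$depth - alt_d[carrier],
        alt_depth = alt_d[carrier],
        vaf = 100 * alt_d[carrier] / cfg$depth,
        pop_af = NA_real_,
        cosmic_flag = sample(c("absent", "present", "heme_associated"), 1,
                             prob = c(0.5, 0.3, 0.2)),
        clinvar_flag = FALSE, stringsAsFactors = FALSE)
    }
  }

  records <- if (length(recs)) .order_records(do.call(rbind, recs)) else
    stop("configuration produced no variant records")
  rownames(records) <- NULL
  validate_records(records)

  ## survival: exponential with cluster-dependent hazard, uniform censoring
  rate <- cfg$hazard_baseline * cfg$hazard_ratio^(cluster == 2L)
  t_true <- stats::rexp(n, rate = rate)
  cens <- stats::runif(n, cfg$censoring_window[1], cfg$censoring_window[2])
  followup <- pmin(t_true, cens)
  event <- t_true <= cens

  ## clinical covariates, independent of cluster
  ipssr_cat <- sample(c("low", "intermediate", "high", "very_high"), n,
                      replace = TRUE, prob = c(0.03, 0.14, 0.52, 0.31))
  clinical <- data.frame(
    patient_id = patients,
    age = round(stats::rnorm(n, 49, 14)),
    ipssr_category = ipssr_cat,
    ipssr_numeric = ipssr_to_numeric(ipssr_cat),
    blasts_pct = round(stats::runif(n, 0, 19), 1),
    hemoglobin = round(stats::rnorm(n, 90, 15)),
    neutrophils = round(stats::rlnorm(n, log(1.0), 0.7), 2),
    platelets = round(stats::rlnorm(n, log(90), 0.6)),
    hsct = stats::runif(n) < 0.54,
    followup_time = round(followup, 3),
    event = event,
    stringsAsFactors = FALSE)

  truth <- list(
    patients = data.frame(patient_id = patients, true_cluster = cluster,
                          true_time = t_true, stringsAsFactors = FALSE),
    variants = do.call(rbind, truth_var))
  structure(list(records = records, clinical = clinical,
                 panel = cfg$panel, truth = truth, config = cfg),
            class = "synthetic_cohort")
}

#' Add longitudinal samples to a synthetic cohort
#'
#' Re-samples a subset of patients at later time points: germline allele
#' fractions stay constant up to binomial noise, while each somatic clone
#' follows a linear trajectory in true clone fraction with a per-clone
#' slope drawn from `slope_range` (percentage points per time step,
#' clipped to [0, 95]\%).
#'
#' @param config A [synthetic_config()].
#' @param n_timepoints Total time points per followed patient (>= 2,
#'   including diagnosis).
#' @param n_followed Number of patients with longitudinal samples
#'   (default 7).
#' @param slope_range Uniform range of per-step somatic VAF slopes.
#' @return A `synthetic_cohort` whose `records` include `sample_time > 0`
#'   rows for the followed patients, with `truth$trajectories` describing
#'   the true clone paths.
#' @export
generate_longitudinal <- function(config, n_timepoints, n_followed = 7L,
                                  slope_range = c(-12, 15)) {
  stopifnot(n_timepoints >= 2L)
  cohort <- generate_cohort(config)
  cfg <- config
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed + 1L)

  base <- cohort$records
  followed <- utils::head(sort(unique(base$patient_id),
                               method = "radix"), n_followed)
  origin <- cohort$truth$variants
  key_all <- variant_key(base$chrom, base$pos, base$ref, base$alt)
  is_som <- origin$origin[match(key_all, origin$variant)] == "somatic"

  extra <- list(); traj <- list()
  for (pid in followed) {
    mine <- which(base$patient_id == pid & base$sample_time == 0L)
    if (!length(mine)) next
    slopes <- stats::runif(length(mine), slope_range[1], slope_range[2])
    slopes[!is_som[mine]] <- 0
    for (tp in seq_len(n_timepoints - 1L)) {
      base_vaf <- base$vaf[mine]
      true_vaf <- ifelse(is_som[mine],
                         pmin(pmax(base_vaf + slopes * tp, 0), 95),
                         base_vaf)
      alt_d <- stats::rbinom(length(mine), cfg$depth,
                             pmin(true_vaf, 100) / 100)
      keep <- alt_d > 0
      if (!any(keep)) next
      r <- base[mine[keep], , drop = FALSE]
      r$sample_time <- tp
      r$alt_depth <- alt_d[keep]
      r$ref_depth <- cfg$depth - alt_d[keep]
      r$vaf <- 100 * alt_d[keep] / cfg$depth
      extra[[length(extra) + 1L]] <- r
    }
    traj[[length(traj) + 1L]] <- data.frame(
      patient_id = pid,
      variant = variant_key(base$chrom[mine], base$pos[mine],
                            base$ref[mine], base$alt[mine]),
      slope = slopes, somatic = is_som[mine], stringsAsFactors = FALSE)
  }
  if (length(extra)) {
    cohort$records <- .order_records(rbind(base, do.call(rbind, extra)))
    rownames(cohort$records) <- NULL
  }
  cohort$truth$trajectories <- if (length(traj)) do.call(rbind, traj)
  cohort
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(records = file.path(dir, "cohort_variants.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             panel = file.path(dir, "panel.bed"),
             truth_patients = file.path(dir, "truth_patients.tsv"),
             truth_variants = file.path(dir, "truth_variants.tsv"))
  write_cohort_tsv(cohort$records, paths["records"])
  utils::write.table(cohort$clinical, paths["clinical"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_panel_bed(cohort$panel, paths["panel"])
  utils::write.table(cohort$truth$patients, paths["truth_patients"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$variants, paths["truth_variants"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}
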