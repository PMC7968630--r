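patients35 <- sprintf("P%02d", 1:35)

test_that("gene prevalence counts patients once per gene and rounds like
           the report", {
  recs <- do.call(rbind, c(
    lapply(1:19, function(i) make_rec(patients35[i], "DICER1", "utr3", 20,
                                      pos = 100)),
    # a second DICER1 variant in an already-counted patient
    list(make_rec(patients35[1], "DICER1", "missense", 9, pos = 150)),
    lapply(1:16, function(i) make_rec(patients35[i], "LAG3", "missense",
                                      12, pos = 200)),
    list(make_rec(patients35[7], "CD274", "missense", 30, pos = 300))))
  tab <- gene_prevalence(recs, patients35)
  expect_equal(tab$n_mutated[tab$gene == "DICER1"], 19L)
  expect_equal(tab$percent[tab$gene == "DICER1"], 54)   # 19/35 = 54.3%
  expect_equal(tab$percent[tab$gene == "LAG3"], 46)     # 16/35 = 45.7%
  expect_equal(tab$percent[tab$gene == "CD274"], 3)     # 1/35 = 2.9%
  zero <- gene_prevalence(recs, patients35, gene_set = c("TP53", "LAG3"))
  expect_equal(zero$n_mutated[zero$gene == "TP53"], 0L)
  expect_error(gene_prevalence(recs, character(0)), "empty cohort")
})

test_that("prevalence is monotone non-increasing in the VAF threshold", {
  toy <- toy_filter_table()
  for (g in c("ASXL1", "DICER1", "SRSF2", "CD276")) {
    p1 <- gene_prevalence(reporting_set(toy, filter_config(
      vaf_threshold_pct = 1)), sprintf("P%d", 1:6), g)
    p5 <- gene_prevalence(reporting_set(toy, filter_config(
      vaf_threshold_pct = 5)), sprintf("P%d", 1:6), g)
    expect_lte(p5$n_mutated, p1$n_mutated)
  }
})

test_that("mutation burden normalises by merged panel megabases", {
  panel <- panel_regions(data.frame(chrom = "chr1", start = 0,
                                    end = 250000))
  recs <- do.call(rbind, lapply(1:50, function(i)
    make_rec("P1", "G", "missense", 20, pos = 100 + i)))
  b <- mutation_burden(recs, panel)
  expect_equal(b$per_mb, 200)
  b0 <- mutation_burden(recs[0, ], panel, patients = "P1")
  expect_equal(b0$per_mb, 0)
  # doubling the panel halves every burden
  panel2 <- panel_regions(data.frame(chrom = c("chr1", "chr2"),
                                     start = 0, end = 250000))
  expect_equal(mutation_burden(recs, panel2)$per_mb, b$per_mb / 2)
})

test_that("quantitative cluster comparison uses the exact Mann-Whitney
           null on small untied samples", {
  clin <- make_clinical(sprintf("P%d", 1:6), followup = rep(10, 6),
                        event = rep(FALSE, 6))
  clin$neutrophils <- c(1, 2, 3, 10, 11, 12)
  labels <- setNames(rep(1:2, each = 3), clin$patient_id)
  res <- compare_clusters_quantitative(clin, labels, "neutrophils")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 0.1)    # 2 * 1/choose(6,3)
  expect_equal(res$median_1, 2); expect_equal(res$median_2, 11)

  # label swap leaves p unchanged
  res2 <- compare_clusters_quantitative(clin, 3L - labels, "neutrophils")
  expect_equal(res2$p, res$p)

  # identical multisets in both groups: p near 1
  clin$age <- rep(c(40, 50, 60), 2)
  labels2 <- setNames(c(1, 1, 1, 2, 2, 2),
                      clin$patient_id[c(1, 2, 3, 4, 5, 6)])
  res3 <- compare_clusters_quantitative(clin, labels2, "age")
  expect_gt(res3$p, 0.9)

  clin$blasts_pct <- rep(5, 6)
  expect_warning(res4 <- compare_clusters_quantitative(clin, labels,
                                                       "blasts_pct"),
                 "tied")
  expect_equal(res4$p, 1)
})

test_that("categorical comparison matches hypergeometric enumeration", {
  clin <- make_clinical(sprintf("P%02d", 1:20), followup = rep(10, 20),
                        event = rep(FALSE, 20))
  clin$hsct <- c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 1), rep(FALSE, 9))
  labels <- setNames(rep(1:2, each = 10), clin$patient_id)
  res <- compare_clusters_categorical(clin, labels, "hsct")
  expect_equal(unname(res$table), matrix(c(8, 2, 1, 9), 2, byrow = TRUE))

  # oracle: enumerate all tables with the same margins
  enum_p <- local({
    a_obs <- 8; r1 <- 10; c1 <- 9; n <- 20
    probs <- vapply(max(0, c1 - (n - r1)):min(r1, c1), function(a)
      choose(r1, a) * choose(n - r1, c1 - a) / choose(n, c1), numeric(1))
    obs <- choose(r1, a_obs) * choose(n - r1, c1 - a_obs) / choose(n, c1)
    sum(probs[probs <= obs + 1e-12])
  })
  expect_equal(res$p, enum_p)
  expect_equal(res$odds_ratio, (8 * 9) / (2 * 1))

  # swapping the groups inverts the odds ratio, same p
  res2 <- compare_clusters_categorical(clin, 3L - labels, "hsct")
  expect_equal(res2$odds_ratio, 1 / res$odds_ratio)
  expect_equal(res2$p, res$p)

  # balanced table: OR 1, p 1
  clin$hsct <- rep(c(TRUE, FALSE), 10)
  res3 <- compare_clusters_categorical(clin, labels, "hsct")
  expect_equal(res3$odds_ratio, 1)
  expect_equal(res3$p, 1)

  # degenerate margin
  clin$hsct <- rep(TRUE, 20)
  expect_warning(res4 <- compare_clusters_categorical(clin, labels,
                                                      "hsct"),
                 "degenerate")
  expect_equal(res4$p, 1)
})

test_that("longitudinal trajectories classify emerging, expanding and
           stable clones", {
  recs <- rbind(
    make_rec("P1", "DICER1", "missense", 35, pos = 100, sample_time = 2L),
    make_rec("P1", "TP53", "missense", 40, pos = 200, sample_time = 0L),
    make_rec("P1", "TP53", "missense", 41, pos = 200, sample_time = 1L),
    make_rec("P1", "TP53", "missense", 42, pos = 200, sample_time = 2L),
    make_rec("P1", "ASXL1", "missense", 10, pos = 300, sample_time = 0L),
    make_rec("P1", "ASXL1", "missense", 18, pos = 300, sample_time = 1L),
    make_rec("P1", "ASXL1", "missense", 25, pos = 300, sample_time = 2L),
    make_rec("P1", "SF3B1", "missense", 30, pos = 400, sample_time = 0L),
    make_rec("P1", "SF3B1", "missense", 18, pos = 400, sample_time = 1L),
    make_rec("P1", "SF3B1", "missense", 5, pos = 400, sample_time = 2L))
  tr <- longitudinal_trajectories(recs, "P1")
  cls <- setNames(tr$classification$class, tr$classification$variant)
  expect_equal(unname(cls[grepl(":100:", names(cls))]), "emerging")
  expect_equal(unname(cls[grepl(":200:", names(cls))]), "stable")
  expect_equal(unname(cls[grepl(":300:", names(cls))]), "expanding")
  expect_equal(unname(cls[grepl(":400:", names(cls))]), "contracting")
  # series cover every time point with zeros where undetected
  emerging <- tr$trajectories[grepl(":100:", tr$trajectories$variant), ]
  expect_equal(emerging$vaf[emerging$sample_time < 2], c(0, 0))
  expect_equal(nrow(emerging), 3L)
  expect_error(longitudinal_trajectories(
    make_rec("P2", "G", "missense", 10), "P2"), "time points")
})

test_that("gene co-occurrence counts patients mutated in both genes", {
  recs <- rbind(make_rec("P1", "A1", "missense", 20, pos = 100),
                make_rec("P1", "B1", "missense", 20, pos = 200),
                make_rec("P2", "A1", "missense", 20, pos = 100),
                make_rec("P3", "B1", "missense", 20, pos = 200))
  m <- gene_cooccurrence(recs)
  expect_equal(m["A1", "B1"], 1L)
  expect_equal(m["A1", "A1"], 2L)
  expect_equal(m["B1", "B1"], 2L)
  expect_true(isSymmetric(unname(m)))
})
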