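test_that("VCF reading computes per-allele VAF from allelic depths", {
  d <- withr::local_tempdir()
  vcf <- write_toy_vcf(file.path(d, "p1.vcf"), "P01", data.frame(
    chrom = c("chr1", "chr2"), pos = c(1000, 2000),
    ref = c("G", "C"), alt = c("A", "A,T"),
    ad = c("900,100", "800,150,50"), stringsAsFactors = FALSE))
  recs <- read_cohort_vcf(vcf)
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$vaf[recs$chrom == "chr1"], 10)
  multi <- recs[recs$chrom == "chr2", ]
  expect_equal(sort(multi$vaf), c(5, 15))
  expect_equal(multi$alt, c("A", "T"))
  # VAF invariant holds record-wise with the total-depth convention
  expect_equal(recs$vaf,
               100 * recs$alt_depth / (recs$ref_depth + recs$alt_depth))
})

test_that("a cohort of single-variant VCFs yields sorted records", {
  d <- withr::local_tempdir()
  paths <- c(
    write_toy_vcf(file.path(d, "b.vcf"), "P02", data.frame(
      chrom = "chr2", pos = 500, ref = "G", alt = "T", ad = "600,400")),
    write_toy_vcf(file.path(d, "a.vcf"), "P01", data.frame(
      chrom = "chr9", pos = 100, ref = "A", alt = "C", ad = "700,300")),
    write_toy_vcf(file.path(d, "c.vcf"), "P01", data.frame(
      chrom = "chr1", pos = 900, ref = "T", alt = "G", ad = "950,50")))
  recs <- read_cohort_vcf(paths)
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$patient_id, c("P01", "P01", "P02"))
  expect_equal(recs$chrom[1:2], c("chr1", "chr9"))  # sorted within patient
  expect_equal(recs$vaf, c(5, 30, 40))
})

test_that("zero-depth sites are rejected with a warning, not fatally", {
  d <- withr::local_tempdir()
  vcf <- write_toy_vcf(file.path(d, "z.vcf"), "P01", data.frame(
    chrom = c("chr1", "chr1"), pos = c(10, 20), ref = c("A", "C"),
    alt = c("T", "G"), ad = c("0,0", "90,10"), stringsAsFactors = FALSE))
  expect_warning(recs <- read_cohort_vcf(vcf), "zero total depth")
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$pos, 20L)
})

test_that("annotation joins by locus and missing rows default to other", {
  d <- withr::local_tempdir()
  vcf <- write_toy_vcf(file.path(d, "p.vcf"), "P01", data.frame(
    chrom = c("chr1", "chr1"), pos = c(10, 20), ref = c("A", "C"),
    alt = c("T", "G"), ad = c("900,100", "800,200"),
    stringsAsFactors = FALSE))
  ann <- file.path(d, "ann.tsv")
  utils::write.table(
    data.frame(chrom = "chr1", pos = 10, ref = "A", alt = "T",
               gene = "TP53", consequence = "missense", pop_af = 0.001,
               cosmic_flag = "present", clinvar_flag = TRUE),
    ann, sep = "\t", quote = FALSE, row.names = FALSE)
  recs <- read_cohort_vcf(vcf, annotation_table = ann)
  hit <- recs[recs$pos == 10, ]; miss <- recs[recs$pos == 20, ]
  expect_equal(hit$gene, "TP53")
  expect_equal(hit$consequence, "missense")
  expect_equal(hit$pop_af, 0.001)
  expect_equal(miss$consequence, "other")
  expect_true(is.na(miss$pop_af))
  expect_error(read_cohort_vcf(file.path(d, "nope.vcf")), "nope.vcf")
})

test_that("clinical reading maps IPSS-R categories and enforces invariants", {
  d <- withr::local_tempdir()
  path <- file.path(d, "clin.tsv")
  df <- data.frame(patient_id = c("P1", "P2", "P3", "P4"),
                   ipssr_category = c("low", "intermediate", "high",
                                      "very high"),
                   followup_time = c(10, 20, 30, 40),
                   event = c(TRUE, FALSE, TRUE, FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  clin <- read_clinical(path)
  expect_equal(clin$ipssr_numeric, 1:4)

  df2 <- df; df2$patient_id[2] <- "P1"
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_clinical(path), "duplicate")

  df3 <- df; df3$followup_time[1] <- -1
  utils::write.table(df3, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_clinical(path), "negative")
})

test_that("panel size merges overlapping intervals before summing", {
  expect_equal(panel_size_mb(panel_regions(
    data.frame(chrom = "chr1", start = 0, end = 250000))), 0.25)
  expect_equal(panel_size_mb(panel_regions(
    data.frame(chrom = "chr1", start = c(0, 50), end = c(100, 150)))),
    150 / 1e6)
  # intervals on different chromosomes never merge
  expect_equal(panel_regions(
    data.frame(chrom = c("chr1", "chr2"), start = c(0, 0),
               end = c(100, 100)))$total_size_bp, 200)
  expect_error(panel_regions(data.frame(chrom = character(),
                                        start = numeric(),
                                        end = numeric())), "interval")
  d <- withr::local_tempdir()
  bed <- file.path(d, "panel.bed")
  writeLines(c("chr1\t0\t1000", "chr1\t500\t1500", "chr2\t0\t200"), bed)
  expect_equal(read_panel_bed(bed)$total_size_bp, 1700)
})

test_that("matrix TSV round-trips bit-exactly", {
  set.seed(11)
  m <- matrix(c(runif(12) * 100, 1/3, sqrt(2), -100, 100, 0, 2e-17),
              nrow = 3, dimnames = list(paste0("v", 1:3), paste0("p", 1:6)))
  d <- withr::local_tempdir()
  path <- write_matrix_tsv(m, file.path(d, "m.tsv"), "variant")
  expect_identical(read_matrix_tsv(path), m)
})

test_that("cohort TSV round-trips through write and read", {
  recs <- toy_filter_table()
  recs$rec_id <- NULL
  d <- withr::local_tempdir()
  path <- write_cohort_tsv(recs, file.path(d, "cohort.tsv"))
  back <- read_cohort_tsv(path)
  ord <- function(x) {
    x <- x[order(x$patient_id, x$pos), ]
    rownames(x) <- NULL
    x
  }
  expect_equal(ord(back), ord(recs))
})
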