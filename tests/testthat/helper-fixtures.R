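## Fixtures built in code: record rows with consistent depths, a toy
## 30-record filter table with hand-enumerated survivors, the 5x4
## hand-computed VAF/shift fixture, and a minimal VCF writer.

make_rec <- function(patient, gene, consequence, vaf, pop_af = NA_real_,
                     chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                     depth = 1000L, sample_time = 0L,
                     cosmic = "absent", clinvar = FALSE) {
  alt_d <- as.integer(round(depth * vaf / 100))
  data.frame(patient_id = patient, sample_time = sample_time,
             chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             gene = gene, consequence = consequence,
             ref_depth = depth - alt_d, alt_depth = alt_d,
             vaf = 100 * alt_d / depth, pop_af = pop_af,
             cosmic_flag = cosmic, clinvar_flag = clinvar,
             stringsAsFactors = FALSE)
}

## 30 records over 6 patients and 17 variants; survivors of each stage of
## the clustering cascade (defaults: 1% VAF, >= 10 alt reads, pop AF 1%)
## were enumerated by hand and are encoded in the `stage` attribute below.
toy_filter_table <- function() {
  v <- function(i) list(chrom = "chr1", pos = 100L * i)
  rows <- list(
    # V1 ASXL1 missense, 2 patients: survives everything
    make_rec("P1", "ASXL1", "missense", 30, pos = 100),
    make_rec("P2", "ASXL1", "missense", 25, pos = 100),
    # V2 DICER1 utr3, 2 patients: kept (UTR not dropped by default)
    make_rec("P1", "DICER1", "utr3", 12, pos = 200),
    make_rec("P3", "DICER1", "utr3", 15, pos = 200),
    # V3 synonymous: removed by the functional filter
    make_rec("P1", "ASXL1", "synonymous", 40, pos = 300),
    make_rec("P2", "ASXL1", "synonymous", 40, pos = 300),
    # V4 intronic: removed by the functional filter
    make_rec("P3", "TET2", "intronic", 20, pos = 400),
    # V5 missense with population AF 2%: removed by population filter
    make_rec("P1", "TP53", "missense", 45, pop_af = 0.02, pos = 500),
    make_rec("P2", "TP53", "missense", 50, pop_af = 0.02, pos = 500),
    # V6 missense, population AF 0.5%: kept
    make_rec("P4", "SF3B1", "missense", 35, pop_af = 0.005, pos = 600),
    make_rec("P5", "SF3B1", "missense", 33, pop_af = 0.005, pos = 600),
    # V7 VAF 0.8%: removed by detection
    make_rec("P4", "RUNX1", "missense", 0.8, pos = 700),
    # V8 VAF 1.2% with 12 alt reads: passes detection, later a singleton
    make_rec("P5", "EZH2", "missense", 1.2, pos = 800),
    # V9 VAF 1.5% but only 6 alt reads (depth 400): removed by read guard
    make_rec("P6", "IDH1", "missense", 1.5, depth = 400L, pos = 900),
    # V10 singleton: removed by singleton exclusion
    make_rec("P6", "LAG3", "missense", 22, pos = 1000),
    # V11 in 4 of 6 patients (67%): clustered, but display-only in tallies
    make_rec("P1", "DNMT3A", "missense", 28, pos = 1100),
    make_rec("P2", "DNMT3A", "missense", 30, pos = 1100),
    make_rec("P3", "DNMT3A", "missense", 26, pos = 1100),
    make_rec("P4", "DNMT3A", "missense", 31, pos = 1100),
    # V12 DROSHA utr5, 2 patients: kept
    make_rec("P2", "DROSHA", "utr5", 8, pos = 1200),
    make_rec("P5", "DROSHA", "utr5", 9, pos = 1200),
    # V13 intergenic: removed by the functional filter
    make_rec("P6", "MFSD11", "intergenic", 50, pos = 1300),
    # V14 common polymorphism (pop AF 50%): removed by population filter
    make_rec("P1", "PIKFYVE", "missense", 52, pop_af = 0.5, pos = 1400),
    make_rec("P2", "PIKFYVE", "missense", 49, pop_af = 0.5, pos = 1400),
    make_rec("P3", "PIKFYVE", "missense", 51, pop_af = 0.5, pos = 1400),
    # V15 kept, 2 patients
    make_rec("P5", "SRSF2", "missense", 6, pos = 1500),
    make_rec("P6", "SRSF2", "missense", 7, pos = 1500),
    # V16 CD276 utr3, low VAF but >= 10 reads: kept at the 1% threshold
    make_rec("P4", "CD276", "utr3", 3, pos = 1600),
    make_rec("P6", "CD276", "utr3", 2.5, pos = 1600),
    # V17 passes filters but is a singleton
    make_rec("P3", "TP53", "nonsense", 18, pop_af = 5e-04, pos = 1700))
  df <- do.call(rbind, rows)
  df$rec_id <- sprintf("V%02d_%s", match(df$pos, unique(df$pos)),
                       df$patient_id)
  df
}

## hand-enumerated surviving variant positions per cascade stage
toy_expected <- list(
  after_functional = c(100, 200, 500, 600, 700, 800, 900, 1000, 1100,
                       1200, 1400, 1500, 1600, 1700),
  after_population = c(100, 200, 600, 700, 800, 900, 1000, 1100, 1200,
                       1500, 1600, 1700),
  after_detection = c(100, 200, 600, 800, 1000, 1100, 1200, 1500, 1600,
                      1700),
  after_singletons = c(100, 200, 600, 1100, 1200, 1500, 1600),
  prevalence_display = 1100)

## 5x4 hand fixture: VAFs, anchors and shifts worked out by hand
hand_fixture <- function() {
  vaf <- matrix(c(10,  0,  0,  0,
                  45, 55, 48, 52,
                  95, 100, 90, 100,
                  30, 20,  0,  0,
                   0,  0, 60, 70),
                nrow = 5, byrow = TRUE,
                dimnames = list(paste0("v", 1:5), c("A", "B", "C", "D")))
  anchors <- c(v1 = 0, v2 = 50, v3 = 100, v4 = 0, v5 = 50)
  shift <- matrix(c(10,   0,   0,  0,
                    -5,   5,  -2,  2,
                    -5,   0, -10,  0,
                    30,  20,   0,  0,
                   -50, -50,  10, 20),
                  nrow = 5, byrow = TRUE, dimnames = dimnames(vaf))
  list(vaf = vaf, anchors = anchors, shift = shift)
}

## records realising the 5x4 fixture (zeros are simply absent records)
hand_fixture_records <- function() {
  f <- hand_fixture()
  rows <- list()
  for (i in seq_len(nrow(f$vaf))) for (p in colnames(f$vaf)) {
    if (f$vaf[i, p] > 0)
      rows[[length(rows) + 1L]] <-
        make_rec(p, "GENE", "missense", f$vaf[i, p], pos = 1000L * i)
  }
  do.call(rbind, rows)
}

write_toy_vcf <- function(path, sample, sites) {
  ## sites: data.frame(chrom, pos, ref, alt, ad) with ad a comma string
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Allelic depths\">"),
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample, sep = "\t"))
  body <- apply(sites, 1, function(r)
    paste(r[["chrom"]], r[["pos"]], ".", r[["ref"]], r[["alt"]], ".",
          "PASS", ".", "GT:AD", paste0("0/1:", r[["ad"]]), sep = "\t"))
  writeLines(c(hdr, body), path)
  path
}

make_clinical <- function(patients, followup, event,
                          ipssr = "high", hsct = FALSE) {
  n <- length(patients)
  data.frame(patient_id = patients,
             age = rep(50, n), ipssr_category = rep_len(ipssr, n),
             ipssr_numeric = ipssr_to_numeric(rep_len(ipssr, n)),
             blasts_pct = rep(5, n), hemoglobin = rep(90, n),
             neutrophils = rep(1, n), platelets = rep(90, n),
             hsct = rep_len(hsct, n),
             followup_time = followup, event = event,
             stringsAsFactors = FALSE)
}

## align a recovered two-cluster labelling to truth by majority agreement
align_labels <- function(recovered, truth) {
  flip <- 3L - recovered
  if (sum(recovered == truth) >= sum(flip == truth)) recovered else flip
}
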