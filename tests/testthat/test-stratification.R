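test_that("VAF matrix places detections and zeros correctly", {
  recs <- make_rec("A", "G", "missense", 40)
  m <- build_vaf_matrix(recs, patients = c("A", "B"))
  expect_equal(dim(m), c(1L, 2L))
  expect_equal(unname(m[1, ]), c(40, 0))

  # three records of one variant collapse to one row
  recs3 <- do.call(rbind, lapply(c("A", "B", "C"), function(p)
    make_rec(p, "G", "missense", 30)))
  expect_equal(nrow(build_vaf_matrix(recs3)), 1L)

  expect_error(build_vaf_matrix(recs3[0, ]), "nothing to cluster")
})

test_that("the 5x4 hand fixture reproduces VAFs, anchors and shifts", {
  f <- hand_fixture()
  m <- build_vaf_matrix(hand_fixture_records(),
                        patients = c("A", "B", "C", "D"))
  expect_equal(unname(m), unname(f$vaf[paste0("v", 1:5), ]))
  s <- compute_shift_matrix(m)
  expect_equal(unname(s$anchors), unname(f$anchors))
  expect_equal(unname(s$values), unname(f$shift))
})

test_that("anchors round the cohort median to the nearest of {0,50,100}", {
  expect_equal(compute_anchor(c(0, 0, 48, 52, 100)), 50)
  expect_equal(compute_anchor(c(0, 0, 0, 0, 30)), 0)
  expect_equal(compute_anchor(c(0, 50)), 0)      # median 25: tie to lower
  expect_equal(compute_anchor(c(50, 100)), 50)   # median 75: tie to lower
  expect_equal(compute_anchor(c(100, 100)), 100)
  expect_error(compute_anchor(numeric(0)), "empty")
})

test_that("shifts are bounded and exact for any valid VAF matrix", {
  set.seed(31)
  for (i in 1:25) {
    m <- matrix(sample(c(0, runif(30, 0, 100)), 40, replace = TRUE),
                nrow = 8, dimnames = list(paste0("v", 1:8),
                                          paste0("p", 1:5)))
    s <- compute_shift_matrix(m)
    expect_true(all(s$anchors %in% c(0, 50, 100)))
    expect_true(all(s$values >= -100 & s$values <= 100))
    expect_equal(s$values, m - s$anchors)
  }
})

test_that("clustering recovers well-separated blocks and is permutation
           invariant", {
  # two blocks of identical columns: any sane method separates them
  vaf <- cbind(A = c(40, 0, 30), B = c(40, 0, 30),
               C = c(0, 45, 0), D = c(0, 45, 0), E = c(0, 45, 0))
  rownames(vaf) <- paste0("v", 1:3)
  s <- compute_shift_matrix(vaf)
  cl <- cluster_patients(s)
  expect_equal(unname(cl$labels[c("A", "B")]), c(1L, 1L))
  expect_equal(unname(cl$labels[c("C", "D", "E")]), c(2L, 2L, 2L))

  # brute force: among all 2-partitions, the blocks minimise total
  # within-cluster squared distance (computed independently below)
  d2 <- as.matrix(dist(t(s$values)))^2
  parts <- c(utils::combn(5, 1, simplify = FALSE),
             utils::combn(5, 2, simplify = FALSE))
  wss <- function(idx) {
    a <- idx; b <- setdiff(1:5, idx)
    sum(d2[a, a]) / (2 * length(a)) + sum(d2[b, b]) / (2 * length(b))
  }
  best <- parts[[which.min(vapply(parts, wss, numeric(1)))]]
  expect_equal(sort(colnames(vaf)[best]), c("A", "B"))

  perm <- c("D", "A", "E", "C", "B")
  cl2 <- cluster_patients(compute_shift_matrix(vaf[, perm]))
  expect_equal(cl2$labels[names(cl$labels)], cl$labels)

  expect_error(cluster_patients(compute_shift_matrix(vaf[, 1,
                                                         drop = FALSE])),
               "fewer patients")
})

test_that("cluster assignment labels are deterministic and the tree has
           n - 1 merges", {
  set.seed(5)
  m <- matrix(runif(60, 0, 100), nrow = 6,
              dimnames = list(paste0("v", 1:6), paste0("p", 1:10)))
  s <- compute_shift_matrix(m)
  a <- cluster_patients(s); b <- cluster_patients(s)
  expect_identical(a$labels, b$labels)
  expect_equal(nrow(a$tree$merge), 9L)
  expect_equal(sort(unique(a$labels)), 1:2)
  # label 1 belongs to the cluster holding the smallest patient id
  expect_equal(unname(a$labels["p1"]), 1L)
})

test_that("variant leaf order puts identical rows adjacent", {
  vaf <- rbind(v1 = c(10, 20, 30, 0), v2 = c(90, 0, 5, 60),
               v3 = c(10, 20, 30, 0))
  colnames(vaf) <- paste0("p", 1:4)
  ord <- cluster_variants(compute_shift_matrix(vaf))
  expect_equal(abs(diff(match(c("v1", "v3"), ord))), 1)
  one <- compute_shift_matrix(vaf[1, , drop = FALSE])
  expect_equal(cluster_variants(one), "v1")
})

test_that("discriminant ranking orders by Mann-Whitney significance", {
  vals <- rbind(
    sep  = c(rep(50, 5), rep(-50, 5)),            # perfect separation
    same = rep(c(3, 1, 4, 1, 5), 2),              # identical distributions
    mid  = c(9, 10, 11, 12, 13, 11.5, 12.5, 13.5, 14.5, 15.5))
  colnames(vals) <- paste0("p", sprintf("%02d", 1:10))
  s <- structure(list(values = vals,
                      anchors = c(sep = 0, same = 0, mid = 0)),
                 class = "shift_matrix")
  labels <- setNames(rep(1:2, each = 5), colnames(vals))
  tab <- rank_discriminant_variants(s, labels)
  expect_equal(tab$variant[1], "sep")
  # exact two-sided p for complete separation with n = 5 vs 5
  expect_equal(tab$p[1], 2 / choose(10, 5))
  expect_equal(tab$variant[3], "same")
  expect_gt(tab$p[3], 0.9)
  # BH never decreases p and preserves the significance order
  expect_true(all(tab$p_adjusted >= tab$p - 1e-15))
  expect_true(!is.unsorted(tab$p_adjusted))
  expect_error(rank_discriminant_variants(
    s, setNames(rep(1L, 10), colnames(vals))), "non-empty")
})

test_that("newick export writes a readable tree with patient tips", {
  set.seed(2)
  m <- matrix(runif(40, 0, 100), nrow = 4,
              dimnames = list(paste0("v", 1:4), paste0("p", 1:10)))
  cl <- cluster_patients(compute_shift_matrix(m))
  d <- withr::local_tempdir()
  path <- export_newick(cl, file.path(d, "tree.nwk"))
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, paste0("p", 1:10))
})
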