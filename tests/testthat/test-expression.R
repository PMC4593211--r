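test_that("cpm follows its definition and scale invariances", {
  m <- matrix(c(5, 5), ncol = 1, dimnames = list(c("a", "b"), "L1"))
  expect_equal(unname(cpm_matrix(m)[, 1]), c(5e5, 5e5))
  m2 <- cbind(L1 = c(10, 30), L2 = c(20, 60))
  expect_equal(cpm_matrix(m2)[, 1], cpm_matrix(m2)[, 2])  # depth invariance
  half <- cpm_matrix(m2, norm_factors = c(2, 1))
  expect_equal(half[, 1], cpm_matrix(m2)[, 1] / 2)
  expect_error(cpm_matrix(cbind(c(0, 0))), "zero column")
  expect_equal(unname(colSums(cpm_matrix(m2))), c(1e6, 1e6))
})

test_that("TMM factors are 1 for identical or depth-scaled columns", {
  set.seed(61)
  x <- rpois(300, 80)
  expect_equal(unname(tmm_factors(cbind(A = x, B = x))), c(1, 1))
  expect_equal(unname(tmm_factors(cbind(A = x, B = 2L * x))), c(1, 1),
               tolerance = 1e-6)
  expect_warning(nf <- tmm_factors(cbind(A = x, B = x, C = 0L * x)),
                 "all-zero")
  expect_equal(unname(nf[3]), 1)
})

test_that("TMM recovers a planted compositional shift", {
  set.seed(62)
  n <- 500
  base <- rpois(n, 60) + 1L
  up <- seq_len(n) <= n * 0.1
  a <- base
  b <- base
  b[up] <- b[up] * 8L
  nf <- tmm_factors(cbind(A = a, B = b))
  ratio <- nf[["B"]] / nf[["A"]]
  # longhand two-sample TMM on the same matrix
  expect_equal(ratio, oracle_tmm_ratio(a, b), tolerance = 0.1)
  # the compositional shift: 10% of rows at 8x inflate B's library by ~1.7,
  # so B's factor must correct by that amount relative to A
  depth_inflation <- sum(b) / sum(a)
  expect_equal(ratio * depth_inflation, 1, tolerance = 0.1)
})

test_that("exact test gives null results on identical groups", {
  set.seed(63)
  ss <- data.frame(library_id = c("e1", "e2", "l1", "l2"),
                   stage = c("egg", "egg", "larva", "larva"),
                   replicate = c(1, 2, 1, 2))
  x <- rpois(50, 100)
  counts <- cbind(e1 = x, e2 = x, l1 = x, l2 = x)
  rownames(counts) <- sprintf("m%02d", 1:50)
  de <- exact_test_pair(counts, ss, "egg", "larva", dispersion = 0)
  expect_true(all(de$p_value == 1))
  expect_true(all(abs(de$log2_fold_change) < 1e-12))
  expect_false(any(de$significant))
})

test_that("a 1000-vs-0 split at zero dispersion is overwhelmingly significant", {
  ss <- data.frame(library_id = c("a1", "b1"), stage = c("A", "B"),
                   replicate = c(1, 1))
  counts <- rbind(hit = c(1000L, 0L),
                  matrix(50L, 40, 2))
  rownames(counts) <- c("hit", sprintf("bg%02d", 1:40))
  colnames(counts) <- c("a1", "b1")
  de <- exact_test_pair(counts, ss, "A", "B", dispersion = 0,
                        norm_factors = c(1, 1))
  hit <- de[de$mirna == "hit", ]
  expect_lt(hit$p_value, 1e-6)
  expect_gt(hit$log2_fold_change, 0)
  # the exact tail of a 1000:0 split is astronomically small, far beyond any
  # normal-approximation scale
  expect_lt(hit$p_value, 1e-100)
})

test_that("the FDR column is the BH adjustment of the p-values", {
  set.seed(64)
  ss <- data.frame(library_id = c("a1", "a2", "b1", "b2"),
                   stage = c("A", "A", "B", "B"), replicate = c(1, 2, 1, 2))
  counts <- matrix(rnbinom(200, mu = 80, size = 10), 50, 4,
                   dimnames = list(sprintf("m%02d", 1:50),
                                   c("a1", "a2", "b1", "b2")))
  counts[1:5, 3:4] <- counts[1:5, 3:4] * 6L
  de <- exact_test_pair(counts, ss, "A", "B", dispersion = 0.1)
  expect_equal(de$fdr, oracle_bh(de$p_value))
  expect_true(all(de$fdr >= de$p_value - 1e-12))
  expect_true(all(de$fdr <= 1))
  # monotone in p
  o <- order(de$p_value)
  expect_true(all(diff(de$fdr[o]) >= -1e-12))
})

test_that("hand-computed BH example is reproduced", {
  expect_equal(oracle_bh(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), "BH"),
               c(0.03, 0.03, 0.04))
})

test_that("the exact test is symmetric under group exchange", {
  set.seed(65)
  ss <- data.frame(library_id = c("a1", "a2", "b1", "b2"),
                   stage = c("A", "A", "B", "B"), replicate = c(1, 2, 1, 2))
  counts <- matrix(rnbinom(120, mu = 60, size = 8), 30, 4,
                   dimnames = list(sprintf("m%02d", 1:30),
                                   c("a1", "a2", "b1", "b2")))
  ab <- exact_test_pair(counts, ss, "A", "B", dispersion = 0.1)
  ba <- exact_test_pair(counts, ss, "B", "A", dispersion = 0.1)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-9)
  expect_equal(ab$log2_fold_change, -ba$log2_fold_change, tolerance = 1e-9)
})

test_that("all-zero miRNAs get p = 1 and zero fold change", {
  ss <- data.frame(library_id = c("a1", "b1"), stage = c("A", "B"),
                   replicate = c(1, 1))
  counts <- rbind(zero = c(0L, 0L), m1 = c(30L, 40L), m2 = c(22L, 18L))
  colnames(counts) <- c("a1", "b1")
  de <- exact_test_pair(counts, ss, "A", "B", dispersion = 0,
                        norm_factors = c(1, 1))
  z <- de[de$mirna == "zero", ]
  expect_equal(z$p_value, 1)
  expect_equal(z$log2_fold_change, 0)
})

test_that("log2 ratios use stage-mean cpm with a 0.5 pseudo-count", {
  ss <- data.frame(library_id = c("a1", "a2", "b1"),
                   stage = c("A", "A", "B"), replicate = c(1, 2, 1))
  counts <- matrix(c(40, 10, 40, 10, 80, 5), 2, 3,
                   dimnames = list(c("m1", "m2"), c("a1", "a2", "b1")))
  lr <- log2_ratio_matrix(counts, ss, cbind("A", "B"))
  cp <- cpm_matrix(counts)
  expected <- log2((rowMeans(cp[, 1:2]) + 0.5) / (cp[, 3] + 0.5))
  expect_equal(unname(lr[, 1]), unname(expected))
  # antisymmetry
  lr_rev <- log2_ratio_matrix(counts, ss, cbind("B", "A"))
  expect_equal(lr[, 1], -lr_rev[, 1])
  # equal stage means give zero
  counts_eq <- matrix(20, 2, 3, dimnames = dimnames(counts))
  expect_equal(unname(log2_ratio_matrix(counts_eq, ss,
                                        cbind("A", "B"))[, 1]), c(0, 0))
})

test_that("hierarchical clustering groups planted profile shapes", {
  set.seed(66)
  base <- rbind(matrix(rep(c(2, 2, -1), each = 8), 8, 3),
                matrix(rep(c(-2, 1, 2), each = 8), 8, 3),
                matrix(rep(c(0, -2, -2), each = 8), 8, 3))
  noisy <- base + matrix(rnorm(length(base), sd = 0.2), nrow(base))
  rownames(noisy) <- sprintf("m%02d", seq_len(nrow(noisy)))
  hc <- hierarchical_cluster(noisy, k = 3)
  truth <- rep(1:3, each = 8)
  # cluster labels must be a relabelling of the planted groups
  tab <- table(hc$groups, truth)
  expect_equal(sum(apply(tab, 2, max)), 24)
  # identical rows merge first
  two <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  hc2 <- hierarchical_cluster(two)
  expect_equal(sort(hc2$merge[1, ]), c(-2, -1))
})

test_that("spearman grids handle perfect, reversed and sparse cases", {
  orth <- data.frame(species_a_id = sprintf("a%d", 1:10),
                     species_b_id = sprintf("b%d", 1:10))
  xa <- matrix(1:10, 10, 1, dimnames = list(orth$species_a_id, "libA"))
  xb_same <- matrix(1:10, 10, 1, dimnames = list(orth$species_b_id, "libB"))
  g1 <- spearman_matrix(xa, xb_same, orth)
  expect_equal(g1$rho, 1)
  expect_equal(g1$n_pairs, 10L)
  xb_rev <- matrix(10:1, 10, 1, dimnames = list(orth$species_b_id, "libB"))
  expect_equal(spearman_matrix(xa, xb_rev, orth)$rho, -1)
  few <- orth[1:3, ]
  g3 <- spearman_matrix(xa, xb_same, few)
  expect_true(g3$insufficient)
  expect_true(is.na(g3$rho))
})

test_that("quantification sums collapsed counts over mature loci", {
  collapsed <- data.frame(sequence = c("AAAA", "CCCC"),
                          L1 = c(3L, 5L), L2 = c(1L, 0L),
                          total_count = c(4L, 5L))
  aln <- data.frame(sequence = c("AAAA", "CCCC"), scaffold = "s1",
                    start = c(100L, 300L), strand = "+",
                    mismatches = 0L, n_hits = 1L)
  mir <- data.frame(id = c("mA", "mB"), scaffold = "s1", strand = "+",
                    mature_start = c(95L, 500L), mature_end = c(120L, 520L))
  q <- quantify_mirnas(aln, collapsed, mir, c("L1", "L2"))
  expect_equal(q["mA", ], c(L1 = 3L, L2 = 1L))
  expect_equal(q["mB", ], c(L1 = 0L, L2 = 0L))
})
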