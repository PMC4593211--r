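tiny_cfg <- function(seed = 5, ...) {
  sim_config(seed = seed, n_scaffolds = 2L, scaffold_len = 75000L,
             n_known_mirnas = 6L, n_novel_mirnas = 2L,
             n_clusters = 1L, cluster_members = 3L, n_decoy_loci = 4L,
             depth_per_library = 1200L, ...)
}

test_that("invalid configurations are rejected", {
  expect_error(sim_config(mature_fraction = 0.9, star_fraction = 0.2,
                          loop_fraction = 0.02, decoy_fraction = 0.15),
               "sum to 1")
  expect_error(sim_config(n_scaffolds = 2L, scaffold_len = 15000L,
                          n_known_mirnas = 30L) |> simulate_genome(),
               "genome too small")
})

test_that("simulation is fully deterministic under a fixed seed", {
  s1 <- simulate_genome(tiny_cfg())
  s2 <- simulate_genome(tiny_cfg())
  expect_identical(s1$truth, s2$truth)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  l1 <- simulate_libraries(s1, tiny_cfg())
  l2 <- simulate_libraries(s2, tiny_cfg())
  expect_identical(l1$counts, l2$counts)
  expect_identical(l1$reads, l2$reads)
  # a different seed changes the data but not the schema
  s3 <- simulate_genome(tiny_cfg(seed = 6))
  expect_false(identical(as.character(s3$genome), as.character(s1$genome)))
  expect_identical(names(s3$truth), names(s1$truth))
})

test_that("every planted hairpin sits verbatim at its recorded locus", {
  sim <- simulate_genome(tiny_cfg())
  g <- stats::setNames(as.character(sim$genome), names(sim$genome))
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    seg <- substr(g[[tr$scaffold]], tr$start, tr$end)
    expected <- if (tr$strand == "+") tr$precursor_seq else
      revcomp(tr$precursor_seq)
    expect_equal(seg, expected, info = tr$id)
    mat <- substr(g[[tr$scaffold]], tr$mature_start, tr$mature_end)
    if (tr$strand == "-") mat <- revcomp(mat)
    expect_equal(mat, tr$mature_seq, info = tr$id)
  }
})

test_that("planted clusters are recovered from the truth table", {
  cfg <- tiny_cfg()
  sim <- simulate_genome(cfg)
  det <- detect_clusters(sim$truth[c("id", "scaffold", "start", "end",
                                     "strand")])
  expect_equal(nrow(det$clusters), cfg$n_clusters)
  expect_equal(det$clusters$n_members, cfg$cluster_members)
  expect_lte(det$clusters$span_bp, 3500L)
  # the first cluster carries a duplicated family label
  cl1 <- sim$truth[!is.na(sim$truth$cluster_id) &
                     sim$truth$cluster_id == "true-cluster-1", ]
  expect_gt(max(table(cl1$family)), 1L)
})

test_that("library structure honours the missing replicate", {
  cfg <- tiny_cfg()
  libs <- simulate_libraries(simulate_genome(cfg), cfg, reads = FALSE)
  expect_equal(nrow(libs$sample_sheet), 14L)
  expect_false("female_pupa_r2" %in% libs$sample_sheet$library_id)
  expect_equal(colnames(libs$counts), libs$sample_sheet$library_id)
})

test_that("pure-mature libraries conserve read counts exactly", {
  cfg <- tiny_cfg(mature_fraction = 1, star_fraction = 0, loop_fraction = 0,
                  decoy_fraction = 0, short_fraction = 0)
  sim <- simulate_genome(cfg)
  libs <- simulate_libraries(sim, cfg)
  for (lib in libs$sample_sheet$library_id) {
    expect_equal(length(libs$reads[[lib]]), sum(libs$counts[, lib]),
                 info = lib)
  }
})

test_that("observed counts track expected cpm at high rank correlation", {
  cfg <- tiny_cfg()
  libs <- simulate_libraries(simulate_genome(cfg), cfg, reads = FALSE)
  for (lib in colnames(libs$counts)) {
    rho <- suppressWarnings(
      cor(libs$counts[, lib], libs$expected_cpm[, lib], method = "spearman"))
    expect_gt(rho, 0.8)
  }
})

test_that("reference databases exercise perfect and near-perfect classes", {
  cfg0 <- tiny_cfg(db_mutation_choices = 0L)
  sim <- simulate_genome(cfg0)
  dbs0 <- make_reference_dbs(sim, cfg0)
  known <- sim$truth[!sim$truth$novel, ]
  for (i in seq_len(nrow(known))) {
    m <- match_mature(known$mature_seq[i], dbs0$mature_db)
    expect_equal(m$class, "perfect", info = known$id[i])
  }
  expect_true(all(dbs0$expected_label[known$id] == "known"))
  expect_true(all(dbs0$expected_label[sim$truth$id[sim$truth$novel]] ==
                    "novel_candidate"))
  # novel miRNAs are omitted from the database
  expect_equal(length(dbs0$mature_db), nrow(known))

  cfg1 <- tiny_cfg(db_mutation_choices = 1L)
  sim1 <- simulate_genome(cfg1)
  dbs1 <- make_reference_dbs(sim1, cfg1)
  known1 <- sim1$truth[!sim1$truth$novel, ]
  for (i in seq_len(nrow(known1))) {
    q <- known1$mature_seq[i]
    ref <- dbs1$mature_db[[paste0("ref-", known1$id[i])]]
    mutpos <- which(strsplit(q, "")[[1]] != strsplit(ref, "")[[1]])
    expect_length(mutpos, 1L)
    m <- match_mature(q, dbs1$mature_db)
    # the shared 16-mer survives iff the mutation sits within 6 nt of
    # either end of the 22-mer; a central mutation hides the entry
    if (max(mutpos - 1L, nchar(q) - mutpos) >= 16L) {
      expect_equal(m$class, "near_perfect", info = known1$id[i])
      expect_equal(m$mismatches, 1L)
    } else {
      expect_null(m, info = known1$id[i])
    }
  }
})

test_that("the cross-species generator hits its configured rank correlation", {
  cfg <- sim_config(seed = 9, n_scaffolds = 8L, scaffold_len = 130000L,
                    n_known_mirnas = 70L, n_novel_mirnas = 0L,
                    n_clusters = 1L, cluster_members = 3L,
                    n_decoy_loci = 4L, cross_rho = 0.8)
  sim <- simulate_genome(cfg)
  dbs <- make_reference_dbs(sim, cfg)
  expect_gte(nrow(dbs$orthologs), 60L)
  w <- mirstack:::stage_weights(sim$truth, cfg)
  rho <- vapply(cfg$stages, function(st) {
    cor(w[, st], dbs$expr_b[, st], method = "spearman")
  }, 0)
  expect_true(all(abs(rho - cfg$cross_rho) <= 0.1))
})
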