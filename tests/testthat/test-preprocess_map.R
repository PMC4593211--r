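test_that("length filter and collapsing follow the 17 nt rule", {
  r17 <- "ACGTACGTACGTACGTA"
  fc <- suppressWarnings(
    filter_and_collapse(list(L1 = c(rep(r17, 3), rep("ACGT", 5)))))
  expect_equal(nrow(fc$collapsed), 1L)
  expect_equal(fc$collapsed$L1, 3L)
  expect_equal(fc$summary$total_reads, 8L)
  expect_equal(fc$summary$usable_reads, 3L)
})

test_that("identical sequences merge across libraries with counts preserved", {
  r <- "ACGTACGTACGTACGTA"
  fc <- filter_and_collapse(list(L1 = rep(r, 2), L2 = rep(r, 7)))
  expect_equal(fc$collapsed$L1, 2L)
  expect_equal(fc$collapsed$L2, 7L)
  expect_equal(fc$collapsed$total_count, 9L)
})

test_that("simulated sub-17 nt fraction is removed as configured", {
  cfg <- sim_config(seed = 3, n_scaffolds = 2L, scaffold_len = 60000L,
                    n_known_mirnas = 5L, n_novel_mirnas = 0L,
                    n_clusters = 1L, cluster_members = 2L,
                    n_decoy_loci = 4L, depth_per_library = 2000L)
  sim <- simulate_genome(cfg)
  libs <- simulate_libraries(sim, cfg)
  reads <- unlist(libs$reads, use.names = FALSE)
  usable <- mean(nchar(reads) >= 17)
  # the generator plants 4.7 % of reads below the cutoff
  expect_equal(1 - usable, cfg$short_fraction, tolerance = 0.25)
  fc <- filter_and_collapse(libs$reads)
  expect_equal(sum(fc$summary$usable_reads) / sum(fc$summary$total_reads),
               usable)
})

test_that("the k-mer index resolves both strands and rejects tiny words", {
  g <- c(s1 = "ACGTACGTACGTACGTAC")
  idx <- build_index(g, word = 18L)
  hit <- index_query(idx, "ACGTACGTACGTACGTAC")
  expect_true(any(hit$pos == 1 & hit$strand == "+"))
  rc <- revcomp("ACGTACGTACGTACGTAC")
  hit_rc <- index_query(idx, rc)
  expect_true(any(hit_rc$strand == "-"))
  expect_equal(nrow(index_query(idx, strrep("G", 18))), 0L)
  expect_error(build_index(g, word = 7L), ">= 8")
})

test_that("mapping applies seed, tail-mismatch and multiplicity rules", {
  set.seed(21)
  g <- c(s1 = random_seq(4000))
  idx <- build_index(g)
  r <- substr(g[["s1"]], 1001, 1022)

  aln <- map_collapsed_reads(data.frame(sequence = r), idx)
  expect_equal(aln$alignments$start, 1001L)
  expect_equal(aln$alignments$mismatches, 0L)
  expect_equal(aln$alignments$n_hits, 1L)

  # one substitution at position 20 (outside the 18 nt seed) still aligns;
  # a brute-force scan confirms this is the only <=2-mismatch locus
  r20 <- r
  substr(r20, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                 substr(r, 20, 20))[1]
  aln20 <- map_collapsed_reads(data.frame(sequence = r20), idx)
  expect_equal(aln20$alignments$mismatches, 1L)
  oracle <- oracle_map_loci(r20, g)
  expect_equal(nrow(oracle), 1L)
  expect_equal(aln20$alignments$start, oracle$start)

  # three substitutions outside the seed exceed the tail budget
  r3 <- r
  for (p in c(19, 20, 21)) {
    substr(r3, p, p) <- setdiff(c("A", "C", "G", "T"), substr(r3, p, p))[1]
  }
  expect_equal(map_collapsed_reads(data.frame(sequence = r3),
                                   idx)$unmapped, r3)

  # a read planted 6 times is dropped under max_hits = 5
  rep_read <- random_seq(22)
  g6 <- g
  for (k in 0:5) {
    s <- 2000 + k * 100
    substr(g6[["s1"]], s, s + 21) <- rep_read
  }
  idx6 <- build_index(g6)
  mp6 <- map_collapsed_reads(data.frame(sequence = rep_read), idx6)
  expect_equal(mp6$dropped, rep_read)
  expect_equal(map_collapsed_reads(data.frame(sequence = rep_read), idx6,
                                   max_hits = 6L)$alignments$n_hits, 6L)
})

test_that("mapper agrees with the brute-force oracle and conserves reads", {
  set.seed(33)
  g <- c(sA = random_seq(3000), sB = random_seq(2500))
  idx <- build_index(g)
  reads <- character(0)
  for (k in 1:12) {   # planted reads, some mutated, some reverse-complement
    sc <- sample(names(g), 1)
    s <- sample(nchar(g[[sc]]) - 30, 1)
    r <- substr(g[[sc]], s, s + sample(18:26, 1))
    if (k %% 3 == 0) {
      p <- sample(19:nchar(r), 1)
      substr(r, p, p) <- setdiff(c("A", "C", "G", "T"), substr(r, p, p))[1]
    }
    if (k %% 4 == 0) r <- revcomp(r)
    reads <- c(reads, r)
  }
  reads <- c(reads, vapply(1:5, function(i) random_seq(22), ""))
  reads <- unique(reads)
  collapsed <- data.frame(sequence = reads)
  mp <- map_collapsed_reads(collapsed, idx)
  for (r in reads) {
    loci <- oracle_map_loci(r, g)
    n <- nrow(loci)
    if (n == 0) {
      expect_true(r %in% mp$unmapped, info = r)
    } else if (n > 5) {
      expect_true(r %in% mp$dropped, info = r)
    } else {
      row <- mp$alignments[mp$alignments$sequence == r, ]
      expect_equal(nrow(row), 1L, info = r)
      o <- loci[order(loci$mismatches, loci$scaffold, loci$start,
                      match(loci$strand, c("+", "-"))), ][1, ]
      expect_equal(row$scaffold, o$scaffold, info = r)
      expect_equal(row$start, o$start, info = r)
      expect_equal(row$strand, o$strand, info = r)
      expect_equal(row$mismatches, o$mismatches, info = r)
      expect_equal(row$n_hits, n, info = r)
    }
  }
  # count conservation and input-order invariance
  expect_equal(nrow(mp$alignments) + length(mp$unmapped) + length(mp$dropped),
               length(reads))
  mp_rev <- map_collapsed_reads(collapsed[rev(seq_len(nrow(collapsed))), ,
                                          drop = FALSE], idx)
  expect_identical(mp$alignments, mp_rev$alignments)
})

test_that("17 nt reads map by exact full-length match only", {
  set.seed(8)
  g <- c(s1 = random_seq(2000))
  idx <- build_index(g)
  r <- substr(g[["s1"]], 501, 517)
  mp <- map_collapsed_reads(data.frame(sequence = r), idx)
  expect_equal(mp$alignments$start, 501L)
  rmut <- r
  substr(rmut, 10, 10) <- setdiff(c("A", "C", "G", "T"), substr(r, 10, 10))[1]
  expect_true(rmut %in% map_collapsed_reads(data.frame(sequence = rmut),
                                            idx)$unmapped)
})
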