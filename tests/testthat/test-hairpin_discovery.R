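make_alignments <- function(seqs, scaffold, starts, strand = "+") {
  data.frame(sequence = seqs, scaffold = scaffold, start = starts,
             strand = strand, mismatches = 0L, n_hits = 1L,
             stringsAsFactors = FALSE)
}

test_that("excision arithmetic matches the two-window contract", {
  g <- c(s1 = strrep("A", 500))
  r <- strrep("C", 22)
  aln <- make_alignments(r, "s1", 100L)
  coll <- data.frame(sequence = r, total_count = 25L)
  w <- excise_candidates(aln, g, coll, min_stack = 5L,
                         flank_up = 70L, flank_down = 70L)
  expect_equal(nrow(w), 2L)
  expect_equal(sort(w$start), c(30L, 100L))
  expect_equal(sort(w$end), c(121L, 191L))
  expect_equal(unique(w$stack_count), 25L)
  # below min_stack: nothing
  coll$total_count <- 4L
  expect_equal(nrow(excise_candidates(aln, g, coll, min_stack = 5L)), 0L)
  # clipping at scaffold start
  aln2 <- make_alignments(r, "s1", 10L)
  coll2 <- data.frame(sequence = r, total_count = 25L)
  w2 <- excise_candidates(aln2, g, coll2)
  expect_true(all(w2$start >= 1L))
})

test_that("excision merges overlapping stacks and ignores input order", {
  g <- c(s1 = strrep("A", 1000))
  seqs <- c(strrep("C", 22), strrep("G", 22))
  aln <- make_alignments(seqs, "s1", c(100L, 110L))
  coll <- data.frame(sequence = seqs, total_count = c(3L, 4L))
  w <- excise_candidates(aln, g, coll)
  expect_equal(unique(w$stack_start), 100L)
  expect_equal(unique(w$stack_end), 131L)
  expect_equal(unique(w$stack_count), 7L)
  w_rev <- excise_candidates(aln[2:1, ], g, coll)
  expect_identical(w, w_rev)
})

test_that("a planted two-arm hairpin is excised, folded and reported", {
  hp <- planted_hairpin_genome(seed = 11)
  reads <- c(rep(hp$mature, 60), rep(hp$star, 6),
             rep(substr(hp$precursor, 20, 40), 2))
  fc <- filter_and_collapse(list(L1 = reads))
  idx <- build_index(hp$genome)
  mp <- map_collapsed_reads(fc$collapsed, idx)
  wins <- excise_candidates(mp$alignments, hp$genome, fc$collapsed)
  expect_true(any(wins$start <= hp$start & wins$end >= hp$end))
  cand <- hairpin_candidates(wins, mp$alignments, fc$collapsed, hp$genome,
                             n_shuffles = 29, seed = 2)
  expect_gte(nrow(cand), 1L)
  top <- cand[which.max(cand$score), ]
  expect_true(top$reported)
  expect_gt(top$score, 2)
  expect_equal(as_dna(top$mature_seq), hp$mature)
  expect_equal(as_dna(top$star_seq), hp$star)
  expect_gte(top$mature_count, top$star_count)
  expect_lte(top$shuffle_p, 0.05)
  expect_equal(nchar(top$structure), nchar(as_dna(top$precursor_seq)))
})

test_that("a minus-strand planted hairpin is recovered in transcript space", {
  hp <- planted_hairpin_genome(seed = 13)
  # insert the reverse complement so the transcript runs on the minus strand
  g <- hp$genome
  gs <- as.character(g[["s1"]])
  substr(gs, hp$start, hp$end) <- revcomp(hp$precursor)
  g <- c(s1 = gs)
  reads <- c(rep(hp$mature, 40), rep(hp$star, 5))
  fc <- filter_and_collapse(list(L1 = reads))
  idx <- build_index(g)
  mp <- map_collapsed_reads(fc$collapsed, idx)
  expect_true(all(mp$alignments$strand == "-"))
  wins <- excise_candidates(mp$alignments, g, fc$collapsed)
  cand <- hairpin_candidates(wins, mp$alignments, fc$collapsed, g,
                             n_shuffles = 29, seed = 2)
  top <- cand[which.max(cand$score), ]
  expect_equal(as_dna(top$mature_seq), hp$mature)
  expect_true(top$reported)
})

test_that("the additive score behaves per its read-class design", {
  # dominant mature arm, star support, significant fold
  s_good <- score_candidate(95, 4, 1, 0, shuffle_p = 0.01)
  expect_equal(s_good, min(log2(96 / 2), 4) + 2 + 3)
  expect_gt(s_good, 2)
  # uniform smear without structure: below the reporting threshold
  s_smear <- score_candidate(20, 0, 30, 50, shuffle_p = 0.5)
  expect_lte(s_smear, 2)
  # an abundant single block without fold support cannot be reported
  expect_lte(score_candidate(5000, 0, 0, 0, shuffle_p = 0.5), 2)
  # malformed hairpins are penalized into rejection
  expect_lte(score_candidate(95, 4, 1, 0, 0.01, mature_on_arm = FALSE), 2)
})

test_that("candidates at or below the hard drop threshold are excluded", {
  hp <- planted_hairpin_genome(seed = 15)
  reads <- rep(hp$mature, 30)
  fc <- filter_and_collapse(list(L1 = reads))
  idx <- build_index(hp$genome)
  mp <- map_collapsed_reads(fc$collapsed, idx)
  wins <- excise_candidates(mp$alignments, hp$genome, fc$collapsed)
  all_c <- hairpin_candidates(wins, mp$alignments, fc$collapsed, hp$genome,
                              n_shuffles = 29, seed = 2)
  none <- hairpin_candidates(wins, mp$alignments, fc$collapsed, hp$genome,
                             n_shuffles = 29, seed = 2,
                             min_score = max(all_c$score) + 1)
  expect_gte(nrow(all_c), 1L)
  expect_equal(nrow(none), 0L)
})

test_that("exon overlap classification covers all interval cases", {
  exons <- data.frame(scaffold = "s1",
                      start = c(100L, 400L, 500L),
                      end = c(200L, 450L, 560L),
                      strand = "+",
                      gene_id = c("gA", "gB", "gB"),
                      feature = "exon", stringsAsFactors = FALSE)
  expect_equal(classify_exon_overlap("s1", 120, 180, exons)$category,
               "within_exon")
  expect_equal(classify_exon_overlap("s1", 90, 210, exons)$category,
               "contains_exon")
  expect_equal(classify_exon_overlap("s1", 90, 150, exons)$category,
               "overlaps_exon_boundary")
  # between gB's exons, touching neither
  expect_equal(classify_exon_overlap("s1", 460, 490, exons)$category,
               "intronic")
  expect_equal(classify_exon_overlap("s1", 700, 760, exons)$category,
               "intergenic")
  expect_equal(classify_exon_overlap("s2", 120, 180, exons)$category,
               "intergenic")
})

test_that("hairpin rendering marks mature, loop and star segments", {
  hp <- planted_hairpin_genome(seed = 17)
  cand <- data.frame(precursor_seq = as_rna(hp$precursor),
                     structure = strrep(".", nchar(hp$precursor)),
                     mature_seq = as_rna(hp$mature),
                     star_seq = as_rna(hp$star),
                     loop_seq = as_rna(hp$loop), stringsAsFactors = FALSE)
  lines <- render_hairpin(cand)
  expect_equal(nchar(lines[3]), nchar(hp$precursor))
  expect_match(lines[3], "M+")
  expect_match(lines[3], "S+")
})
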