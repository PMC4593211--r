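test_that("mature matching applies the perfect and near-perfect rules", {
  set.seed(51)
  db <- c(ref1 = random_seq(22), ref2 = random_seq(23))
  q <- db[["ref1"]]
  m <- match_mature(q, db)
  expect_equal(m$class, "perfect")
  expect_equal(m$subject_id, "ref1")
  expect_equal(m$mismatches, 0L)

  # one substitution at position 20 (shared 16-mer retained)
  q1 <- q
  substr(q1, 20, 20) <- setdiff(c("A", "C", "G", "T"), substr(q, 20, 20))[1]
  m1 <- match_mature(q1, db)
  expect_equal(m1$class, "near_perfect")
  expect_equal(m1$mismatches, 1L)

  # 2 nt truncation at the 3' end, no mismatch
  m2 <- match_mature(substr(q, 1, 20), db)
  expect_equal(m2$class, "near_perfect")
  expect_equal(m2$aligned_len, 20L)

  # 3 nt truncation exceeds the length-difference rule
  m3 <- match_mature(substr(q, 1, 19), db)
  expect_false(is.null(m3))
  expect_equal(m3$class, "weak")
})

test_that("queries without a shared 16-mer yield no match", {
  set.seed(52)
  db <- c(ref1 = random_seq(22))
  q <- db[["ref1"]]
  for (p in c(6, 12, 18)) {   # three scattered substitutions
    substr(q, p, p) <- setdiff(c("A", "C", "G", "T"), substr(q, p, p))[1]
  }
  # brute-force check: no 16-mer is shared after the substitutions
  words <- function(s) substring(s, 1:(nchar(s) - 15), 16:nchar(s))
  expect_length(intersect(words(q), words(db[["ref1"]])), 0L)
  expect_null(match_mature(q, db))
})

test_that("mature matching equals the exhaustive oracle", {
  set.seed(53)
  db <- stats::setNames(vapply(1:120, function(i) random_seq(sample(20:24, 1)),
                               ""), sprintf("ref%03d", 1:120))
  queries <- character(0)
  for (k in 1:30) {
    q <- db[[sample(length(db), 1)]]
    nm <- sample(0:3, 1)
    if (nm > 0) {
      for (p in sample(nchar(q), nm)) {
        substr(q, p, p) <- setdiff(c("A", "C", "G", "T"), substr(q, p, p))[1]
      }
    }
    if (k %% 5 == 0) q <- substr(q, 1, nchar(q) - sample(1:3, 1))
    queries <- c(queries, q)
  }
  for (q in queries) {
    got <- match_mature(q, db)
    exp <- oracle_match_mature(q, db)
    if (is.null(exp)) {
      expect_null(got, info = q)
    } else {
      expect_equal(got$class, exp$class, info = q)
      expect_equal(got$mismatches, exp$mismatches, info = q)
    }
  }
})

test_that("hairpin matching enforces the 8-base coverage rule", {
  set.seed(54)
  hp <- random_seq(90)
  db <- c(refh = hp)
  m <- match_hairpin(hp, db)
  expect_equal(m$aligned_len, 90L)
  expect_equal(m$class, "perfect")

  # query 100 nt whose alignable core covers only 88 nt: discarded
  q_long <- paste0(random_seq(6), substr(hp, 1, 88), random_seq(6))
  expect_null(match_hairpin(q_long, db))
  expect_false(is.null(match_hairpin(q_long, db, max_len_slack = 12)))

  # query 95 nt with a 90 nt aligned stretch: kept (5 <= 8)
  q_ok <- paste0(random_seq(5), hp)
  m_ok <- match_hairpin(q_ok, db)
  expect_false(is.null(m_ok))
  expect_gte(m_ok$aligned_len, 90L)

  # reverse-complement queries are found via the minus orientation
  m_rc <- match_hairpin(revcomp(hp), db)
  expect_equal(m_rc$strand, "-")
  expect_equal(m_rc$aligned_len, 90L)
})

test_that("candidate classification is a partition into known/iso/novel", {
  set.seed(55)
  mature <- random_seq(22)
  hairpin <- paste0(mature, random_seq(15), revcomp(mature))
  mature_db <- c(refm = mature)
  hairpin_db <- c(refh = hairpin)
  mut <- mature
  substr(mut, 21, 21) <- setdiff(c("A", "C", "G", "T"), substr(mut, 21, 21))[1]
  cands <- data.frame(
    id = c("known", "iso_mature", "iso_hairpin_only", "novel"),
    mature_seq = c(mature, mut, random_seq(22), random_seq(22)),
    precursor_seq = c(hairpin, hairpin, hairpin, random_seq(60)),
    stringsAsFactors = FALSE)
  lab <- classify_candidates(cands, mature_db, hairpin_db)
  expect_equal(lab$label,
               c("known", "iso", "iso", "novel_candidate"))
  # exactly one label each
  expect_true(all(lab$label %in% c("known", "iso", "novel_candidate")))
  expect_equal(nrow(lab), nrow(cands))
})

test_that("reciprocal best hits require mutual best matches", {
  set.seed(56)
  h1 <- random_seq(80)
  a <- c(a1 = h1)
  b <- c(b1 = h1)
  expect_equal(reciprocal_best_hits(a, b),
               data.frame(species_a_id = "a1", species_b_id = "b1"))
  # a2 maps best to b1, but b1 maps best to a1: no pair for a2
  a2 <- h1
  substr(a2, 40, 40) <- setdiff(c("A", "C", "G", "T"), substr(h1, 40, 40))[1]
  ab <- reciprocal_best_hits(c(a1 = h1, a2 = a2), b)
  expect_equal(ab$species_a_id, "a1")
})

test_that("RBH recovers planted ortholog families symmetrically", {
  set.seed(57)
  fams <- vapply(1:6, function(i) random_seq(80), "")
  mut <- function(s, n) {
    for (p in sample(nchar(s), n)) {
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), substr(s, p, p))[1]
    }
    s
  }
  a <- stats::setNames(vapply(fams, mut, "", n = 2), sprintf("a%d", 1:6))
  b <- stats::setNames(vapply(fams, mut, "", n = 2), sprintf("b%d", 1:6))
  # decoys without counterparts
  a <- c(a, a_decoy = random_seq(80))
  b <- c(b, b_decoy = random_seq(80))
  pairs <- reciprocal_best_hits(a, b)
  expect_equal(pairs$species_a_id, sprintf("a%d", 1:6))
  expect_equal(pairs$species_b_id, sprintf("b%d", 1:6))
  # symmetry: swapping species yields the same pair set
  rev_pairs <- reciprocal_best_hits(b, a)
  expect_equal(rev_pairs$species_a_id, sprintf("b%d", 1:6))
  expect_equal(rev_pairs$species_b_id, sprintf("a%d", 1:6))
  # each id in at most one pair
  expect_false(any(duplicated(pairs$species_a_id)))
  expect_false(any(duplicated(pairs$species_b_id)))
})
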