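# Shared fixtures built in code.

# Sample sheet of the study design: 5 stages x 3 replicates, with the
# female pupa replicate 2 library never sequenced (14 libraries).
study_sample_sheet <- function() {
  ss <- expand.grid(replicate = 1:3,
                    stage = c("egg", "larva", "male_pupa", "female_pupa",
                              "ovary"),
                    stringsAsFactors = FALSE)[, c("stage", "replicate")]
  ss <- ss[!(ss$stage == "female_pupa" & ss$replicate == 2), ]
  ss$library_id <- sprintf("%s_r%d", ss$stage, ss$replicate)
  ss$path <- ""
  rownames(ss) <- NULL
  ss[c("library_id", "stage", "replicate", "path")]
}

# The unmatched-candidate fixture shaped like the published triage narrative:
# 1 candidate present in all libraries, 1 missing exactly one replicate,
# 7 restricted to egg/larva/ovary (absent from both pupa stages) of which
# 3 fail on low count/no star and 1 on a malformed hairpin, and the rest
# detected in a single replicate of a single stage. Totals 35 candidates;
# exactly 5 should be accepted.
triage_fixture <- function(n_total = 35L) {
  ss <- study_sample_sheet()
  libs <- ss$library_id
  pupa <- libs[grepl("pupa", libs)]
  non_pupa <- setdiff(libs, pupa)
  n_single <- n_total - 9L
  ids <- sprintf("novel-%02d", seq_len(n_total))
  counts <- matrix(0L, n_total, length(libs), dimnames = list(ids, libs))
  meta <- data.frame(id = ids, mature_count = 0L, star_count = 0L,
                     hairpin_ok = TRUE, stringsAsFactors = FALSE)
  # 1: present everywhere
  counts[1, ] <- 50L
  meta$mature_count[1] <- 600L; meta$star_count[1] <- 40L
  # 2: absent in exactly one replicate (larva r2), low but present elsewhere
  counts[2, ] <- 5L; counts[2, "larva_r2"] <- 0L
  meta$mature_count[2] <- 60L; meta$star_count[2] <- 6L
  # 3-9: stage-restricted (absent from all pupa libraries)
  for (i in 3:9) counts[i, non_pupa] <- 30L
  # 3 fail R3a: low total count and/or no star
  counts[3, ] <- 0L; counts[3, non_pupa] <- 1L          # total 8 < 10
  meta$mature_count[3] <- 6L; meta$star_count[3] <- 1L
  meta$mature_count[4] <- 200L; meta$star_count[4] <- 0L  # no star
  counts[5, ] <- 0L; counts[5, non_pupa] <- 1L          # low count, no star
  meta$mature_count[5] <- 6L; meta$star_count[5] <- 0L
  # 1 fails R3b: malformed hairpin
  meta$mature_count[6] <- 250L; meta$star_count[6] <- 20L
  meta$hairpin_ok[6] <- FALSE
  # 3 pass R3
  for (i in 7:9) {
    meta$mature_count[i] <- 220L; meta$star_count[i] <- 15L
  }
  # the rest: one replicate of one stage
  single_libs <- rep(libs, length.out = n_single)
  for (k in seq_len(n_single)) {
    counts[9L + k, single_libs[k]] <- 12L
    meta$mature_count[9L + k] <- 12L; meta$star_count[9L + k] <- 1L
  }
  list(counts = counts, sample_sheet = ss, meta = meta)
}

# A small genome with one perfect planted hairpin (22 nt arms, 15 nt loop)
# and a known mature/star read population.
planted_hairpin_genome <- function(seed = 11L, scaffold_len = 2000L,
                                   insert_at = 801L) {
  set.seed(seed)
  arm <- random_seq(22L)
  loop <- random_seq(15L)
  # the star arm carries 2 mismatches: an exact reverse complement would be
  # a palindrome mapping to both strands
  star <- mirstack::revcomp(arm)
  for (p in c(5L, 14L)) {
    substr(star, p, p) <- setdiff(c("A", "C", "G", "T"), substr(star, p, p))[1]
  }
  pre <- paste0(arm, loop, star)
  g <- random_seq(scaffold_len)
  g <- paste0(substr(g, 1, insert_at - 1L), pre,
              substr(g, insert_at + nchar(pre), scaffold_len))
  list(genome = c(s1 = g), mature = arm, star = star,
       loop = loop, precursor = pre, start = insert_at,
       end = insert_at + nchar(pre) - 1L)
}
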