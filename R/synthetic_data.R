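#' Simulation configuration
#'
#' Defaults encode the stage-structured study design the pipeline assumes:
#' five developmental stages (egg, larva, male pupa, female pupa, ovary) with
#' three biological replicates and one unsequenced library (female pupa
#' replicate 2); read classes dominated by mature miRNA with minor star, loop
#' and decoy fractions; 4.7 % of sequenced reads below the 17 nt cutoff;
#' negative-binomial count noise with dispersion 0.1; three stage-profile
#' groups (rising towards pupa; larva-peaked; pupa-depleted/ovary-high) with
#' 4-fold profile contrasts; and a multi-copy decoy repeat (6 copies) to trip
#' the mapping multiplicity filter.
#'
#' @param seed integer seed; all downstream simulation is reproducible
#'   given it.
#' @param n_scaffolds,scaffold_len genome shape.
#' @param n_known_mirnas,n_novel_mirnas planted miRNAs with/without reference
#'   counterparts.
#' @param n_clusters,cluster_members tandem clusters planted among the known
#'   miRNAs (the first cluster carries a duplicated family label).
#' @param stages,replicates,missing library structure; `missing` is a
#'   data.frame of (stage, replicate) pairs that were never sequenced.
#' @param depth_per_library reads per library.
#' @param mature_fraction,star_fraction,loop_fraction,decoy_fraction read
#'   class composition (must sum to 1).
#' @param short_fraction extra reads below 17 nt, as a fraction of total
#'   sequenced reads.
#' @param group_profiles named list of per-stage multipliers for the three
#'   expression groups.
#' @param fold_change_grid planted fold changes used by the group profiles.
#' @param dispersion negative-binomial dispersion of counts.
#' @param n_decoy_loci number of decoy degradation hotspots.
#' @param repeat_copies genomic copy number of the decoy repeat.
#' @param db_mutation_choices mutations applied to reference database entries
#'   (0 keeps a planted known miRNA `perfect`, 1 makes it `near_perfect`).
#' @param cross_rho target Spearman correlation between matched-stage
#'   expression of the two species.
#' @return a `mirstack_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 6L, scaffold_len = 88000L,
                       n_known_mirnas = 16L, n_novel_mirnas = 4L,
                       n_clusters = 2L, cluster_members = 4L,
                       stages = c("egg", "larva", "male_pupa", "female_pupa",
                                  "ovary"),
                       replicates = 3L,
                       missing = data.frame(stage = "female_pupa",
                                            replicate = 2L),
                       depth_per_library = 3000L,
                       mature_fraction = 0.75, star_fraction = 0.08,
                       loop_fraction = 0.02, decoy_fraction = 0.15,
                       short_fraction = 0.047,
                       group_profiles = list(
                         group1 = c(egg = 1, larva = 2, male_pupa = 4,
                                    female_pupa = 4, ovary = 2),
                         group2 = c(egg = 1, larva = 4, male_pupa = 0.5,
                                    female_pupa = 0.5, ovary = 1),
                         group3 = c(egg = 4, larva = 2, male_pupa = 0.25,
                                    female_pupa = 0.25, ovary = 4)),
                       fold_change_grid = c(4),
                       dispersion = 0.1,
                       n_decoy_loci = 30L,
                       repeat_copies = 6L,
                       db_mutation_choices = c(0L, 1L),
                       cross_rho = 0.8) {
  fr <- mature_fraction + star_fraction + loop_fraction + decoy_fraction
  if (abs(fr - 1) > 1e-9) stop("read-class fractions must sum to 1")
  stopifnot(n_scaffolds > 0L, scaffold_len > 0L, depth_per_library > 0L,
            replicates >= 1L, dispersion >= 0)
  structure(as.list(environment()), class = "mirstack_sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, n_mut) {
  if (n_mut == 0L) return(seq)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), n_mut)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

# A planted precursor: 22 nt mature arm + 15 nt loop + near-perfect
# reverse-complement star arm (2 mismatches). 59 nt total.
make_hairpin <- function() {
  mature <- random_dna(22L)
  loop <- random_dna(15L)
  star <- mutate_seq(revcomp(mature), 2L)
  list(mature = mature, loop = loop, star = star,
       precursor = paste0(mature, loop, star))
}

#' Simulate a genome with planted miRNA hairpins and annotation
#'
#' Background scaffolds are random sequence; each planted miRNA is a strong
#' fold-back (22 nt mature arm, 15 nt loop, near-reverse-complement star arm)
#' inserted at a recorded locus. A configurable number of tandem clusters is
#' planted on one strand within cluster spacing (the first with a duplicated
#' family label). Genes, exons and 3'UTRs are planted so that every
#' exon-overlap category occurs, and two UTRs carry perfect target sites for
#' planted matures. A decoy repeat is inserted at `repeat_copies` loci.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (DNAStringSet), `annotation` (exon/UTR
#'   data.frame), `truth` (per-miRNA locus/sequence/expression-group table),
#'   `repeat_seq`, and `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "mirstack_sim_config"))
  set.seed(config$seed)
  n_mir <- config$n_known_mirnas + config$n_novel_mirnas
  n_cluster_loci <- config$n_clusters * config$cluster_members
  if (n_cluster_loci > config$n_known_mirnas) {
    stop("more cluster members than known miRNAs")
  }
  scaff_names <- sprintf("scaffold%02d", seq_len(config$n_scaffolds))
  scaffs <- stats::setNames(
    vapply(seq_len(config$n_scaffolds),
           function(i) random_dna(config$scaffold_len), ""),
    scaff_names)

  hp <- replicate(n_mir, make_hairpin(), simplify = FALSE)
  plen <- 59L
  ids <- sprintf("sim-mir-%02d", seq_len(n_mir))
  novel <- c(rep(FALSE, config$n_known_mirnas),
             rep(TRUE, config$n_novel_mirnas))
  family <- sprintf("mir-%d", 100L + seq_len(n_mir))
  groups <- rep_len(1:3, n_mir)

  occupied <- stats::setNames(
    rep(list(data.frame(start = integer(0), end = integer(0))), length(scaffs)),
    scaff_names)
  place <- function(sc, pos, len) {
    occ <- occupied[[sc]]
    ok <- pos >= 1L && pos + len - 1L <= nchar(scaffs[[sc]]) &&
      !any(occ$start <= pos + len + 200L & occ$end >= pos - 200L)
    if (ok) {
      occupied[[sc]] <<- rbind(occ, data.frame(start = pos,
                                               end = pos + len - 1L))
    }
    ok
  }

  # unrelated read-producing loci live in slots spaced wider than the 10 kb
  # tandem-cluster gap: in a real genome miRNA loci are ~1 Mb apart, and at
  # toy scale everything on one strand of one scaffold would otherwise chain
  # into one spurious "cluster"
  slot_gap <- 11500L
  slots <- do.call(rbind, lapply(scaff_names, function(sc) {
    starts <- seq(1000L, config$scaffold_len - 4000L, by = slot_gap)
    data.frame(scaffold = sc, start = starts, stringsAsFactors = FALSE)
  }))
  slots <- slots[sample.int(nrow(slots)), , drop = FALSE]
  slot_i <- 0L
  next_slot <- function() {
    slot_i <<- slot_i + 1L
    if (slot_i > nrow(slots)) {
      stop("genome too small for the requested loci: increase scaffold_len ",
           "or n_scaffolds")
    }
    slots[slot_i, ]
  }

  truth <- data.frame(id = ids, family = family, scaffold = NA_character_,
                      start = NA_integer_, end = NA_integer_,
                      strand = NA_character_, mature_seq = NA_character_,
                      star_seq = NA_character_, precursor_seq = NA_character_,
                      mature_start = NA_integer_, mature_end = NA_integer_,
                      novel = novel, cluster_id = NA_character_,
                      group = groups, base_weight = NA_real_,
                      stringsAsFactors = FALSE)

  # tandem clusters first (known miRNAs, one strand, tight spacing inside
  # one slot)
  idx <- 1L
  for (cl in seq_len(config$n_clusters)) {
    sl <- next_slot()
    sc <- sl$scaffold
    strand <- "+"
    pos <- sl$start
    for (m in seq_len(config$cluster_members)) {
      while (!place(sc, pos, plen)) pos <- pos + 100L
      truth$scaffold[idx] <- sc; truth$start[idx] <- pos
      truth$end[idx] <- pos + plen - 1L; truth$strand[idx] <- strand
      truth$cluster_id[idx] <- sprintf("true-cluster-%d", cl)
      pos <- pos + plen + sample(150:300, 1L)
      idx <- idx + 1L
    }
    if (cl == 1L && config$cluster_members >= 2L) {
      # duplicated family inside the first cluster (mir-309-6 style)
      first <- idx - config$cluster_members
      truth$family[idx - 1L] <- truth$family[first]
    }
  }
  # remaining miRNAs at scattered slots, random strand
  for (i in seq_len(n_mir)[seq_len(n_mir) >= idx]) {
    repeat {
      sl <- next_slot()
      pos <- sl$start + sample(0:1000, 1L)
      if (place(sl$scaffold, pos, plen)) break
    }
    truth$scaffold[i] <- sl$scaffold; truth$start[i] <- pos
    truth$end[i] <- pos + plen - 1L
    truth$strand[i] <- sample(c("+", "-"), 1L)
  }

  # write hairpins into the scaffolds and record sequences/coordinates
  for (i in seq_len(n_mir)) {
    h <- hp[[i]]
    ins <- if (truth$strand[i] == "+") h$precursor else revcomp(h$precursor)
    sc <- truth$scaffold[i]; s <- truth$start[i]
    scaffs[[sc]] <- paste0(substr(scaffs[[sc]], 1L, s - 1L), ins,
                           substr(scaffs[[sc]], s + plen,
                                  nchar(scaffs[[sc]])))
    truth$mature_seq[i] <- h$mature
    truth$star_seq[i] <- h$star
    truth$precursor_seq[i] <- h$precursor
    if (truth$strand[i] == "+") {
      truth$mature_start[i] <- s
      truth$mature_end[i] <- s + 21L
    } else {
      truth$mature_start[i] <- s + plen - 22L
      truth$mature_end[i] <- s + plen - 1L
    }
  }

  # decoy degradation loci: a limited set of abundant non-miRNA positions
  # (mimicking tRNA/rRNA fragment hotspots), so decoy reads pile into
  # single-block stacks instead of tiling the genome
  n_decoy_loci <- config$n_decoy_loci
  decoy_loci <- data.frame(scaffold = character(n_decoy_loci),
                           start = integer(n_decoy_loci),
                           weight = stats::rlnorm(n_decoy_loci, 0, 1),
                           stringsAsFactors = FALSE)
  dplaced <- 0L
  while (dplaced < n_decoy_loci) {
    sl <- next_slot()
    pos <- sl$start + sample(0:1000, 1L)
    if (place(sl$scaffold, pos, 30L)) {
      dplaced <- dplaced + 1L
      decoy_loci$scaffold[dplaced] <- sl$scaffold
      decoy_loci$start[dplaced] <- pos
    }
  }

  # decoy repeat at repeat_copies loci
  repeat_seq <- random_dna(22L)
  placed <- 0L
  while (placed < config$repeat_copies) {
    sc <- sample(scaff_names, 1L)
    pos <- sample(200:(config$scaffold_len - 250L), 1L)
    if (place(sc, pos, 22L)) {
      scaffs[[sc]] <- paste0(substr(scaffs[[sc]], 1L, pos - 1L), repeat_seq,
                             substr(scaffs[[sc]], pos + 22L,
                                    nchar(scaffs[[sc]])))
      placed <- placed + 1L
    }
  }

  # annotation: one gene per exon-overlap category, anchored on planted
  # hairpins, plus UTR-bearing genes with perfect target sites
  ann <- list()
  add_feat <- function(sc, s, e, strand, gid, feat) {
    ann[[length(ann) + 1L]] <<- data.frame(scaffold = sc, start = s, end = e,
                                           strand = strand, gene_id = gid,
                                           feature = feat,
                                           stringsAsFactors = FALSE)
  }
  anchor <- utils::head(which(!truth$novel & is.na(truth$cluster_id)), 3L)
  if (length(anchor) >= 1L) {  # hairpin within exon
    i <- anchor[1]
    add_feat(truth$scaffold[i], truth$start[i] - 40L, truth$end[i] + 40L,
             "+", "gene_within", "exon")
  }
  if (length(anchor) >= 2L) {  # exon contained in the hairpin region
    i <- anchor[2]
    add_feat(truth$scaffold[i], truth$start[i] + 10L, truth$start[i] + 30L,
             "+", "gene_contained", "exon")
  }
  if (length(anchor) >= 3L) {  # exon overlapping the hairpin start
    i <- anchor[3]
    add_feat(truth$scaffold[i], truth$start[i] - 30L, truth$start[i] + 10L,
             "+", "gene_boundary", "exon")
  }
  # an intron-hosted case: two exons flanking the last scattered miRNA
  free <- which(!truth$novel & is.na(truth$cluster_id))
  if (length(free) >= 4L) {
    i <- free[4]
    add_feat(truth$scaffold[i], truth$start[i] - 200L, truth$start[i] - 100L,
             "+", "gene_intron", "exon")
    add_feat(truth$scaffold[i], truth$end[i] + 100L, truth$end[i] + 200L,
             "+", "gene_intron", "exon")
  }
  # UTR genes carrying perfect complements of two planted matures
  utr_targets <- utils::head(which(!truth$novel), 2L)
  for (k in seq_along(utr_targets)) {
    i <- utr_targets[k]
    site <- revcomp(truth$mature_seq[i])
    repeat {
      sl <- next_slot()
      s <- sl$start + sample(0:1000, 1L)
      if (place(sl$scaffold, s, 151L)) break
    }
    utr_sc <- sl$scaffold
    scaffs[[utr_sc]] <- paste0(substr(scaffs[[utr_sc]], 1L, s + 59L),
                               site,
                               substr(scaffs[[utr_sc]], s + 60L + nchar(site),
                                      nchar(scaffs[[utr_sc]])))
    add_feat(utr_sc, s, s + 150L, "+", sprintf("gene_utr_%d", k),
             "three_prime_UTR")
  }
  annotation <- do.call(rbind, ann)
  rownames(annotation) <- NULL
  # continuous (lognormal) baseline expression: real miRNA abundances span
  # orders of magnitude without ties
  truth$base_weight <- stats::rlnorm(n_mir, meanlog = log(5), sdlog = 1)

  list(genome = Biostrings::DNAStringSet(scaffs), annotation = annotation,
       truth = truth, repeat_seq = repeat_seq, decoy_loci = decoy_loci,
       config = config)
}

#' Sample sheet implied by a simulation configuration
#'
#' @param config a [sim_config()].
#' @return data.frame `library_id, stage, replicate, path` (path empty).
#' @export
sim_sample_sheet <- function(config) {
  ss <- expand.grid(replicate = seq_len(config$replicates),
                    stage = config$stages, stringsAsFactors = FALSE)
  ss <- ss[, c("stage", "replicate")]
  if (nrow(config$missing)) {
    drop <- paste(ss$stage, ss$replicate) %in%
      paste(config$missing$stage, config$missing$replicate)
    ss <- ss[!drop, , drop = FALSE]
  }
  ss$library_id <- sprintf("%s_r%d", ss$stage, ss$replicate)
  ss$path <- ""
  rownames(ss) <- NULL
  ss[c("library_id", "stage", "replicate", "path")]
}

# Expected per-stage read weight of each miRNA (unnormalized).
stage_weights <- function(truth, config) {
  prof <- config$group_profiles
  sapply(config$stages, function(st) {
    mult <- vapply(truth$group, function(g) prof[[g]][[st]], 1)
    truth$base_weight * mult
  })
}

#' Simulate stage-structured small-RNA libraries
#'
#' Per library, mature read counts are negative-binomial draws around
#' stage-profile means; star and loop reads follow the configured class
#' fractions; decoys are random genomic fragments plus copies of the planted
#' multi-copy repeat; an additional `short_fraction` of reads falls below
#' 17 nt. Mature reads carry a +/- 1 nt 3' end wobble. The observed mature
#' count matrix and the expected cpm matrix (the simulation truth) are
#' returned alongside the reads.
#'
#' @param sim result of [simulate_genome()].
#' @param config the same [sim_config()].
#' @param reads materialize read sequences? (`FALSE` returns counts only,
#'   for count-level experiments at depths where reads are not needed.)
#' @return list `sample_sheet, reads, counts, expected_cpm, truth`.
#' @export
simulate_libraries <- function(sim, config = sim$config, reads = TRUE) {
  set.seed(config$seed + 1L)
  truth <- sim$truth
  ss <- sim_sample_sheet(config)
  w <- stage_weights(truth, config)   # miRNA x stage
  n_mir <- nrow(truth)
  counts <- matrix(0L, n_mir, nrow(ss),
                   dimnames = list(truth$id, ss$library_id))
  expected_cpm <- matrix(0, n_mir, nrow(ss),
                         dimnames = list(truth$id, ss$library_id))
  reads_out <- if (reads) stats::setNames(vector("list", nrow(ss)),
                                          ss$library_id) else NULL
  depth <- config$depth_per_library
  n_mature_target <- depth * config$mature_fraction
  size <- if (config$dispersion > 0) 1 / config$dispersion else Inf

  genome_chr <- stats::setNames(as.character(sim$genome), names(sim$genome))

  for (li in seq_len(nrow(ss))) {
    st <- ss$stage[li]
    mu <- n_mature_target * w[, st] / sum(w[, st])
    expected_cpm[, li] <- mu / sum(mu) * 1e6
    cnt <- if (is.finite(size)) {
      rnbinom(n_mir, mu = mu, size = size)
    } else {
      rpois(n_mir, mu)
    }
    counts[, li] <- as.integer(cnt)
    if (!reads) next
    lib_reads <- character(0)
    for (i in seq_len(n_mir)) {
      if (cnt[i] == 0L) next
      pre <- truth$precursor_seq[i]
      # mature reads with 3' end wobble: -1, 0, +1 nt
      wob <- sample(c(-1L, 0L, 1L), cnt[i], replace = TRUE,
                    prob = c(0.15, 0.7, 0.15))
      mr <- substring(pre, 1L, 22L + wob)
      n_star <- rpois(1L, cnt[i] * config$star_fraction /
                        config$mature_fraction)
      n_loop <- rpois(1L, cnt[i] * config$loop_fraction /
                        config$mature_fraction)
      sr <- rep(substr(pre, 38L, 59L), n_star)
      lr <- rep(substr(pre, 20L, 40L), n_loop)
      lib_reads <- c(lib_reads, mr, sr, lr)
    }
    n_decoy <- round(depth * config$decoy_fraction)
    n_rep_reads <- min(30L, n_decoy %/% 3L)
    # scatter is kept sparse: genome-wide uniform unique-read coverage would
    # chain read stacks across whole scaffolds at toy genome scale, which
    # real small-RNA background (hotspot-concentrated degradation) does not
    n_scatter <- round(0.05 * (n_decoy - n_rep_reads))
    n_hotspot <- n_decoy - n_rep_reads - n_scatter
    if (n_hotspot > 0L) {  # degradation-hotspot reads with slight end jitter
      dl <- sim$decoy_loci
      li_loc <- sample(nrow(dl), n_hotspot, replace = TRUE,
                       prob = dl$weight)
      dpos <- dl$start[li_loc] + sample(-2:2, n_hotspot, replace = TRUE)
      dlen <- sample(20:24, n_hotspot, replace = TRUE)
      lib_reads <- c(lib_reads,
                     substring(genome_chr[dl$scaffold[li_loc]], dpos,
                               dpos + dlen - 1L))
    }
    if (n_scatter > 0L) {  # uniform low-level genomic scatter
      dsc <- sample(names(genome_chr), n_scatter, replace = TRUE)
      dlen <- sample(17:28, n_scatter, replace = TRUE)
      dpos <- vapply(seq_along(dsc), function(k) {
        sample.int(nchar(genome_chr[[dsc[k]]]) - dlen[k], 1L)
      }, 1L)
      lib_reads <- c(lib_reads,
                     substring(genome_chr[dsc], dpos, dpos + dlen - 1L))
    }
    lib_reads <- c(lib_reads, rep(sim$repeat_seq, n_rep_reads))
    n_short <- round(length(lib_reads) / (1 - config$short_fraction) *
                       config$short_fraction)
    if (n_short > 0L) {
      lib_reads <- c(lib_reads,
                     vapply(sample(10:16, n_short, replace = TRUE),
                            random_dna, ""))
    }
    reads_out[[ss$library_id[li]]] <- sample(lib_reads)
  }
  list(sample_sheet = ss, reads = reads_out, counts = counts,
       expected_cpm = expected_cpm, truth = truth)
}

#' Build reference databases and a second-species expression table
#'
#' Known planted miRNAs are emitted into a miRBase-style mature/hairpin
#' reference with 0--2 mutations (0 keeps the planted entry a perfect match,
#' 1 exercises the near-perfect class); novel planted miRNAs are omitted. A
#' pseudo-species expression table is generated with per-stage profiles
#' rank-correlated with the simulation's expected expression at the
#' configured target Spearman rho (via a Gaussian copula).
#'
#' @param sim result of [simulate_genome()].
#' @param config the same [sim_config()].
#' @return list `mature_db, hairpin_db` (named vectors), `expected_label`
#'   (per planted miRNA: known/iso/novel_candidate), `orthologs`
#'   (`species_a_id` = planted id, `species_b_id` = reference id), `expr_b`
#'   (reference-species cpm-scale matrix, miRNA x stage).
#' @export
make_reference_dbs <- function(sim, config = sim$config) {
  set.seed(config$seed + 2L)
  truth <- sim$truth
  known <- truth[!truth$novel, , drop = FALSE]
  n <- nrow(known)
  muts <- sample(config$db_mutation_choices, n, replace = TRUE)
  ref_ids <- sprintf("ref-%s", known$id)
  mature_db <- stats::setNames(
    vapply(seq_len(n), function(i) mutate_seq(known$mature_seq[i], muts[i]),
           ""), ref_ids)
  # reference hairpins carry ~15 nt of genomic flank, as miRBase hairpin
  # entries typically extend beyond the fold-back itself
  genome_chr <- stats::setNames(as.character(sim$genome), names(sim$genome))
  hairpin_db <- stats::setNames(
    vapply(seq_len(n), function(i) {
      sc <- known$scaffold[i]
      s <- max(1L, known$start[i] - 15L)
      e <- min(nchar(genome_chr[[sc]]), known$end[i] + 15L)
      h <- substr(genome_chr[[sc]], s, e)
      if (known$strand[i] == "-") h <- revcomp(h)
      mutate_seq(h, muts[i])
    }, ""), ref_ids)
  expected_label <- stats::setNames(
    ifelse(truth$novel, "novel_candidate",
           ifelse(truth$id %in% known$id[muts == 0L], "known", "iso")),
    truth$id)
  orthologs <- data.frame(species_a_id = known$id, species_b_id = ref_ids,
                          stringsAsFactors = FALSE)

  # second-species stage profiles, rank-correlated at cross_rho via a
  # Gaussian copula: Spearman rho_s of a bivariate normal with Pearson r is
  # (6/pi) asin(r/2), so invert for the target
  r <- 2 * sin(pi * config$cross_rho / 6)
  w <- stage_weights(known, config)
  la <- scale(log(w))   # per-stage standardized log expression
  expr_b <- matrix(0, n, length(config$stages),
                   dimnames = list(ref_ids, config$stages))
  for (j in seq_len(ncol(w))) {
    z <- r * la[, j] + sqrt(1 - r^2) * stats::rnorm(n)
    expr_b[, j] <- 10^(2 + z)  # arbitrary positive cpm-like scale
  }
  list(mature_db = mature_db, hairpin_db = hairpin_db,
       expected_label = expected_label, orthologs = orthologs,
       expr_b = expr_b)
}
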