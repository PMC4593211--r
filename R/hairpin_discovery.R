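#' Fold a sequence into its maximum-weight hairpin structure
#'
#' A Nussinov-style maximum-weight, pseudoknot-free pairing with pair weights
#' GC = 3, AU = 2, GU = 1 and a minimum hairpin loop of 3 unpaired bases. This
#' is a deliberately simple stand-in for a thermodynamic MFE model, so the
#' stability value is unit-free: `mfe_proxy = -(total pair weight)`, more
#' negative meaning more stable. N (or any non-ACGU character) is unpairable.
#'
#' @param seq RNA or DNA sequence (single string).
#' @param warn warn when the length is outside the 40--200 nt precursor range
#'   (the candidate path sets this).
#' @return list with `structure` (dot-bracket, same length as `seq`),
#'   `mfe_proxy` and `score` (= `-mfe_proxy`).
#' @export
fold <- function(seq, warn = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (warn && (nchar(seq) < 40L || nchar(seq) > 200L)) {
    warning("sequence length ", nchar(seq),
            " outside the typical precursor range 40-200 nt")
  }
  res <- nussinov_fold_cpp(seq, 3L)
  list(structure = res$structure, mfe_proxy = -res$score, score = res$score)
}

#' Dinucleotide-preserving shuffle of a sequence
#'
#' Altschul--Erickson Eulerian-path shuffle: the shuffled sequence has exactly
#' the original dinucleotide composition (and hence mononucleotide
#' composition, first and last base).
#'
#' @param seq a single sequence string.
#' @return a shuffled sequence of identical dinucleotide composition.
#' @export
dinucleotide_shuffle <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  if (n < 3L) return(seq)
  verts <- unique(ch)
  sn <- ch[n]
  out <- split(ch[-1L], factor(ch[-n], levels = verts))
  for (attempt in 1:1000) {
    # choose a random "last exit" edge per vertex (except the end vertex)
    last <- stats::setNames(rep(NA_character_, length(verts)), verts)
    for (v in verts) {
      if (v == sn) next
      es <- out[[v]]
      if (length(es)) last[v] <- es[sample.int(length(es), 1L)]
    }
    # the last-exit edges must lead every vertex to the end vertex
    connected <- TRUE
    for (v in verts) {
      if (v == sn || is.na(last[v])) next
      cur <- v; seen <- character(0); reached <- FALSE
      repeat {
        if (cur == sn) { reached <- TRUE; break }
        if (cur %in% seen || is.na(last[cur])) break
        seen <- c(seen, cur); cur <- last[[cur]]
      }
      if (!reached) { connected <- FALSE; break }
    }
    if (!connected) next
    adj <- list()
    for (v in verts) {
      es <- out[[v]]
      if (!length(es)) { adj[[v]] <- character(0); next }
      if (v != sn && !is.na(last[v])) {
        idx <- which(es == last[v])[1L]
        rest <- es[-idx]
        adj[[v]] <- c(if (length(rest) > 1L) sample(rest) else rest, last[[v]])
      } else {
        adj[[v]] <- if (length(es) > 1L) sample(es) else es
      }
    }
    res <- character(n)
    res[1L] <- ch[1L]
    cur <- ch[1L]
    ptr <- stats::setNames(rep(1L, length(verts)), verts)
    good <- TRUE
    for (i in 2:n) {
      es <- adj[[cur]]
      if (ptr[[cur]] > length(es)) { good <- FALSE; break }
      nx <- es[ptr[[cur]]]
      ptr[cur] <- ptr[[cur]] + 1L
      res[i] <- nx
      cur <- nx
    }
    if (good) return(paste(res, collapse = ""))
  }
  seq
}

#' Randomization p-value for fold stability
#'
#' Compares the observed fold stability against `n_shuffles`
#' dinucleotide-preserving shuffles:
#' `p = (1 + #\{shuffled mfe_proxy <= observed\}) / (n_shuffles + 1)`.
#' Sequences shorter than 10 nt cannot be meaningfully shuffled and return 1.
#'
#' @param seq sequence string.
#' @param n_shuffles number of shuffles (>= 19; default 99).
#' @param seed optional integer seed for reproducibility (caller RNG state is
#'   restored afterwards).
#' @return p-value in (0, 1].
#' @export
shuffle_p_value <- function(seq, n_shuffles = 99L, seed = NULL) {
  stopifnot(n_shuffles >= 19L)
  if (nchar(seq) < 10L) return(1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  obs <- fold(seq)$mfe_proxy
  hits <- 0L
  for (i in seq_len(n_shuffles)) {
    if (fold(dinucleotide_shuffle(seq))$mfe_proxy <= obs) hits <- hits + 1L
  }
  (1 + hits) / (n_shuffles + 1)
}

#' Excise candidate precursor windows from read stacks
#'
#' Maximal sets of overlapping same-strand alignments form read stacks; each
#' stack with a summed count of at least `min_stack` yields two candidate
#' windows: the stack as prospective 5' arm (flank added downstream in
#' transcript orientation) and as prospective 3' arm (flank added upstream).
#' Windows are clipped at scaffold ends and deduplicated; the result is
#' independent of alignment input order.
#'
#' @param alignments data.frame from [map_collapsed_reads()].
#' @param genome named scaffold sequences (for clipping).
#' @param collapsed optional collapsed-read frame supplying `total_count` per
#'   sequence; if absent each alignment counts 1.
#' @param min_stack minimum summed stack count (default 5).
#' @param flank_up,flank_down flank lengths in nt (default 70, the typical
#'   metazoan precursor scale).
#' @return data.frame `scaffold, start, end, strand, stack_start, stack_end,
#'   stack_count`.
#' @export
excise_candidates <- function(alignments, genome, collapsed = NULL,
                              min_stack = 5L, flank_up = 70L,
                              flank_down = 70L) {
  if (nrow(alignments) == 0L) {
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stack_start = integer(0), stack_end = integer(0),
                      stack_count = integer(0)))
  }
  cnt <- if (is.null(collapsed)) rep(1L, nrow(alignments)) else {
    collapsed$total_count[match(alignments$sequence, collapsed$sequence)]
  }
  cnt[is.na(cnt)] <- 1L
  a <- data.frame(scaffold = alignments$scaffold, start = alignments$start,
                  end = alignments$start + nchar(alignments$sequence) - 1L,
                  strand = alignments$strand, count = cnt,
                  stringsAsFactors = FALSE)
  lens <- stats::setNames(vapply(as.character(genome), nchar, 1L),
                          names(genome))
  out <- list()
  for (key in unique(paste(a$scaffold, a$strand))) {
    sub <- a[paste(a$scaffold, a$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    sc <- sub$scaffold[1]; strand <- sub$strand[1]
    slen <- lens[[sc]]
    # merge overlapping intervals into maximal stacks
    cur_s <- sub$start[1]; cur_e <- sub$end[1]; cur_c <- sub$count[1]
    stacks <- list()
    if (nrow(sub) > 1L) for (i in 2:nrow(sub)) {
      if (sub$start[i] <= cur_e) {
        cur_e <- max(cur_e, sub$end[i]); cur_c <- cur_c + sub$count[i]
      } else {
        stacks <- c(stacks, list(c(cur_s, cur_e, cur_c)))
        cur_s <- sub$start[i]; cur_e <- sub$end[i]; cur_c <- sub$count[i]
      }
    }
    stacks <- c(stacks, list(c(cur_s, cur_e, cur_c)))
    for (st in stacks) {
      if (st[3] < min_stack) next
      if (strand == "+") {
        wins <- rbind(c(st[1], min(slen, st[2] + flank_down)),
                      c(max(1L, st[1] - flank_up), st[2]))
      } else {  # transcript 5'->3' runs right-to-left on the genome
        wins <- rbind(c(max(1L, st[1] - flank_down), st[2]),
                      c(st[1], min(slen, st[2] + flank_up)))
      }
      for (r in 1:2) {
        out <- c(out, list(data.frame(
          scaffold = sc, start = as.integer(wins[r, 1]),
          end = as.integer(wins[r, 2]), strand = strand,
          stack_start = as.integer(st[1]), stack_end = as.integer(st[2]),
          stack_count = as.integer(st[3]), stringsAsFactors = FALSE)))
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stack_start = integer(0), stack_end = integer(0),
                      stack_count = integer(0)))
  }
  res <- unique(do.call(rbind, out))
  res <- res[order(res$scaffold, res$start, res$end, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Score a hairpin candidate
#'
#' Additive log-odds-style surrogate for a discovery score: mature-arm read
#' dominance over loop/other reads (capped, so sheer abundance alone cannot
#' carry a candidate), a bonus for observed star reads, a stability bonus when
#' the shuffle test is significant and an equal penalty when it is not, and a
#' penalty when the mature block does not lie cleanly on one arm. The
#' downstream thresholds (drop at <= -50, report at > 2) are meaningful knobs
#' on this scale: an abundant single-block stack without a significant fold
#' tops out at `dominance_cap - stability_bonus <= 2`.
#'
#' @param mature_count,star_count,loop_count,other_count read-class counts.
#' @param shuffle_p shuffle-test p-value.
#' @param mature_on_arm is the mature block fully on one arm of the hairpin?
#' @param star_bonus,stability_bonus,malformed_penalty,dominance_cap score
#'   components.
#' @return numeric score.
#' @export
score_candidate <- function(mature_count, star_count, loop_count, other_count,
                            shuffle_p, mature_on_arm = TRUE,
                            star_bonus = 2, stability_bonus = 3,
                            malformed_penalty = -12, dominance_cap = 4) {
  min(log2((mature_count + 1) / (loop_count + other_count + 1)),
      dominance_cap) +
    star_bonus * (star_count > 0) +
    stability_bonus * (shuffle_p <= 0.05) -
    stability_bonus * (shuffle_p > 0.05) +
    malformed_penalty * (!mature_on_arm)
}

# Locate the main hairpin loop of a dot-bracket structure: the innermost pair
# around the last '('. Returns c(arm5_end, arm3_start) in sequence coords, or
# NULL when the structure has no pairs.
hairpin_loop_bounds <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  opens <- which(ch == "(")
  if (length(opens) == 0L) return(NULL)
  i <- max(opens)
  closes <- which(ch == ")")
  j <- min(closes[closes > i])
  c(i, j)
}

#' Assemble, fold, test and score hairpin candidates
#'
#' For every excised window: the precursor sequence is taken in transcript
#' orientation, folded, and shuffle-tested; window-local reads are assigned to
#' mature (the most abundant read's block), star (most abundant block on the
#' opposite arm), loop and other classes; the candidate is scored. Candidates
#' scoring at or below `min_score` are dropped from the list entirely;
#' `reported` flags those above `report_score`.
#'
#' @param windows data.frame from [excise_candidates()].
#' @param alignments data.frame from [map_collapsed_reads()].
#' @param collapsed collapsed-read frame supplying `total_count` per sequence.
#' @param genome named scaffold sequences.
#' @param n_shuffles shuffles for the stability test (default 99).
#' @param seed integer seed for the shuffle test.
#' @param min_score hard drop threshold (default -50).
#' @param report_score reporting threshold (default 2).
#' @param min_precursor,max_precursor window length bounds (default 40--250
#'   nt); windows outside the precursor scale are skipped, which also guards
#'   the cubic fold against degenerate multi-kilobase stacks.
#' @return data.frame of candidates (coordinates, sequences as RNA, structure,
#'   counts, `score`, `shuffle_p`, `reported`, mature genomic coordinates).
#'   Windows describing the same mature locus are deduplicated, keeping the
#'   best-scoring one.
#' @export
hairpin_candidates <- function(windows, alignments, collapsed, genome,
                               n_shuffles = 99L, seed = 1L,
                               min_score = -50, report_score = 2,
                               min_precursor = 40L, max_precursor = 250L) {
  seqs <- stats::setNames(as.character(genome), names(genome))
  cnt_of <- function(s) {
    i <- match(s, collapsed$sequence)
    ifelse(is.na(i), 1L, collapsed$total_count[i])
  }
  aend <- alignments$start + nchar(alignments$sequence) - 1L

  evaluate_window <- function(sc, ws, we, strand, shuffle_seed,
                              do_shuffle = TRUE) {
    gseq <- substr(seqs[[sc]], ws, we)
    pre <- if (strand == "+") gseq else revcomp(gseq)
    fr <- fold(pre, warn = FALSE)
    lb <- hairpin_loop_bounds(fr$structure)
    sel <- alignments$scaffold == sc & alignments$strand == strand &
      alignments$start <= we & aend >= ws
    rd <- alignments[sel, , drop = FALSE]
    mature_seq <- star_seq <- loop_seq <- NA_character_
    mature_count <- star_count <- loop_count <- other_count <- 0L
    mature_on_arm <- FALSE
    m_gs <- m_ge <- s_gs <- s_ge <- NA_integer_
    if (nrow(rd)) {
      rd$count <- cnt_of(rd$sequence)
      rd$gend <- rd$start + nchar(rd$sequence) - 1L
      if (strand == "+") {
        rd$p1 <- rd$start - ws + 1L; rd$p2 <- rd$gend - ws + 1L
      } else {
        rd$p1 <- we - rd$gend + 1L; rd$p2 <- we - rd$start + 1L
      }
      rd <- rd[order(-rd$count, rd$sequence), , drop = FALSE]
      mat <- rd[1, ]
      mature_seq <- mat$sequence
      m_gs <- mat$start; m_ge <- mat$gend
      in_mature <- rd$p1 <= mat$p2 & rd$p2 >= mat$p1
      mature_count <- sum(rd$count[in_mature])
      if (!is.null(lb)) {
        arm_of <- function(p1, p2) {
          ifelse(p2 <= lb[1], "5p", ifelse(p1 >= lb[2], "3p", "loop"))
        }
        m_arm <- arm_of(mat$p1, mat$p2)
        mature_on_arm <- m_arm %in% c("5p", "3p")
        rest <- rd[!in_mature, , drop = FALSE]
        if (nrow(rest)) {
          rest$arm <- arm_of(rest$p1, rest$p2)
          opp <- if (m_arm == "5p") "3p" else if (m_arm == "3p") "5p" else ""
          star_cand <- rest[rest$arm == opp, , drop = FALSE]
          if (nrow(star_cand)) {
            sb <- star_cand[1, ]
            star_seq <- sb$sequence
            s_gs <- sb$start; s_ge <- sb$gend
            in_star <- rest$p1 <= sb$p2 & rest$p2 >= sb$p1 & rest$arm == opp
            star_count <- sum(rest$count[in_star])
            rest <- rest[!in_star, , drop = FALSE]
          }
          if (nrow(rest)) {
            in_loop <- rest$p1 <= (lb[2] - 1L) & rest$p2 >= (lb[1] + 1L)
            loop_count <- sum(rest$count[in_loop])
            other_count <- sum(rest$count[!in_loop])
          }
        }
        loop_seq <- substr(pre, lb[1] + 1L, lb[2] - 1L)
      } else {
        other_count <- sum(rd$count[!in_mature])
      }
    }
    # the shuffle test is the expensive part and must be run once per locus
    # (not once per extent trial, which would inflate its false-positive
    # rate by selection): trials are compared on the shuffle-free score and
    # only the selected extent is tested, when a significant fold could
    # lift it above the reporting threshold
    potential <- score_candidate(mature_count, star_count, loop_count,
                                 other_count, 0, mature_on_arm)
    p <- if (do_shuffle && potential > report_score) {
      shuffle_p_value(pre, n_shuffles = n_shuffles, seed = shuffle_seed)
    } else {
      1
    }
    score <- score_candidate(mature_count, star_count, loop_count,
                             other_count, p, mature_on_arm)
    list(row = data.frame(
      scaffold = sc, start = ws, end = we, strand = strand,
      precursor_seq = as_rna(pre), structure = fr$structure,
      mfe_proxy = fr$mfe_proxy,
      mature_seq = if (is.na(mature_seq)) NA_character_ else as_rna(mature_seq),
      star_seq = if (is.na(star_seq)) NA_character_ else as_rna(star_seq),
      loop_seq = if (is.na(loop_seq)) NA_character_ else as_rna(loop_seq),
      mature_count = mature_count, star_count = star_count,
      loop_count = loop_count, other_count = other_count,
      score = score, shuffle_p = p,
      mature_start = m_gs, mature_end = m_ge,
      reported = score > report_score,
      stringsAsFactors = FALSE),
      star_start = s_gs, star_end = s_ge)
  }

  # each window is evaluated at several stack-anchored precursor lengths and
  # the best-scoring trial is kept: a maximum-weight pairing fold cannot
  # discount unpaired flanking junk the way a thermodynamic model does, so
  # the precursor extent itself is searched
  flank_trials <- c(3L, 25L, 40L, 55L, 70L)
  rows <- list()
  for (w in seq_len(nrow(windows))) {
    sc <- windows$scaffold[w]; ws <- windows$start[w]; we <- windows$end[w]
    strand <- windows$strand[w]
    if (we - ws + 1L < min_precursor || we - ws + 1L > max_precursor) next
    ss <- windows$stack_start[w]; se <- windows$stack_end[w]
    trials <- if (!is.null(ss) && !is.na(ss) && ws == ss && we > se) {
      lapply(flank_trials, function(f) c(ss, min(we, se + f)))
    } else if (!is.null(ss) && !is.na(ss) && we == se && ws < ss) {
      lapply(flank_trials, function(f) c(max(ws, ss - f), se))
    } else {
      list(c(ws, we))
    }
    best <- NULL
    for (tr in unique(trials)) {
      if (tr[2] - tr[1] + 1L < min_precursor) next
      ev <- evaluate_window(sc, tr[1], tr[2], strand, seed + w,
                            do_shuffle = FALSE)
      if (is.null(best) || ev$row$score > best$row$score) {
        best <- ev
        best_tr <- tr
      }
    }
    if (is.null(best)) next
    best <- evaluate_window(sc, best_tr[1], best_tr[2], strand, seed + w)
    if (best$row$score <= min_score) next
    rows <- c(rows, list(best$row))
  }
  if (length(rows) == 0L) {
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      precursor_seq = character(0), structure = character(0),
                      mfe_proxy = numeric(0), mature_seq = character(0),
                      star_seq = character(0), loop_seq = character(0),
                      mature_count = integer(0), star_count = integer(0),
                      loop_count = integer(0), other_count = integer(0),
                      score = numeric(0), shuffle_p = numeric(0),
                      mature_start = integer(0), mature_end = integer(0),
                      reported = logical(0)))
  }
  res <- do.call(rbind, rows)
  # one candidate per mature locus: keep the best-scoring window
  key <- paste(res$scaffold, res$strand, res$mature_start, res$mature_end)
  res <- res[order(key, -res$score), , drop = FALSE]
  res <- res[!duplicated(paste(res$scaffold, res$strand, res$mature_start,
                               res$mature_end)), , drop = FALSE]
  # one candidate per precursor: the two arms of a hairpin are each found as
  # a "mature" stack; overlapping same-strand precursors are merged, keeping
  # the best-scoring representative
  res <- res[order(res$scaffold, res$strand, res$start, res$end), ,
             drop = FALSE]
  grp <- integer(nrow(res)); g <- 0L; last_end <- -1L; last_key <- ""
  for (i in seq_len(nrow(res))) {
    k <- paste(res$scaffold[i], res$strand[i])
    if (k != last_key || res$start[i] > last_end) {
      g <- g + 1L
      last_end <- res$end[i]
    } else {
      last_end <- max(last_end, res$end[i])
    }
    last_key <- k
    grp[i] <- g
  }
  best_in_grp <- unlist(lapply(split(seq_len(nrow(res)), grp), function(ix) {
    ix[order(-res$score[ix], res$start[ix])][1]
  }), use.names = FALSE)
  res <- res[sort(best_in_grp), , drop = FALSE]
  res <- res[order(res$scaffold, res$start, res$end, res$strand), ,
             drop = FALSE]
  res$id <- sprintf("cand-%03d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[c("id", setdiff(names(res), "id"))]
}

#' Classify a hairpin's relation to annotated exons
#'
#' Pure interval arithmetic on one scaffold, ignoring exon strand: the hairpin
#' contained in an exon is `within_exon`; an exon contained in the hairpin is
#' `contains_exon`; a partial overlap crossing an exon boundary is
#' `overlaps_exon_boundary`; inside a gene span (range of that gene's exons)
#' without touching an exon is `intronic`; anything else is `intergenic`.
#'
#' @param scaffold,start,end hairpin interval (1-based inclusive).
#' @param exons data.frame from [read_annotation()] (feature `exon` rows are
#'   used for gene spans; all requested features are tested for overlap).
#' @return list with `category` and `gene_id` (NA for intergenic).
#' @export
classify_exon_overlap <- function(scaffold, start, end, exons) {
  ex <- exons[exons$scaffold == scaffold, , drop = FALSE]
  if (nrow(ex)) {
    within <- ex$start <= start & end <= ex$end
    if (any(within)) {
      return(list(category = "within_exon", gene_id = ex$gene_id[within][1]))
    }
    contains <- start <= ex$start & ex$end <= end
    if (any(contains)) {
      return(list(category = "contains_exon", gene_id = ex$gene_id[contains][1]))
    }
    partial <- ex$start <= end & ex$end >= start
    if (any(partial)) {
      return(list(category = "overlaps_exon_boundary",
                  gene_id = ex$gene_id[partial][1]))
    }
    for (g in unique(ex$gene_id[!is.na(ex$gene_id)])) {
      gs <- ex[ex$gene_id %in% g, , drop = FALSE]
      if (min(gs$start) <= start && end <= max(gs$end)) {
        return(list(category = "intronic", gene_id = g))
      }
    }
  }
  list(category = "intergenic", gene_id = NA_character_)
}

#' Text rendering of a hairpin candidate
#'
#' Marks the mature (M), loop (L) and star (S) segments under the precursor
#' sequence and its dot-bracket structure.
#'
#' @param candidate one row of the [hairpin_candidates()] frame.
#' @return character vector of three lines.
#' @export
render_hairpin <- function(candidate) {
  pre <- as_dna(candidate$precursor_seq)
  marks <- rep(".", nchar(pre))
  mark_seq <- function(sub, chr, marks) {
    if (is.na(sub)) return(marks)
    i <- regexpr(as_dna(sub), pre, fixed = TRUE)
    if (i > 0) marks[i:(i + nchar(sub) - 1L)] <- chr
    marks
  }
  marks <- mark_seq(candidate$loop_seq, "L", marks)
  marks <- mark_seq(candidate$mature_seq, "M", marks)
  marks <- mark_seq(candidate$star_seq, "S", marks)
  c(as_rna(pre), candidate$structure, paste(marks, collapse = ""))
}
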