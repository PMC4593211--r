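#' Match a mature miRNA against a reference database
#'
#' Candidate subjects are found by a shared exact word (default 16, so only
#' nearly identical sequences are considered); every shared-word offset defines
#' an ungapped end-to-end comparison over the overlap. The best match (fewest
#' mismatches, longest aligned length, then lexicographic subject id) is
#' classified: `perfect` when mismatch-free and identical in length;
#' `near_perfect` when there is at most one mismatch and at most a 2 nt length
#' difference between query and subject; otherwise `weak`. `NULL` is returned
#' when no subject shares a word.
#'
#' @param query mature sequence (DNA or RNA; matched in given orientation).
#' @param db named character vector of reference mature sequences.
#' @param word exact shared-word size (default 16).
#' @return list `subject_id, query_len, subject_len, aligned_len, mismatches,
#'   class`, or `NULL` for no shared-word hit.
#' @export
match_mature <- function(query, db, word = 16L) {
  query <- toupper(as_dna(query))
  db <- stats::setNames(toupper(as_dna(db)), names(db))
  qlen <- nchar(query)
  if (qlen < word) return(NULL)
  qwords <- substring(query, 1:(qlen - word + 1L), word:qlen)
  best <- NULL
  for (sid in sort(names(db))) {
    subj <- db[[sid]]
    slen <- nchar(subj)
    if (slen < word) next
    swords <- substring(subj, 1:(slen - word + 1L), word:slen)
    qpos <- which(qwords %in% swords)
    if (length(qpos) == 0L) next
    offsets <- unique(unlist(lapply(qpos, function(qp) {
      sp <- which(swords == qwords[qp])
      qp - sp
    })))
    for (off in offsets) {
      # query position i aligns subject position i - off
      qs <- max(1L, 1L + off); qe <- min(qlen, slen + off)
      if (qe < qs) next
      alen <- qe - qs + 1L
      mm <- hamming(substr(query, qs, qe), substr(subj, qs - off, qe - off))
      cand <- list(subject_id = sid, query_len = qlen, subject_len = slen,
                   aligned_len = alen, mismatches = mm)
      if (is.null(best) || mm < best$mismatches ||
          (mm == best$mismatches && alen > best$aligned_len)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$class <- if (best$mismatches == 0L &&
                    best$query_len == best$subject_len &&
                    best$aligned_len == best$query_len) {
    "perfect"
  } else if (best$mismatches <= 1L &&
             abs(best$query_len - best$subject_len) <= 2L) {
    "near_perfect"
  } else {
    "weak"
  }
  best
}

# Ungapped seed-and-extend local alignment score between two sequences,
# match +1 / mismatch -2, X-drop termination. Returns the best HSP found from
# shared words of length `word`, or NULL.
best_hsp <- function(query, subj, word = 16L, xdrop = 12L) {
  qlen <- nchar(query); slen <- nchar(subj)
  if (qlen < word || slen < word) return(NULL)
  qwords <- substring(query, 1:(qlen - word + 1L), word:qlen)
  swords <- substring(subj, 1:(slen - word + 1L), word:slen)
  shared <- intersect(qwords, swords)
  if (length(shared) == 0L) return(NULL)
  qv <- utf8ToInt(query); sv <- utf8ToInt(subj)
  seen <- character(0)
  best <- NULL
  for (wd in shared) {
    for (qp in which(qwords == wd)) for (sp in which(swords == wd)) {
      key <- sprintf("%d", qp - sp)  # one extension per diagonal
      if (key %in% seen) next
      seen <- c(seen, key)
      # extend left from (qp, sp) and right from word end
      score <- word; qs <- qp; ss <- sp
      cur <- score; i <- qp - 1L; j <- sp - 1L
      while (i >= 1L && j >= 1L) {
        cur <- cur + if (qv[i] == sv[j]) 1L else -2L
        if (cur > score) { score <- cur; qs <- i; ss <- j }
        if (score - cur > xdrop) break
        i <- i - 1L; j <- j - 1L
      }
      qe <- qp + word - 1L; se <- sp + word - 1L
      cur <- score; i <- qe + 1L; j <- se + 1L
      best_right <- score; qe_best <- qe
      while (i <= qlen && j <= slen) {
        cur <- cur + if (qv[i] == sv[j]) 1L else -2L
        if (cur > best_right) { best_right <- cur; qe_best <- i }
        if (best_right - cur > xdrop) break
        i <- i + 1L; j <- j + 1L
      }
      score <- best_right; qe <- qe_best; se <- ss + (qe - qs)
      if (is.null(best) || score > best$score ||
          (score == best$score && (qe - qs + 1L) > best$aligned_len)) {
        best <- list(score = score, q_start = qs, q_end = qe,
                     s_start = ss, s_end = se, aligned_len = qe - qs + 1L)
      }
    }
  }
  best
}

#' Match a hairpin precursor against a reference database
#'
#' Seed-and-extend ungapped local alignment (match +1, mismatch -2, X-drop)
#' from shared 16-mers, both orientations, keeping the better. Hits must reach
#' `min_score` (a bit-score proxy standing in for a near-identity E-value
#' cutoff); a surviving hit is then discarded when the query is more than
#' `max_len_slack` bases longer than the aligned stretch.
#'
#' @param query precursor sequence.
#' @param db named character vector of reference hairpins.
#' @param word shared-word size (default 16).
#' @param min_score minimum alignment score (default 40: a ~45 nt perfect
#'   local match passes, sub-word matches cannot).
#' @param max_len_slack maximum allowed `query_len - aligned_len` (default 8).
#' @return list `subject_id, query_len, subject_len, aligned_len, mismatches,
#'   score, strand, class` (class is `perfect`/`near_perfect`/`weak` on the
#'   same definition as mature matches), or `NULL`.
#' @export
match_hairpin <- function(query, db, word = 16L, min_score = 40L,
                          max_len_slack = 8L) {
  query <- toupper(as_dna(query))
  db <- stats::setNames(toupper(as_dna(db)), names(db))
  qlen <- nchar(query)
  best <- NULL
  for (sid in sort(names(db))) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") query else revcomp(query)
      h <- best_hsp(q, db[[sid]], word = word)
      if (is.null(h) || h$score < min_score) next
      if (qlen - h$aligned_len > max_len_slack) next
      mm <- hamming(substr(q, h$q_start, h$q_end),
                    substr(db[[sid]], h$s_start, h$s_end))
      cand <- list(subject_id = sid, query_len = qlen,
                   subject_len = nchar(db[[sid]]),
                   aligned_len = h$aligned_len, mismatches = mm,
                   score = h$score, strand = strand)
      if (is.null(best) || cand$score > best$score ||
          (cand$score == best$score && cand$aligned_len > best$aligned_len)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$class <- if (best$mismatches == 0L &&
                    best$query_len == best$subject_len &&
                    best$aligned_len == best$query_len) {
    "perfect"
  } else if (best$mismatches <= 1L &&
             abs(best$query_len - best$subject_len) <= 2L) {
    "near_perfect"
  } else {
    "weak"
  }
  best
}

#' Classify candidates as known, iso or novel
#'
#' `known`: perfect mature match. `iso`: near-perfect mature match, or a
#' hairpin-only match surviving the score and length-slack filters. Everything
#' else is a `novel_candidate`. Every candidate receives exactly one label.
#'
#' @param candidates data.frame with columns `id`, `mature_seq`,
#'   `precursor_seq` (RNA or DNA).
#' @param mature_db,hairpin_db named reference sequence vectors.
#' @param word shared-word size (default 16).
#' @return data.frame `id, label, mature_class, mature_subject, hairpin_class,
#'   hairpin_subject`.
#' @export
classify_candidates <- function(candidates, mature_db, hairpin_db,
                                word = 16L) {
  n <- nrow(candidates)
  out <- data.frame(id = candidates$id,
                    label = character(n), mature_class = character(n),
                    mature_subject = NA_character_,
                    hairpin_class = character(n),
                    hairpin_subject = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    mm <- if (!is.na(candidates$mature_seq[i])) {
      match_mature(candidates$mature_seq[i], mature_db, word = word)
    } else NULL
    hm <- if (!is.na(candidates$precursor_seq[i])) {
      match_hairpin(candidates$precursor_seq[i], hairpin_db, word = word)
    } else NULL
    out$mature_class[i] <- if (is.null(mm)) "none" else mm$class
    out$mature_subject[i] <- if (is.null(mm)) NA_character_ else mm$subject_id
    out$hairpin_class[i] <- if (is.null(hm)) "none" else hm$class
    out$hairpin_subject[i] <- if (is.null(hm)) NA_character_ else hm$subject_id
    hairpin_hit <- !is.null(hm) && hm$class %in% c("perfect", "near_perfect",
                                                   "weak")
    out$label[i] <- if (!is.null(mm) && mm$class == "perfect") {
      "known"
    } else if ((!is.null(mm) && mm$class == "near_perfect") || hairpin_hit) {
      "iso"
    } else {
      "novel_candidate"
    }
  }
  out
}

#' Reciprocal best hits between two hairpin sets
#'
#' A pair (a, b) is emitted iff b is a's best hairpin match in set B and a is
#' b's best match in set A (ties broken by alignment score, then aligned
#' length, then lexicographic subject id). Each id appears in at most one
#' pair; output is sorted by `species_a_id`. The operation is symmetric in its
#' two arguments.
#'
#' The length-slack filter of [match_hairpin()] is disabled here by default:
#' it belongs to the reference-database screen, and hairpin conventions
#' (with/without genomic flank) differ between species' sets.
#'
#' @param hairpins_a,hairpins_b named character vectors of hairpin sequences.
#' @param max_len_slack forwarded to [match_hairpin()] (default `Inf`).
#' @param ... passed to [match_hairpin()].
#' @return data.frame `species_a_id, species_b_id`.
#' @export
reciprocal_best_hits <- function(hairpins_a, hairpins_b,
                                 max_len_slack = Inf, ...) {
  stopifnot(length(hairpins_a) > 0L, length(hairpins_b) > 0L)
  best_ab <- vapply(sort(names(hairpins_a)), function(a) {
    h <- match_hairpin(hairpins_a[[a]], hairpins_b,
                       max_len_slack = max_len_slack, ...)
    if (is.null(h)) NA_character_ else h$subject_id
  }, "")
  best_ba <- vapply(sort(names(hairpins_b)), function(b) {
    h <- match_hairpin(hairpins_b[[b]], hairpins_a,
                       max_len_slack = max_len_slack, ...)
    if (is.null(h)) NA_character_ else h$subject_id
  }, "")
  a_ids <- names(best_ab)[!is.na(best_ab) &
                            best_ba[best_ab] == names(best_ab)]
  a_ids <- a_ids[!is.na(a_ids)]
  out <- data.frame(species_a_id = a_ids,
                    species_b_id = unname(best_ab[a_ids]),
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out$species_b_id), , drop = FALSE]
  out[order(out$species_a_id), , drop = FALSE]
}
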