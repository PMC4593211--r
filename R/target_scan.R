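#' Extract spliced 3'UTR sequences
#'
#' `three_prime_UTR` features are grouped by gene id, ordered by start,
#' concatenated and reverse-complemented for minus-strand genes, so each UTR
#' is reported in transcript orientation. Features exceeding scaffold bounds
#' are skipped with a warning.
#'
#' @param annotation data.frame from [read_annotation()].
#' @param genome named scaffold sequences.
#' @return named character vector (transcript id -> UTR sequence, DNA).
#' @export
extract_utrs <- function(annotation, genome) {
  utr <- annotation[annotation$feature == "three_prime_UTR", , drop = FALSE]
  if (nrow(utr) == 0L) {
    warning("no three_prime_UTR features in annotation")
    return(stats::setNames(character(0), character(0)))
  }
  seqs <- stats::setNames(as.character(genome), names(genome))
  lens <- vapply(seqs, nchar, 1L)
  oob <- !(utr$scaffold %in% names(seqs)) | utr$start < 1L |
    utr$end > lens[utr$scaffold]
  oob[is.na(oob)] <- TRUE
  if (any(oob)) {
    warning("skipped ", sum(oob), " 3'UTR feature(s) outside scaffold bounds")
    utr <- utr[!oob, , drop = FALSE]
  }
  out <- character(0)
  for (g in unique(utr$gene_id)) {
    sub <- utr[utr$gene_id == g, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    s <- paste(substring(seqs[[sub$scaffold[1]]], sub$start, sub$end),
               collapse = "")
    if (sub$strand[1] == "-") s <- revcomp(s)
    out[g] <- s
  }
  out
}

# Pair weight on the miRNA:target duplex in DNA space.
# Returns +5 Watson-Crick, +2 G:U wobble, 0 otherwise.
duplex_pair_score <- function(q, u) {
  if ((q == "A" && u == "T") || (q == "T" && u == "A") ||
      (q == "G" && u == "C") || (q == "C" && u == "G")) return(5)
  if ((q == "G" && u == "T") || (q == "T" && u == "G")) return(2)
  0
}

duplex_pair_energy <- function(q, u) {
  if ((q == "G" && u == "C") || (q == "C" && u == "G")) return(-3)
  if ((q == "A" && u == "T") || (q == "T" && u == "A")) return(-2)
  if ((q == "G" && u == "T") || (q == "T" && u == "G")) return(-1)
  0
}

# Align miRNA positions 8..L leftwards from the seed anchor against the UTR
# segment immediately 5' of the anchor. Linear gap penalty; pair scores at
# miRNA positions >= half_from are halved (3' half weight). Returns score,
# energy (over paired bases on the optimal path) and UTR bases consumed.
extend_3p <- function(mir, useg_rev, half_from = 12L, mismatch = -3,
                      gap = -8) {
  L <- nchar(mir)
  qc <- strsplit(mir, "")[[1]]
  uc <- strsplit(useg_rev, "")[[1]]
  I <- L - 7L
  J <- length(uc)
  if (I <= 0L) return(list(score = 0, energy = 0, used = 0L))
  M <- matrix(-Inf, I + 1L, J + 1L)
  M[1L, ] <- gap * (0:J)
  M[, 1L] <- gap * (0:I)
  M[1L, 1L] <- 0
  ptr <- matrix(0L, I + 1L, J + 1L)  # 1 diag, 2 up (miRNA gap), 3 left
  ptr[1L, -1L] <- 3L; ptr[-1L, 1L] <- 2L
  for (i in seq_len(I)) {
    p <- 7L + i
    w <- if (p >= half_from) 0.5 else 1
    for (j in seq_len(J)) {
      ps <- duplex_pair_score(qc[p], uc[j])
      d <- M[i, j] + if (ps > 0) ps * w else mismatch
      u <- M[i, j + 1L] + gap
      l <- M[i + 1L, j] + gap
      best <- max(d, u, l)
      M[i + 1L, j + 1L] <- best
      ptr[i + 1L, j + 1L] <- which.max(c(d, u, l))
    }
  }
  jbest <- which.max(M[I + 1L, ]) - 1L
  # traceback for the energy of paired bases
  energy <- 0
  i <- I + 1L; j <- jbest + 1L
  while (i > 1L || j > 1L) {
    mv <- ptr[i, j]
    if (mv == 1L && i > 1L && j > 1L) {
      p <- 7L + (i - 1L)
      if (duplex_pair_score(qc[p], uc[j - 1L]) > 0) {
        energy <- energy + duplex_pair_energy(qc[p], uc[j - 1L])
      }
      i <- i - 1L; j <- j - 1L
    } else if (mv == 2L || j == 1L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(score = M[I + 1L, jbest + 1L], energy = energy, used = jbest)
}

#' Scan 3'UTRs for candidate miRNA target sites
#'
#' Sites are anchored by an exact Watson--Crick complement of the miRNA seed
#' (positions 2--7; a 6mer), extended to 7mer (2--8) and 8mer (1--8) classes
#' when adjacent positions also pair. The 3' remainder of the miRNA is
#' aligned against the adjacent UTR segment with +5 per WC pair, +2 per G:U
#' wobble (wobble is forbidden inside the seed), -3 per mismatch and a linear
#' -8 gap penalty, with pairs at miRNA positions >= 12 contributing half
#' weight. Raw scores are rescaled so a perfect 22-mer duplex scores ~190,
#' putting the conventional pairing-score gate (default > 155) on its usual
#' scale; the energy proxy sums -3/-2/-1 per GC/AU/GU pair and is gated at
#' `energy_cut` (default < -7). Overlapping sites within a 25 nt window keep
#' only the best scorer per miRNA/transcript.
#'
#' @param mirnas named character vector of mature sequences (RNA or DNA,
#'   17--28 nt).
#' @param utrs named character vector of UTR sequences (from
#'   [extract_utrs()]).
#' @param score_cut pairing-score gate on the rescaled score (default 155).
#' @param energy_cut energy gate (default -7).
#' @param gap linear gap penalty (default -8, matching a -8 open / -8 extend
#'   convention).
#' @param scale_ref rescaling so that a perfect 22-mer duplex scores this
#'   (default 190).
#' @return data.frame `mirna_id, transcript_id, utr_start, utr_end,
#'   pairing_score, energy_proxy, seed_match`.
#' @export
scan_targets <- function(mirnas, utrs, score_cut = 155, energy_cut = -7,
                         gap = -8, scale_ref = 190) {
  # raw score of a perfect 22-mer duplex: 11 pairs full + 11 at half weight
  raw_perfect22 <- 11 * 5 + 11 * 2.5
  scale <- scale_ref / raw_perfect22
  empty <- data.frame(mirna_id = character(0), transcript_id = character(0),
                      utr_start = integer(0), utr_end = integer(0),
                      pairing_score = numeric(0), energy_proxy = numeric(0),
                      seed_match = character(0), stringsAsFactors = FALSE)
  out <- list()
  for (mid in names(mirnas)) {
    mir <- toupper(as_dna(mirnas[[mid]]))
    L <- nchar(mir)
    stopifnot(L >= 17L, L <= 28L)
    qc <- strsplit(mir, "")[[1]]
    seed_rc <- revcomp(substr(mir, 2L, 7L))
    for (tid in names(utrs)) {
      utr <- toupper(as_dna(utrs[[tid]]))
      nU <- nchar(utr)
      anchors <- integer(0)
      from <- 1L
      repeat {
        m <- regexpr(seed_rc, substr(utr, from, nU), fixed = TRUE)
        if (m == -1L) break
        t0 <- from + as.integer(m) - 1L
        anchors <- c(anchors, t0)
        from <- t0 + 1L
      }
      sites <- list()
      for (t0 in anchors) {
        # seed: miRNA 2..7 pair UTR t0..t0+5 (all WC by construction)
        s_raw <- 6 * 5
        energy <- sum(vapply(2:7, function(p) {
          duplex_pair_energy(qc[p], substr(utr, t0 + 7L - p, t0 + 7L - p))
        }, 0))
        p8_pair <- t0 > 1L &&
          duplex_pair_score(qc[8], substr(utr, t0 - 1L, t0 - 1L)) == 5
        p1_pair <- t0 + 6L <= nU &&
          duplex_pair_score(qc[1], substr(utr, t0 + 6L, t0 + 6L)) == 5
        seed_match <- if (p8_pair && p1_pair) "8mer"
                      else if (p8_pair) "7mer" else "6mer"
        if (p1_pair) {
          s_raw <- s_raw + 5
          energy <- energy + duplex_pair_energy(qc[1],
                                                substr(utr, t0 + 6L, t0 + 6L))
        }
        # 3' extension against the UTR 5' of the anchor
        wlen <- min(t0 - 1L, (L - 7L) + 4L)
        useg_rev <- if (wlen > 0L) {
          paste(rev(strsplit(substr(utr, t0 - wlen, t0 - 1L), "")[[1]]),
                collapse = "")
        } else ""
        ext <- extend_3p(mir, useg_rev, gap = gap)
        s_raw <- s_raw + ext$score
        energy <- energy + ext$energy
        site_start <- t0 - ext$used
        site_end <- if (p1_pair) t0 + 6L else t0 + 5L
        score <- s_raw * scale
        if (score > score_cut && energy < energy_cut) {
          sites <- c(sites, list(data.frame(
            mirna_id = mid, transcript_id = tid,
            utr_start = site_start, utr_end = site_end,
            pairing_score = score, energy_proxy = energy,
            seed_match = seed_match, stringsAsFactors = FALSE)))
        }
      }
      if (length(sites)) {
        s <- do.call(rbind, sites)
        s <- s[order(-s$pairing_score, s$utr_start), , drop = FALSE]
        kept <- integer(0)
        for (r in seq_len(nrow(s))) {
          if (!length(kept) ||
              all(abs(s$utr_start[r] - s$utr_start[kept]) >= 25L)) {
            kept <- c(kept, r)
          }
        }
        out <- c(out, list(s[kept, , drop = FALSE]))
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$mirna_id, res$transcript_id, res$utr_start), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
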