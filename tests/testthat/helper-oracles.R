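# Independent oracles used to freeze expected values. These deliberately use
# brute force / enumeration rather than the package's algorithms.

# Maximum pairing score over ALL pseudoknot-free structures with loop >= 3,
# by explicit recursion over structures (exponential enumeration, no tables).
oracle_fold_score <- function(seq) {
  s <- strsplit(chartr("Uu", "Tt", toupper(seq)), "")[[1]]
  n <- length(s)
  pw <- function(a, b) {
    k <- paste0(a, b)
    if (k %in% c("GC", "CG")) 3
    else if (k %in% c("AT", "TA")) 2
    else if (k %in% c("GT", "TG")) 1
    else 0
  }
  rec <- function(i, j) {
    if (j - i < 4L) return(0)
    best <- rec(i + 1L, j)
    for (k in (i + 4L):j) {
      w <- pw(s[i], s[k])
      if (w > 0) {
        v <- w + rec(i + 1L, k - 1L) + if (k < j) rec(k + 1L, j) else 0
        if (v > best) best <- v
      }
    }
    best
  }
  if (n < 2L) return(0)
  rec(1L, n)
}

# Parse a dot-bracket string into a pair list; stops on imbalance.
parse_pairs <- function(db) {
  ch <- strsplit(db, "")[[1]]
  stack <- integer(0)
  pairs <- NULL
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      stopifnot(length(stack) > 0L)
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  stopifnot(length(stack) == 0L)
  pairs
}

# Score of a specific structure under the GC=3/AU=2/GU=1 weights.
structure_score <- function(seq, db) {
  s <- strsplit(chartr("Uu", "Tt", toupper(seq)), "")[[1]]
  pairs <- parse_pairs(db)
  if (is.null(pairs)) return(0)
  w <- c(GC = 3, CG = 3, AT = 2, TA = 2, GT = 1, TG = 1)
  sum(vapply(seq_len(nrow(pairs)), function(r) {
    k <- paste0(s[pairs[r, 1]], s[pairs[r, 2]])
    if (k %in% names(w)) w[[k]] else 0
  }, 0))
}

# Brute-force scan of every genomic window on both strands for <=
# max_tail-mismatch, seed-clean alignments of one read.
oracle_map_loci <- function(read, genome, seed_len = 18L, max_tail = 2L) {
  out <- list()
  L <- nchar(read)
  sl <- min(seed_len, L)
  g_chr <- stats::setNames(as.character(genome), names(genome))
  for (sc in names(g_chr)) {
    gv <- utf8ToInt(g_chr[[sc]])
    n <- length(gv)
    if (n < L) next
    for (strand in c("+", "-")) {
      q <- if (strand == "+") read else mirstack::revcomp(read)
      qv <- utf8ToInt(q)
      seed_rng <- if (strand == "+") 1:sl else (L - sl + 1L):L
      for (s in 1:(n - L + 1L)) {
        mm <- which(qv != gv[s:(s + L - 1L)])
        if (length(mm) > 0L && L < seed_len) next  # short reads: exact only
        if (any(mm %in% seed_rng)) next
        if (length(mm) > max_tail) next
        out <- c(out, list(data.frame(scaffold = sc, start = s,
                                      strand = strand,
                                      mismatches = length(mm),
                                      stringsAsFactors = FALSE)))
      }
    }
  }
  if (length(out)) {
    res <- do.call(rbind, out)
    res[order(res$scaffold, res$start, res$strand), , drop = FALSE]
  } else {
    data.frame(scaffold = character(0), start = integer(0),
               strand = character(0), mismatches = integer(0))
  }
}

# Exhaustive mature-match oracle: the shared-word gate computed brute force,
# then every ungapped offset scored by Hamming distance over the overlap.
oracle_match_mature <- function(query, db, word = 16L) {
  query <- toupper(chartr("Uu", "Tt", query))
  qlen <- nchar(query)
  best <- NULL
  for (sid in sort(names(db))) {
    subj <- toupper(chartr("Uu", "Tt", db[[sid]]))
    slen <- nchar(subj)
    for (off in (-slen):qlen) {
      qs <- max(1L, 1L + off); qe <- min(qlen, slen + off)
      if (qe < qs) next
      a <- substr(query, qs, qe)
      b <- substr(subj, qs - off, qe - off)
      match_run <- rle(utf8ToInt(a) == utf8ToInt(b))
      # a diagonal is only considered when it carries an exact shared word
      if (!any(match_run$lengths[match_run$values] >= word)) next
      mm <- sum(utf8ToInt(a) != utf8ToInt(b))
      cand <- list(subject_id = sid, query_len = qlen, subject_len = slen,
                   aligned_len = qe - qs + 1L, mismatches = mm)
      if (is.null(best) || mm < best$mismatches ||
          (mm == best$mismatches && cand$aligned_len > best$aligned_len)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$class <- if (best$mismatches == 0L && best$query_len == best$subject_len
                    && best$aligned_len == best$query_len) "perfect"
  else if (best$mismatches <= 1L &&
           abs(best$query_len - best$subject_len) <= 2L) "near_perfect"
  else "weak"
  best
}

# Benjamini-Hochberg by the textbook formula (monotone minimum of n*p/i).
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, n * p[o[i]] / i)
    adj[o[i]] <- running
  }
  adj
}

# Longhand two-sample TMM factor ratio (column 2 relative to column 1):
# weighted trimmed mean of M-values, 30 % M-trim and 5 % A-trim.
oracle_tmm_ratio <- function(x1, x2, trim_m = 0.3, trim_a = 0.05) {
  n1 <- sum(x1); n2 <- sum(x2)
  keep <- x1 > 0 & x2 > 0
  p1 <- x1[keep] / n1; p2 <- x2[keep] / n2
  M <- log2(p2 / p1)
  A <- 0.5 * log2(p2 * p1)
  w <- 1 / ((n1 - x1[keep]) / (n1 * x1[keep]) +
              (n2 - x2[keep]) / (n2 * x2[keep]))
  lm <- stats::quantile(M, c(trim_m, 1 - trim_m), type = 7)
  la <- stats::quantile(A, c(trim_a, 1 - trim_a), type = 7)
  sel <- M >= lm[1] & M <= lm[2] & A >= la[1] & A <= la[2]
  2^(sum(w[sel] * M[sel]) / sum(w[sel]))
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
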