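#' Length-filter and collapse reads across libraries
#'
#' Reads shorter than `min_len` are discarded (the paper-scale size selection
#' leaves ~5 % of reads below the cutoff); identical sequences are merged
#' across libraries with per-library counts preserved. The per-library summary
#' mirrors a sequencing-summary table: total reads, usable reads and unique
#' sequence counts.
#'
#' @param reads_by_library named list of character vectors of read sequences,
#'   one element per library.
#' @param min_len minimum usable read length (default 17).
#' @return list with `collapsed` (data.frame: `sequence`, one count column per
#'   library, `total_count`, sorted by sequence) and `summary` (data.frame:
#'   `library_id, total_reads, usable_reads, unique_sequences`).
#' @export
filter_and_collapse <- function(reads_by_library, min_len = 17L) {
  stopifnot(is.list(reads_by_library), !is.null(names(reads_by_library)))
  libs <- names(reads_by_library)
  per_lib <- lapply(libs, function(lib) {
    r <- reads_by_library[[lib]]
    usable <- r[nchar(r) >= min_len]
    if (length(usable) == 0L) {
      warning("library ", lib, " has zero usable reads (>= ", min_len, " nt)")
      dt <- data.table(sequence = character(0), count = integer(0))
    } else {
      dt <- data.table(sequence = usable)[, list(count = .N), by = "sequence"]
    }
    list(dt = dt, total = length(r), usable = length(usable))
  })
  names(per_lib) <- libs

  all_seqs <- sort(unique(unlist(lapply(per_lib, function(x) x$dt$sequence))))
  collapsed <- data.frame(sequence = all_seqs, stringsAsFactors = FALSE)
  for (lib in libs) {
    cnt <- integer(length(all_seqs))
    dt <- per_lib[[lib]]$dt
    if (nrow(dt)) cnt[match(dt$sequence, all_seqs)] <- dt$count
    collapsed[[lib]] <- cnt
  }
  collapsed$total_count <- if (length(all_seqs)) {
    rowSums(as.matrix(collapsed[libs]))
  } else integer(0)

  summary <- data.frame(
    library_id = libs,
    total_reads = vapply(per_lib, function(x) x$total, 1L),
    usable_reads = vapply(per_lib, function(x) x$usable, 1L),
    unique_sequences = vapply(per_lib, function(x) nrow(x$dt), 1L),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  list(collapsed = collapsed, summary = summary)
}

#' Build an exact k-mer index of a genome
#'
#' Indexes every forward-strand word; minus-strand queries are answered by
#' reverse-complement canonicalization, so both strands are searchable.
#'
#' @param genome named `DNAStringSet` or named character vector of scaffolds.
#' @param word word size (default 18; must be >= 8 to avoid index blowup).
#' @return an object of class `mirstack_index`.
#' @export
build_index <- function(genome, word = 18L) {
  word <- as.integer(word)
  if (word < 8L) stop("index word size must be >= 8")
  seqs <- stats::setNames(as.character(genome), names(genome))
  if (length(seqs) == 0L) stop("empty genome")
  tabs <- lapply(names(seqs), function(sc) {
    n <- nchar(seqs[[sc]])
    if (n < word) return(NULL)
    data.table(kmer = substring(seqs[[sc]], 1:(n - word + 1L), word:n),
               scaffold = sc, pos = 1:(n - word + 1L))
  })
  kmers <- rbindlist(tabs)
  if (nrow(kmers)) setkey(kmers, kmer)
  structure(list(kmers = kmers, word = word, seqs = seqs,
                 lens = vapply(seqs, nchar, 1L)),
            class = "mirstack_index")
}

#' Query an index for a word on both strands
#'
#' @param index a `mirstack_index`.
#' @param word_seq a word of exactly the index word size.
#' @return data.frame `scaffold, pos, strand`: `+` rows are forward occurrences
#'   of `word_seq`; `-` rows are forward positions of its reverse complement
#'   (i.e. minus-strand occurrences of the query).
#' @export
index_query <- function(index, word_seq) {
  stopifnot(inherits(index, "mirstack_index"),
            nchar(word_seq) == index$word)
  fw <- index$kmers[list(word_seq), nomatch = 0L]
  rv <- index$kmers[list(revcomp(word_seq)), nomatch = 0L]
  out <- data.frame(
    scaffold = c(fw$scaffold, rv$scaffold),
    pos = c(fw$pos, rv$pos),
    strand = rep(c("+", "-"), c(nrow(fw), nrow(rv))),
    stringsAsFactors = FALSE
  )
  out[order(out$scaffold, out$pos, out$strand), , drop = FALSE]
}

# All candidate loci for one read: exact seed, <= max_tail mismatches outside.
# Returns data.frame(scaffold, start, strand, mismatches).
read_loci <- function(seq, index, seed_len, max_tail_mismatch) {
  L <- nchar(seq)
  sl <- min(seed_len, L)
  word <- index$word
  hits <- list()

  check_window <- function(sc, s, strand) {
    if (s < 1L || s + L - 1L > index$lens[[sc]]) return(NULL)
    win <- substr(index$seqs[[sc]], s, s + L - 1L)
    qry <- if (strand == "+") seq else revcomp(seq)
    mm_pos <- which(utf8ToInt(win) != utf8ToInt(qry))
    # seed = 5' prefix of the read: window coords [1, sl] on +, [L-sl+1, L] on -
    seed_rng <- if (strand == "+") c(1L, sl) else c(L - sl + 1L, L)
    if (any(mm_pos >= seed_rng[1] & mm_pos <= seed_rng[2])) return(NULL)
    if (length(mm_pos) > max_tail_mismatch) return(NULL)
    data.frame(scaffold = sc, start = s, strand = strand,
               mismatches = length(mm_pos), stringsAsFactors = FALSE)
  }

  if (sl >= word) {
    w_fw <- substr(seq, 1L, word)
    fw <- index$kmers[list(w_fw), nomatch = 0L]
    if (nrow(fw)) {
      hits <- c(hits, mapply(check_window, fw$scaffold, fw$pos,
                             MoreArgs = list(strand = "+"), SIMPLIFY = FALSE))
    }
    rv <- index$kmers[list(revcomp(w_fw)), nomatch = 0L]
    if (nrow(rv)) {
      starts <- rv$pos - (L - word)
      hits <- c(hits, mapply(check_window, rv$scaffold, starts,
                             MoreArgs = list(strand = "-"), SIMPLIFY = FALSE))
    }
  } else {
    # read shorter than the index word: whole read is the seed, exact match,
    # found by direct string search on both strands
    find_all <- function(pat, subject) {  # allows overlapping occurrences
      res <- integer(0); from <- 1L
      repeat {
        m <- regexpr(pat, substr(subject, from, nchar(subject)), fixed = TRUE)
        if (m == -1L) break
        pos <- from + as.integer(m) - 1L
        res <- c(res, pos); from <- pos + 1L
      }
      res
    }
    for (sc in names(index$seqs)) {
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") seq else revcomp(seq)
        for (s in find_all(pat, index$seqs[[sc]])) {
          hits <- c(hits, list(data.frame(scaffold = sc, start = s,
                                          strand = strand, mismatches = 0L,
                                          stringsAsFactors = FALSE)))
        }
      }
    }
  }
  hits <- hits[!vapply(hits, is.null, TRUE)]
  if (length(hits) == 0L) {
    return(data.frame(scaffold = character(0), start = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  out <- unique(do.call(rbind, hits))
  rownames(out) <- NULL
  out
}

#' Map collapsed reads to the genome under stringent small-RNA settings
#'
#' Candidate loci are found by exact match of the seed (the 5' prefix of length
#' `min(seed_len, read length)`); up to `max_tail_mismatch` substitutions are
#' allowed outside the seed (no indels). Reads hitting more than `max_hits`
#' loci are dropped entirely; otherwise only the best alignment is reported
#' (fewest mismatches, ties broken by scaffold name, start, then `+` before
#' `-`). Output is sorted by sequence, so results are independent of input
#' order.
#'
#' @param collapsed data.frame from [filter_and_collapse()] (or any frame with
#'   a `sequence` column).
#' @param index a `mirstack_index` built with `word <= seed_len`.
#' @param seed_len seed length (default 18).
#' @param max_tail_mismatch maximum substitutions outside the seed (default 2).
#' @param max_hits drop reads with more genomic hits than this (default 5; the
#'   source protocol says "more than 5 times" while its summary table header
#'   says "up to 4 locations" — the threshold is deliberately configurable).
#' @return list with `alignments` (data.frame `sequence, scaffold, start,
#'   strand, mismatches, n_hits`), `unmapped` and `dropped` (character vectors
#'   of sequences).
#' @export
map_collapsed_reads <- function(collapsed, index, seed_len = 18L,
                                max_tail_mismatch = 2L, max_hits = 5L) {
  stopifnot(inherits(index, "mirstack_index"), index$word <= seed_len)
  seqs <- sort(unique(collapsed$sequence))
  aln <- vector("list", length(seqs))
  unmapped <- character(0)
  dropped <- character(0)
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    loci <- read_loci(s, index, seed_len, max_tail_mismatch)
    n <- nrow(loci)
    if (n == 0L) {
      unmapped <- c(unmapped, s)
    } else if (n > max_hits) {
      dropped <- c(dropped, s)
    } else {
      o <- order(loci$mismatches, loci$scaffold, loci$start,
                 match(loci$strand, c("+", "-")))
      best <- loci[o[1], , drop = FALSE]
      best$sequence <- s
      best$n_hits <- n
      aln[[i]] <- best
    }
  }
  aln <- aln[!vapply(aln, is.null, TRUE)]
  alignments <- if (length(aln)) {
    out <- do.call(rbind, aln)
    rownames(out) <- NULL
    out[c("sequence", "scaffold", "start", "strand", "mismatches", "n_hits")]
  } else {
    data.frame(sequence = character(0), scaffold = character(0),
               start = integer(0), strand = character(0),
               mismatches = integer(0), n_hits = integer(0))
  }
  list(alignments = alignments, unmapped = unmapped, dropped = dropped)
}
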