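#' Load the packaged miRNA cluster locus fixture
#'
#' Thirty-one mature miRNA loci over ten scaffolds of the oriental fruit fly
#' genome assembly, shipped as a plain-text fixture for cluster detection.
#'
#' @return data.frame `id, scaffold, start, end, strand, mature_sequence,
#'   mature_count`.
#' @export
load_cluster_fixture <- function() {
  path <- system.file("extdata", "table4_clusters.tsv", package = "mirstack",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' miRNA family label from an identifier
#'
#' Strips the species prefix and variant suffixes: `bdo-mir-2a-2` and
#' `bdo-mir-2b` are both family `mir-2`; `bdo-mir-5`, `bdo-mir-5b` and
#' `bdo-mir-5c` are all `mir-5`; `bdo-let-7` stays `let-7`.
#'
#' @param id character vector of miRNA identifiers.
#' @return character vector of family labels.
#' @export
mirna_family <- function(id) {
  m <- regexpr("(mir|miR|let|bantam)-?[0-9]+", id)
  out <- id
  out[m > 0] <- regmatches(id, m)
  tolower(out)
}

#' Detect tandem genomic miRNA clusters
#'
#' Loci are grouped by (scaffold, strand), sorted by start, and chained while
#' the gap between consecutive loci is at most `max_gap` (gap measured
#' end-to-start by default, configurable to start-to-start). Chains with at
#' least two members are clusters. Output is invariant to input permutation.
#'
#' @param loci data.frame with `id, scaffold, start, end, strand` (and
#'   optionally `family`).
#' @param max_gap maximum gap in bp (default 10000, the "<10 kb apart" rule).
#' @param gap_mode `"end_to_start"` (default) or `"start_to_start"`.
#' @return list with `members` (the input loci plus `cluster_id`, NA for
#'   unclustered, ordered by scaffold/start) and `clusters` (one row per
#'   cluster: `cluster_id, scaffold, strand, n_members, start, end, span_bp,
#'   span_kb`), clusters sorted by scaffold then start.
#' @export
detect_clusters <- function(loci, max_gap = 10000L,
                            gap_mode = c("end_to_start", "start_to_start")) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(all(loci$start <= loci$end))
  loci <- loci[order(loci$scaffold, loci$start, loci$end, loci$id), ,
               drop = FALSE]
  loci$cluster_id <- NA_character_
  chains <- list()
  for (key in unique(paste(loci$scaffold, loci$strand))) {
    sel <- which(paste(loci$scaffold, loci$strand) == key)
    if (length(sel) < 2L) next
    sub <- loci[sel, , drop = FALSE]
    gap <- if (gap_mode == "end_to_start") {
      sub$start[-1L] - sub$end[-nrow(sub)]
    } else {
      sub$start[-1L] - sub$start[-nrow(sub)]
    }
    chain <- cumsum(c(0L, as.integer(gap > max_gap)))
    for (ch in unique(chain)) {
      members <- sel[chain == ch]
      if (length(members) >= 2L) chains <- c(chains, list(members))
    }
  }
  if (length(chains)) {
    # order clusters by scaffold then leftmost start
    ord <- order(vapply(chains, function(m) loci$scaffold[m[1]], ""),
                 vapply(chains, function(m) min(loci$start[m]), 1L))
    chains <- chains[ord]
    for (i in seq_along(chains)) {
      loci$cluster_id[chains[[i]]] <- sprintf("cluster-%02d", i)
    }
  }
  clusters <- do.call(rbind, lapply(seq_along(chains), function(i) {
    m <- loci[chains[[i]], , drop = FALSE]
    sp <- cluster_span(m)
    data.frame(cluster_id = sprintf("cluster-%02d", i),
               scaffold = m$scaffold[1], strand = m$strand[1],
               n_members = nrow(m), start = min(m$start), end = max(m$end),
               span_bp = sp$span_bp, span_kb = sp$span_kb,
               stringsAsFactors = FALSE)
  }))
  if (is.null(clusters)) {
    clusters <- data.frame(cluster_id = character(0), scaffold = character(0),
                           strand = character(0), n_members = integer(0),
                           start = integer(0), end = integer(0),
                           span_bp = integer(0), span_kb = numeric(0))
  }
  rownames(loci) <- NULL
  list(members = loci, clusters = clusters)
}

#' Span of a genomic cluster
#'
#' @param members data.frame of at least two loci with `start, end` on one
#'   scaffold and strand.
#' @return list `span_bp` (max end - min start) and `span_kb` (rounded to one
#'   decimal).
#' @export
cluster_span <- function(members) {
  if (nrow(members) < 2L) stop("a cluster needs at least 2 members")
  span_bp <- max(members$end) - min(members$start)
  list(span_bp = span_bp, span_kb = round(span_bp / 1000, 1L))
}

#' Compare the arrangement of two miRNA clusters
#'
#' Members are read in transcript order (clusters on opposite strands are
#' orientation-normalized by reversing one). The shared families are
#' extracted; when the shared set covers at least one cluster's full family
#' complement the ordered, duplicate-preserving family sequences are compared:
#' `identical` when equal, `reversed` when one is the exact reverse,
#' `rearranged` otherwise (the duplicated-family case included). When the
#' shared set covers neither cluster the verdict is `partial_overlap`, and
#' `disjoint` when no family is shared.
#'
#' @param cluster_a,cluster_b data.frames with `id, start` and either a
#'   `family` column or ids resolvable by `family_map`/[mirna_family()];
#'   optionally a `strand` column (first value used for orientation).
#' @param family_map optional named vector id -> family.
#' @return one of `"identical", "reversed", "rearranged", "partial_overlap",
#'   "disjoint"`.
#' @export
compare_arrangement <- function(cluster_a, cluster_b, family_map = NULL) {
  fam_of <- function(cl) {
    if ("family" %in% names(cl)) return(cl$family)
    if (!is.null(family_map)) return(unname(family_map[cl$id]))
    mirna_family(cl$id)
  }
  seq_of <- function(cl) fam_of(cl)[order(cl$start)]
  fa <- seq_of(cluster_a)
  fb <- seq_of(cluster_b)
  sa <- if ("strand" %in% names(cluster_a)) cluster_a$strand[1] else "+"
  sb <- if ("strand" %in% names(cluster_b)) cluster_b$strand[1] else "+"
  if (sa != sb) fb <- rev(fb)  # read both 5' -> 3'
  shared <- intersect(fa, fb)
  if (length(shared) == 0L) return("disjoint")
  covers_a <- all(fa %in% shared)
  covers_b <- all(fb %in% shared)
  if (!covers_a && !covers_b) return("partial_overlap")
  pa <- fa[fa %in% shared]
  pb <- fb[fb %in% shared]
  if (identical(pa, pb)) return("identical")
  if (identical(pa, rev(pb))) return("reversed")
  "rearranged"
}
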