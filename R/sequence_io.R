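#' Read a genome from FASTA
#'
#' Scaffolds are returned as an uppercase DNA [Biostrings::DNAStringSet] with U
#' normalized to T and input order preserved. Scaffold names must be unique and
#' sequences non-empty.
#'
#' @param path path to a FASTA file.
#' @return a named `DNAStringSet` of scaffolds.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty genome FASTA: ", path)
  nm <- sub("\\s.*$", "", names(raw))
  if (any(nm == "")) stop("scaffold with empty name in ", path)
  if (anyDuplicated(nm)) {
    stop("duplicate scaffold name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  nd <- normalize_dna(as.character(raw))
  if (!all(nd$ok)) {
    stop("non-nucleotide characters in scaffold(s): ",
         paste(nm[!nd$ok], collapse = ", "))
  }
  if (any(nchar(nd$seq) == 0L)) stop("zero-length scaffold in ", path)
  out <- Biostrings::DNAStringSet(nd$seq)
  names(out) <- nm
  out
}

#' Write a genome to FASTA
#'
#' @param genome a named `DNAStringSet` (or named character vector).
#' @param path output FASTA path.
#' @export
write_genome <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(unlist(genome))
  }
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read exon/3'UTR records from GFF3
#'
#' Returns a data.frame of the requested feature types with 1-based inclusive
#' coordinates exactly as in the file. Records whose start exceeds their end are
#' skipped with a warning reporting the skip count; requesting an absent feature
#' type returns an empty frame, not an error. The gene/record identifier is
#' taken from the `ID=` attribute, falling back to `Parent=`.
#'
#' @param path path to a GFF3 file.
#' @param features character vector of feature types to keep
#'   (e.g. `c("exon", "three_prime_UTR")`).
#' @return data.frame with columns `scaffold, start, end, strand, gene_id,
#'   feature`.
#' @export
read_annotation <- function(path, features = c("exon", "three_prime_UTR")) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  empty <- data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      gene_id = character(0), feature = character(0),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad_ncol <- vapply(parts, length, 1L) < 9L
  parts <- parts[!bad_ncol]
  if (length(parts) == 0L) return(empty)
  m <- do.call(rbind, parts)
  keep <- m[, 3L] %in% features
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) return(empty)
  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  bad <- is.na(start) | is.na(end) | start > end
  n_skipped <- sum(bad) + sum(bad_ncol)
  if (n_skipped > 0L) {
    warning("skipped ", n_skipped, " malformed GFF3 record(s) in ", path)
  }
  m <- m[!bad, , drop = FALSE]
  start <- start[!bad]; end <- end[!bad]
  attr_field <- function(attrs, key) {
    has <- grepl(paste0("(^|;)", key, "="), attrs)
    val <- rep(NA_character_, length(attrs))
    val[has] <- sub(paste0("(^|.*;)", key, "=([^;]+).*"), "\\2", attrs[has])
    val
  }
  attr_id <- function(attrs) {
    id <- attr_field(attrs, "ID")
    ifelse(is.na(id), attr_field(attrs, "Parent"), id)
  }
  out <- data.frame(scaffold = m[, 1L], start = start, end = end,
                    strand = m[, 7L],
                    gene_id = if (nrow(m)) attr_id(m[, 9L]) else character(0),
                    feature = m[, 3L], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write exon records to GFF3
#'
#' @param ann data.frame as returned by [read_annotation()].
#' @param path output path.
#' @param source source column value.
#' @export
write_annotation <- function(ann, path, source = "mirstack") {
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                   ann$scaffold, source, ann$feature,
                   as.integer(ann$start), as.integer(ann$end),
                   ann$strand, ann$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read raw small-RNA reads from FASTQ or FASTA
#'
#' Qualities, if present, are discarded (the pipeline operates on called,
#' adapter-trimmed sequences). Reads containing characters outside A/C/G/T/U/N
#' are rejected with a warning. No trimming is performed.
#'
#' @param path FASTQ or FASTA file; format detected from the first record.
#' @return character vector of uppercase DNA read sequences.
#' @export
read_small_rna_reads <- function(path) {
  if (!file.exists(path)) stop("reads file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return(character(0))
  fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
  raw <- Biostrings::readBStringSet(path, format = fmt)
  nd <- normalize_dna(as.character(raw))
  if (any(!nd$ok)) {
    warning("rejected ", sum(!nd$ok),
            " read(s) with non-nucleotide characters in ", path)
  }
  unname(nd$seq[nd$ok])
}

#' Write reads as FASTQ (constant dummy quality)
#'
#' @param reads character vector of read sequences.
#' @param path output path.
#' @param ids optional read identifiers.
#' @export
write_reads_fastq <- function(reads, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read_%d", seq_along(reads))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(reads)) {
    qual <- vapply(nchar(reads), function(n) strrep("I", n), "")
    writeLines(paste0("@", ids, "\n", reads, "\n+\n", qual), con)
  }
  invisible(path)
}

#' Read a library sample sheet
#'
#' Tab-separated with header `library_id  stage  replicate  path`. The
#' (stage, replicate) pairs must be unique; missing replicates are simply
#' absent rows (e.g. an unsequenced library).
#'
#' @param path TSV path.
#' @return data.frame with columns `library_id, stage, replicate, path`.
#' @export
read_sample_sheet <- function(path) {
  ss <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("library_id", "stage", "replicate", "path")
  if (!all(req %in% names(ss))) {
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  }
  ss$replicate <- as.integer(ss$replicate)
  validate_sample_sheet(ss)
  ss[req]
}

validate_sample_sheet <- function(ss) {
  if (nrow(ss) == 0L) stop("sample sheet is empty")
  if (any(ss$replicate < 1L)) stop("replicate numbers must be positive")
  key <- paste(ss$stage, ss$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (stage, replicate) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  if (anyDuplicated(ss$library_id)) stop("duplicate library_id")
  invisible(ss)
}

#' Read a miRBase-style reference FASTA (mature or hairpin)
#'
#' @param path FASTA path.
#' @return named character vector of uppercase DNA sequences (U normalized).
#' @export
read_reference_fasta <- function(path) {
  x <- read_genome(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a named sequence set as FASTA, optionally in RNA alphabet
#'
#' @param seqs named character vector (DNA internally).
#' @param path output path.
#' @param rna report sequences as RNA (mature miRNA convention)?
#' @export
write_fasta <- function(seqs, path, rna = FALSE) {
  s <- if (rna) as_rna(seqs) else seqs
  writeLines(paste0(">", names(seqs), "\n", unname(s)), path)
  invisible(path)
}
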