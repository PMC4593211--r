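#' Counts per million
#'
#' `cpm = count / (column_sum * norm_factor) * 1e6`. With unit normalization
#' factors each column sums to one million.
#'
#' @param counts non-negative count matrix (miRNAs x libraries).
#' @param norm_factors per-column positive factors (default 1).
#' @param use_norm_factors apply the factors?
#' @return real-valued matrix of the same shape.
#' @export
cpm_matrix <- function(counts, norm_factors = NULL, use_norm_factors = TRUE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  cs <- colSums(counts)
  if (any(cs == 0)) stop("zero column sum in count matrix")
  nf <- if (is.null(norm_factors) || !use_norm_factors) {
    rep(1, ncol(counts))
  } else norm_factors
  stopifnot(length(nf) == ncol(counts), all(nf > 0))
  sweep(counts, 2L, cs * nf, "/") * 1e6
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values against an automatically chosen reference column
#' (30 % trim on M, 5 % on A, delta-method precision weights), rescaled to a
#' geometric mean of 1 — the standard compositional normalization for count
#' libraries, via edgeR's implementation. All-zero columns get factor 1 with a
#' warning.
#'
#' @param counts count matrix.
#' @return numeric vector of per-column factors with geometric mean 1.
#' @export
tmm_factors <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) >= 2L)
  zero <- colSums(counts) == 0
  if (any(zero)) {
    warning("all-zero column(s) given factor 1: ",
            paste(colnames(counts)[zero], collapse = ", "))
    nf <- rep(1, ncol(counts))
    if (sum(!zero) >= 2L) {
      nf[!zero] <- edgeR::calcNormFactors(counts[, !zero, drop = FALSE],
                                          method = "TMM")
    }
    return(stats::setNames(nf, colnames(counts)))
  }
  stats::setNames(edgeR::calcNormFactors(counts, method = "TMM"),
                  colnames(counts))
}

#' Pairwise exact test for differential abundance between two stages
#'
#' Counts are scaled to a common effective library size and each miRNA's
#' pooled-count split between the two conditions is tested two-sided under a
#' negative-binomial model with a single common dispersion (edgeR's exact
#' test; `dispersion = 0` gives the binomial/Poisson limit). P-values are
#' BH-adjusted across miRNAs within the contrast; the log2 fold change is
#' computed from normalized stage means with a 0.5 pseudo-count.
#'
#' @param counts count matrix (miRNAs x libraries).
#' @param sample_sheet data.frame `library_id, stage, replicate`.
#' @param stage_a,stage_b the two stages to contrast (fold change is
#'   `stage_a` over `stage_b`).
#' @param dispersion `"auto"` (common dispersion estimated from the data) or a
#'   non-negative number.
#' @param norm_factors optional per-library factors (aligned with
#'   `sample_sheet$library_id`); default TMM.
#' @param fdr_cut significance threshold on the adjusted p-value (default
#'   0.05).
#' @return data.frame `mirna, stage_a, stage_b, log2_fold_change, p_value,
#'   fdr, significant`.
#' @export
exact_test_pair <- function(counts, sample_sheet, stage_a, stage_b,
                            dispersion = "auto", norm_factors = NULL,
                            fdr_cut = 0.05) {
  counts <- as.matrix(counts)
  libs_a <- sample_sheet$library_id[sample_sheet$stage == stage_a]
  libs_b <- sample_sheet$library_id[sample_sheet$stage == stage_b]
  stopifnot(length(libs_a) >= 1L, length(libs_b) >= 1L)
  sub <- counts[, c(libs_a, libs_b), drop = FALSE]
  group <- factor(rep(c("a", "b"), c(length(libs_a), length(libs_b))),
                  levels = c("b", "a"))
  nf <- if (is.null(norm_factors)) {
    tmm_factors(sub)
  } else {
    norm_factors[match(colnames(sub), sample_sheet$library_id)]
  }
  nf <- nf / exp(mean(log(nf)))  # geometric mean 1 within the contrast
  dge <- edgeR::DGEList(counts = sub, group = group, norm.factors = nf)
  if (identical(dispersion, "auto")) {
    dge <- edgeR::estimateCommonDisp(dge)
    disp <- dge$common.dispersion
    if (is.na(disp)) disp <- 0
  } else {
    disp <- as.numeric(dispersion)
  }
  et <- edgeR::exactTest(dge, pair = c("b", "a"), dispersion = disp)
  p <- et$table$PValue
  allzero <- rowSums(sub) == 0
  p[allzero] <- 1
  cp <- cpm_matrix(sub, norm_factors = nf)
  mean_a <- rowMeans(cp[, libs_a, drop = FALSE])
  mean_b <- rowMeans(cp[, libs_b, drop = FALSE])
  lfc <- log2((mean_a + 0.5) / (mean_b + 0.5))
  lfc[allzero] <- 0
  fdr <- p.adjust(p, method = "BH")
  data.frame(mirna = rownames(sub), stage_a = stage_a, stage_b = stage_b,
             log2_fold_change = lfc, p_value = p, fdr = fdr,
             significant = fdr < fdr_cut,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' All pairwise stage contrasts
#'
#' Runs [exact_test_pair()] for every unordered stage pair (10 contrasts for
#' 5 stages) and row-binds the results.
#'
#' @inheritParams exact_test_pair
#' @param contrasts optional 2-column matrix/data.frame of stage pairs;
#'   default all unordered pairs.
#' @return data.frame as in [exact_test_pair()], one block per contrast.
#' @export
exact_test_all_pairs <- function(counts, sample_sheet, dispersion = "auto",
                                 norm_factors = NULL, fdr_cut = 0.05,
                                 contrasts = NULL) {
  stages <- unique(sample_sheet$stage)
  if (is.null(contrasts)) {
    contrasts <- t(utils::combn(stages, 2L))
  }
  res <- lapply(seq_len(nrow(contrasts)), function(i) {
    exact_test_pair(counts, sample_sheet, contrasts[i, 1], contrasts[i, 2],
                    dispersion = dispersion, norm_factors = norm_factors,
                    fdr_cut = fdr_cut)
  })
  do.call(rbind, res)
}

#' Log2-ratio matrix over stage contrasts
#'
#' Stage means are cpm averaged over available replicates; each entry is
#' `log2((mean_a + 0.5) / (mean_b + 0.5))`, so swapping a contrast negates
#' its column.
#'
#' @param counts count matrix.
#' @param sample_sheet data.frame `library_id, stage, replicate`.
#' @param contrasts 2-column matrix of (stage_a, stage_b) pairs.
#' @param norm_factors optional per-library factors.
#' @param pseudo pseudo-count (default 0.5).
#' @return matrix (miRNAs x contrasts) with columns named `a/b`.
#' @export
log2_ratio_matrix <- function(counts, sample_sheet, contrasts,
                              norm_factors = NULL, pseudo = 0.5) {
  counts <- as.matrix(counts)
  cp <- cpm_matrix(counts[, sample_sheet$library_id, drop = FALSE],
                   norm_factors = norm_factors,
                   use_norm_factors = !is.null(norm_factors))
  stage_mean <- function(stg) {
    rowMeans(cp[, sample_sheet$library_id[sample_sheet$stage == stg],
                drop = FALSE])
  }
  out <- vapply(seq_len(nrow(contrasts)), function(i) {
    log2((stage_mean(contrasts[i, 1]) + pseudo) /
           (stage_mean(contrasts[i, 2]) + pseudo))
  }, numeric(nrow(counts)))
  out <- matrix(out, nrow = nrow(counts))
  rownames(out) <- rownames(counts)
  colnames(out) <- paste(contrasts[, 1], contrasts[, 2], sep = "/")
  out
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering of rows with Euclidean distance and complete
#' linkage; deterministic given input order.
#'
#' @param ratio_matrix numeric matrix (e.g. from [log2_ratio_matrix()]).
#' @param k optional number of groups to cut into.
#' @return list with `order` (row order), `merge` (merge tree), `hclust` (the
#'   full object) and, when `k` is given, `groups` (named membership vector).
#' @export
hierarchical_cluster <- function(ratio_matrix, k = NULL) {
  stopifnot(nrow(ratio_matrix) >= 2L)
  hc <- stats::hclust(stats::dist(ratio_matrix, method = "euclidean"),
                      method = "complete")
  out <- list(order = hc$order, merge = hc$merge, hclust = hc)
  if (!is.null(k)) out$groups <- stats::cutree(hc, k = k)
  out
}

#' Cross-species Spearman correlation grid
#'
#' For every pair of one species-A and one species-B library, the Spearman
#' rank correlation of ortholog-paired cpm values, with a two-sided p-value
#' from the t approximation. Cells with fewer than `min_pairs` ortholog pairs
#' carry `rho = NA` and `insufficient = TRUE`.
#'
#' @param cpm_a,cpm_b cpm matrices for species A and B (rows named by miRNA
#'   id, columns by library).
#' @param orthologs data.frame `species_a_id, species_b_id`.
#' @param min_pairs minimum ortholog pairs per cell (default 5).
#' @return data.frame `library_a, library_b, rho, p_value, n_pairs,
#'   insufficient`.
#' @export
spearman_matrix <- function(cpm_a, cpm_b, orthologs, min_pairs = 5L) {
  keep <- orthologs$species_a_id %in% rownames(cpm_a) &
    orthologs$species_b_id %in% rownames(cpm_b)
  orth <- orthologs[keep, , drop = FALSE]
  out <- list()
  for (la in colnames(cpm_a)) for (lb in colnames(cpm_b)) {
    x <- cpm_a[orth$species_a_id, la]
    y <- cpm_b[orth$species_b_id, lb]
    n <- length(x)
    if (n < min_pairs) {
      out <- c(out, list(data.frame(library_a = la, library_b = lb,
                                    rho = NA_real_, p_value = NA_real_,
                                    n_pairs = n, insufficient = TRUE)))
      next
    }
    rho <- stats::cor(x, y, method = "spearman")
    p <- if (abs(rho) >= 1) 0 else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tstat), df = n - 2)
    }
    out <- c(out, list(data.frame(library_a = la, library_b = lb,
                                  rho = rho, p_value = p, n_pairs = n,
                                  insufficient = FALSE)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Quantify miRNA expression from alignments
#'
#' Per miRNA and library, sums the counts of collapsed reads whose best
#' alignment overlaps the miRNA's mature interval on the same strand.
#'
#' @param alignments data.frame from [map_collapsed_reads()].
#' @param collapsed collapsed-read frame with per-library count columns.
#' @param mirnas data.frame with `id, scaffold, strand, mature_start,
#'   mature_end`.
#' @param libraries library column names in `collapsed`.
#' @return count matrix (miRNAs x libraries).
#' @export
quantify_mirnas <- function(alignments, collapsed, mirnas, libraries) {
  m <- matrix(0L, nrow = nrow(mirnas), ncol = length(libraries),
              dimnames = list(mirnas$id, libraries))
  if (nrow(alignments) == 0L) return(m)
  aend <- alignments$start + nchar(alignments$sequence) - 1L
  idx <- match(alignments$sequence, collapsed$sequence)
  for (i in seq_len(nrow(mirnas))) {
    sel <- which(alignments$scaffold == mirnas$scaffold[i] &
                   alignments$strand == mirnas$strand[i] &
                   alignments$start <= mirnas$mature_end[i] &
                   aend >= mirnas$mature_start[i])
    if (length(sel)) {
      cc <- collapsed[idx[sel], libraries, drop = FALSE]
      m[i, ] <- as.integer(round(colSums(as.matrix(cc))))
    }
  }
  m
}
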