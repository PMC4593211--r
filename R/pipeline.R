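#' Default pipeline configuration
#'
#' One flat list holding every stage's thresholds at its conventional value:
#' 17 nt length cutoff, 18 nt exact seed with up to 2 tail mismatches and a
#' 5-hit multiplicity cap, stack excision with 70 nt flanks, -50 hard drop and
#' >2 reporting score, word-16 homology with the 1-mismatch/2-nt near-perfect
#' rule and 8-base hairpin slack, 10 kb cluster gap, FDR 0.05, and target
#' gates 155 / -7 / -8.
#'
#' @param seed integer seed driving the simulation and shuffle tests.
#' @param out_dir directory for stage artifacts.
#' @param ... overrides for any config entry (unknown keys are an error).
#' @return a `mirstack_config` list.
#' @export
default_config <- function(seed = 1L, out_dir = file.path("results",
                                                          "pipeline"), ...) {
  cfg <- list(
    seed = as.integer(seed), out_dir = out_dir,
    min_len = 17L, seed_len = 18L, max_tail_mismatch = 2L, max_hits = 5L,
    index_word = 18L,
    min_stack = 5L, flank_up = 70L, flank_down = 70L, n_shuffles = 99L,
    min_score = -50, report_score = 2,
    word = 16L, hairpin_min_score = 40L, hairpin_len_slack = 8L,
    min_total_count = 10L,
    max_gap = 10000L,
    fdr = 0.05, dispersion = "auto",
    target_score_cut = 155, target_energy_cut = -7, target_gap = -8,
    sim = sim_config(seed = as.integer(seed))
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "mirstack_config")
}

config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

artifact_path <- function(config, name) file.path(config$out_dir, name)

write_stage_tsv <- function(df, path, stage, config) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mirstack %s; stage=%s; seed=%d; config=%s",
                     as.character(utils::packageVersion("mirstack")), stage,
                     config$seed, config_hash(config)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline TSV artifact (provenance comments skipped)
#'
#' @param path artifact path.
#' @return data.frame.
#' @export
read_stage_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

need_artifact <- function(config, name, producer) {
  p <- artifact_path(config, name)
  if (!file.exists(p)) {
    stop("missing artifact '", name, "': run stage '", producer, "' first")
  }
  p
}

pipeline_stages <- c("simulate", "preprocess", "map", "discover", "homology",
                     "triage", "express", "clusters", "targets",
                     "crossspecies")

stage_outputs <- list(
  simulate = c("genome.fa", "annotation.gff3", "sample_sheet.tsv",
               "truth_mirnas.tsv", "expected_counts.tsv", "mature_db.fa",
               "hairpin_db.fa", "expr_b.tsv"),
  preprocess = c("collapsed_reads.tsv", "library_summary.tsv"),
  map = c("alignments.tsv", "mapping_summary.tsv"),
  discover = "candidates.tsv",
  homology = "homology.tsv",
  triage = c("novel_triage.tsv", "novel_mirnas.fa"),
  express = c("counts.tsv", "de_results.tsv", "log2_ratios.tsv",
              "cluster_order.txt"),
  clusters = "clusters.tsv",
  targets = "targets.tsv",
  crossspecies = c("orthologs.tsv", "spearman_grid.tsv")
)

#' Run the analysis pipeline
#'
#' Orchestrates all stages over a single configuration, writing TSV artifacts
#' with a provenance header (package version, stage, seed, config hash) so two
#' runs with the same config and seed are byte-identical. `stage = "all"` runs
#' every stage in order, skipping stages whose outputs already exist (delete a
#' downstream file to regenerate just it); a single stage errors with the name
#' of the producing stage when its inputs are missing.
#'
#' @param stage one of `"all"`, `"simulate"`, `"preprocess"`, `"map"`,
#'   `"discover"`, `"homology"`, `"triage"`, `"express"`, `"clusters"`,
#'   `"targets"`, `"crossspecies"`.
#' @param config a [default_config()].
#' @param quiet suppress progress messages?
#' @return invisibly, the vector of artifact paths the stage(s) wrote.
#' @export
run_pipeline <- function(stage = "all", config = default_config(),
                         quiet = FALSE) {
  stopifnot(inherits(config, "mirstack_config"))
  stage <- match.arg(stage, c("all", pipeline_stages))
  log_msg <- function(...) if (!quiet) message("[mirstack] ", ...)
  if (stage == "all") {
    written <- character(0)
    for (st in pipeline_stages) {
      outs <- file.path(config$out_dir, stage_outputs[[st]])
      if (all(file.exists(outs))) {
        log_msg("stage ", st, ": outputs exist, skipping")
        next
      }
      written <- c(written, run_pipeline(st, config, quiet = quiet))
    }
    return(invisible(written))
  }
  log_msg("running stage ", st <- stage)
  fn <- get(paste0("stage_", stage), mode = "function")
  out <- fn(config)
  invisible(out)
}

stage_simulate <- function(config) {
  sim <- simulate_genome(config$sim)
  libs <- simulate_libraries(sim, config$sim, reads = TRUE)
  dbs <- make_reference_dbs(sim, config$sim)
  od <- config$out_dir
  dir.create(file.path(od, "reads"), showWarnings = FALSE, recursive = TRUE)
  write_genome(sim$genome, artifact_path(config, "genome.fa"))
  write_annotation(sim$annotation, artifact_path(config, "annotation.gff3"))
  ss <- libs$sample_sheet
  ss$path <- file.path("reads", paste0(ss$library_id, ".fastq"))
  for (i in seq_len(nrow(ss))) {
    write_reads_fastq(libs$reads[[ss$library_id[i]]],
                      file.path(od, ss$path[i]))
  }
  write_stage_tsv(ss, artifact_path(config, "sample_sheet.tsv"),
                  "simulate", config)
  write_stage_tsv(libs$truth, artifact_path(config, "truth_mirnas.tsv"),
                  "simulate", config)
  cnt <- data.frame(id = rownames(libs$counts), libs$counts,
                    check.names = FALSE)
  write_stage_tsv(cnt, artifact_path(config, "expected_counts.tsv"),
                  "simulate", config)
  write_fasta(dbs$mature_db, artifact_path(config, "mature_db.fa"))
  write_fasta(dbs$hairpin_db, artifact_path(config, "hairpin_db.fa"))
  eb <- data.frame(id = rownames(dbs$expr_b), dbs$expr_b, check.names = FALSE)
  write_stage_tsv(eb, artifact_path(config, "expr_b.tsv"), "simulate", config)
  write_stage_tsv(dbs$orthologs,
                  artifact_path(config, "orthologs_truth.tsv"),
                  "simulate", config)
  file.path(config$out_dir, stage_outputs$simulate)
}

stage_preprocess <- function(config) {
  ssp <- need_artifact(config, "sample_sheet.tsv", "simulate")
  ss <- read_stage_tsv(ssp)
  reads <- lapply(seq_len(nrow(ss)), function(i) {
    read_small_rna_reads(file.path(config$out_dir, ss$path[i]))
  })
  names(reads) <- ss$library_id
  fc <- filter_and_collapse(reads, min_len = config$min_len)
  write_stage_tsv(fc$collapsed, artifact_path(config, "collapsed_reads.tsv"),
                  "preprocess", config)
  write_stage_tsv(fc$summary, artifact_path(config, "library_summary.tsv"),
                  "preprocess", config)
  file.path(config$out_dir, stage_outputs$preprocess)
}

stage_map <- function(config) {
  genome <- read_genome(need_artifact(config, "genome.fa", "simulate"))
  collapsed <- read_stage_tsv(need_artifact(config, "collapsed_reads.tsv",
                                            "preprocess"))
  summary <- read_stage_tsv(need_artifact(config, "library_summary.tsv",
                                          "preprocess"))
  idx <- build_index(genome, word = config$index_word)
  mp <- map_collapsed_reads(collapsed, idx, seed_len = config$seed_len,
                            max_tail_mismatch = config$max_tail_mismatch,
                            max_hits = config$max_hits)
  write_stage_tsv(mp$alignments, artifact_path(config, "alignments.tsv"),
                  "map", config)
  libs <- setdiff(colnames(collapsed), c("sequence", "total_count"))
  mapped <- collapsed$sequence %in% mp$alignments$sequence
  summary$unique_mapped <- vapply(libs, function(l) {
    sum(collapsed[[l]][mapped] > 0)
  }, 1L)[match(summary$library_id, libs)]
  summary$reads_mapped <- vapply(libs, function(l) {
    sum(collapsed[[l]][mapped])
  }, 1L)[match(summary$library_id, libs)]
  write_stage_tsv(summary, artifact_path(config, "mapping_summary.tsv"),
                  "map", config)
  file.path(config$out_dir, stage_outputs$map)
}

stage_discover <- function(config) {
  genome <- read_genome(need_artifact(config, "genome.fa", "simulate"))
  collapsed <- read_stage_tsv(need_artifact(config, "collapsed_reads.tsv",
                                            "preprocess"))
  alignments <- read_stage_tsv(need_artifact(config, "alignments.tsv", "map"))
  ann <- read_annotation(need_artifact(config, "annotation.gff3", "simulate"))
  wins <- excise_candidates(alignments, genome, collapsed,
                            min_stack = config$min_stack,
                            flank_up = config$flank_up,
                            flank_down = config$flank_down)
  cand <- hairpin_candidates(wins, alignments, collapsed, genome,
                             n_shuffles = config$n_shuffles,
                             seed = config$seed,
                             min_score = config$min_score,
                             report_score = config$report_score)
  if (nrow(cand)) {
    ov <- lapply(seq_len(nrow(cand)), function(i) {
      classify_exon_overlap(cand$scaffold[i], cand$start[i], cand$end[i], ann)
    })
    cand$exon_overlap <- vapply(ov, `[[`, "", "category")
    cand$exon_gene <- vapply(ov, `[[`, "", "gene_id")
  }
  write_stage_tsv(cand, artifact_path(config, "candidates.tsv"),
                  "discover", config)
  file.path(config$out_dir, stage_outputs$discover)
}

stage_homology <- function(config) {
  cand <- read_stage_tsv(need_artifact(config, "candidates.tsv", "discover"))
  mature_db <- read_reference_fasta(need_artifact(config, "mature_db.fa",
                                                  "simulate"))
  hairpin_db <- read_reference_fasta(need_artifact(config, "hairpin_db.fa",
                                                   "simulate"))
  cand <- cand[cand$reported, , drop = FALSE]
  lab <- classify_candidates(cand, mature_db, hairpin_db, word = config$word)
  write_stage_tsv(lab, artifact_path(config, "homology.tsv"),
                  "homology", config)
  file.path(config$out_dir, stage_outputs$homology)
}

pipeline_count_matrix <- function(config) {
  cand <- read_stage_tsv(need_artifact(config, "candidates.tsv", "discover"))
  cand <- cand[cand$reported, , drop = FALSE]
  collapsed <- read_stage_tsv(need_artifact(config, "collapsed_reads.tsv",
                                            "preprocess"))
  alignments <- read_stage_tsv(need_artifact(config, "alignments.tsv", "map"))
  ss <- read_stage_tsv(need_artifact(config, "sample_sheet.tsv", "simulate"))
  counts <- quantify_mirnas(alignments, collapsed, cand, ss$library_id)
  list(counts = counts, candidates = cand, sample_sheet = ss)
}

stage_triage <- function(config) {
  lab <- read_stage_tsv(need_artifact(config, "homology.tsv", "homology"))
  q <- pipeline_count_matrix(config)
  novel <- q$candidates[q$candidates$id %in%
                          lab$id[lab$label == "novel_candidate"], ,
                        drop = FALSE]
  novel$hairpin_ok <- novel$shuffle_p <= 0.05
  pres <- build_presence(q$counts[novel$id, , drop = FALSE], q$sample_sheet)
  rep <- triage_report(pres, novel, min_total_count = config$min_total_count)
  out <- merge(rep$verdicts, novel[c("id", "scaffold", "start", "end",
                                     "strand", "mature_count", "star_count")],
               by = "id", sort = TRUE)
  write_stage_tsv(out, artifact_path(config, "novel_triage.tsv"),
                  "triage", config)
  acc <- rep$verdicts$id[rep$verdicts$decision == "accept"]
  seqs <- stats::setNames(as_dna(novel$mature_seq[match(acc, novel$id)]), acc)
  write_fasta(seqs, artifact_path(config, "novel_mirnas.fa"), rna = TRUE)
  file.path(config$out_dir, stage_outputs$triage)
}

stage_express <- function(config) {
  q <- pipeline_count_matrix(config)
  counts <- q$counts
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  write_stage_tsv(data.frame(id = rownames(counts), counts,
                             check.names = FALSE),
                  artifact_path(config, "counts.tsv"), "express", config)
  nf <- tmm_factors(counts)
  de <- exact_test_all_pairs(counts, q$sample_sheet,
                             dispersion = config$dispersion,
                             norm_factors = nf, fdr_cut = config$fdr)
  write_stage_tsv(de, artifact_path(config, "de_results.tsv"),
                  "express", config)
  stages <- unique(q$sample_sheet$stage)
  contrasts <- cbind(stages[-1], stages[1])
  lr <- log2_ratio_matrix(counts, q$sample_sheet, contrasts,
                          norm_factors = nf)
  write_stage_tsv(data.frame(id = rownames(lr), lr, check.names = FALSE),
                  artifact_path(config, "log2_ratios.tsv"),
                  "express", config)
  ord <- if (nrow(lr) >= 2L) hierarchical_cluster(lr)$order else seq_len(nrow(lr))
  writeLines(rownames(lr)[ord],
             artifact_path(config, "cluster_order.txt"))
  file.path(config$out_dir, stage_outputs$express)
}

stage_clusters <- function(config) {
  cand <- read_stage_tsv(need_artifact(config, "candidates.tsv", "discover"))
  cand <- cand[cand$reported, , drop = FALSE]
  det <- detect_clusters(cand[c("id", "scaffold", "start", "end", "strand")],
                         max_gap = config$max_gap)
  out <- merge(det$members, cand[c("id", "mature_seq", "mature_count")],
               by = "id", sort = FALSE)
  out <- out[order(out$scaffold, out$start), , drop = FALSE]
  write_stage_tsv(out, artifact_path(config, "clusters.tsv"),
                  "clusters", config)
  file.path(config$out_dir, stage_outputs$clusters)
}

stage_targets <- function(config) {
  genome <- read_genome(need_artifact(config, "genome.fa", "simulate"))
  ann <- read_annotation(need_artifact(config, "annotation.gff3", "simulate"))
  cand <- read_stage_tsv(need_artifact(config, "candidates.tsv", "discover"))
  cand <- cand[cand$reported & !is.na(cand$mature_seq), , drop = FALSE]
  utrs <- extract_utrs(ann, genome)
  mir <- stats::setNames(as_dna(cand$mature_seq), cand$id)
  mir <- mir[nchar(mir) >= 17 & nchar(mir) <= 28]
  tg <- if (length(utrs) && length(mir)) {
    scan_targets(mir, utrs, score_cut = config$target_score_cut,
                 energy_cut = config$target_energy_cut,
                 gap = config$target_gap)
  } else {
    data.frame(mirna_id = character(0), transcript_id = character(0),
               utr_start = integer(0), utr_end = integer(0),
               pairing_score = numeric(0), energy_proxy = numeric(0),
               seed_match = character(0))
  }
  write_stage_tsv(tg, artifact_path(config, "targets.tsv"),
                  "targets", config)
  file.path(config$out_dir, stage_outputs$targets)
}

stage_crossspecies <- function(config) {
  cand <- read_stage_tsv(need_artifact(config, "candidates.tsv", "discover"))
  cand <- cand[cand$reported, , drop = FALSE]
  hairpin_db <- read_reference_fasta(need_artifact(config, "hairpin_db.fa",
                                                   "simulate"))
  q <- pipeline_count_matrix(config)
  hp_a <- stats::setNames(as_dna(cand$precursor_seq), cand$id)
  orth <- reciprocal_best_hits(hp_a, hairpin_db,
                               word = config$word,
                               min_score = config$hairpin_min_score)
  write_stage_tsv(orth, artifact_path(config, "orthologs.tsv"),
                  "crossspecies", config)
  eb <- read_stage_tsv(need_artifact(config, "expr_b.tsv", "simulate"))
  expr_b <- as.matrix(eb[, -1, drop = FALSE])
  rownames(expr_b) <- eb$id
  counts <- q$counts[rowSums(q$counts) > 0, , drop = FALSE]
  grid <- if (nrow(orth) >= 5L && nrow(counts) >= 5L) {
    spearman_matrix(cpm_matrix(counts), expr_b, orth)
  } else {
    data.frame(library_a = character(0), library_b = character(0),
               rho = numeric(0), p_value = numeric(0), n_pairs = integer(0),
               insufficient = logical(0))
  }
  write_stage_tsv(grid, artifact_path(config, "spearman_grid.tsv"),
                  "crossspecies", config)
  file.path(config$out_dir, stage_outputs$crossspecies)
}
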