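#' Build a presence matrix for triage
#'
#' Presence is count > 0. Missing libraries (e.g. an unsequenced replicate)
#' are simply absent from the sample sheet and shrink "all libraries"
#' denominators rather than counting as absences.
#'
#' @param counts matrix (candidates x libraries) of counts; column names must
#'   match `sample_sheet$library_id`.
#' @param sample_sheet data.frame with `library_id, stage, replicate`.
#' @return list with `counts`, `presence` (logical matrix), `sample_sheet`,
#'   and per-candidate `flags` (data.frame: `id, present_in_all_libraries,
#'   n_libraries_detected, n_replicates_detected, stages_absent`).
#' @export
build_presence <- function(counts, sample_sheet) {
  stopifnot(is.matrix(counts))
  if (!all(sample_sheet$library_id %in% colnames(counts))) {
    stop("count table lacks columns for libraries: ",
         paste(setdiff(sample_sheet$library_id, colnames(counts)),
               collapse = ", "))
  }
  counts <- counts[, sample_sheet$library_id, drop = FALSE]
  presence <- counts > 0
  stages <- unique(sample_sheet$stage)
  stages_absent <- apply(presence, 1L, function(pr) {
    ab <- stages[vapply(stages, function(st) {
      !any(pr[sample_sheet$stage == st])
    }, TRUE)]
    paste(ab, collapse = ",")
  })
  flags <- data.frame(
    id = rownames(counts),
    present_in_all_libraries = apply(presence, 1L, all),
    n_libraries_detected = rowSums(presence),
    n_replicates_detected = rowSums(presence),
    stages_absent = stages_absent,
    stringsAsFactors = FALSE
  )
  rownames(flags) <- NULL
  list(counts = counts, presence = presence, sample_sheet = sample_sheet,
       flags = flags)
}

#' Triage one novel-miRNA candidate
#'
#' Decision tree over stage/replicate presence, star-read evidence and hairpin
#' quality, evaluated in order:
#' \describe{
#'   \item{R1_all_libraries}{present in every sequenced library: accept.}
#'   \item{R2_one_missing_replicate}{absent in exactly one replicate of
#'     exactly one stage, present everywhere else: accept.}
#'   \item{R3_stage_restricted_pass}{present in at least 2 stages with at
#'     least 2 detected replicates each while absent in one or more whole
#'     stages: accept, unless the total count is below `min_total_count` or no
#'     star reads were seen (R3a_low_count_or_no_star), or the hairpin is
#'     malformed (R3b_bad_hairpin).}
#'   \item{R4_single_replicate}{detected in only one replicate of a single
#'     stage (and any presence pattern matching no other rule): reject.}
#'   \item{R5_star_dominant}{an accept-path candidate whose mature count does
#'     not exceed its star count is rejected.}
#' }
#'
#' @param presence logical vector over sequenced libraries, named by
#'   library_id and aligned with `sample_sheet`.
#' @param sample_sheet data.frame with `library_id, stage, replicate` for the
#'   sequenced libraries.
#' @param total_count candidate's summed read count.
#' @param mature_count,star_count mature and star read counts.
#' @param hairpin_ok does the hairpin look like a canonical precursor?
#' @param min_total_count low-count threshold for R3a (default 10).
#' @return list `decision` ("accept"/"reject"), `rule_fired`, `notes`.
#' @export
triage <- function(presence, sample_sheet, total_count, mature_count,
                   star_count, hairpin_ok = TRUE, min_total_count = 10L) {
  stopifnot(length(presence) == nrow(sample_sheet))
  st <- sample_sheet$stage
  stages <- unique(st)
  per_stage_present <- vapply(stages, function(s) sum(presence[st == s]), 1L)
  per_stage_total <- vapply(stages, function(s) sum(st == s), 1L)
  guard <- function(decision, rule, notes = "") {
    if (decision == "accept" && mature_count <= star_count) {
      list(decision = "reject", rule_fired = "R5_star_dominant",
           notes = "accept path but mature count not dominant over star")
    } else {
      list(decision = decision, rule_fired = rule, notes = notes)
    }
  }
  if (all(presence)) {
    return(guard("accept", "R1_all_libraries",
                 "present in every sequenced library"))
  }
  n_absent <- sum(!presence)
  stages_with_absence <- stages[per_stage_present < per_stage_total]
  if (n_absent == 1L && length(stages_with_absence) == 1L) {
    return(guard("accept", "R2_one_missing_replicate",
                 paste0("absent only in one replicate of ",
                        stages_with_absence)))
  }
  whole_stages_absent <- stages[per_stage_present == 0L]
  stages_2rep <- stages[per_stage_present >= 2L]
  if (length(whole_stages_absent) >= 1L && length(stages_2rep) >= 2L) {
    if (total_count < min_total_count || star_count == 0L) {
      return(list(decision = "reject", rule_fired = "R3a_low_count_or_no_star",
                  notes = "stage-restricted but low count and/or no star reads"))
    }
    if (!hairpin_ok) {
      return(list(decision = "reject", rule_fired = "R3b_bad_hairpin",
                  notes = "stage-restricted but unusual secondary structure"))
    }
    return(guard("accept", "R3_stage_restricted_pass",
                 paste0("absent in stage(s) ",
                        paste(whole_stages_absent, collapse = ","),
                        ", consistent elsewhere")))
  }
  list(decision = "reject", rule_fired = "R4_single_replicate",
       notes = "insufficient breadth across replicates/stages")
}

#' Triage all novel candidates and build the report table
#'
#' Runs [triage()] per candidate and emits a per-candidate verdict plus a
#' novel-miRNA summary table (genomic location, total read count, consensus
#' mature sequence reported as RNA, per-stage presence).
#'
#' @param presence_obj result of [build_presence()].
#' @param candidates data.frame with per-candidate columns `id, mature_count,
#'   star_count` and optionally `hairpin_ok` (default TRUE), `scaffold, start,
#'   end, strand, mature_seq`.
#' @param min_total_count forwarded to [triage()].
#' @return list with `verdicts` (id, decision, rule_fired, notes) and `table`
#'   (accepted candidates in a publication-style layout).
#' @export
triage_report <- function(presence_obj, candidates, min_total_count = 10L) {
  ss <- presence_obj$sample_sheet
  stages <- unique(ss$stage)
  n <- nrow(candidates)
  verdicts <- data.frame(id = candidates$id,
                         decision = character(n), rule_fired = character(n),
                         notes = character(n), stringsAsFactors = FALSE)
  if (n == 0L) {
    return(list(verdicts = verdicts,
                table = data.frame(id = character(0))))
  }
  hk <- if ("hairpin_ok" %in% names(candidates)) candidates$hairpin_ok
        else rep(TRUE, n)
  for (i in seq_len(n)) {
    row <- match(candidates$id[i], rownames(presence_obj$counts))
    if (is.na(row)) stop("candidate absent from count table: ",
                         candidates$id[i])
    pr <- presence_obj$presence[row, ]
    v <- triage(pr, ss, total_count = sum(presence_obj$counts[row, ]),
                mature_count = candidates$mature_count[i],
                star_count = candidates$star_count[i],
                hairpin_ok = hk[i], min_total_count = min_total_count)
    verdicts$decision[i] <- v$decision
    verdicts$rule_fired[i] <- v$rule_fired
    verdicts$notes[i] <- v$notes
  }
  acc <- which(verdicts$decision == "accept")
  tab <- data.frame(id = candidates$id[acc], stringsAsFactors = FALSE)
  if ("scaffold" %in% names(candidates)) {
    tab$genomic_location <- sprintf("%s:%s..%s(%s)",
                                    candidates$scaffold[acc],
                                    candidates$start[acc],
                                    candidates$end[acc],
                                    candidates$strand[acc])
  }
  rows <- match(candidates$id[acc], rownames(presence_obj$counts))
  tab$total_read_count <- rowSums(presence_obj$counts[rows, , drop = FALSE])
  if ("mature_seq" %in% names(candidates)) {
    tab$consensus_mature_sequence <- as_rna(candidates$mature_seq[acc])
  }
  for (stg in stages) {
    lib <- ss$library_id[ss$stage == stg]
    tab[[stg]] <- ifelse(rowSums(
      presence_obj$presence[rows, lib, drop = FALSE]) > 0, "yes", "no")
  }
  rownames(tab) <- NULL
  list(verdicts = verdicts, table = tab)
}
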