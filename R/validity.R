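#' Questionnaire validity rules
#'
#' The three screening rules applied to each respondent: (1) completion
#' time at least `min_minutes`; (2) the repeated consistency task answered
#' identically to its original; (3) a respondent failing (2) but passing
#' (1) is rescued when their SMART importance rankings are logically
#' aligned with their SMART scores.
#'
#' @param min_minutes Minimum completion time in minutes (compared as
#'   `>=`; sub-minute precision is preserved).
#' @param consistency_required Apply rule (2).
#' @param smart_alignment_fallback Apply rule (3) as a fallback for
#'   respondents failing rule (2).
#' @return A `dce_validity_rules` list.
#' @export
validity_rules <- function(min_minutes = 8, consistency_required = TRUE,
                           smart_alignment_fallback = TRUE) {
  if (min_minutes <= 0) stop("min_minutes must be positive", call. = FALSE)
  structure(list(min_minutes = min_minutes,
                 consistency_required = consistency_required,
                 smart_alignment_fallback = smart_alignment_fallback),
            class = "dce_validity_rules")
}

#' Internal-consistency check for one respondent
#'
#' `TRUE` iff the chosen alternative on the repeated consistency task is
#' identical to the choice on its original presentation.
#'
#' @param record A respondent's choices: tibble with `position`, `choice`
#'   (and optionally `is_repeat`).
#' @param questionnaire The `dce_questionnaire` the respondent answered.
#' @return Logical flag.
#' @export
check_consistency <- function(record, questionnaire) {
  pair <- questionnaire$consistency_pair
  if (is.null(pair)) stop("questionnaire has no consistency pair", call. = FALSE)
  orig <- record$choice[record$position == pair[["original"]]]
  rep_ <- record$choice[record$position == pair[["repeated"]]]
  if (length(orig) != 1 || length(rep_) != 1) {
    stop("record does not cover the consistency pair", call. = FALSE)
  }
  orig == rep_
}

#' SMART rank/score alignment check
#'
#' `TRUE` iff the respondent's attribute importance ranking is logically
#' aligned with their importance scores: for every pair of attributes, a
#' strictly higher score implies a strictly better (smaller) rank. Tied
#' scores impose no constraint. Equivalently, scores sorted by rank must be
#' non-increasing.
#'
#' @param scores Numeric importance scores (0-100), one per attribute.
#' @param ranks Integer ranks, a permutation of `1:length(scores)`.
#' @return Logical flag.
#' @export
check_smart_alignment <- function(scores, ranks) {
  n <- length(scores)
  if (length(ranks) != n || !setequal(ranks, seq_len(n))) {
    stop("ranks must be a permutation of 1..", n, call. = FALSE)
  }
  all(diff(scores[order(ranks)]) <= 0)
}

#' Apply the validity rules to a survey
#'
#' Screens every respondent against [validity_rules()] and returns the
#' valid subset alongside a per-respondent audit table. A respondent is
#' valid iff they pass the time rule and either the consistency rule or
#' (when enabled) the SMART alignment fallback. Verdicts depend only on
#' the respondent's own record, so filtering is idempotent and independent
#' of dataset order.
#'
#' @param survey A `dce_survey` (from [simulate_responses()] or
#'   [ingest_survey()]).
#' @param rules A [validity_rules()].
#' @return A list with `survey` (the filtered `dce_survey`) and `audit`
#'   (tibble: respondent_id, completion_minutes, time_pass,
#'   consistency_pass, smart_pass, valid, reasons). Reason codes:
#'   `TIME_FAIL`, `CONSISTENCY_FAIL`, `SMART_ALIGN_PASS`,
#'   `SMART_ALIGN_FAIL`.
#' @export
filter_survey <- function(survey, rules = validity_rules()) {
  resp <- survey$respondents
  q_by_block <- if (!is.null(survey$questionnaires)) {
    stats::setNames(survey$questionnaires,
                    vapply(survey$questionnaires, function(q) q$block_id, 1))
  } else NULL

  audit <- purrr::map_dfr(seq_len(nrow(resp)), function(i) {
    id <- resp$respondent_id[i]
    time_pass <- resp$completion_minutes[i] >= rules$min_minutes
    rec <- survey$choices[survey$choices$respondent_id == id, ]
    q <- if (!is.null(q_by_block)) q_by_block[[as.character(resp$block_id[i])]] else NULL
    consistency_pass <- if (!rules$consistency_required) {
      TRUE
    } else if (!is.null(q) && !is.null(q$consistency_pair)) {
      check_consistency(rec, q)
    } else {
      ## fall back to matching repeated set ids when the questionnaire
      ## object is unavailable (ingested data)
      rep_rows <- rec[rec$is_repeat, ]
      if (nrow(rep_rows) == 0) TRUE else {
        all(vapply(seq_len(nrow(rep_rows)), function(j) {
          orig <- rec$choice[!rec$is_repeat & rec$set_id == rep_rows$set_id[j]]
          length(orig) == 1 && orig == rep_rows$choice[j]
        }, logical(1)))
      }
    }
    sm <- survey$smart[survey$smart$respondent_id == id, ]
    smart_pass <- if (nrow(sm) > 0) check_smart_alignment(sm$score, sm$rank) else NA
    valid <- time_pass && (consistency_pass ||
                             (rules$smart_alignment_fallback && isTRUE(smart_pass)))
    reasons <- c(
      if (!time_pass) "TIME_FAIL",
      if (!consistency_pass) "CONSISTENCY_FAIL",
      if (!consistency_pass && rules$smart_alignment_fallback && !is.na(smart_pass))
        if (smart_pass) "SMART_ALIGN_PASS" else "SMART_ALIGN_FAIL"
    )
    tibble::tibble(respondent_id = id,
                   completion_minutes = resp$completion_minutes[i],
                   time_pass = time_pass, consistency_pass = consistency_pass,
                   smart_pass = smart_pass, valid = valid,
                   reasons = paste(reasons, collapse = ";"))
  })

  keep <- audit$respondent_id[audit$valid]
  out <- survey
  out$choices <- survey$choices[survey$choices$respondent_id %in% keep, ]
  out$respondents <- resp[resp$respondent_id %in% keep, ]
  out$smart <- survey$smart[survey$smart$respondent_id %in% keep, ]
  attr(out, "filtered") <- TRUE
  list(survey = out, audit = audit)
}

#' Write the validity audit table as CSV
#' @param audit The audit tibble from [filter_survey()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_audit_csv <- function(audit, path) {
  readr::write_csv(audit, path)
  invisible(path)
}
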