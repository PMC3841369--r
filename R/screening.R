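#' Screen a single submission
#'
#' Applies the completeness filter and the 5-question eligibility screen.
#' A record is judged on eligibility only if it is complete: `incomplete`
#' takes precedence over `ineligible`. A complete record is retained iff
#' all five screen answers are affirmative; otherwise it is ineligible
#' and the failing questions are reported (an unanswered screen question
#' on a complete record counts as failing).
#'
#' @param record A one-row submission tibble (or a named list with the
#'   `complete` flag and the five `screen_*` answers).
#' @return A list with `status` (`"incomplete"`, `"ineligible"` or
#'   `"retained"`) and `failed_questions` (character, empty unless
#'   ineligible).
#' @export
#' @examples
#' rec <- list(complete = TRUE, screen_reads_english = TRUE,
#'             screen_writes_english = TRUE, screen_resides_region = FALSE,
#'             screen_parent_child = TRUE,
#'             screen_immunization_decisions = TRUE)
#' screen_record(rec)$status  # "ineligible"
screen_record <- function(record) {
  complete <- isTRUE(record$complete[[1]])
  if (!complete) {
    return(list(status = "incomplete", failed_questions = character()))
  }
  answers <- vapply(screen_columns,
                    function(col) isTRUE(record[[col]][[1]]), logical(1))
  if (all(answers)) {
    list(status = "retained", failed_questions = character())
  } else {
    list(status = "ineligible",
         failed_questions = screen_columns[!answers])
  }
}

#' Screen a cohort of submissions
#'
#' Vectorised screening of a submission table. The partition is exact and
#' disjoint: `incomplete + ineligible + retained == nrow(records)`.
#'
#' @param records Submission tibble.
#' @return A list with:
#'   * `retained` — the retained rows, input order preserved;
#'   * `counts` — list of `incomplete`, `ineligible`, `retained`, `total`;
#'   * `status` — tibble of `submission_id`, `status`.
#' @export
screen_cohort <- function(records) {
  if (nrow(records) == 0) {
    return(list(retained = records,
                counts = list(incomplete = 0L, ineligible = 0L,
                              retained = 0L, total = 0L),
                status = tibble::tibble(submission_id = character(),
                                        status = character())))
  }
  complete <- !is.na(records$complete) & records$complete
  ans <- sapply(screen_columns, function(col) {
    !is.na(records[[col]]) & records[[col]]
  })
  if (is.null(dim(ans))) ans <- matrix(ans, nrow = 1)
  pass <- rowSums(ans) == length(screen_columns)
  status <- ifelse(!complete, "incomplete",
                   ifelse(pass, "retained", "ineligible"))
  counts <- list(
    incomplete = sum(status == "incomplete"),
    ineligible = sum(status == "ineligible"),
    retained   = sum(status == "retained"),
    total      = nrow(records)
  )
  stopifnot(counts$incomplete + counts$ineligible + counts$retained ==
              counts$total)
  list(retained = records[status == "retained", , drop = FALSE],
       counts = counts,
       status = tibble::tibble(submission_id = records$submission_id,
                               status = status))
}

#' Derive a completeness flag when the platform supplies none
#'
#' Operationalisation used when the source export lacks a completeness
#' flag: a record is complete when all five screen answers are present
#' and, if the screen was passed, the demographic block is non-empty
#' (at least one demographic answer given).
#'
#' @param records Submission tibble (the `complete` column is ignored).
#' @return Logical vector.
#' @export
derive_complete <- function(records) {
  screens_present <- rowSums(
    sapply(screen_columns, function(col) !is.na(records[[col]]))
  ) == length(screen_columns)
  screens_pass <- rowSums(
    sapply(screen_columns, function(col) {
      !is.na(records[[col]]) & records[[col]]
    })
  ) == length(screen_columns)
  demo_cols <- c("age_group", "sex", "marital", "ethnicity", "education",
                 "postal_code")
  demo_any <- rowSums(
    sapply(demo_cols, function(col) !is.na(records[[col]]))
  ) > 0
  screens_present & (!screens_pass | demo_any)
}
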