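#' Charge each retained record to its exclusion stage
#'
#' Applies the staged exclusion order: a record is charged to the first
#' stage that removes it. Non-region records go first; among validated
#' records, those whose email key is nonunique over the retained cohort
#' are charged to the email-duplicate stage, then those whose IP is
#' nonunique to the IP-duplicate stage; the remainder are unique
#' eligible. Key nonuniqueness is computed over the whole retained
#' cohort (a duplicate partner excluded at the geography stage still
#' marks a record as a duplicate).
#'
#' @param retained Submission tibble of post-screening records.
#' @param verdicts Output of [classify_geography()] for `retained`.
#' @param email_threshold Variant-email threshold (see
#'   [cluster_submissions()]).
#' @return Tibble `submission_id`, `charge` (one of `non_region`,
#'   `email_dup`, `ip_dup`, `unique_eligible`).
#' @export
charge_exclusions <- function(retained, verdicts, email_threshold = 0) {
  stopifnot(nrow(retained) == nrow(verdicts))
  lk <- record_link_keys(retained, email_threshold)
  charge <- ifelse(!verdicts$validated_in_region, "non_region",
            ifelse(lk$email_nonunique, "email_dup",
            ifelse(lk$ip_nonunique, "ip_dup", "unique_eligible")))
  tibble::tibble(submission_id = retained$submission_id, charge = charge)
}

#' Assemble the staged participant-flow accounting
#'
#' Builds the staged exclusion counts with conservation checks:
#' `retained_after_screen = submitted - incomplete - ineligible_screen`
#' and `unique_eligible = retained_after_screen - excluded_non_region -
#' excluded_email_dup - excluded_ip_dup`. A violated identity raises a
#' hard error naming it. Every derived percentage stores its denominator
#' (stage percentages use mixed denominators by design: the screen
#' stages are out of all submissions, the later stages out of the
#' post-screen total).
#'
#' @param screen_counts `counts` element of [screen_cohort()].
#' @param charges Output of [charge_exclusions()].
#' @return An object of class `flow_counts`: a list of the named stage
#'   counts plus a `stages` tibble (`stage`, `n`, `pct`, `denominator`).
#' @export
build_flow <- function(screen_counts, charges) {
  submitted <- screen_counts$total
  incomplete <- screen_counts$incomplete
  ineligible <- screen_counts$ineligible
  retained <- screen_counts$retained
  if (retained != submitted - incomplete - ineligible) {
    stop("flow identity violated: retained_after_screen != submitted - ",
         "incomplete - ineligible_screen", call. = FALSE)
  }
  if (nrow(charges) != retained) {
    stop("flow identity violated: charged records != retained_after_screen",
         call. = FALSE)
  }
  n_non_region <- sum(charges$charge == "non_region")
  n_email <- sum(charges$charge == "email_dup")
  n_ip <- sum(charges$charge == "ip_dup")
  n_unique <- sum(charges$charge == "unique_eligible")
  if (n_unique != retained - n_non_region - n_email - n_ip) {
    stop("flow identity violated: unique_eligible != retained_after_screen",
         " - exclusions", call. = FALSE)
  }
  stages <- tibble::tibble(
    stage = c("submitted", "incomplete", "ineligible_screen",
              "retained_after_screen", "excluded_non_region",
              "excluded_email_dup", "excluded_ip_dup", "unique_eligible"),
    n = c(submitted, incomplete, ineligible, retained, n_non_region,
          n_email, n_ip, n_unique),
    denominator = c(submitted, submitted, submitted, submitted,
                    retained, retained, retained, retained)
  )
  stages$pct <- ifelse(stages$denominator > 0,
                       100 * stages$n / stages$denominator, NA_real_)
  structure(
    list(submitted = submitted, incomplete = incomplete,
         ineligible_screen = ineligible, retained_after_screen = retained,
         excluded_non_region = n_non_region, excluded_email_dup = n_email,
         excluded_ip_dup = n_ip, unique_eligible = n_unique,
         stages = stages),
    class = "flow_counts"
  )
}

#' Render a participant flow as text or JSON
#'
#' @param flow A `flow_counts` object from [build_flow()].
#' @param format `"text"` or `"json"`.
#' @return Character vector of lines (`"text"`) or a JSON string.
#' @export
render_flow <- function(flow, format = c("text", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    return(jsonlite::toJSON(strip_report(flow), auto_unbox = TRUE,
                            digits = NA))
  }
  st <- flow$stages
  lines <- sprintf("%-22s %5d  (%5.1f%% of %d)",
                   st$stage, st$n, st$pct, st$denominator)
  c("Participant flow", lines)
}

#' @export
print.flow_counts <- function(x, ...) {
  cat(render_flow(x, "text"), sep = "\n")
  invisible(x)
}
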