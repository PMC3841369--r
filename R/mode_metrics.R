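#' Referral uptake per advertising mode and period
#'
#' Tabulates the self-reported referral source of unique eligible
#' participants, with counts and within-period percentages. Sources that
#' cannot be attributed to an advertising mode (friend or family, word
#' of mouth, no answer) are kept as their own rows; missing sources are
#' reported as `"no_answer"`.
#'
#' @param records Submission tibble of unique eligible participants.
#' @param by Grouping column (default `"period"`).
#' @return Tibble with columns `period` (or the chosen grouping),
#'   `referral_source`, `n`, `pct`. Within-group percentages sum to 100
#'   up to rounding.
#' @export
uptake_table <- function(records, by = "period") {
  src <- ifelse(is.na(records$referral_source), "no_answer",
                records$referral_source)
  grp <- records[[by]]
  out <- tibble::tibble(group = grp, referral_source = src) %>%
    dplyr::count(.data$group, .data$referral_source, name = "n") %>%
    dplyr::group_by(.data$group) %>%
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$group, dplyr::desc(.data$n))
  names(out)[names(out) == "group"] <- by
  out
}

# round half away from zero, the bookkeeping convention for efficiency
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Recruitment efficiency of an advertising mode
#'
#' Staff hours invested in a mode divided by the number of unique
#' eligible participants it recruited, rounded half-up to 2 decimals.
#' A mode that recruited nobody has undefined (`NA`) efficiency, with a
#' warning; negative hours are an error.
#'
#' @param mode Mode label(s).
#' @param staff_hours Nonnegative hours per mode.
#' @param unique_eligible_count Nonnegative participant counts per mode.
#' @param uptake Optional free-form uptake annotation (views, likes,
#'   followers), passed through.
#' @return Tibble with columns `mode`, `staff_hours`,
#'   `unique_eligible_count`, `efficiency`, `uptake`.
#' @export
#' @examples
#' efficiency("redflagdeals", 6, 202)   # 0.03 hours per questionnaire
efficiency <- function(mode, staff_hours, unique_eligible_count,
                       uptake = NA_character_) {
  if (any(staff_hours < 0)) stop("staff hours must be nonnegative",
                                 call. = FALSE)
  if (any(unique_eligible_count < 0 |
          unique_eligible_count != floor(unique_eligible_count))) {
    stop("participant counts must be nonnegative integers", call. = FALSE)
  }
  eff <- rep(NA_real_, length(mode))
  ok <- unique_eligible_count > 0
  eff[ok] <- round_half_up(staff_hours[ok] / unique_eligible_count[ok], 2)
  if (any(!ok)) {
    warning("efficiency undefined for mode(s) with zero participants: ",
            paste(mode[!ok], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(mode = mode, staff_hours = staff_hours,
                 unique_eligible_count = unique_eligible_count,
                 efficiency = eff,
                 uptake = rep_len(as.character(uptake), length(mode)))
}

#' Efficiency table from a staff-hours ledger
#'
#' @param ledger Tibble with columns `mode`, `hours`, `participants`, and
#'   optionally `uptake`.
#' @return See [efficiency()].
#' @export
efficiency_table <- function(ledger) {
  stopifnot(all(c("mode", "hours", "participants") %in% names(ledger)))
  efficiency(ledger$mode, ledger$hours, ledger$participants,
             uptake = if ("uptake" %in% names(ledger)) ledger$uptake else
               NA_character_)
}
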