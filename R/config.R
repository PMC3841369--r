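#' Pipeline configuration
#'
#' Bundles the tunable parameters of the submission-screening pipeline:
#' which forward-sortation-area (FSA) letters count as the target region,
#' the injected IP-to-region lookup tables, the interval windows used to
#' profile burst submissions, the demographic variables tracked for
#' missingness, and the entry/exit p-value thresholds of the stepwise
#' logistic regression.
#'
#' The IP lookup is fully injected (a table of CIDR blocks or exact
#' addresses mapped to region labels) so that runs are reproducible and
#' never touch the network. A second, fallback table models a manual
#' reverse lookup consulted only when the primary table yields `unknown`.
#'
#' @param region_prefixes One-letter FSA prefixes defining the target
#'   region. Defaults to the Ontario prefixes `K, L, M, N, P`.
#' @param ip_region_table Tibble with columns `cidr` (an IPv4 CIDR block
#'   such as `"198.51.100.0/24"`, or an exact address) and `region`.
#' @param ip_fallback_table Optional second lookup table, same format,
#'   consulted when the primary lookup is `unknown`.
#' @param target_ip_regions Region labels in the lookup tables treated as
#'   consistent with target-region residence. The country-level label
#'   `"canada"` is accepted alongside `"ontario"` because an IP database
#'   may only resolve the country.
#' @param interval_windows Strictly increasing window bounds in seconds
#'   for the burst interval profile (default 5 minutes, 1 hour, 24 hours).
#' @param missingness_vars Demographic columns summarised for missingness.
#' @param email_threshold Normalised edit-distance threshold for variant
#'   email matching of local parts; 0 keeps only exact local-part matches.
#' @param entry_p,exit_p Stepwise logistic regression entry and exit
#'   p-value thresholds, both in (0, 1).
#' @param seed Integer seed recorded for downstream simulation calls.
#'
#' @return An object of class `pipeline_config` (a named list).
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$region_prefixes
pipeline_config <- function(region_prefixes = c("K", "L", "M", "N", "P"),
                            ip_region_table = default_ip_region_table(),
                            ip_fallback_table = NULL,
                            target_ip_regions = c("ontario", "canada"),
                            interval_windows = c(300, 3600, 86400),
                            missingness_vars = c("postal_code", "education",
                                                 "age_group", "marital",
                                                 "ethnicity"),
                            email_threshold = 0,
                            entry_p = 0.05,
                            exit_p = 0.10,
                            seed = 1L) {
  stopifnot(is.character(region_prefixes), length(region_prefixes) >= 1)
  if (length(interval_windows) < 1 || any(diff(interval_windows) <= 0)) {
    stop("`interval_windows` must be strictly increasing", call. = FALSE)
  }
  if (!(entry_p > 0 && entry_p < 1) || !(exit_p > 0 && exit_p < 1)) {
    stop("`entry_p` and `exit_p` must lie in (0, 1)", call. = FALSE)
  }
  check_ip_table(ip_region_table)
  if (!is.null(ip_fallback_table)) check_ip_table(ip_fallback_table)
  structure(
    list(
      region_prefixes = toupper(region_prefixes),
      ip_region_table = ip_region_table,
      ip_fallback_table = ip_fallback_table,
      target_ip_regions = target_ip_regions,
      interval_windows = as.numeric(interval_windows),
      missingness_vars = missingness_vars,
      email_threshold = email_threshold,
      entry_p = entry_p,
      exit_p = exit_p,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

check_ip_table <- function(tab) {
  if (!is.data.frame(tab) || !all(c("cidr", "region") %in% names(tab))) {
    stop("an IP region table needs columns `cidr` and `region`", call. = FALSE)
  }
  invisible(tab)
}

#' Default synthetic IP-to-region lookup table
#'
#' Maps the documentation/benchmarking IPv4 ranges used by the synthetic
#' cohort generators to region labels. Real addresses never appear in
#' generated data. The table deliberately contains nested blocks (a /15
#' country block refined by /16 and /24 blocks) so that longest-prefix
#' resolution is exercised.
#'
#' @return Tibble with columns `cidr` and `region`.
#' @export
default_ip_region_table <- function() {
  tibble::tribble(
    ~cidr,               ~region,
    "198.18.0.0/15",     "canada",
    "198.18.0.0/16",     "ontario",
    "198.19.0.0/16",     "other_canada",
    "198.19.255.0/24",   "ontario",
    "100.64.0.0/16",     "us",
    "100.65.0.0/16",     "international"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat("  region prefixes: ", paste(x$region_prefixes, collapse = ", "), "\n")
  cat("  IP table entries:", nrow(x$ip_region_table),
      if (!is.null(x$ip_fallback_table)) "(+ fallback)" else "", "\n")
  cat("  interval windows:", paste(x$interval_windows, collapse = ", "), "s\n")
  cat("  missingness vars:", paste(x$missingness_vars, collapse = ", "), "\n")
  cat("  stepwise entry/exit p:", x$entry_p, "/", x$exit_p, "\n")
  invisible(x)
}
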