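#' @name submission-table
#' @title The submission table
#'
#' @description
#' One row per submitted questionnaire. The canonical columns are:
#'
#' * `submission_id` — opaque character id (assigned as 1-based row
#'   numbers when the source has none).
#' * `timestamp` — `POSIXct`, UTC. Inputs without a timezone are assumed
#'   UTC.
#' * `ip` — dotted IPv4 or compressed IPv6 string.
#' * `email` — character or `NA`.
#' * `screen_reads_english`, `screen_writes_english`,
#'   `screen_resides_region`, `screen_parent_child`,
#'   `screen_immunization_decisions` — the five eligibility-screen
#'   answers, logical.
#' * `postal_code` — 6-character Canadian postal code, normalised
#'   (uppercase, internal whitespace stripped), or `NA`.
#' * `age_group` — `"<20"`, `"20-29"`, `"30-39"`, `">=40"` or `NA`.
#' * `sex` — `"female"`, `"male"` or `NA`.
#' * `marital` — `"single"`, `"married"` or `NA`.
#' * `ethnicity` — `"white"`, `"chinese"`, `"south_asian"`,
#'   `"southeast_asian_filipino"`, `"korean_japanese"`, `"mixed"`,
#'   `"other"` or `NA`.
#' * `education` — `"high_school_or_less"`, `"postsecondary"` or `NA`.
#' * `referral_source` — self-reported advertising mode (see
#'   [referral_levels()]).
#' * `completion_seconds` — nonnegative numeric.
#' * `period` — recruitment period, `1` (incentive, no restrictions) or
#'   `2` (no incentive, one submission per IP enforced by the platform).
#' * `complete` — platform completeness flag, logical.
#'
#' Categorical unknowns are stored as `NA` and surfaced as an explicit
#' "missing" level by the summary functions, never dropped.
NULL

submission_columns <- c(
  "submission_id", "timestamp", "ip", "email",
  "screen_reads_english", "screen_writes_english", "screen_resides_region",
  "screen_parent_child", "screen_immunization_decisions",
  "postal_code", "age_group", "sex", "marital", "ethnicity", "education",
  "referral_source", "completion_seconds", "period", "complete"
)

screen_columns <- c(
  "screen_reads_english", "screen_writes_english", "screen_resides_region",
  "screen_parent_child", "screen_immunization_decisions"
)

#' Categorical levels used by the submission schema
#'
#' @return A character vector of levels.
#' @export
age_levels <- function() c("<20", "20-29", "30-39", ">=40")

#' @rdname age_levels
#' @export
ethnicity_levels <- function() {
  c("white", "chinese", "south_asian", "southeast_asian_filipino",
    "korean_japanese", "mixed", "other")
}

#' @rdname age_levels
#' @export
referral_levels <- function() {
  c("redflagdeals", "friend_family", "facebook", "smartcanucks",
    "word_of_mouth", "twitter", "no_answer", "email_list_website",
    "craigslist_kijiji", "mass_media", "other")
}

#' Normalise Canadian postal codes
#'
#' Uppercases and strips all whitespace. Codes that then fail the
#' letter-digit alternation (`A1A1A1`) are returned as `NA` with a
#' warning, never silently coerced.
#'
#' @param x Character vector of raw postal codes.
#' @return Character vector of normalised codes or `NA`.
#' @export
#' @examples
#' normalize_postal_code("n0p 1l0")  # "N0P1L0"
normalize_postal_code <- function(x) {
  out <- toupper(gsub("\\s+", "", as.character(x)))
  out[!nzchar(out)] <- NA_character_
  bad <- !is.na(out) & !grepl("^[A-Z][0-9][A-Z][0-9][A-Z][0-9]$", out)
  if (any(bad)) {
    warning(sum(bad), " postal code(s) failed letter-digit alternation; ",
            "set to missing", call. = FALSE)
    out[bad] <- NA_character_
  }
  out
}

#' Read a submission table
#'
#' Reads a flat table of questionnaire submissions from CSV (RFC-4180,
#' UTF-8, header row) or JSON lines, applies an optional column-name
#' mapping, and coerces every row into the canonical submission schema
#' (see [submission-table]). Unparseable timestamps and postal codes
#' become `NA` with a warning; rows are never dropped, and input order is
#' preserved. Missing mandatory columns (`timestamp`, `ip`, `period`)
#' raise an error naming the column; a missing `submission_id` column is
#' filled with 1-based row numbers.
#'
#' @param path Path to a `.csv` or `.jsonl`/`.ndjson` file.
#' @param config A [pipeline_config()] (reserved for schema options).
#' @param col_map Named character vector or list mapping canonical column
#'   names to source column names, e.g. `c(ip = "IP Address")`. May also
#'   be a path to a YAML or JSON file holding that mapping.
#' @param format `"auto"` (by extension), `"csv"` or `"jsonl"`.
#'
#' @return A tibble in submission-table form, one row per input row.
#' @export
read_submissions <- function(path, config = pipeline_config(),
                             col_map = NULL,
                             format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl|ndjson)$", path)) "jsonl" else "csv"
  }
  raw <- switch(format,
    csv = readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE, show_col_types = FALSE),
    jsonl = {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      dplyr::bind_rows(lapply(lines, function(l) {
        tibble::as_tibble(lapply(jsonlite::fromJSON(l), as.character))
      }))
    }
  )
  col_map <- load_col_map(col_map)
  if (length(col_map)) {
    for (canonical in names(col_map)) {
      src <- col_map[[canonical]]
      if (src %in% names(raw)) names(raw)[names(raw) == src] <- canonical
    }
  }
  for (col in c("timestamp", "ip", "period")) {
    if (!col %in% names(raw)) {
      stop("mandatory column `", col, "` is missing from ", path,
           call. = FALSE)
    }
  }
  as_submission_table(raw)
}

load_col_map <- function(col_map) {
  if (is.null(col_map)) return(list())
  if (is.character(col_map) && length(col_map) == 1 && file.exists(col_map)) {
    col_map <- if (grepl("\\.ya?ml$", col_map)) {
      yaml::read_yaml(col_map)
    } else {
      jsonlite::read_json(col_map, simplifyVector = TRUE)
    }
  }
  as.list(col_map)
}

#' Coerce a raw data frame into the canonical submission table
#'
#' @param raw A data frame with (a subset of) the canonical column names.
#' @return A tibble in submission-table form.
#' @export
as_submission_table <- function(raw) {
  n <- nrow(raw)
  if (!"submission_id" %in% names(raw) || all(is.na(raw[["submission_id"]]))) {
    raw$submission_id <- as.character(seq_len(n))
  }
  missing_cols <- setdiff(submission_columns, names(raw))
  for (col in missing_cols) raw[[col]] <- NA
  ts <- parse_utc_timestamp(raw$timestamp)
  lvl <- function(x, levels) {
    x <- as.character(x)
    x[!is.na(x) & !x %in% levels] <- NA
    x
  }
  out <- tibble::tibble(
    submission_id = as.character(raw$submission_id),
    timestamp = ts,
    ip = as.character(raw$ip),
    email = dplyr::na_if(trimws(as.character(raw$email)), ""),
    postal_code = normalize_postal_code(raw$postal_code),
    age_group = lvl(raw$age_group, age_levels()),
    sex = lvl(raw$sex, c("female", "male")),
    marital = lvl(raw$marital, c("single", "married")),
    ethnicity = lvl(raw$ethnicity, ethnicity_levels()),
    education = lvl(raw$education, c("high_school_or_less", "postsecondary")),
    referral_source = lvl(raw$referral_source, referral_levels()),
    completion_seconds = as.numeric(raw$completion_seconds),
    period = as.integer(raw$period),
    complete = parse_logical(raw$complete)
  )
  for (col in screen_columns) out[[col]] <- parse_logical(raw[[col]])
  out <- out[, submission_columns]
  if (!all(out$period %in% c(1L, 2L) | is.na(out$period))) {
    stop("`period` must be 1 or 2", call. = FALSE)
  }
  if (any(!is.na(out$completion_seconds) & out$completion_seconds < 0)) {
    stop("`completion_seconds` must be nonnegative", call. = FALSE)
  }
  out
}

parse_utc_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")) {
    todo <- is.na(out) & !is.na(x)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(x[todo], format = fmt, tz = "UTC")
  }
  bad <- is.na(out) & !is.na(x) & nzchar(x)
  if (any(bad)) {
    warning(sum(bad), " timestamp(s) could not be parsed; set to missing",
            call. = FALSE)
  }
  out
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[x %in% c("false", "f", "no", "n", "0")] <- FALSE
  out
}

#' Write a submission table to CSV
#'
#' @param records Submission tibble.
#' @param path Output path.
#' @export
write_submissions <- function(records, path) {
  out <- records
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write and read pipeline reports
#'
#' Serialises any report object produced by the pipeline (flow counts,
#' comparison tables, efficiency tables, ...). JSON output is round-trip
#' safe: `read_report(write_report(x, path, "json"))` reconstructs the
#' object field-for-field, including its class. TSV requires a tabular
#' report (a data frame); `"text"` uses the report's print rendering.
#'
#' @param report The report object (a tibble or classed list).
#' @param path Output file path.
#' @param format One of `"json"`, `"tsv"`, `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = "json") {
  supported <- c("json", "tsv", "text")
  if (!is.character(format) || length(format) != 1 || !format %in% supported) {
    stop("unknown format; supported formats: ",
         paste(supported, collapse = ", "), call. = FALSE)
  }
  switch(format,
    json = {
      payload <- list(report_type = class(report)[1],
                      payload = strip_report(report))
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                           na = "null", null = "null", POSIXt = "ISO8601")
    },
    tsv = {
      tab <- if (is.data.frame(report)) report else as_report_table(report)
      readr::write_tsv(tab, path, na = "", progress = FALSE)
    },
    text = {
      writeLines(utils::capture.output(print(report)), path)
    }
  )
  invisible(path)
}

# recursively unclass report objects into plain lists/data.frames for JSON
strip_report <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) {
    x <- unclass(x)
    return(lapply(x, strip_report))
  }
  x
}

as_report_table <- function(report) {
  if (!is.null(report$stages)) return(report$stages)
  stop("report has no tabular representation for TSV output", call. = FALSE)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = TRUE)
  obj <- rebuild_report(payload$payload)
  if (!is.null(payload$report_type) && payload$report_type != "list" &&
      !is.data.frame(obj)) {
    class(obj) <- c(payload$report_type, class(obj))
  } else if (is.data.frame(obj) && payload$report_type %in%
             c("tbl_df", "data.frame")) {
    obj <- tibble::as_tibble(obj)
  }
  obj
}

rebuild_report <- function(x) {
  if (is.data.frame(x)) return(tibble::as_tibble(x))
  if (is.list(x)) return(lapply(x, rebuild_report))
  x
}
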