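test_that("CSV round trip preserves rows, order, and normalises fields", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "submission_id,timestamp,ip,email,postal_code,period,complete,completion_seconds",
    "a,2012-10-09 10:00:00,198.18.0.1,Jim@Example.com,n0p 1l0,1,true,120",
    "b,2012-10-09 10:05:00,198.18.0.2,,m5g 1x8,1,true,200",
    "c,2012-10-09 10:10:00,198.18.0.3,kim@example.com,,2,false,50"
  ), path)
  rec <- read_submissions(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$submission_id, c("a", "b", "c"))
  expect_equal(rec$postal_code, c("N0P1L0", "M5G1X8", NA))
  expect_true(is.na(rec$email[2]))
  expect_equal(rec$period, c(1L, 1L, 2L))
  expect_equal(rec$complete, c(TRUE, TRUE, FALSE))
})

test_that("missing mandatory columns raise an error naming the column", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("submission_id,timestamp,period", "a,2012-10-09,1"), path)
  expect_error(read_submissions(path), "`ip`")
})

test_that("column mapping and auto-assigned ids work", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("When,Address,Phase", "2012-10-09 10:00:00,198.18.0.1,1",
               "2012-10-09 11:00:00,198.18.0.2,2"), path)
  rec <- read_submissions(path, col_map = c(timestamp = "When",
                                            ip = "Address",
                                            period = "Phase"))
  expect_equal(rec$submission_id, c("1", "2"))
  expect_equal(rec$period, c(1L, 2L))
})

test_that("JSON lines input parses like CSV", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"submission_id":"x","timestamp":"2012-10-09T10:00:00","ip":"198.18.0.1","period":1,"complete":true}',
    '{"submission_id":"y","timestamp":"2012-10-09T11:00:00","ip":"198.18.0.2","period":2,"complete":false}'
  ), path)
  rec <- read_submissions(path)
  expect_equal(rec$submission_id, c("x", "y"))
  expect_s3_class(rec$timestamp, "POSIXct")
})

test_that("unparseable timestamps and postal codes warn and become NA", {
  raw <- tibble::tibble(timestamp = c("2012-10-09 10:00:00", "not a date"),
                        ip = c("1.2.3.4", "1.2.3.5"),
                        postal_code = c("XXX", "N0P1L0"),
                        period = c(1, 1))
  expect_warning(expect_warning(rec <- as_submission_table(raw),
                                "timestamp"), "postal")
  expect_true(is.na(rec$timestamp[2]))
  expect_equal(rec$postal_code, c(NA, "N0P1L0"))
})

test_that("report JSON round-trips field-for-field", {
  cohort <- random_cohort(40, seed = 11)
  res <- run_pipeline(cohort)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(res$flow, path, "json")
  back <- read_report(path)
  expect_s3_class(back, "flow_counts")
  for (f in c("submitted", "incomplete", "ineligible_screen",
              "retained_after_screen", "excluded_non_region",
              "excluded_email_dup", "excluded_ip_dup", "unique_eligible")) {
    expect_equal(back[[f]], res$flow[[f]], info = f)
  }
  expect_equal(as.data.frame(back$stages), as.data.frame(res$flow$stages))

  # a plain tabular report round-trips too
  tab <- efficiency_table(benchmark_staff_hours())
  write_report(tab, path, "json")
  expect_equal(as.data.frame(read_report(path)), as.data.frame(tab))
})

test_that("TSV output has one row per mode and empty reports are valid", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- efficiency_table(benchmark_staff_hours())
  write_report(tab, path, "tsv")
  expect_equal(nrow(readr::read_tsv(path, show_col_types = FALSE)),
               nrow(benchmark_staff_hours()))

  empty <- tab[0, ]
  expect_no_error(write_report(empty, path, "json"))
  expect_no_error(read_report(path))
})

test_that("unknown report formats error and list the supported ones", {
  expect_error(write_report(tibble::tibble(), tempfile(), "xml"),
               "json, tsv, text")
})
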