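test_that("flow accounting holds its conservation identities", {
  screen_counts <- list(total = 1346L, incomplete = 223L,
                        ineligible = 34L, retained = 1089L)
  charges <- tibble::tibble(
    submission_id = as.character(1:1089),
    charge = c(rep("non_region", 246), rep("email_dup", 65),
               rep("ip_dup", 298), rep("unique_eligible", 480))
  )
  flow <- build_flow(screen_counts, charges)
  expect_equal(flow$unique_eligible, 480)
  expect_equal(flow$retained_after_screen, 1089)
  expect_s3_class(flow, "flow_counts")

  # zero exclusions: unique_eligible == submitted
  sc0 <- list(total = 10L, incomplete = 0L, ineligible = 0L,
              retained = 10L)
  ch0 <- tibble::tibble(submission_id = as.character(1:10),
                        charge = rep("unique_eligible", 10))
  expect_equal(build_flow(sc0, ch0)$unique_eligible, 10)

  # violated identity raises a hard error naming it
  bad <- list(total = 10L, incomplete = 3L, ineligible = 2L,
              retained = 6L)
  expect_error(build_flow(bad, ch0), "retained_after_screen")
  expect_error(build_flow(sc0, ch0[1:5, ]), "charged records")
})

test_that("flow rendering lists stage, count, percentage and denominator", {
  sc <- list(total = 100L, incomplete = 10L, ineligible = 5L,
             retained = 85L)
  ch <- tibble::tibble(submission_id = as.character(1:85),
                       charge = c(rep("non_region", 10),
                                  rep("unique_eligible", 75)))
  flow <- build_flow(sc, ch)
  txt <- render_flow(flow, "text")
  expect_true(any(grepl("unique_eligible", txt)))
  expect_true(any(grepl("of 85", txt)))
  parsed <- jsonlite::fromJSON(render_flow(flow, "json"))
  expect_equal(parsed$unique_eligible, 75)
})

test_that("stage charging order changes stage counts, never the total kept", {
  for (seed in c(5, 15, 25)) {
    cohort <- random_cohort(120, seed = seed)
    scr <- screen_cohort(cohort)
    verdicts <- classify_geography(scr$retained, pipeline_config())
    charges <- charge_exclusions(scr$retained, verdicts)
    flow <- build_flow(scr$counts, charges)

    # swap the email/IP priority by hand
    lk <- recruitqc:::record_link_keys(scr$retained)
    alt <- ifelse(!verdicts$validated_in_region, "non_region",
           ifelse(lk$ip_nonunique, "ip_dup",
           ifelse(lk$email_nonunique, "email_dup", "unique_eligible")))
    alt_flow <- build_flow(scr$counts,
                           tibble::tibble(
                             submission_id = scr$retained$submission_id,
                             charge = alt))
    expect_equal(alt_flow$unique_eligible, flow$unique_eligible)
    expect_equal(alt_flow$excluded_email_dup + alt_flow$excluded_ip_dup,
                 flow$excluded_email_dup + flow$excluded_ip_dup)
  }
})

test_that("pipeline flow equals a per-record label recount", {
  cohort <- random_cohort(150, seed = 77)
  res <- run_pipeline(cohort)
  expect_equal(res$flow$excluded_non_region,
               sum(res$charges$charge == "non_region"))
  expect_equal(res$flow$unique_eligible,
               sum(res$charges$charge == "unique_eligible"))
  expect_equal(nrow(res$unique_eligible), res$flow$unique_eligible)
})
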