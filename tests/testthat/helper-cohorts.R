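# Random cohort builder for property tests: small IP/email pools force
# collisions so that duplicate clusters actually occur.
random_cohort <- function(n, seed, ip_pool = max(2L, n %/% 3),
                          email_pool = max(2L, n %/% 4),
                          p_email_na = 0.2, p_incomplete = 0.15,
                          p_ineligible = 0.05) {
  set.seed(seed)
  base <- as.POSIXct("2012-10-09 00:00:00", tz = "UTC")
  domains <- c("a.example", "b.example", "c.example")
  locals <- sprintf("user%03d", sample.int(email_pool, n, replace = TRUE))
  email <- ifelse(stats::runif(n) < p_email_na, NA_character_,
                  paste0(locals, "@", sample(domains, n, replace = TRUE)))
  u <- stats::runif(n)
  complete <- u >= p_incomplete
  resides <- u >= p_incomplete + p_ineligible | !complete
  postal_pool <- c("N0P1L0", "M5G1X8", "K1A0B1", "T2X3Y4", NA)
  tibble::tibble(
    submission_id = sprintf("r%04d", seq_len(n)),
    timestamp = base + sort(sample.int(400000, n)),
    ip = sprintf("198.18.50.%d", sample.int(ip_pool, n, replace = TRUE)),
    email = email,
    screen_reads_english = TRUE, screen_writes_english = TRUE,
    screen_resides_region = resides,
    screen_parent_child = TRUE, screen_immunization_decisions = TRUE,
    postal_code = sample(postal_pool, n, replace = TRUE),
    age_group = sample(c(age_levels(), NA), n, replace = TRUE),
    sex = sample(c("female", "male", NA), n, replace = TRUE),
    marital = sample(c("single", "married", NA), n, replace = TRUE),
    ethnicity = sample(c(ethnicity_levels(), NA), n, replace = TRUE),
    education = sample(c("high_school_or_less", "postsecondary", NA), n,
                       replace = TRUE),
    referral_source = sample(referral_levels(), n, replace = TRUE),
    completion_seconds = round(stats::rlnorm(n, log(200), 0.5)),
    period = sample(1:2, n, replace = TRUE, prob = c(0.8, 0.2)),
    complete = complete
  )
}
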