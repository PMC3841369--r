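#' Simulator configuration
#'
#' Parameters of the synthetic-cohort generator. The defaults emulate
#' the recruitment structure the pipeline is designed for: two
#' recruitment periods (period 1 with an incentive and no software
#' restrictions, period 2 with no incentive and a one-submission-per-IP
#' restriction), a majority of unique responders, a minority of
#' incentive-driven "gamer" actors who submit bursts of questionnaires
#' from a shared IP with reused or variant email addresses, shorter
#' completion times and higher missingness, and an admixture of
#' out-of-region respondents (other provinces, US, international).
#'
#' @param seed Integer; fully determines the output.
#' @param n_unique Number of unique responders (default 620).
#' @param n_gamer_actors Number of gamer actors (default 118); each
#'   actor emits one burst.
#' @param burst_size_probs Named numeric: probability mass over burst
#'   sizes (names are sizes, all at least 2). The default puts mass 0.89
#'   on sizes 2-5, 0.068 spread over 6-16 and 0.042 over 17-30.
#' @param gap_probs Probability mass over the four gap bins
#'   `(5, 300]`, `(300, 3600]`, `(3600, 86400]`, `(86400, 604800]`
#'   seconds; gaps are uniform within their bin. Defaults 0.58, 0.22,
#'   0.16, 0.04 so the burst-gap CDF at 300/3600/86400 s is
#'   0.58/0.80/0.96.
#' @param unique_median_p1,unique_median_p2,gamer_median Median
#'   completion seconds by class (log-normal; defaults 215, 266, 166).
#' @param sdlog Log-scale SD of completion times.
#' @param repeat_decay Multiplicative completion-time decay per repeat
#'   submission within a burst (familiarity effect), default 0.9.
#' @param p_missing_unique,p_missing_gamer Per-variable missingness
#'   probability by class (defaults 0.076 and 0.15, the aggregate rates
#'   the generator targets).
#' @param p_nonregion Probability that a responder (either class) is
#'   physically outside the target region despite passing the screen.
#' @param nonregion_mix Mixture over `other_province`, `us`,
#'   `international` for out-of-region responders (default 26:182:38
#'   normalised).
#' @param p_period2_unique Probability a unique responder submits in
#'   period 2 (default 136/620).
#' @param p_period2_gamer Probability a gamer actor acts in period 2;
#'   the IP restriction then truncates the burst to one submission.
#' @param p_email_exact,p_email_variant,p_email_missing Within a burst,
#'   probability that a repeat submission reuses the actor's exact email,
#'   a variant (same local part, new domain), or omits the email; the
#'   remainder are fresh addresses.
#' @param p_ip_switch Probability that a repeat submission in a burst
#'   switches to a fresh IP (default 0: same-IP bursts).
#' @param p_rural Probability of a rural postal code for in-region
#'   responders.
#' @param n_incomplete,n_ineligible Extra records failing the
#'   completeness filter / the eligibility screen (defaults 223 and 34).
#' @param sex_shift_log_odds Added to the log-odds of female sex in
#'   period 2 (default `log(7.67)`).
#' @param ethnicity_shift Named log-odds adjustments applied to the
#'   ethnicity mixture in period 2.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_unique = 620L,
                       n_gamer_actors = 118L,
                       burst_size_probs = default_burst_size_probs(),
                       gap_probs = c(0.58, 0.22, 0.16, 0.04),
                       unique_median_p1 = 215,
                       unique_median_p2 = 266,
                       gamer_median = 166,
                       sdlog = 0.5,
                       repeat_decay = 0.9,
                       p_missing_unique = 0.076,
                       p_missing_gamer = 0.15,
                       p_nonregion = 0.226,
                       nonregion_mix = c(other_province = 26, us = 182,
                                         international = 38) / 246,
                       p_period2_unique = 136 / 620,
                       p_period2_gamer = 0.02,
                       p_email_exact = 0.10,
                       p_email_variant = 0.05,
                       p_email_missing = 0.05,
                       p_ip_switch = 0,
                       p_rural = 0.07,
                       n_incomplete = 223L,
                       n_ineligible = 34L,
                       sex_shift_log_odds = log(7.67),
                       ethnicity_shift = c(chinese = log(0.05))) {
  if (length(burst_size_probs) == 0 || any(burst_size_probs < 0) ||
      abs(sum(burst_size_probs) - 1) > 1e-8) {
    stop("`burst_size_probs` must be a nonempty probability mass",
         call. = FALSE)
  }
  if (any(as.integer(names(burst_size_probs)) < 2)) {
    stop("burst sizes must be >= 2", call. = FALSE)
  }
  if (abs(sum(gap_probs) - 1) > 1e-8 || length(gap_probs) != 4) {
    stop("`gap_probs` must be 4 probabilities summing to 1", call. = FALSE)
  }
  probs <- c(p_missing_unique, p_missing_gamer, p_nonregion,
             p_period2_unique, p_period2_gamer, p_email_exact,
             p_email_variant, p_email_missing, p_ip_switch, p_rural)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

default_burst_size_probs <- function() {
  small <- c(60, 25, 12, 8) / 118 * (0.89 / (105 / 118))
  mid <- rep((8 / 118) / 11, 11)
  large <- rep((5 / 118) / 14, 14)
  p <- c(small, mid, large)
  stats::setNames(p / sum(p), c(2:5, 6:16, 17:30))
}

# deterministic IP allocator over synthetic /16 blocks
ip_allocator <- function() {
  bases <- c(ontario = ipv4_to_num("198.18.0.0"),
             other_province = ipv4_to_num("198.19.0.0"),
             us = ipv4_to_num("100.64.0.0"),
             international = ipv4_to_num("100.65.0.0"),
             noise = ipv4_to_num("198.18.200.0"))
  counters <- new.env(parent = emptyenv())
  for (nm in names(bases)) assign(nm, 0, envir = counters)
  function(region) {
    k <- get(region, envir = counters)
    assign(region, k + 1, envir = counters)
    num_to_ipv4(bases[[region]] + k)
  }
}

num_to_ipv4 <- function(num) {
  paste(num %/% 256^3 %% 256, num %/% 256^2 %% 256,
        num %/% 256 %% 256, num %% 256, sep = ".")
}

period_windows <- function() {
  list(p1 = as.POSIXct(c("2012-10-09 00:00:00", "2012-10-11 23:59:59"),
                       tz = "UTC"),
       p2 = as.POSIXct(c("2012-11-16 00:00:00", "2013-02-17 23:59:59"),
                       tz = "UTC"))
}

draw_gap <- function(n, gap_probs) {
  bin <- sample.int(4, n, replace = TRUE, prob = gap_probs)
  lo <- c(5, 300, 3600, 86400)[bin]
  hi <- c(300, 3600, 86400, 604800)[bin]
  stats::runif(n, lo, hi)
}

sample_lvl <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

demographic_probs <- function() {
  list(
    sex_female_p1 = 0.45,
    age = c("<20" = 0.01, "20-29" = 0.24, "30-39" = 0.45, ">=40" = 0.30),
    marital = c(single = 0.17, married = 0.83),
    ethnicity = c(white = 0.50, chinese = 0.22, south_asian = 0.11,
                  southeast_asian_filipino = 0.04, korean_japanese = 0.02,
                  mixed = 0.03, other = 0.08),
    education = c(high_school_or_less = 0.09, postsecondary = 0.91),
    referral = c(redflagdeals = 0.42, friend_family = 0.12,
                 facebook = 0.14, smartcanucks = 0.06,
                 word_of_mouth = 0.04, twitter = 0.03, no_answer = 0.03,
                 email_list_website = 0.03, craigslist_kijiji = 0.06,
                 mass_media = 0.06, other = 0.01)
  )
}

#' Simulate a recruitment cohort with ground-truth labels
#'
#' Generates a submission table with the statistical structure described
#' in [sim_config()], together with per-record ground truth (class,
#' actor id, true region). Identical seeds give identical tables. Gamer
#' actors emit time-ordered bursts from a single IP (unless
#' `p_ip_switch > 0`), reuse or vary their email, answer faster on each
#' repeat, and skip more questions; the period-2 regime suppresses
#' repeat submissions from the same IP at source.
#'
#' @param config A [sim_config()].
#' @return A list with `records` (submission tibble) and `truth`
#'   (tibble `submission_id`, `class`, `actor_id`, `true_region`,
#'   `burst_index`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  alloc <- ip_allocator()
  win <- period_windows()
  dp <- demographic_probs()
  rows <- list()
  truth <- list()

  draw_demo <- function(n, period, class) {
    p_missing <- if (class == "gamer") config$p_missing_gamer else
      config$p_missing_unique
    sex_logit <- stats::qlogis(dp$sex_female_p1) +
      if (period == 2) config$sex_shift_log_odds else 0
    eth <- dp$ethnicity
    if (period == 2 && length(config$ethnicity_shift)) {
      lo <- log(eth)
      for (nm in names(config$ethnicity_shift)) {
        lo[nm] <- lo[nm] + config$ethnicity_shift[[nm]]
      }
      eth <- exp(lo) / sum(exp(lo))
    }
    out <- tibble::tibble(
      sex = ifelse(stats::runif(n) < stats::plogis(sex_logit),
                   "female", "male"),
      age_group = sample_lvl(n, dp$age),
      marital = sample_lvl(n, dp$marital),
      ethnicity = sample_lvl(n, eth),
      education = sample_lvl(n, dp$education),
      referral_source = sample_lvl(n, dp$referral)
    )
    for (v in c("age_group", "marital", "ethnicity", "education")) {
      out[[v]][stats::runif(n) < p_missing] <- NA
    }
    out
  }

  make_postal <- function(region, p_missing) {
    if (stats::runif(1) < p_missing) return(NA_character_)
    if (region == "ontario") {
      prefix <- sample(c("K", "L", "M", "N", "P"), 1)
      second <- if (stats::runif(1) < config$p_rural) "0" else
        as.character(sample(1:9, 1))
      paste0(prefix, second, "A", sample(1:9, 1), "B", sample(1:9, 1))
    } else if (region == "other_province") {
      paste0("T", sample(1:9, 1), "A", sample(1:9, 1), "B",
             sample(1:9, 1))
    } else {
      # out-of-country responders gaming the screen often self-report an
      # in-region postal code
      if (stats::runif(1) < 0.5) {
        paste0(sample(c("K", "L", "M", "N", "P"), 1), sample(1:9, 1),
               "A", sample(1:9, 1), "B", sample(1:9, 1))
      } else {
        NA_character_
      }
    }
  }

  base_row <- function(id, ts, ip, email, postal, period, secs, demo) {
    tibble::tibble(
      submission_id = id, timestamp = ts, ip = ip, email = email,
      screen_reads_english = TRUE, screen_writes_english = TRUE,
      screen_resides_region = TRUE, screen_parent_child = TRUE,
      screen_immunization_decisions = TRUE,
      postal_code = postal, age_group = demo$age_group, sex = demo$sex,
      marital = demo$marital, ethnicity = demo$ethnicity,
      education = demo$education, referral_source = demo$referral_source,
      completion_seconds = secs, period = period, complete = TRUE
    )
  }

  idc <- 0
  next_id <- function() {
    idc <<- idc + 1
    sprintf("s%05d", idc)
  }

  # unique responders
  for (i in seq_len(config$n_unique)) {
    period <- if (stats::runif(1) < config$p_period2_unique) 2L else 1L
    region <- if (stats::runif(1) < config$p_nonregion) {
      sample_lvl(1, config$nonregion_mix)
    } else {
      "ontario"
    }
    w <- if (period == 1) win$p1 else win$p2
    ts <- w[1] + stats::runif(1, 0, as.numeric(difftime(w[2], w[1],
                                                        units = "secs")))
    med <- if (period == 1) config$unique_median_p1 else
      config$unique_median_p2
    demo <- draw_demo(1, period, "unique")
    id <- next_id()
    rows[[length(rows) + 1]] <- base_row(
      id, ts, alloc(region), sprintf("resp%05d@example.com", i),
      make_postal(region, config$p_missing_unique), period,
      stats::rlnorm(1, log(med), config$sdlog), demo)
    truth[[length(truth) + 1]] <- tibble::tibble(
      submission_id = id, class = "unique",
      actor_id = sprintf("u%05d", i), true_region = region,
      burst_index = 1L)
  }

  # gamer actors
  domains <- c("gmail.example", "yahoo.example", "mail.example",
               "inbox.example", "post.example")
  sizes <- as.integer(names(config$burst_size_probs))
  for (a in seq_len(config$n_gamer_actors)) {
    period <- if (stats::runif(1) < config$p_period2_gamer) 2L else 1L
    size <- sizes[sample.int(length(sizes), 1,
                             prob = config$burst_size_probs)]
    if (period == 2L) size <- 1L  # per-IP restriction active
    region <- if (stats::runif(1) < config$p_nonregion) {
      sample_lvl(1, config$nonregion_mix)
    } else {
      "ontario"
    }
    w <- if (period == 1) win$p1 else win$p2
    span <- as.numeric(difftime(w[2], w[1], units = "secs"))
    ts <- w[1] + stats::runif(1, 0, span * 0.5)
    ip <- alloc(region)
    local <- sprintf("actor%04d", a)
    base_domain <- sample(domains, 1)
    for (j in seq_len(size)) {
      if (j > 1) {
        ts <- ts + draw_gap(1, config$gap_probs)
        if (stats::runif(1) < config$p_ip_switch) ip <- alloc(region)
      }
      u <- stats::runif(1)
      email <- if (j == 1) {
        paste0(local, "@", base_domain)
      } else if (u < config$p_email_exact) {
        paste0(local, "@", base_domain)
      } else if (u < config$p_email_exact + config$p_email_variant) {
        paste0(local, "@", sample(setdiff(domains, base_domain), 1))
      } else if (u < config$p_email_exact + config$p_email_variant +
                 config$p_email_missing) {
        NA_character_
      } else {
        sprintf("a%04dm%02d@example.com", a, j)
      }
      med <- config$gamer_median * config$repeat_decay^(j - 1)
      demo <- draw_demo(1, period, "gamer")
      id <- next_id()
      rows[[length(rows) + 1]] <- base_row(
        id, ts, ip, email, make_postal(region, config$p_missing_gamer),
        period, stats::rlnorm(1, log(med), config$sdlog), demo)
      truth[[length(truth) + 1]] <- tibble::tibble(
        submission_id = id, class = if (size >= 2) "gamer" else "unique",
        actor_id = sprintf("g%04d", a), true_region = region,
        burst_index = j)
    }
  }

  # screen-failing noise: incomplete and ineligible submissions
  n_noise <- config$n_incomplete + config$n_ineligible
  for (k in seq_len(n_noise)) {
    incomplete <- k <= config$n_incomplete
    period <- if (stats::runif(1) < 0.2) 2L else 1L
    w <- if (period == 1) win$p1 else win$p2
    ts <- w[1] + stats::runif(1, 0, as.numeric(difftime(w[2], w[1],
                                                        units = "secs")))
    id <- next_id()
    row <- base_row(id, ts, alloc("noise"), NA_character_, NA_character_,
                    period, stats::runif(1, 10, 120),
                    tibble::tibble(sex = NA_character_,
                                   age_group = NA_character_,
                                   marital = NA_character_,
                                   ethnicity = NA_character_,
                                   education = NA_character_,
                                   referral_source = NA_character_))
    if (incomplete) {
      row$complete <- FALSE
    } else {
      row$screen_resides_region <- FALSE
    }
    rows[[length(rows) + 1]] <- row
    truth[[length(truth) + 1]] <- tibble::tibble(
      submission_id = id,
      class = if (incomplete) "incomplete" else "ineligible",
      actor_id = sprintf("n%05d", k), true_region = "ontario",
      burst_index = 1L)
  }

  records <- dplyr::bind_rows(rows)[, submission_columns]
  truth <- dplyr::bind_rows(truth)
  perm <- sample.int(nrow(records))
  list(records = records[perm, ], truth = truth[perm, ])
}

#' Expected multiple-submission fraction under a simulator configuration
#'
#' Closed-form expectation of the fraction of retained records belonging
#' to bursts of size two or more, used to check simulator fidelity.
#'
#' @param config A [sim_config()].
#' @return A single proportion.
#' @export
expected_multiple_fraction <- function(config = sim_config()) {
  sizes <- as.integer(names(config$burst_size_probs))
  es <- sum(sizes * config$burst_size_probs)
  p2 <- config$p_period2_gamer
  g_mult <- config$n_gamer_actors * (1 - p2) * es
  g_single <- config$n_gamer_actors * p2
  g_mult / (config$n_unique + g_mult + g_single)
}

#' Simulate period assignment from a known sex effect
#'
#' Draws a cohort of unique eligible participants whose probability of
#' submitting in period 2 follows a logistic model in sex with a known
#' log-odds coefficient; used for parameter-recovery checks of the
#' regression stage.
#'
#' @param n Number of participants.
#' @param beta_sex True log-odds of period 2 for female vs male.
#' @param p_female Marginal probability of female sex.
#' @param intercept Baseline log-odds of period 2 for males.
#' @return Tibble with columns `period` and `sex`.
#' @export
simulate_period_assignment <- function(n = 390, beta_sex = log(7.67),
                                       p_female = 0.5,
                                       intercept = -2) {
  sex <- ifelse(stats::runif(n) < p_female, "female", "male")
  eta <- intercept + beta_sex * (sex == "female")
  period <- ifelse(stats::runif(n) < stats::plogis(eta), 2L, 1L)
  tibble::tibble(period = period, sex = sex)
}
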