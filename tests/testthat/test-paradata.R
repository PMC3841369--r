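test_that("missingness summary reproduces hand counts and the recount oracle", {
  # group with per-variable missing 176/48/25/28/75 of n=469 aggregates
  # to 352 cells, 15.0%
  n <- 469
  rec <- tibble::tibble(
    postal_code = c(rep(NA, 176), rep("M5G1X8", n - 176)),
    education = c(rep(NA, 48), rep("postsecondary", n - 48)),
    age_group = c(rep(NA, 25), rep("30-39", n - 25)),
    marital = c(rep(NA, 28), rep("married", n - 28)),
    ethnicity = c(rep(NA, 75), rep("white", n - 75))
  )
  ms <- missingness_summary(rec, rep("multiple", n))
  total <- ms[ms$variable == "total", ]
  expect_equal(total$n_missing, 352)
  expect_equal(round(total$pct_missing, 1), 15.0)

  # fully observed group: zero everywhere
  full <- rec[177:nrow(rec), ]
  full$postal_code <- "M5G1X8"
  for (v in c("education", "age_group", "marital", "ethnicity")) {
    full[[v]][is.na(full[[v]])] <- "x"
  }
  ms0 <- missingness_summary(full, rep("g", nrow(full)))
  expect_true(all(ms0$n_missing == 0))

  # random cohorts: aggregate equals a cell-by-cell brute recount
  cohort <- random_cohort(120, seed = 21)
  grp <- rep(c("a", "b"), length.out = 120)
  ms <- missingness_summary(cohort, grp)
  vars <- c("postal_code", "education", "age_group", "marital",
            "ethnicity")
  for (g in c("a", "b")) {
    brute <- sum(vapply(vars, function(v) sum(is.na(cohort[[v]][grp == g])),
                        numeric(1)))
    expect_equal(ms$n_missing[ms$group == g & ms$variable == "total"],
                 brute)
  }
})

test_that("proportion comparison switches chi-square/Fisher on expected counts", {
  out <- compare_proportions(141, 152, 702, 937)
  expect_equal(out$test, "chi-square")
  expect_equal(round(100 * out$prop_a, 1), 92.8)
  expect_equal(round(100 * out$prop_b, 1), 74.9)  # 702/937
  expect_lt(out$p_value, 0.001)

  # identical tiny groups: Fisher, p = 1
  out <- compare_proportions(2, 4, 2, 4)
  expect_equal(out$test, "fisher")
  expect_equal(out$p_value, 1)

  expect_error(compare_proportions(1, 0, 1, 2), "sizes")

  # the switch is a pure function of the expected table
  out <- compare_proportions(1, 50, 3, 50)  # min expected cell = 2 < 5
  expect_equal(out$test, "fisher")
})

test_that("Fisher p equals hypergeometric enumeration for small margins", {
  set.seed(31)
  for (rep in 1:25) {
    n1 <- sample(2:15, 1)
    n2 <- sample(2:15, 1)
    a <- sample(0:n1, 1)
    b <- sample(0:n2, 1)
    got <- compare_proportions(a, n1, b, n2)
    if (got$test == "fisher") {
      expect_equal(got$p_value, oracle_fisher_p(a, n1 - a, b, n2 - b),
                   tolerance = 1e-10)
    }
  }
})

test_that("completion-time comparison: medians exact, small-sample p exact", {
  out <- compare_completion_time(c(1, 2, 3), c(1, 2, 3))
  expect_equal(out$median_a, 2)
  expect_equal(out$p_value, 1)

  set.seed(41)
  for (rep in 1:15) {
    na <- sample(2:6, 1)
    nb <- sample(2:6, 1)
    a <- sample(1:8, na, replace = TRUE)   # ties likely
    b <- sample(1:8, nb, replace = TRUE)
    got <- compare_completion_time(a, b)
    expect_equal(got$method, "wilcoxon-exact")
    expect_equal(got$p_value, oracle_wilcox_p(a, b), tolerance = 1e-12)
  }

  # untied cases also agree with the classical exact distribution
  set.seed(43)
  for (rep in 1:10) {
    a <- sample(1:50, 5)
    b <- setdiff(1:50, a)[1:5]
    got <- compare_completion_time(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(got$p_value, ref, tolerance = 1e-12)
  }

  expect_error(compare_completion_time(numeric(), 1:3), "nonempty")
})

test_that("single-predictor logistic OR equals the 2x2 cross-product ratio", {
  # period 2 vs 1 by sex; closed form (a*d)/(b*c)
  counts <- c(f2 = 104, f1 = 146, m2 = 21, m1 = 209)
  rec <- tibble::tibble(
    period = c(rep(2L, counts["f2"]), rep(1L, counts["f1"]),
               rep(2L, counts["m2"]), rep(1L, counts["m1"])),
    sex = c(rep("female", counts["f2"] + counts["f1"]),
            rep("male", counts["m2"] + counts["m1"]))
  )
  fit <- stepwise_logistic(rec, candidates = "sex", mode = "full")
  or_female <- fit$or_table$or[fit$or_table$level == "female"]
  closed_form <- (104 * 209) / (146 * 21)
  expect_equal(or_female, closed_form, tolerance = 1e-6)
  expect_equal(fit$or_table$or[fit$or_table$reference], 1)
})

test_that("perfectly balanced response gives OR 1 for every level", {
  rec <- tibble::tibble(
    period = rep(c(1L, 2L), 60),
    sex = rep(c("female", "female", "male", "male"), 30),
    education = rep(c("postsecondary", "high_school_or_less"), each = 60)
  )
  fit <- stepwise_logistic(rec, candidates = c("sex", "education"),
                           mode = "full")
  expect_true(all(abs(fit$or_table$or - 1) < 1e-8))
})

test_that("stepwise keeps the null model when the response is independent", {
  set.seed(61)
  empty <- 0
  for (rep in 1:100) {
    rec <- tibble::tibble(
      period = sample(1:2, 120, replace = TRUE),
      sex = sample(c("female", "male"), 120, replace = TRUE)
    )
    fit <- stepwise_logistic(rec, candidates = "sex")
    if (length(fit$selected) == 0) empty <- empty + 1
  }
  expect_gte(empty, 90)
})

test_that("stepwise selects a strong predictor and drops missing rows", {
  set.seed(71)
  dat <- simulate_period_assignment(n = 390, beta_sex = log(7.67))
  dat$age_group <- sample(c("20-29", "30-39", NA), 390, replace = TRUE,
                          prob = c(0.45, 0.45, 0.1))
  fit <- stepwise_logistic(dat, candidates = c("sex", "age_group"))
  expect_true("sex" %in% fit$selected)
  expect_equal(fit$n_used + fit$n_dropped, 390)
  expect_gt(fit$n_dropped, 0)
  tab <- fit$or_table
  fem <- tab[tab$level == "female" & !tab$reference, ]
  expect_true(fem$ci_lower < fem$or & fem$or < fem$ci_upper)
})
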