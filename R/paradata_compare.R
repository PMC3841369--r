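#' Missingness summary per group
#'
#' Per-variable missing counts and percentages for each group, plus an
#' aggregate row (`variable == "total"`): missing cells divided by
#' group size times number of variables. Empty groups report `NA`
#' percentages rather than propagating `NaN`.
#'
#' @param records Submission tibble.
#' @param group Vector of group labels, one per record.
#' @param variables Columns to summarise (must exist in `records`).
#' @return Tibble with columns `group`, `variable`, `n`, `n_missing`,
#'   `pct_missing`. The aggregate row's `n` is `group size * length(variables)`
#'   (cells).
#' @export
missingness_summary <- function(records, group,
                                variables = c("postal_code", "education",
                                              "age_group", "marital",
                                              "ethnicity")) {
  stopifnot(length(group) == nrow(records))
  missing_vars <- setdiff(variables, names(records))
  if (length(missing_vars)) {
    stop("unknown variable(s): ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  groups <- unique(group)
  rows <- lapply(groups, function(g) {
    sub <- records[group == g, , drop = FALSE]
    gn <- nrow(sub)
    per_var <- unname(vapply(variables, function(v) sum(is.na(sub[[v]])),
                             numeric(1)))
    pct <- if (gn > 0) {
      100 * c(per_var / gn, sum(per_var) / (gn * length(variables)))
    } else {
      rep(NA_real_, length(variables) + 1)
    }
    tibble::tibble(
      group = g,
      variable = c(variables, "total"),
      n = c(rep(gn, length(variables)), gn * length(variables)),
      n_missing = c(per_var, sum(per_var)),
      pct_missing = pct
    )
  })
  dplyr::bind_rows(rows)
}

#' Compare two proportions
#'
#' Chi-square test (without continuity correction by default) when all
#' expected cell counts are at least 5, otherwise the Fisher exact test;
#' two-sided p-values throughout. The switch rule is a pure function of
#' the expected-count table.
#'
#' @param success_a,n_a Successes and size of group a (`0 <= x <= n`,
#'   `n >= 1`).
#' @param success_b,n_b Same for group b.
#' @param correct Apply Yates continuity correction to the chi-square
#'   test (default `FALSE`).
#' @return One-row tibble: `prop_a`, `prop_b`, `n_a`, `n_b`, `test`
#'   (`"chi-square"` or `"fisher"`), `p_value`.
#' @export
#' @examples
#' compare_proportions(141, 152, 702, 937)
compare_proportions <- function(success_a, n_a, success_b, n_b,
                                correct = FALSE) {
  if (n_a < 1 || n_b < 1) stop("group sizes must be >= 1", call. = FALSE)
  if (success_a < 0 || success_a > n_a || success_b < 0 ||
      success_b > n_b) {
    stop("successes must lie in [0, n]", call. = FALSE)
  }
  tab <- matrix(c(success_a, n_a - success_a,
                  success_b, n_b - success_b), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    test <- "chi-square"
    p <- suppressWarnings(
      stats::chisq.test(tab, correct = correct)$p.value
    )
  } else {
    test <- "fisher"
    p <- stats::fisher.test(tab)$p.value
  }
  tibble::tibble(prop_a = success_a / n_a, prop_b = success_b / n_b,
                 n_a = n_a, n_b = n_b, test = test, p_value = p)
}

# exact two-sided rank-sum p by enumeration of all group-a subsets;
# handles ties through midranks. Extremeness is measured as deviation of
# the rank sum from its permutation mean.
rank_sum_exact_p <- function(a, b) {
  x <- c(a, b)
  r <- rank(x)
  na <- length(a)
  w_obs <- sum(r[seq_len(na)])
  mu <- na * mean(r)
  sets <- utils::combn(length(x), na)
  w_all <- apply(sets, 2, function(idx) sum(r[idx]))
  eps <- 1e-9
  mean(abs(w_all - mu) >= abs(w_obs - mu) - eps)
}

#' Compare completion times between two groups
#'
#' Reports exact medians and a two-sided Wilcoxon rank-sum p-value:
#' exact enumeration over all group assignments when the combined sample
#' size is at most `exact_max` (ties handled through midranks),
#' otherwise the tie-corrected normal approximation.
#'
#' @param times_a,times_b Nonempty numeric vectors (seconds).
#' @param exact_max Combined-size cutoff for exact enumeration.
#' @return One-row tibble: `median_a`, `median_b`, `n_a`, `n_b`,
#'   `method`, `p_value`.
#' @export
compare_completion_time <- function(times_a, times_b, exact_max = 20) {
  if (length(times_a) == 0 || length(times_b) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  n <- length(times_a) + length(times_b)
  if (n <= exact_max) {
    p <- rank_sum_exact_p(times_a, times_b)
    method <- "wilcoxon-exact"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(times_a, times_b, exact = FALSE,
                         correct = FALSE)$p.value
    )
    method <- "wilcoxon-normal"
  }
  tibble::tibble(median_a = stats::median(times_a),
                 median_b = stats::median(times_b),
                 n_a = length(times_a), n_b = length(times_b),
                 method = method, p_value = p)
}

# ---- stepwise logistic regression --------------------------------------

default_reference_levels <- function() {
  list(sex = "male", age_group = "<=29", marital = "married",
       ethnicity = "white", education = "high_school_or_less")
}

prepare_regression_data <- function(records, candidates, forced,
                                    collapse_age, reference_levels) {
  dat <- records[, c("period", unique(c(candidates, forced))),
                 drop = FALSE]
  if (collapse_age && "age_group" %in% names(dat)) {
    dat$age_group <- ifelse(dat$age_group %in% c("<20", "20-29"),
                            "<=29", dat$age_group)
  }
  keep <- stats::complete.cases(dat)
  dropped <- sum(!keep)
  dat <- dat[keep, , drop = FALSE]
  dat$.y <- as.integer(dat$period == 2)
  for (v in setdiff(names(dat), c("period", ".y"))) {
    ref <- reference_levels[[v]]
    lv <- unique(dat[[v]])
    if (!is.null(ref) && ref %in% lv) {
      dat[[v]] <- factor(dat[[v]], levels = c(ref, setdiff(sort(lv), ref)))
    } else {
      dat[[v]] <- factor(dat[[v]])
    }
  }
  list(data = dat, n_dropped = dropped)
}

or_table_from_fit <- function(fit, variables, data) {
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  pz <- 2 * stats::pnorm(-abs(est / se))
  rows <- list()
  for (v in variables) {
    lv <- levels(data[[v]])
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = v, level = lv[1], or = 1, ci_lower = NA_real_,
      ci_upper = NA_real_, p_value = NA_real_, reference = TRUE,
      separation = FALSE
    )
    for (l in lv[-1]) {
      nm <- paste0(v, l)
      if (!nm %in% names(est)) next
      b <- est[[nm]]
      s <- se[[nm]]
      sep <- !is.finite(b) || !is.finite(s) || abs(b) > 15 || s > 100
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = v, level = l,
        or = exp(b),
        ci_lower = if (sep) 0 else exp(b - 1.959964 * s),
        ci_upper = if (sep) Inf else exp(b + 1.959964 * s),
        p_value = pz[[nm]], reference = FALSE, separation = sep
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Stepwise logistic regression of period membership on demographics
#'
#' Models the log-odds of submitting during period 2 (no incentive,
#' IP restriction) versus period 1 as a function of categorical
#' demographic predictors, restricted to unique eligible participants.
#' Forward selection with backward elimination on likelihood-ratio
#' p-values at the configured entry/exit thresholds; the final model is
#' refit and reported as adjusted odds ratios with Wald 95% CIs.
#' Reference rows carry OR exactly 1 and no CI. Rows with missing values
#' in any candidate (or forced) variable are dropped and the count
#' reported. The `<20` age band is merged with `20-29` by default
#' (sparse cell). Quasi-separated levels are flagged and reported with
#' unbounded CIs; the run continues. `mode = "full"` skips selection and
#' reports the model with every candidate (useful when all candidates
#' are retained anyway).
#'
#' @param records Submission tibble of unique eligible participants with
#'   a `period` column.
#' @param candidates Candidate predictor columns.
#' @param entry_p,exit_p Entry and exit p-value thresholds (defaults
#'   0.05 / 0.10).
#' @param forced Columns always kept in the model (e.g. a rural-residence
#'   indicator for the adjusted variant), never eligible for removal.
#' @param reference_levels Named list of reference levels per predictor.
#' @param collapse_age Merge `<20` into `20-29` (default `TRUE`).
#' @param mode `"stepwise"` or `"full"`.
#' @return A list of class `stepwise_logistic`: `or_table`, `path`
#'   (selection steps), `selected`, `n_used`, `n_dropped`, `fit`.
#' @export
stepwise_logistic <- function(records,
                              candidates = c("sex", "age_group", "marital",
                                             "ethnicity", "education"),
                              entry_p = 0.05, exit_p = 0.10,
                              forced = character(),
                              reference_levels = default_reference_levels(),
                              collapse_age = TRUE,
                              mode = c("stepwise", "full")) {
  mode <- match.arg(mode)
  prep <- prepare_regression_data(records, candidates, forced,
                                  collapse_age, reference_levels)
  dat <- prep$data
  # drop candidates with a single observed level (no contrast to fit)
  usable <- candidates[vapply(candidates,
                              function(v) nlevels(droplevels(dat[[v]])) > 1,
                              logical(1))]
  for (v in c(usable, forced)) dat[[v]] <- droplevels(dat[[v]])

  path <- list()
  if (mode == "full") {
    selected <- usable
  } else {
    selected <- character()
    repeat {
      remaining <- setdiff(usable, selected)
      changed <- FALSE
      if (length(remaining)) {
        base_fml <- stats::as.formula(paste(
          ".y ~", paste(c("1", forced, selected), collapse = " + ")))
        fit0 <- suppressWarnings(
          stats::glm(base_fml, data = dat, family = stats::binomial()))
        scope <- stats::as.formula(paste(
          "~ . +", paste(remaining, collapse = " + ")))
        a1 <- suppressWarnings(stats::add1(fit0, scope = scope,
                                           test = "LRT"))
        cand_p <- a1[["Pr(>Chi)"]][-1]
        names(cand_p) <- rownames(a1)[-1]
        best <- names(cand_p)[which.min(cand_p)]
        if (length(best) && min(cand_p, na.rm = TRUE) < entry_p) {
          selected <- c(selected, best)
          path[[length(path) + 1]] <- tibble::tibble(
            action = "enter", variable = best,
            p_value = min(cand_p, na.rm = TRUE))
          changed <- TRUE
        }
      }
      if (length(selected)) {
        fml <- stats::as.formula(paste(
          ".y ~", paste(c("1", forced, selected), collapse = " + ")))
        fit1 <- suppressWarnings(
          stats::glm(fml, data = dat, family = stats::binomial()))
        d1 <- suppressWarnings(stats::drop1(fit1, test = "LRT"))
        drop_p <- d1[["Pr(>Chi)"]][-1]
        names(drop_p) <- rownames(d1)[-1]
        drop_p <- drop_p[names(drop_p) %in% selected]
        if (length(drop_p) && max(drop_p, na.rm = TRUE) > exit_p) {
          worst <- names(drop_p)[which.max(drop_p)]
          selected <- setdiff(selected, worst)
          path[[length(path) + 1]] <- tibble::tibble(
            action = "remove", variable = worst,
            p_value = max(drop_p, na.rm = TRUE))
          changed <- TRUE
        }
      }
      if (!changed) break
      # guard against enter/remove cycling
      if (length(path) > 4 * length(usable) + 4) break
    }
  }
  terms <- c(forced, selected)
  fml <- stats::as.formula(paste(
    ".y ~", paste(c("1", terms), collapse = " + ")))
  fit <- suppressWarnings(
    stats::glm(fml, data = dat, family = stats::binomial())
  )
  structure(
    list(
      or_table = or_table_from_fit(fit, terms, dat),
      path = if (length(path)) {
        dplyr::bind_rows(path) %>% dplyr::mutate(step = dplyr::row_number())
      } else {
        tibble::tibble(action = character(), variable = character(),
                       p_value = numeric(), step = integer())
      },
      selected = selected,
      n_used = nrow(dat),
      n_dropped = prep$n_dropped,
      fit = fit
    ),
    class = "stepwise_logistic"
  )
}

#' @export
print.stepwise_logistic <- function(x, ...) {
  cat("Stepwise logistic regression (period 2 vs period 1)\n")
  cat("  n used:", x$n_used, " (", x$n_dropped,
      "dropped for missingness )\n")
  cat("  selected:", if (length(x$selected))
    paste(x$selected, collapse = ", ") else "(none)", "\n\n")
  print(x$or_table, n = Inf)
  invisible(x)
}
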