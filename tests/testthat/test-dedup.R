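test_that("email canonicalisation strips dots, plus-suffixes and case", {
  k <- canonicalize_email("Jim.Doe+x@Gmail.com")
  expect_equal(k$local_key, "jimdoe")
  expect_equal(k$domain, "gmail.com")
  expect_equal(canonicalize_email("a@b.c")$key, "a@b.c")
  expect_equal(canonicalize_email("jim.doe@yahoo.com")$local_key, "jimdoe")
  expect_error(canonicalize_email("not-an-address"), "malformed")
})

test_that("variant matching joins same local parts across domains", {
  g <- canonicalize_email("jim.doe@gmail.com")
  y <- canonicalize_email("jim.doe@yahoo.com")
  other <- canonicalize_email("janedoe@gmail.com")
  expect_true(email_variant_match(g, y))
  expect_true(email_variant_match(g, g))
  expect_false(email_variant_match(g, other))
  # a nonzero threshold admits close local parts
  expect_true(email_variant_match(g, canonicalize_email("jimdo@x.com"),
                                  threshold = 0.2))
})

make_records <- function(ips, emails, t0 = 0) {
  n <- length(ips)
  tibble::tibble(
    submission_id = sprintf("m%02d", seq_len(n)),
    timestamp = as.POSIXct("2012-10-09", tz = "UTC") + t0 + seq_len(n) * 60,
    ip = ips, email = emails
  )
}

test_that("clusters are connected components over IP and email links", {
  # A,B share an IP; B,C share a variant email -> one cluster of 3
  rec <- make_records(c("1.1.1.1", "1.1.1.1", "2.2.2.2"),
                      c("x@a.com", "p.q@a.com", "pq@b.com"))
  cl <- cluster_submissions(rec)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size, 3)
  expect_setequal(cl$evidence[[1]], c("same-ip", "variant-email"))

  # all distinct: n singletons with empty evidence
  rec <- make_records(sprintf("9.9.9.%d", 1:4),
                      sprintf("u%d@a.com", 1:4))
  cl <- cluster_submissions(rec)
  expect_equal(cl$size, rep(1, 4))
  expect_true(all(lengths(cl$evidence) == 0))

  # five submissions from one IP: one cluster, same-ip evidence
  rec <- make_records(rep("5.5.5.5", 5), sprintf("u%d@a.com", 1:5))
  cl <- cluster_submissions(rec)
  expect_equal(cl$size, 5)
  expect_equal(cl$evidence[[1]], "same-ip")
  expect_equal(length(cl$gaps[[1]]), 4)
  expect_true(all(cl$gaps[[1]] >= 0))
})

test_that("clustering is independent of input order", {
  cohort <- random_cohort(80, seed = 7)
  cl1 <- cluster_submissions(cohort)
  set.seed(99)
  cl2 <- cluster_submissions(cohort[sample.int(nrow(cohort)), ])
  expect_equal(cl1$size, cl2$size)
  expect_equal(cl1$members, cl2$members)
})

test_that("clustering equals the quadratic transitive-closure oracle", {
  for (case in list(c(30, 101), c(80, 202), c(200, 303))) {
    cohort <- random_cohort(case[1], seed = case[2])
    cl <- cluster_submissions(cohort)
    lab <- label_multiplicity(cl, cohort)
    oracle <- oracle_multiplicity(cohort)
    expect_equal(lab$labels$label,
                 oracle$label[match(lab$labels$submission_id,
                                    oracle$submission_id)])
    # same partition: identical member sets
    impl_sets <- sort(vapply(cl$members,
                             function(m) paste(sort(m), collapse = "|"),
                             character(1)))
    oracle_sets <- sort(unname(vapply(split(oracle$submission_id,
                                            oracle$component),
                                      function(m) paste(sort(m),
                                                        collapse = "|"),
                                      character(1))))
    expect_equal(impl_sets, oracle_sets)
  }
})

test_that("adding a record can merge clusters but never split one", {
  cohort <- random_cohort(60, seed = 13)
  cl_small <- cluster_submissions(cohort[1:59, ])
  cl_full <- cluster_submissions(cohort)
  full_sets <- cl_full$members
  for (m in cl_small$members) {
    contained <- any(vapply(full_sets, function(f) all(m %in% f),
                            logical(1)))
    expect_true(contained)
  }
})

test_that("multiplicity labels every member of a multi-record cluster", {
  rec <- make_records(c("1.1.1.1", "1.1.1.1", "1.1.1.1", "2.2.2.2",
                        "3.3.3.3"),
                      sprintf("u%d@a.com", 1:5))
  cl <- cluster_submissions(rec)
  lab <- label_multiplicity(cl, rec)
  expect_equal(lab$n_multiple, 3)
  expect_equal(lab$n_unique, 2)
  expect_equal(lab$nonunique_ips, 1)
  expect_equal(lab$nonunique_ip_records, 3)

  # overlapping clusters are a hard error
  bad <- cl
  bad$members[[2]] <- c(bad$members[[2]], rec$submission_id[1])
  expect_error(label_multiplicity(bad, rec), "overlapping")
})

test_that("interval profile counts gaps against each window", {
  # one size-3 cluster with gaps 60 s and 7200 s
  rec <- make_records(rep("1.1.1.1", 3), sprintf("u%d@a.com", 1:3))
  rec$timestamp <- as.POSIXct("2012-10-09", tz = "UTC") +
    c(0, 60, 60 + 7200)
  cl <- cluster_submissions(rec)
  prof <- interval_profile(cl, c(300, 3600, 86400))
  expect_equal(prof$n_within, c(1, 1, 2))
  expect_true(all(diff(prof$n_within) >= 0))
  expect_equal(attr(prof, "n_multiple"), 3)
  expect_equal(attr(prof, "n_gaps"), 2)

  # all-zero gaps: every record with a predecessor is inside every window
  rec$timestamp <- rep(as.POSIXct("2012-10-09", tz = "UTC"), 3)
  prof <- interval_profile(cluster_submissions(rec), c(300, 3600))
  expect_equal(prof$prop_of_with_predecessor, c(1, 1))

  # no multiple submissions at all: proportions are absent, not zero
  rec <- make_records(sprintf("8.8.8.%d", 1:3), sprintf("u%d@a.com", 1:3))
  prof <- interval_profile(cluster_submissions(rec), c(300, 3600))
  expect_true(all(is.na(prof$prop_of_multiple)))
})
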