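#' Canonicalise an email address
#'
#' Lowercases, strips surrounding whitespace, and splits at the final
#' `@`. The local-part key additionally removes dots and any `+suffix`,
#' so `Jim.Doe+x@Gmail.com` and `jimdoe@gmail.com` share a key. Variant
#' detection (same person, new mailbox provider) then reduces to
#' comparing local-part keys across domains.
#'
#' @param addr Character vector of nonempty addresses containing `@`.
#' @return Tibble with columns `local_key`, `domain`, `key`
#'   (`local_key@domain`).
#' @export
#' @examples
#' canonicalize_email("Jim.Doe+x@Gmail.com")
canonicalize_email <- function(addr) {
  addr <- trimws(tolower(as.character(addr)))
  if (any(is.na(addr) | !grepl("@", addr, fixed = TRUE))) {
    stop("malformed email address (no '@')", call. = FALSE)
  }
  at <- regexpr("@[^@]*$", addr)
  local <- substr(addr, 1, at - 1)
  domain <- substr(addr, at + 1, nchar(addr))
  local <- sub("\\+.*$", "", local)
  local <- gsub(".", "", local, fixed = TRUE)
  tibble::tibble(local_key = local, domain = domain,
                 key = paste0(local, "@", domain))
}

# canonical keys for a whole cohort; malformed addresses are treated as
# absent with a warning (the record then participates only in IP linking)
email_keys <- function(records) {
  out <- tibble::tibble(local_key = rep(NA_character_, nrow(records)),
                        domain = NA_character_, key = NA_character_)
  has <- !is.na(records$email)
  ok <- has & grepl("@", records$email, fixed = TRUE)
  if (any(has & !ok)) {
    warning(sum(has & !ok),
            " malformed email address(es) treated as absent", call. = FALSE)
  }
  if (any(ok)) out[ok, ] <- canonicalize_email(records$email[ok])
  out
}

#' Do two canonical email keys match as variants?
#'
#' True iff the full keys are identical, or the local-part keys are
#' identical on different domains, or the local-part keys are within a
#' normalised edit-distance threshold. The default threshold 0 keeps
#' only exact local-part matches.
#'
#' @param key1,key2 One-row results of [canonicalize_email()].
#' @param threshold Normalised Levenshtein distance
#'   (`adist / max(nchar)`) allowed between local-part keys.
#' @return Logical scalar.
#' @export
email_variant_match <- function(key1, key2, threshold = 0) {
  if (key1$key == key2$key) return(TRUE)
  if (key1$local_key == key2$local_key) return(TRUE)
  if (threshold > 0) {
    d <- utils::adist(key1$local_key, key2$local_key)[1, 1]
    return(d / max(nchar(key1$local_key), nchar(key2$local_key)) <=
             threshold)
  }
  FALSE
}

# ---- union-find ---------------------------------------------------------

uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

# link-group ids per record: records sharing an IP, or whose canonical
# email local keys match at the configured threshold, get the same group
link_components <- function(records, email_threshold = 0) {
  n <- nrow(records)
  parent <- uf_new(n)

  ip_groups <- split(seq_len(n), records$ip)
  for (g in ip_groups) {
    if (length(g) > 1) {
      for (k in seq_along(g)[-1]) parent <- uf_union(parent, g[1], g[k])
    }
  }

  keys <- email_keys(records)
  has_key <- which(!is.na(keys$local_key))
  if (length(has_key)) {
    locals <- keys$local_key[has_key]
    email_groups <- split(has_key, locals)
    for (g in email_groups) {
      if (length(g) > 1) {
        for (k in seq_along(g)[-1]) parent <- uf_union(parent, g[1], g[k])
      }
    }
    if (email_threshold > 0) {
      # fuzzy matching across distinct local keys
      uniq <- unique(locals)
      if (length(uniq) > 1) {
        d <- utils::adist(uniq, uniq)
        norm <- outer(nchar(uniq), nchar(uniq), pmax)
        close <- which(d / norm <= email_threshold & upper.tri(d),
                       arr.ind = TRUE)
        if (nrow(close)) {
          reps <- vapply(uniq, function(u) email_groups[[u]][1], integer(1))
          for (r in seq_len(nrow(close))) {
            parent <- uf_union(parent, reps[close[r, 1]], reps[close[r, 2]])
          }
        }
      }
    }
  }
  vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
}

# per-record key multiplicity over the cohort: is the record's IP shared,
# and is its email key shared (exactly or as a variant)?
record_link_keys <- function(records, email_threshold = 0) {
  keys <- email_keys(records)
  ip_n <- table(records$ip)
  ip_nonunique <- as.vector(ip_n[records$ip]) >= 2

  email_nonunique <- rep(FALSE, nrow(records))
  has <- !is.na(keys$local_key)
  if (any(has)) {
    locals <- keys$local_key
    grp <- locals
    if (email_threshold > 0) {
      uniq <- unique(locals[has])
      if (length(uniq) > 1) {
        d <- utils::adist(uniq, uniq)
        norm <- outer(nchar(uniq), nchar(uniq), pmax)
        parent <- uf_new(length(uniq))
        close <- which(d / norm <= email_threshold & upper.tri(d),
                       arr.ind = TRUE)
        if (nrow(close)) {
          for (r in seq_len(nrow(close))) {
            parent <- uf_union(parent, close[r, 1], close[r, 2])
          }
        }
        roots <- vapply(seq_along(uniq),
                        function(i) uf_find(parent, i), integer(1))
        grp[has] <- as.character(roots[match(locals[has], uniq)])
      }
    }
    key_n <- table(grp[has])
    email_nonunique[has] <- as.vector(key_n[grp[has]]) >= 2
  }
  tibble::tibble(submission_id = records$submission_id,
                 ip = records$ip,
                 email_key = keys$key,
                 local_key = keys$local_key,
                 ip_nonunique = ip_nonunique,
                 email_nonunique = email_nonunique)
}

#' Cluster submissions linked by shared IP or variant email
#'
#' Clusters are the connected components of the graph whose edges join
#' submissions from the same IP address or with same/variant email keys
#' (see [email_variant_match()]). Members are ordered by timestamp
#' (ties broken by `submission_id`); clusters are ordered by earliest
#' timestamp, then by first member id, so the output is deterministic
#' and independent of input order. Records with no email participate
#' only in IP-based linking.
#'
#' @param records Submission tibble with timestamps.
#' @param email_threshold Normalised edit-distance threshold for variant
#'   local-part matching (default 0: exact local-part match only).
#' @return Tibble with one row per cluster: `cluster_id`, `size`,
#'   list-columns `members` (ids, time-ordered), `ips`, `email_keys`,
#'   `evidence` (subset of `same-ip`, `same-email`, `variant-email`;
#'   empty for singletons), `gaps` (inter-submission gaps in seconds,
#'   length `size - 1`), and `first_timestamp`.
#' @export
cluster_submissions <- function(records, email_threshold = 0) {
  n <- nrow(records)
  if (n == 0) {
    return(tibble::tibble(cluster_id = integer(), size = integer(),
                          members = list(), ips = list(),
                          email_keys = list(), evidence = list(),
                          gaps = list(),
                          first_timestamp = as.POSIXct(character(),
                                                       tz = "UTC")))
  }
  comp <- link_components(records, email_threshold)
  keys <- email_keys(records)

  ord <- order(records$timestamp, records$submission_id)
  comp_of <- split(ord, comp[ord])

  rows <- lapply(comp_of, function(idx) {
    ips <- records$ip[idx]
    kk <- keys[idx, ]
    evidence <- character()
    if (anyDuplicated(ips)) evidence <- c(evidence, "same-ip")
    kk_has <- kk[!is.na(kk$key), ]
    if (nrow(kk_has) > 1) {
      if (anyDuplicated(kk_has$key)) evidence <- c(evidence, "same-email")
      dup_local <- duplicated(kk_has$local_key) |
        duplicated(kk_has$local_key, fromLast = TRUE)
      variant <- any(dup_local & !(duplicated(kk_has$key) |
                                     duplicated(kk_has$key,
                                                fromLast = TRUE)))
      if (email_threshold > 0 &&
          length(unique(kk_has$local_key)) > 1) {
        d <- utils::adist(kk_has$local_key, kk_has$local_key)
        norm <- outer(nchar(kk_has$local_key), nchar(kk_has$local_key),
                      pmax)
        variant <- variant || any(d / norm <= email_threshold &
                                    upper.tri(d))
      }
      if (variant) evidence <- c(evidence, "variant-email")
    }
    ts <- as.numeric(records$timestamp[idx])
    tibble::tibble(
      size = length(idx),
      members = list(records$submission_id[idx]),
      ips = list(unique(ips)),
      email_keys = list(unique(kk$key[!is.na(kk$key)])),
      evidence = list(evidence),
      gaps = list(if (length(idx) > 1) diff(ts) else numeric()),
      first_timestamp = records$timestamp[idx[1]]
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$first_timestamp,
                   vapply(out$members, `[`, character(1), 1)), ]
  out$cluster_id <- seq_len(nrow(out))
  out[, c("cluster_id", "size", "members", "ips", "email_keys",
          "evidence", "gaps", "first_timestamp")]
}

#' Label each record unique vs multiple
#'
#' Every member of a cluster of size two or more is labelled `multiple`,
#' including the first submission; singletons are `unique`. Also counts
#' nonunique IPs and nonunique email keys (keys appearing on at least
#' two records) and tabulates the cluster-size histogram. Overlapping
#' clusters (a record appearing in more than one cluster) are an
#' invariant breach and raise a hard error.
#'
#' @param clusters Output of [cluster_submissions()].
#' @param records The submission tibble the clusters were built from.
#' @param email_threshold Threshold used when clustering.
#' @return A list with `labels` (tibble `submission_id`, `label`),
#'   `n_multiple`, `n_unique`, `nonunique_ips`, `nonunique_ip_records`,
#'   `nonunique_email_keys`, `nonunique_email_records`,
#'   `overlap_records` (records linked by both IP and email evidence),
#'   and `size_histogram`.
#' @export
label_multiplicity <- function(clusters, records, email_threshold = 0) {
  ids <- unlist(clusters$members)
  if (anyDuplicated(ids)) {
    stop("overlapping clusters: a record appears in more than one cluster",
         call. = FALSE)
  }
  if (!setequal(ids, records$submission_id) ||
      length(ids) != nrow(records)) {
    stop("clusters do not cover the records exactly once", call. = FALSE)
  }
  multiple_ids <- unlist(clusters$members[clusters$size >= 2])
  labels <- tibble::tibble(
    submission_id = records$submission_id,
    label = ifelse(records$submission_id %in% multiple_ids,
                   "multiple", "unique")
  )
  lk <- record_link_keys(records, email_threshold)
  ip_keys <- unique(lk$ip[lk$ip_nonunique])
  email_recs <- lk$submission_id[lk$email_nonunique]
  email_key_count <- length(unique(lk$local_key[lk$email_nonunique]))
  hist <- dplyr::count(clusters, .data$size, name = "n_clusters")
  list(
    labels = labels,
    n_multiple = sum(labels$label == "multiple"),
    n_unique = sum(labels$label == "unique"),
    nonunique_ips = length(ip_keys),
    nonunique_ip_records = sum(lk$ip_nonunique),
    nonunique_email_keys = email_key_count,
    nonunique_email_records = length(email_recs),
    overlap_records = sum(lk$ip_nonunique & lk$email_nonunique),
    size_histogram = hist
  )
}

#' Profile the time intervals inside multiple-submission clusters
#'
#' For every member of a multi-record cluster (other than the first),
#' the gap to the previous member is compared against the configured
#' windows. Two denominators are reported: all multiple-labelled records
#' (the first member of each cluster then counts against no window), and
#' only the records that have a predecessor in their cluster.
#'
#' @param clusters Output of [cluster_submissions()].
#' @param windows Strictly increasing window bounds in seconds.
#' @return Tibble with one row per window: `window_seconds`, `n_within`
#'   (cumulative), `prop_of_multiple`, `prop_of_with_predecessor`.
#'   Attributes `n_multiple` and `n_gaps` carry the denominators. With
#'   no multiple-labelled records the proportions are `NA`, not zero.
#' @export
interval_profile <- function(clusters, windows = c(300, 3600, 86400)) {
  if (any(diff(windows) <= 0)) {
    stop("`windows` must be strictly increasing", call. = FALSE)
  }
  multi <- clusters[clusters$size >= 2, , drop = FALSE]
  gaps <- unlist(multi$gaps)
  n_multiple <- sum(multi$size)
  n_gaps <- length(gaps)
  n_within <- vapply(windows, function(w) sum(gaps <= w), numeric(1))
  out <- tibble::tibble(
    window_seconds = as.numeric(windows),
    n_within = n_within,
    prop_of_multiple = if (n_multiple > 0) n_within / n_multiple else
      rep(NA_real_, length(windows)),
    prop_of_with_predecessor = if (n_gaps > 0) n_within / n_gaps else
      rep(NA_real_, length(windows))
  )
  attr(out, "n_multiple") <- n_multiple
  attr(out, "n_gaps") <- n_gaps
  out
}
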