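# Independent brute-force oracles used to cross-check the implementation.

# O(n^2) pairwise linkage + transitive closure by Floyd-Warshall-style
# sweeps; deliberately naive and independent of the union-find path.
oracle_multiplicity <- function(records) {
  n <- nrow(records)
  canon_local <- function(e) {
    e <- tolower(trimws(e))
    local <- sub("@[^@]*$", "", e)
    gsub(".", "", sub("\\+.*$", "", local), fixed = TRUE)
  }
  loc <- ifelse(is.na(records$email), NA, canon_local(records$email))
  adj <- diag(n) > 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      linked <- records$ip[i] == records$ip[j] ||
        (!is.na(loc[i]) && !is.na(loc[j]) && loc[i] == loc[j])
      adj[i, j] <- adj[j, i] <- linked
    }
  }
  for (k in seq_len(n)) {
    adj <- adj | (adj[, k] %o% adj[k, ])
  }
  comp <- integer(n)
  cid <- 0
  for (i in seq_len(n)) {
    if (comp[i] == 0) {
      cid <- cid + 1
      comp[adj[i, ]] <- cid
    }
  }
  sizes <- table(comp)
  tibble::tibble(
    submission_id = records$submission_id,
    component = comp,
    label = ifelse(as.vector(sizes[as.character(comp)]) >= 2,
                   "multiple", "unique")
  )
}

# two-sided Fisher p by direct hypergeometric enumeration
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c
  nn <- b + d
  k <- a + b
  support <- max(0, k - nn):min(k, m)
  probs <- stats::dhyper(support, m, nn, k)
  p_obs <- stats::dhyper(a, m, nn, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided rank-sum p by recursive subset enumeration (distinct
# code path from the implementation's combn-based enumeration)
oracle_wilcox_p <- function(a, b) {
  x <- c(a, b)
  r <- rank(x)
  na <- length(a)
  n <- length(x)
  mu <- na * mean(r)
  obs <- abs(sum(r[seq_len(na)]) - mu)
  count_extreme <- 0
  count_total <- 0
  recurse <- function(pos, left, acc) {
    if (left == 0) {
      count_total <<- count_total + 1
      if (abs(acc - mu) >= obs - 1e-9) count_extreme <<- count_extreme + 1
      return(invisible())
    }
    if (n - pos + 1 < left) return(invisible())
    recurse(pos + 1, left - 1, acc + r[pos])
    recurse(pos + 1, left, acc)
  }
  recurse(1, na, 0)
  count_extreme / count_total
}
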