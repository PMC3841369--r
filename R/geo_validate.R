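#' Validate a postal code against the target region
#'
#' The first character of a Canadian postal code (the FSA letter) encodes
#' the province region; the code is in-region iff that letter is among
#' the configured prefixes. A zero in the second position marks a rural
#' code (no letter-carrier delivery). Rurality is only resolved for
#' in-region codes; out-of-region and absent codes report `"unknown"`.
#' Malformed codes (failing the letter-digit alternation) yield
#' `("unknown", "unknown")` with a warning, never an error.
#'
#' @param code Character vector of normalised postal codes (see
#'   [normalize_postal_code()]); `NA` allowed.
#' @param region_prefixes One-letter FSA prefixes of the target region.
#' @return Tibble with columns `postal_in_region` (`"yes"/"no"/"unknown"`)
#'   and `rurality` (`"rural"/"urban"/"unknown"`).
#' @export
#' @examples
#' validate_postal_code("N0P1L0", c("K", "L", "M", "N", "P"))
validate_postal_code <- function(code, region_prefixes) {
  code <- as.character(code)
  valid <- !is.na(code) & grepl("^[A-Z][0-9][A-Z][0-9][A-Z][0-9]$", code)
  if (any(!is.na(code) & !valid)) {
    warning(sum(!is.na(code) & !valid),
            " malformed postal code(s) treated as unknown", call. = FALSE)
  }
  in_region <- rep("unknown", length(code))
  in_region[valid] <- ifelse(substr(code[valid], 1, 1) %in% region_prefixes,
                             "yes", "no")
  rurality <- rep("unknown", length(code))
  rural <- valid & in_region == "yes"
  rurality[rural] <- ifelse(substr(code[rural], 2, 2) == "0",
                            "rural", "urban")
  tibble::tibble(postal_in_region = in_region, rurality = rurality)
}

# ---- IP handling --------------------------------------------------------

ipv4_to_num <- function(ip) {
  parts <- strsplit(ip, ".", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 4) return(NA_real_)
    v <- suppressWarnings(as.numeric(p))
    if (anyNA(v) || any(v < 0 | v > 255 | v != floor(v))) return(NA_real_)
    sum(v * 256^(3:0))
  }, numeric(1))
}

#' Resolve the region of an IP address from injected lookup tables
#'
#' Longest-prefix match of each address against a table of CIDR blocks
#' and exact addresses; no network access ever. Addresses unmatched by
#' the primary table are retried against an optional fallback table
#' (modelling a manual reverse lookup as a second injected table, so runs
#' stay reproducible offline). Exact entries (no `/`) match any address
#' string, including IPv6; CIDR prefix matching is IPv4. Unmatched or
#' syntactically invalid addresses yield `"unknown"` (invalid ones with a
#' warning).
#'
#' @param ip Character vector of addresses.
#' @param ip_region_table Tibble with columns `cidr`, `region`.
#' @param ip_fallback_table Optional second table, same format.
#' @return Character vector of region labels (`"unknown"` when
#'   unresolved).
#' @export
resolve_ip_region <- function(ip, ip_region_table, ip_fallback_table = NULL) {
  check_ip_table(ip_region_table)
  out <- lookup_ip(ip, ip_region_table, warn_invalid = TRUE)
  if (!is.null(ip_fallback_table)) {
    todo <- out == "unknown"
    if (any(todo)) {
      out[todo] <- lookup_ip(ip[todo], ip_fallback_table,
                             warn_invalid = FALSE)
    }
  }
  out
}

lookup_ip <- function(ip, tab, warn_invalid = FALSE) {
  ip <- as.character(ip)
  out <- rep("unknown", length(ip))

  exact <- !grepl("/", tab$cidr, fixed = TRUE)
  if (any(exact)) {
    hit <- match(ip, tab$cidr[exact])
    out[!is.na(hit)] <- tab$region[exact][hit[!is.na(hit)]]
  }

  cidr <- tab[!exact, , drop = FALSE]
  if (nrow(cidr)) {
    base <- sub("/.*", "", cidr$cidr)
    bits <- as.integer(sub(".*/", "", cidr$cidr))
    base_num <- ipv4_to_num(base)
    ipv4ish <- grepl("^[0-9.]+$", ip)
    num <- rep(NA_real_, length(ip))
    num[ipv4ish] <- ipv4_to_num(ip[ipv4ish])
    if (warn_invalid && any(ipv4ish & is.na(num))) {
      warning(sum(ipv4ish & is.na(num)),
              " syntactically invalid IP address(es) treated as unknown",
              call. = FALSE)
    }
    # exact matches take precedence (treated as /32); otherwise the
    # longest matching prefix wins
    unresolved <- which(out == "unknown" & !is.na(num))
    for (i in unresolved) {
      matches <- num[i] %/% 2^(32 - bits) == base_num %/% 2^(32 - bits)
      if (any(matches)) {
        out[i] <- cidr$region[matches][which.max(bits[matches])]
      }
    }
  }
  out
}

#' Reconcile postal code and IP evidence into a geographic verdict
#'
#' A record is validated as resident in the target region iff both
#' evidence streams affirm it, or exactly one stream is unknown and the
#' other affirms it. The policy is deliberately conservative: an
#' in-region postal code paired with a foreign IP is *not* validated
#' (self-reported postal codes are cheap to fake), and records with both
#' streams unknown are not validated either.
#'
#' For non-validated records an origin label is derived, primarily from
#' the IP region (`other_province`, `us`, `international`); a valid
#' Canadian postal code outside the target region with an unresolved IP
#' maps to `other_province`.
#'
#' @param records Submission tibble (post-screening).
#' @param config A [pipeline_config()].
#' @return Tibble with columns `submission_id`, `postal_in_region`,
#'   `rurality`, `ip_region`, `validated_in_region`, `origin_label`.
#' @export
classify_geography <- function(records, config = pipeline_config()) {
  pc <- validate_postal_code(records$postal_code, config$region_prefixes)
  ipr <- resolve_ip_region(records$ip, config$ip_region_table,
                           config$ip_fallback_table)
  ip_target <- ipr %in% config$target_ip_regions
  ip_unknown <- ipr == "unknown"

  validated <- (pc$postal_in_region == "yes" & ip_target) |
    (pc$postal_in_region == "yes" & ip_unknown) |
    (pc$postal_in_region == "unknown" & ip_target)

  origin <- rep("unknown", nrow(records))
  origin[validated] <- "target_region"
  nv <- !validated
  origin[nv & ipr == "other_canada"] <- "other_province"
  origin[nv & ipr == "us"] <- "us"
  origin[nv & ipr == "international"] <- "international"
  # IP affirms target but the postal code contradicts: treat as
  # other-province (the postal evidence is a valid Canadian code)
  origin[nv & ip_target & pc$postal_in_region == "no"] <- "other_province"
  origin[nv & ip_unknown & pc$postal_in_region == "no"] <- "other_province"

  tibble::tibble(
    submission_id = records$submission_id,
    postal_in_region = pc$postal_in_region,
    rurality = pc$rurality,
    ip_region = ipr,
    validated_in_region = validated,
    origin_label = origin
  )
}
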