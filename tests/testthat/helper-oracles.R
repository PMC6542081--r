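# Independent oracles, deliberately written without the package's set /
# table machinery: nested loops and exhaustive enumeration only.

# distinct-substance count by a plain loop with a "seen" vector
oracle_distinct_count <- function(cohort, id) {
  seen <- character()
  rx <- cohort$prescriptions
  for (r in seq_len(nrow(rx))) {
    if (rx$patient_id[r] == id) {
      d <- rx$drug[r]
      already <- FALSE
      for (s in seen) if (s == d) already <- TRUE
      if (!already) seen <- c(seen, d)
    }
  }
  length(seen)
}

# threshold counts recomputed per patient with nested loops
oracle_threshold_counts <- function(cohort, min_drugs) {
  total <- 0
  for (id in cohort$patients$patient_id) {
    if (oracle_distinct_count(cohort, id) >= min_drugs) total <- total + 1
  }
  total
}

oracle_category_count_in_threshold <- function(cohort, min_drugs, category) {
  reg <- cohort$registry
  total <- 0
  for (id in cohort$patients$patient_id) {
    if (oracle_distinct_count(cohort, id) < min_drugs) next
    has_cat <- FALSE
    rx <- cohort$prescriptions
    for (r in seq_len(nrow(rx))) {
      if (rx$patient_id[r] == id) {
        for (j in seq_len(nrow(reg))) {
          if (reg$name[j] == rx$drug[r] && reg$category[j] == category) {
            has_cat <- TRUE
          }
        }
      }
    }
    if (has_cat) total <- total + 1
  }
  total
}

# brute-force first-ranked selection: score every matched pair with the
# full lexicographic comparator and scan for the maximum
oracle_first_ranked <- function(drugs, kb) {
  best <- NULL
  drugs <- sort(unique(tolower(drugs)))
  if (length(drugs) < 2) return(NULL)
  for (i in seq_along(drugs)) {
    for (j in seq_along(drugs)) {
      if (i >= j) next
      for (r in seq_len(nrow(kb))) {
        pr <- sort(c(kb$drug_a[r], kb$drug_b[r]))
        if (pr[1] == drugs[i] && pr[2] == drugs[j]) {
          cand <- list(pair = paste(pr, collapse = "|"),
                       key = c(kb$action_ord[r], kb$documentation_ord[r],
                               kb$severity_ord[r]))
          if (is.null(best)) {
            best <- cand
          } else {
            a <- cand$key; b <- best$key
            better <- FALSE
            if (a[1] != b[1]) better <- a[1] > b[1]
            else if (a[2] != b[2]) better <- a[2] > b[2]
            else if (a[3] != b[3]) better <- a[3] > b[3]
            else better <- cand$pair < best$pair # alphabetical tie-break
            if (better) best <- cand
          }
        }
      }
    }
  }
  best
}

# exhaustive count of a patient's matched pairs
oracle_match_count <- function(drugs, kb) {
  drugs <- unique(tolower(drugs))
  hits <- 0
  for (i in seq_along(drugs)) {
    for (j in seq_along(drugs)) {
      if (i >= j) next
      for (r in seq_len(nrow(kb))) {
        pr <- sort(c(kb$drug_a[r], kb$drug_b[r]))
        qr <- sort(c(drugs[i], drugs[j]))
        if (pr[1] == qr[1] && pr[2] == qr[2]) hits <- hits + 1
      }
    }
  }
  hits
}

# Fisher two-sided p by explicit hypergeometric tail summation over all
# 2x2 tables with the observed margins
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  prob <- function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }
  p_obs <- prob(a)
  total <- 0
  for (x in lo:hi) {
    px <- prob(x)
    if (px <= p_obs * (1 + 1e-7)) total <- total + px
  }
  total
}

# exact two-sided Mann-Whitney p by enumerating every assignment of ranks
# to group A (no ties assumed)
oracle_mw_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  ranks <- rank(pooled)
  u_stat <- function(ra) sum(ra) - nx * (nx + 1) / 2
  u_obs <- u_stat(ranks[seq_len(nx)])
  mu <- nx * ny / 2
  combos <- utils::combn(nx + ny, nx)
  dev_obs <- abs(u_obs - mu)
  hits <- 0
  for (cc in seq_len(ncol(combos))) {
    u <- u_stat(ranks[combos[, cc]])
    if (abs(u - mu) >= dev_obs - 1e-9) hits <- hits + 1
  }
  hits / ncol(combos)
}
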