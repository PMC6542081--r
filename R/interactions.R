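# Drug-drug interaction engine: knowledge-base loading, attribute-level
# collapsing, pairwise matching and first-ranked selection.
#
# Each knowledge-base record classifies one unordered substance pair by
# mechanism (pharmacodynamic/pharmacokinetic), recommended action,
# documentation and severity. The four raw action levels collapse to three
# ("monitor" and "adjust dose" merge), the four raw documentation levels
# collapse to three ("study" and "extensive" merge). A patient's
# first-ranked interaction is the lexicographic maximum over
# (action, documentation, severity) ordinals — recommended action dominates
# documentation, which dominates severity.

KB_COLUMNS <- c("drug_a", "drug_b", "mechanism", "action", "documentation",
                "severity", "description")
ACTION_RAW <- c("informative", "monitor", "adjust dose", "avoid")
DOCUMENTATION_RAW <- c("theoretical", "case", "study", "extensive")
SEVERITY_LEVELS <- c("mild", "moderate", "severe")
ACTION_LEVELS <- c("informative", "monitor_or_adjust", "avoid")
DOCUMENTATION_LEVELS <- c("theoretical", "case", "study")
MECHANISMS <- c("pharmacodynamic", "pharmacokinetic")

#' Collapse raw interaction attribute levels
#'
#' Maps the raw four-level action and documentation vocabularies onto the
#' three-level ranking scales: "monitor" and "adjust dose" both become
#' `monitor_or_adjust`; "study" and "extensive" both become `study`.
#' Severity is already three-level. The mapping is order-preserving.
#'
#' @param action,documentation,severity character vectors of raw tokens
#'   (case-insensitive).
#' @return data.frame with collapsed `action`, `documentation`, `severity`.
#' @export
#' @examples
#' collapse_levels("adjust dose", "extensive", "moderate")
collapse_levels <- function(action, documentation, severity) {
  action <- tolower(trimws(action))
  documentation <- tolower(trimws(documentation))
  severity <- tolower(trimws(severity))
  stopifnot(all(action %in% ACTION_RAW),
            all(documentation %in% DOCUMENTATION_RAW),
            all(severity %in% SEVERITY_LEVELS))
  data.frame(
    action = ifelse(action %in% c("monitor", "adjust dose"),
                    "monitor_or_adjust", action),
    documentation = ifelse(documentation == "extensive", "study",
                           documentation),
    severity = severity,
    stringsAsFactors = FALSE)
}

#' Ranking key of collapsed interaction levels
#'
#' Encodes collapsed levels as ordinal triples compared lexicographically:
#' action (informative=1 < monitor_or_adjust=2 < avoid=3), then
#' documentation (theoretical=1 < case=2 < study=3), then severity
#' (mild=1 < moderate=2 < severe=3). A larger triple means a more important
#' interaction.
#'
#' @param action,documentation,severity collapsed level tokens.
#' @return integer matrix with columns `action`, `documentation`,
#'   `severity`, one row per input.
#' @export
rank_key <- function(action, documentation, severity) {
  a <- match(action, ACTION_LEVELS)
  d <- match(documentation, DOCUMENTATION_LEVELS)
  s <- match(severity, SEVERITY_LEVELS)
  if (anyNA(a) || anyNA(d) || anyNA(s)) {
    stop("rank_key expects collapsed level tokens", call. = FALSE)
  }
  cbind(action = a, documentation = d, severity = s)
}

pair_key <- function(a, b) {
  a <- tolower(trimws(a)); b <- tolower(trimws(b))
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

new_kb <- function(df, source = "in-memory") {
  miss <- setdiff(KB_COLUMNS, names(df))
  if (length(miss)) {
    stop("Knowledge base missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in KB_COLUMNS) df[[col]] <- trimws(df[[col]])
  df$drug_a <- tolower(df$drug_a)
  df$drug_b <- tolower(df$drug_b)
  df$mechanism <- tolower(df$mechanism)
  tok_ok <- function(x, vocab) tolower(x) %in% vocab
  check <- function(col, vocab) {
    bad <- which(!tok_ok(df[[col]], vocab))
    if (length(bad)) {
      stop(sprintf("Unknown %s token '%s' in knowledge-base row %d",
                   col, df[[col]][bad[1]], bad[1]), call. = FALSE)
    }
  }
  check("mechanism", MECHANISMS)
  check("action", ACTION_RAW)
  check("documentation", DOCUMENTATION_RAW)
  check("severity", SEVERITY_LEVELS)
  if (any(df$drug_a == df$drug_b)) {
    stop("Interaction pair members must be distinct substances",
         call. = FALSE)
  }
  key <- pair_key(df$drug_a, df$drug_b)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("Duplicate unordered pair(s) in knowledge base: ",
         paste(gsub("\\|", " / ", dup), collapse = "; "), call. = FALSE)
  }
  df$action_raw <- tolower(df$action)
  df$documentation_raw <- tolower(df$documentation)
  df$severity <- tolower(df$severity)
  coll <- collapse_levels(df$action_raw, df$documentation_raw, df$severity)
  df$action <- coll$action
  df$documentation <- coll$documentation
  df$pair <- key
  rk <- rank_key(df$action, df$documentation, df$severity)
  df$action_ord <- rk[, "action"]
  df$documentation_ord <- rk[, "documentation"]
  df$severity_ord <- rk[, "severity"]
  rownames(df) <- NULL
  attr(df, "source") <- source
  class(df) <- c("interaction_kb", "data.frame")
  df
}

#' Load an interaction knowledge base
#'
#' Reads a delimited file with header `drug_a,drug_b,mechanism,action,
#' documentation,severity,description`. Tokens are case-insensitive and
#' must come from the raw vocabularies (action: informative/monitor/
#' "adjust dose"/avoid; documentation: theoretical/case/study/extensive;
#' severity: mild/moderate/severe; mechanism: pharmacodynamic/
#' pharmacokinetic). Each unordered substance pair may appear once;
#' `(A,B)` and `(B,A)` conflict.
#'
#' @param path file path.
#' @return an `interaction_kb` data.frame carrying both raw
#'   (`action_raw`, `documentation_raw`) and collapsed levels plus their
#'   ranking ordinals.
#' @export
read_kb <- function(path) {
  if (!file.exists(path)) {
    stop_stage("interaction_engine", "knowledge-base file not found: ", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", strip.white = TRUE)
  new_kb(df, source = path)
}

#' @export
print.interaction_kb <- function(x, ...) {
  cat(sprintf("Interaction knowledge base: %d pairs (%s)\n", nrow(x),
              attr(x, "source")))
  cat(sprintf("  mechanism: %d pharmacodynamic, %d pharmacokinetic\n",
              sum(x$mechanism == "pharmacodynamic"),
              sum(x$mechanism == "pharmacokinetic")))
  invisible(x)
}

#' Match a cohort's drug pairs against a knowledge base
#'
#' For every patient, every unordered pair of distinct substances is looked
#' up in the knowledge base; the first-ranked interaction is the
#' lexicographic maximum over (action, documentation, severity) ordinals.
#' When two matches tie on the full triple, the pair earlier in alphabetical
#' order of its sorted substance names is selected and the tie is recorded.
#'
#' @param cohort a `cohort`.
#' @param kb an `interaction_kb`.
#' @return a `patient_interactions` object: `$matches` (one row per matched
#'   pair per patient), `$first_ranked` (one row per patient with >= 1
#'   match, with a `tie` flag), `$n_patients`, `$n_matches`.
#' @export
match_interactions <- function(cohort, kb) {
  subs <- distinct_substances(cohort)
  kb_idx <- stats::setNames(seq_len(nrow(kb)), kb$pair)

  match_rows <- list()
  for (id in names(subs)) {
    set <- sort(subs[[id]])
    if (length(set) < 2) next
    pairs <- utils::combn(set, 2)
    keys <- pair_key(pairs[1, ], pairs[2, ])
    hit <- keys %in% names(kb_idx)
    if (!any(hit)) next
    rows <- kb[kb_idx[keys[hit]], , drop = FALSE]
    match_rows[[id]] <- data.frame(
      patient_id = id,
      drug_a = rows$drug_a, drug_b = rows$drug_b,
      mechanism = rows$mechanism,
      action = rows$action, documentation = rows$documentation,
      severity = rows$severity,
      action_ord = rows$action_ord,
      documentation_ord = rows$documentation_ord,
      severity_ord = rows$severity_ord,
      description = rows$description,
      pair = rows$pair,
      stringsAsFactors = FALSE)
  }
  matches <- if (length(match_rows)) do.call(rbind, match_rows) else
    data.frame(patient_id = character(), drug_a = character(),
               drug_b = character(), mechanism = character(),
               action = character(), documentation = character(),
               severity = character(), action_ord = integer(),
               documentation_ord = integer(), severity_ord = integer(),
               description = character(), pair = character(),
               stringsAsFactors = FALSE)
  rownames(matches) <- NULL

  fr_rows <- lapply(split(matches, matches$patient_id), function(m) {
    ord <- order(-m$action_ord, -m$documentation_ord, -m$severity_ord,
                 m$pair)
    top <- m[ord[1], , drop = FALSE]
    is_max <- m$action_ord == top$action_ord &
      m$documentation_ord == top$documentation_ord &
      m$severity_ord == top$severity_ord
    top$tie <- sum(is_max) > 1
    top$n_matches <- nrow(m)
    top
  })
  first_ranked <- if (length(fr_rows)) do.call(rbind, fr_rows) else
    cbind(matches, tie = logical(), n_matches = integer())
  first_ranked <- first_ranked[order(match(first_ranked$patient_id,
                                           cohort$patients$patient_id)), ]
  rownames(first_ranked) <- NULL

  structure(list(matches = matches, first_ranked = first_ranked,
                 n_patients = n_patients(cohort),
                 n_matches = nrow(matches), label = cohort$label),
            class = "patient_interactions")
}

#' @export
print.patient_interactions <- function(x, ...) {
  cat(sprintf("Interactions in cohort '%s': %d matches in %d of %d patients\n",
              x$label, x$n_matches, nrow(x$first_ranked), x$n_patients))
  if (nrow(x$first_ranked)) {
    cat(sprintf("  first-ranked share of all matches: %.1f%%; %d tie(s)\n",
                100 * nrow(x$first_ranked) / x$n_matches,
                sum(x$first_ranked$tie)))
  }
  invisible(x)
}

top_two_substances <- function(fr) {
  drugs <- c(fr$drug_a, fr$drug_b)
  if (!length(drugs)) {
    return(data.frame(first_drug = NA_character_, first_pct = NA_real_,
                      second_drug = NA_character_, second_pct = NA_real_))
  }
  # patients whose first-ranked pair involves the substance
  tab <- sort(table(drugs), decreasing = TRUE)
  # alphabetical tie-break for determinism
  tab <- tab[order(-as.integer(tab), names(tab))]
  n <- nrow(fr)
  get <- function(i) {
    if (length(tab) >= i) {
      c(names(tab)[i], pct(as.integer(tab[i]), n))
    } else c(NA_character_, NA_real_)
  }
  f <- get(1); s <- get(2)
  data.frame(first_drug = f[1], first_pct = as.numeric(f[2]),
             second_drug = s[1], second_pct = as.numeric(s[2]),
             stringsAsFactors = FALSE)
}

#' Classify first-ranked interactions
#'
#' Tabulates patients' first-ranked interactions by mechanism, recommended
#' action, documentation and severity. Percentages are of the patients with
#' at least one interaction; within each stratum the two most frequently
#' involved substances are reported with the share of the stratum's
#' patients whose first-ranked pair involves them.
#'
#' @param interactions a `patient_interactions` object, or a `cohort` (in
#'   which case `kb` must be given and matching is run first).
#' @param kb an `interaction_kb`, required when `interactions` is a cohort.
#' @return data.frame with `section`, `label`, `count`, `denom`, `pct`,
#'   `first_drug`, `first_pct`, `second_drug`, `second_pct`.
#' @export
mechanism_summary <- function(interactions, kb = NULL) {
  if (inherits(interactions, "cohort")) {
    if (is.null(kb)) stop("kb required when passing a cohort")
    interactions <- match_interactions(interactions, kb)
  }
  fr <- interactions$first_ranked
  n_pi <- nrow(fr)
  strata <- list(
    mechanism = stats::setNames(MECHANISMS,
                                c("Pharmacodynamic", "Pharmacokinetic")),
    action = stats::setNames(rev(ACTION_LEVELS),
                             c("Avoid", "Monitor or adjust dose",
                               "Informative")),
    documentation = stats::setNames(rev(DOCUMENTATION_LEVELS),
                                    c("Study", "Case", "Theoretical")),
    severity = stats::setNames(rev(SEVERITY_LEVELS),
                               c("Severe", "Moderate", "Mild")))
  rows <- list()
  rows[[1]] <- cbind(
    data.frame(section = "interactions", label = "Patients with interactions",
               count = n_pi, denom = n_pi,
               pct = if (n_pi > 0) 100.0 else NA_real_,
               stringsAsFactors = FALSE),
    top_two_substances(fr))
  for (sec in names(strata)) {
    for (lab in names(strata[[sec]])) {
      level <- strata[[sec]][[lab]]
      in_stratum <- fr[fr[[sec]] == level, , drop = FALSE]
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(section = sec, label = lab, count = nrow(in_stratum),
                   denom = n_pi, pct = pct(nrow(in_stratum), n_pi),
                   stringsAsFactors = FALSE),
        top_two_substances(in_stratum))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
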