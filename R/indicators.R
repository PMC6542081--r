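# Prescribing-quality indicators: psychotropic polypharmacy, PICP
# (potentially inappropriate combinations) and PIPS (potentially
# inappropriate substances), plus the cohort-level tables.
#
# Definitions: polypharmacy = concurrent use of >= 3 distinct psychotropic
# substances (ATC level 5). PICP = >= 2 psychotropics from the same ATC
# level-3 category, or >= 2 psychotropics with anticholinergic effects (a
# drug-property rule that crosses categories); the antiepileptic-pair rule
# is tabulated but excluded from the PICP flag. PIPS = use of >= 1
# long-acting benzodiazepine or anticholinergic psychotropic.

PICP_RULES <- c("2+_antidepressants", "2+_antipsychotics",
                "2+_anxiolytics_hypnotics", "2+_antiepileptics",
                "2+_anticholinergic")
PICP_RULES_IN_DEFINITION <- setdiff(PICP_RULES, "2+_antiepileptics")

#' Per-patient indicator profiles
#'
#' Computes, for every patient, the distinct-substance count, per-category
#' use flags and counts, the polypharmacy flag, the PICP rule hits and flag,
#' and the PIPS substances and flag.
#'
#' @param cohort a `cohort`.
#' @return data.frame with one row per patient: `patient_id`, `age`,
#'   `gender`, `n_substances`, one logical column per category, per-category
#'   substance counts (`n_<category>`), `n_anticholinergic`, `polypharmacy`,
#'   one logical column per PICP rule (`picp_antidepressants`, ...,
#'   `picp_anticholinergic`), `picp`, `pips`, and list columns
#'   `pips_substances` and `picp_rules_hit`.
#' @export
indicator_profiles <- function(cohort) {
  reg <- cohort$registry
  subs <- distinct_substances(cohort)
  ids <- cohort$patients$patient_id
  cats <- psychotropic_categories()

  n_sub <- vapply(subs, length, integer(1))
  cat_count <- function(set, category) {
    sum(reg$category[match(set, reg$name)] == category)
  }
  counts <- sapply(cats, function(cc)
    vapply(subs, cat_count, integer(1), category = cc))
  if (length(ids) == 1L) counts <- matrix(counts, nrow = 1,
                                          dimnames = list(NULL, cats))
  if (length(ids) == 0L) counts <- matrix(integer(), nrow = 0, ncol = 4,
                                          dimnames = list(NULL, cats))
  n_achol <- vapply(subs, function(set)
    sum(reg$anticholinergic[match(set, reg$name)]), integer(1))
  pips_list <- lapply(subs, function(set) {
    # registry order, as the PIPS table lists drugs
    hit <- reg$name[reg$name %in% set &
                      (reg$long_acting_benzo | reg$anticholinergic)]
    hit
  })

  prof <- data.frame(
    patient_id = ids,
    age = cohort$patients$age,
    gender = cohort$patients$gender,
    n_substances = n_sub,
    stringsAsFactors = FALSE)
  for (cc in cats) {
    prof[[cc]] <- counts[, cc] >= 1
    prof[[paste0("n_", cc)]] <- counts[, cc]
  }
  prof$n_anticholinergic <- n_achol
  prof$polypharmacy <- n_sub >= 3
  prof$picp_antidepressants <- counts[, "antidepressant"] >= 2
  prof$picp_antipsychotics <- counts[, "antipsychotic"] >= 2
  prof$picp_anxiolytics_hypnotics <- counts[, "anxiolytic_hypnotic"] >= 2
  prof$picp_antiepileptics <- counts[, "antiepileptic"] >= 2
  prof$picp_anticholinergic <- n_achol >= 2
  prof$picp <- prof$picp_antidepressants | prof$picp_antipsychotics |
    prof$picp_anxiolytics_hypnotics | prof$picp_anticholinergic
  prof$pips <- vapply(pips_list, length, integer(1)) > 0
  prof$pips_substances <- I(unname(pips_list))
  prof$picp_rules_hit <- I(lapply(seq_along(ids), function(i) {
    hits <- c("2+_antidepressants"[prof$picp_antidepressants[i]],
              "2+_antipsychotics"[prof$picp_antipsychotics[i]],
              "2+_anxiolytics_hypnotics"[prof$picp_anxiolytics_hypnotics[i]],
              "2+_antiepileptics"[prof$picp_antiepileptics[i]],
              "2+_anticholinergic"[prof$picp_anticholinergic[i]])
    hits[!is.na(hits)]
  }))
  rownames(prof) <- NULL
  prof
}

#' Polypharmacy flag for one patient
#'
#' @param cohort a `cohort`.
#' @param patient_id patient identifier.
#' @return `TRUE` iff the patient uses three or more distinct psychotropic
#'   substances.
#' @export
polypharmacy_flag <- function(cohort, patient_id) {
  length(distinct_substances(cohort, patient_id)) >= 3
}

#' PICP rule hits for one patient
#'
#' @inheritParams polypharmacy_flag
#' @return character vector of rule identifiers among
#'   `2+_antidepressants`, `2+_antipsychotics`, `2+_anxiolytics_hypnotics`,
#'   `2+_antiepileptics` (reported but excluded from the PICP flag) and
#'   `2+_anticholinergic`. The attribute `picp` carries the overall flag.
#' @export
picp_rules <- function(cohort, patient_id) {
  prof <- indicator_profiles(cohort)
  row <- prof[prof$patient_id == patient_id, ]
  if (!nrow(row)) stop("No such patient: ", patient_id)
  hits <- row$picp_rules_hit[[1]]
  structure(hits, picp = row$picp[1])
}

#' PIPS substances for one patient
#'
#' @inheritParams polypharmacy_flag
#' @return character vector of the patient's PIPS-listed substances, in
#'   registry order.
#' @export
pips_hits <- function(cohort, patient_id) {
  set <- distinct_substances(cohort, patient_id)
  reg <- cohort$registry
  reg$name[reg$name %in% set & (reg$long_acting_benzo | reg$anticholinergic)]
}

CATEGORY_LABELS <- c(antidepressant = "Antidepressants",
                     antipsychotic = "Antipsychotics",
                     anxiolytic_hypnotic = "Anxiolytics-hypnotics",
                     antiepileptic = "Antiepileptics")

#' Cohort indicator table (threshold rows with category shares)
#'
#' The audit's main descriptive table: for each threshold (all patients,
#' >= 1, >= 2, >= 3 distinct psychotropics — the last being polypharmacy),
#' the count of qualifying patients, and within each threshold row the count
#' of patients using each category. Category percentages use the threshold
#' row's count as denominator; an optional interaction row (patients with
#' >= 1 matched interaction) uses the same convention.
#'
#' @param cohort a `cohort`.
#' @param interactions optional `patient_interactions` object (from
#'   [match_interactions()]) appending the interaction rows.
#' @return data.frame with columns `section`, `label`, `count`, `denom`,
#'   `pct`. Empty cohorts yield zero counts and `NA` percentages.
#' @export
cohort_indicator_table <- function(cohort, interactions = NULL) {
  prof <- indicator_profiles(cohort)
  n <- nrow(prof)
  cats <- psychotropic_categories()

  rows <- list()
  add <- function(section, label, count, denom) {
    rows[[length(rows) + 1L]] <<- data.frame(
      section = section, label = label, count = count, denom = denom,
      pct = pct(count, denom), stringsAsFactors = FALSE)
  }
  thresholds <- list(
    list(section = "all_patients", label = "All patients", min = 0L),
    list(section = "1_or_more", label = "One or more drugs", min = 1L),
    list(section = "2_or_more", label = "Two or more drugs", min = 2L),
    list(section = "3_or_more", label = "Three or more drugs (polypharmacy)",
         min = 3L))
  for (th in thresholds) {
    in_row <- prof$n_substances >= th$min
    k <- sum(in_row)
    add(th$section, th$label, k, n)
    for (cc in cats) {
      add(th$section, CATEGORY_LABELS[[cc]], sum(in_row & prof[[cc]]), k)
    }
  }
  if (!is.null(interactions)) {
    with_pi <- prof$patient_id %in% interactions$first_ranked$patient_id
    k <- sum(with_pi)
    add("1_or_more_interactions", ">= 1 interaction", k, n)
    for (cc in cats) {
      add("1_or_more_interactions", CATEGORY_LABELS[[cc]],
          sum(with_pi & prof[[cc]]), k)
    }
  }
  do.call(rbind, rows)
}

CATEGORY_PAIRS <- utils::combn(psychotropic_categories(), 2, simplify = FALSE)

#' Combination, PICP and PIPS table
#'
#' The audit's inappropriate-prescribing table: patients with >= 2
#' concurrent categories and each unordered category pair among them; the
#' PICP family count with its five rules; the PIPS family count with the
#' per-drug breakdown. Sub-row percentages use the family count as
#' denominator (chosen to surface the most frequent inappropriate pattern
#' within each family).
#'
#' @param cohort a `cohort`.
#' @return data.frame with columns `section`, `label`, `count`, `denom`,
#'   `pct`.
#' @export
combination_table <- function(cohort) {
  prof <- indicator_profiles(cohort)
  n <- nrow(prof)
  rows <- list()
  add <- function(section, label, count, denom) {
    rows[[length(rows) + 1L]] <<- data.frame(
      section = section, label = label, count = count, denom = denom,
      pct = pct(count, denom), stringsAsFactors = FALSE)
  }

  n_cats <- rowSums(as.matrix(prof[, psychotropic_categories(), drop = FALSE]))
  multi <- n_cats >= 2
  add("combinations", "Combination of categories", sum(multi), n)
  for (pair in CATEGORY_PAIRS) {
    lab <- paste(CATEGORY_LABELS[[pair[1]]], "+",
                 tolower(CATEGORY_LABELS[[pair[2]]]))
    add("combinations", lab, sum(prof[[pair[1]]] & prof[[pair[2]]]),
        sum(multi))
  }

  n_picp <- sum(prof$picp)
  add("picp", "Potentially inappropriate combinations (PICP)", n_picp, n)
  picp_rows <- c(picp_antidepressants = "Two or more antidepressants",
                 picp_antipsychotics = "Two or more antipsychotics",
                 picp_anxiolytics_hypnotics = "Two or more anxiolytics-hypnotics",
                 picp_antiepileptics = "Two or more antiepileptics (not in PICP)",
                 picp_anticholinergic = "Two or more anticholinergic psychotropics")
  for (col in names(picp_rows)) {
    add("picp", picp_rows[[col]], sum(prof[[col]]), n_picp)
  }

  n_pips <- sum(prof$pips)
  add("pips", "Potentially inappropriate substances (PIPS)", n_pips, n)
  reg <- cohort$registry
  pips_drugs <- reg[reg$long_acting_benzo | reg$anticholinergic, ]
  used <- unlist(prof$pips_substances, use.names = FALSE)
  for (i in seq_len(nrow(pips_drugs))) {
    d <- pips_drugs$name[i]
    grp <- if (pips_drugs$long_acting_benzo[i]) "Long-acting benzodiazepine"
           else "Anticholinergic"
    add("pips", sprintf("%s (%s)", d, grp), sum(used == d), n_pips)
  }
  do.call(rbind, rows)
}

#' Compare two cohort tables row-by-row
#'
#' Joins two tables produced by [cohort_indicator_table()],
#' [combination_table()] or [mechanism_summary()] on `section` + `label` and
#' appends a chi-square / Fisher's-exact comparison of proportions per row.
#'
#' @param table_a,table_b tables with `section`, `label`, `count`, `denom`.
#' @param suffixes column name suffixes for the two cohorts.
#' @return merged data.frame with `test_used`, `p_value` and `significant`
#'   (p < 0.01) columns; rows with a zero denominator get `NA`.
#' @export
compare_tables <- function(table_a, table_b, suffixes = c("_a", "_b")) {
  m <- merge(table_a, table_b, by = c("section", "label"), sort = FALSE,
             suffixes = suffixes)
  ca <- m[[paste0("count", suffixes[1])]]
  da <- m[[paste0("denom", suffixes[1])]]
  cb <- m[[paste0("count", suffixes[2])]]
  db <- m[[paste0("denom", suffixes[2])]]
  res <- lapply(seq_len(nrow(m)), function(i) {
    if (da[i] == 0 || db[i] == 0) {
      return(data.frame(test_used = NA_character_, p_value = NA_real_,
                        significant = NA))
    }
    cmp <- compare_proportions(ca[i], da[i], cb[i], db[i])
    data.frame(test_used = cmp$test_used, p_value = cmp$p_value,
               significant = cmp$significant)
  })
  cbind(m, do.call(rbind, res))
}
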