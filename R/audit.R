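# Audit orchestration: the full one- or two-cohort report bundle.

#' Published aggregate counts of the two audits
#'
#' The headline aggregate results of the two nursing-home point-prevalence
#' audits (386 patients in 2000, 416 in 2016), as published: numerators and
#' denominators for the indicator prevalences, total prescription and
#' interaction counts. Useful as worked-example inputs and for comparing a
#' synthetic run against the study's scale.
#'
#' @return data.frame with columns `quantity`, `count_2000`, `denom_2000`,
#'   `count_2016`, `denom_2016`.
#' @export
#' @examples
#' ref <- reference_counts()
#' pct(ref$count_2000[ref$quantity == "polypharmacy"], 386) # 6.2
reference_counts <- function() {
  df <- data.frame(
    quantity = c("patients", "prescriptions", "one_or_more", "two_or_more",
                 "polypharmacy", "picp", "pips", "patients_with_pi",
                 "total_pi", "first_ranked_pharmacodynamic"),
    count_2000 = c(386, 352, 230, 94, 24, 30, 69, 63, 94, 44),
    denom_2000 = c(386, 386, 386, 386, 386, 386, 386, 386, 94, 63),
    count_2016 = c(416, 765, 335, 233, 123, 116, 47, 146, 236, 135),
    denom_2016 = c(416, 416, 416, 416, 416, 416, 416, 416, 236, 146),
    stringsAsFactors = FALSE)
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     eol = "\n", na = "")
  invisible(path)
}

drug_frequency_table <- function(cohort) {
  prof_sets <- distinct_substances(cohort)
  used <- unlist(prof_sets, use.names = FALSE)
  reg <- cohort$registry
  counts <- vapply(reg$name, function(d) sum(used == d), integer(1))
  data.frame(section = reg$category, label = reg$name,
             count = unname(counts), denom = n_patients(cohort),
             pct = pct(unname(counts), n_patients(cohort)),
             stringsAsFactors = FALSE)
}

#' Run the full prescribing-quality audit
#'
#' Orchestrates every stage on one or two cohorts: drug-frequency table,
#' indicator table, combination/PICP/PIPS table, first-ranked interaction
#' classification, and (when the population permits) the three-step
#' logistic regression. With two cohorts, every shared table row gets a
#' chi-square / Fisher comparison. All tables are written as TSV to
#' `out_dir` together with a JSON metadata file; outputs are deterministic
#' functions of the inputs.
#'
#' @param cohorts a `cohort`, a list of one or two `cohort`s, or character
#'   paths read via [read_cohort()].
#' @param kb an `interaction_kb` or a path read via [read_kb()].
#' @param out_dir output directory, created if needed; `NULL` skips
#'   writing.
#' @param registry registry used when `cohorts` are paths.
#' @param skip_unknown_drugs passed to [read_cohort()].
#' @return a `report_bundle` list of the tables, invisibly when writing.
#' @export
run_audit <- function(cohorts, kb, out_dir = NULL,
                      registry = default_registry(),
                      skip_unknown_drugs = FALSE) {
  if (inherits(cohorts, "cohort")) cohorts <- list(cohorts)
  if (is.character(cohorts)) cohorts <- as.list(cohorts)
  if (!is.list(cohorts) || !length(cohorts) %in% 1:2) {
    stop_stage("audit", "expected one or two cohorts")
  }
  cohorts <- lapply(cohorts, function(co) {
    if (is.character(co)) {
      tryCatch(
        read_cohort(co, registry, skip_unknown_drugs = skip_unknown_drugs),
        error = function(e) {
          msg <- conditionMessage(e)
          if (grepl("^\\[", msg)) stop(msg, call. = FALSE)
          stop_stage("cohort_io", msg)
        })
    } else co
  })
  if (is.character(kb)) kb <- read_kb(kb)
  if (!inherits(kb, "interaction_kb")) {
    stop_stage("interaction_engine", "kb must be an interaction_kb or a path")
  }

  per_cohort <- lapply(cohorts, function(co) {
    pi <- tryCatch(match_interactions(co, kb),
                   error = function(e) stop_stage("interaction_engine",
                                                  conditionMessage(e)))
    ind <- tryCatch(cohort_indicator_table(co, interactions = pi),
                    error = function(e) stop_stage("indicators",
                                                   conditionMessage(e)))
    comb <- tryCatch(combination_table(co),
                     error = function(e) stop_stage("indicators",
                                                    conditionMessage(e)))
    mech <- mechanism_summary(pi)
    logit <- tryCatch(logistic_procedure(co, kb), error = function(e) NULL)
    list(cohort = co, interactions = pi, drug_freq = drug_frequency_table(co),
         indicator = ind, combination = comb, mechanism = mech,
         logistic = logit)
  })

  two <- length(per_cohort) == 2
  bundle <- list(
    labels = vapply(per_cohort, function(x) x$cohort$label, character(1)),
    per_cohort = per_cohort)
  if (two) {
    bundle$indicator_comparison <- compare_tables(
      per_cohort[[1]]$indicator, per_cohort[[2]]$indicator)
    bundle$combination_comparison <- compare_tables(
      per_cohort[[1]]$combination, per_cohort[[2]]$combination)
    bundle$mechanism_comparison <- compare_tables(
      per_cohort[[1]]$mechanism[, c("section", "label", "count", "denom",
                                    "pct")],
      per_cohort[[2]]$mechanism[, c("section", "label", "count", "denom",
                                    "pct")])
  }
  class(bundle) <- "report_bundle"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(per_cohort)) {
      lab <- gsub("[^A-Za-z0-9_.-]", "_", bundle$labels[i])
      pc <- per_cohort[[i]]
      write_tsv(pc$drug_freq, file.path(out_dir,
                                        sprintf("drug_frequency_%s.tsv", lab)))
      write_tsv(pc$indicator, file.path(out_dir,
                                        sprintf("indicators_%s.tsv", lab)))
      write_tsv(pc$combination, file.path(out_dir,
                                          sprintf("combinations_%s.tsv", lab)))
      write_tsv(pc$mechanism, file.path(out_dir,
                                        sprintf("interactions_%s.tsv", lab)))
      if (!is.null(pc$logistic)) {
        lg <- pc$logistic
        lg_tab <- merge(lg$step1, lg$step3, by = "predictor", all.x = TRUE,
                        suffixes = c("_unadjusted", "_final"), sort = TRUE)
        write_tsv(lg_tab, file.path(out_dir,
                                    sprintf("logistic_%s.tsv", lab)))
        write_tsv(lg$vif, file.path(out_dir, sprintf("vif_%s.tsv", lab)))
      }
    }
    if (two) {
      write_tsv(bundle$indicator_comparison,
                file.path(out_dir, "comparison_indicators.tsv"))
      write_tsv(bundle$combination_comparison,
                file.path(out_dir, "comparison_combinations.tsv"))
      write_tsv(bundle$mechanism_comparison,
                file.path(out_dir, "comparison_interactions.tsv"))
    }
    meta <- list(
      cohorts = lapply(per_cohort, function(pc) list(
        label = pc$cohort$label,
        n_patients = n_patients(pc$cohort),
        excluded_by_age = pc$cohort$excluded_count,
        n_prescriptions = nrow(pc$cohort$prescriptions),
        n_interaction_matches = pc$interactions$n_matches,
        first_ranked_ties = sum(pc$interactions$first_ranked$tie))),
      kb_pairs = nrow(kb),
      indicator_conventions = list(
        polypharmacy_threshold = 3,
        age_filter = ">=65 (indicators originally recommended for >=75)",
        substance_level = "ATC level 5; regular and as-needed deduplicated",
        picp_excludes = "2+_antiepileptics",
        gender_coding = "male = 1"))
    jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(bundle))
  }
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("Audit report bundle: %s\n", paste(x$labels, collapse = " vs ")))
  for (pc in x$per_cohort) {
    ind <- pc$indicator
    poly <- ind[ind$label == "Three or more drugs (polypharmacy)", ]
    cat(sprintf("  %s: n = %d, polypharmacy %d (%.1f%%), interactions in %d\n",
                pc$cohort$label, n_patients(pc$cohort), poly$count, poly$pct,
                nrow(pc$interactions$first_ranked)))
  }
  invisible(x)
}
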