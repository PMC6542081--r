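# Cohort I/O: read, validate and filter patient-level prescription charts.
#
# The interchange format is long: one row per prescription, with patient
# attributes repeated on every row and checked for consistency. A patient
# with no psychotropic prescriptions is encoded as a single row with an
# empty drug_name (such patients are part of every denominator).

COHORT_COLUMNS <- c("patient_id", "age", "gender", "drug_name", "atc",
                    "as_needed")

new_cohort <- function(label, patients, prescriptions, excluded_count,
                       registry) {
  stopifnot(!anyDuplicated(patients$patient_id), all(patients$age >= 65))
  rownames(patients) <- NULL
  rownames(prescriptions) <- NULL
  structure(
    list(label = label, patients = patients, prescriptions = prescriptions,
         excluded_count = excluded_count, registry = registry),
    class = "cohort")
}

#' Read a patient-level prescription chart
#'
#' Reads the long-format cohort CSV (header `patient_id,age,gender,
#' drug_name,atc,as_needed[,dose,time]`), validates every field, resolves
#' every drug against the registry, collapses duplicated prescription rows
#' (with a warning) and applies the age >= 65 inclusion filter, counting the
#' excluded patients.
#'
#' Both regularly scheduled and as-needed (PRN) prescriptions are retained:
#' the audit's point-prevalence indicators deliberately include on-demand
#' drugs. Gender must be `F` or `M` (the downstream predictor coding is
#' binary). Rows with an empty `drug_name` declare a patient without
#' psychotropic prescriptions.
#'
#' @param path cohort CSV path.
#' @param registry a `drug_registry` used to resolve drug names.
#' @param label cohort label (e.g. the audit year); defaults to the file
#'   name.
#' @param skip_unknown_drugs if `TRUE`, prescriptions whose drug name is not
#'   in the registry are dropped with a message instead of raising an error.
#' @return a `cohort` object: `$patients` (patient_id, age, gender),
#'   `$prescriptions` (patient_id, drug, atc, category, as_needed),
#'   `$excluded_count`, `$label`, `$registry`.
#' @export
read_cohort <- function(path, registry = default_registry(),
                        label = basename(path), skip_unknown_drugs = FALSE) {
  if (!file.exists(path)) {
    stop_stage("cohort_io", "cohort file not found: ", path)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", strip.white = TRUE)
  miss <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(miss)) {
    stop_stage("cohort_io", "missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    patients <- data.frame(patient_id = character(), age = integer(),
                           gender = character(), stringsAsFactors = FALSE)
    rx <- data.frame(patient_id = character(), drug = character(),
                     atc = character(), category = character(),
                     as_needed = logical(), stringsAsFactors = FALSE)
    return(new_cohort(label, patients, rx, 0L, registry))
  }

  age_num <- suppressWarnings(as.numeric(raw$age))
  if (anyNA(age_num)) {
    stop_stage("cohort_io", "non-numeric age for patient(s): ",
               paste(unique(raw$patient_id[is.na(age_num)]), collapse = ", "))
  }
  raw$age <- age_num
  raw$gender <- toupper(raw$gender)
  if (!all(raw$gender %in% c("F", "M"))) {
    bad <- unique(raw$gender[!raw$gender %in% c("F", "M")])
    stop_stage("cohort_io", "gender must be F or M; found: ",
               paste(bad, collapse = ", "))
  }

  # patient attributes must agree across a patient's rows
  pat <- unique(raw[, c("patient_id", "age", "gender")])
  if (anyDuplicated(pat$patient_id)) {
    bad <- unique(pat$patient_id[duplicated(pat$patient_id)])
    stop_stage("cohort_io", "inconsistent age/gender across rows for: ",
               paste(bad, collapse = ", "))
  }

  has_drug <- !is.na(raw$drug_name) & trimws(raw$drug_name) != ""
  rx <- raw[has_drug, , drop = FALSE]
  if (nrow(rx)) {
    if (!all(rx$as_needed %in% c("0", "1"))) {
      stop_stage("cohort_io", "as_needed must be coded 0/1")
    }
    idx <- lookup_drug(registry, rx$drug_name,
                       skip_unknown = skip_unknown_drugs)
    keep <- !is.na(idx)
    rx <- rx[keep, , drop = FALSE]
    idx <- idx[keep]
    rx_atc <- trimws(rx$atc)
    if (any(rx_atc != "")) {
      given <- toupper(rx_atc[rx_atc != ""])
      expect <- registry$atc[idx][rx_atc != ""]
      if (any(given != expect)) {
        warning("ATC code(s) in file disagree with registry; registry codes used",
                call. = FALSE)
      }
    }
    rx <- data.frame(patient_id = rx$patient_id,
                     drug = registry$name[idx],
                     atc = registry$atc[idx],
                     category = registry$category[idx],
                     as_needed = rx$as_needed == "1",
                     stringsAsFactors = FALSE)
    dup <- duplicated(rx[, c("patient_id", "drug", "as_needed")])
    if (any(dup)) {
      warning(sprintf("%d duplicate prescription row(s) collapsed", sum(dup)),
              call. = FALSE)
      rx <- rx[!dup, , drop = FALSE]
    }
  } else {
    rx <- data.frame(patient_id = character(), drug = character(),
                     atc = character(), category = character(),
                     as_needed = logical(), stringsAsFactors = FALSE)
  }

  young <- pat$age < 65
  excluded <- sum(young)
  pat <- pat[!young, , drop = FALSE]
  pat$age <- as.integer(pat$age)
  rx <- rx[rx$patient_id %in% pat$patient_id, , drop = FALSE]
  new_cohort(label, pat, rx, as.integer(excluded), registry)
}

#' Number of patients in a cohort
#' @param cohort a `cohort`.
#' @return integer patient count (after the age filter).
#' @export
n_patients <- function(cohort) nrow(cohort$patients)

#' Distinct substances per patient
#'
#' Deduplicates each patient's prescriptions at ATC level 5 (chemical
#' substance): a drug prescribed both regularly and as-needed counts once.
#'
#' @param cohort a `cohort`.
#' @param patient_id optional single id; if omitted, returns a named list
#'   over all patients (empty character vectors for drug-free patients).
#' @return character vector of substance names, or a named list of them.
#' @export
distinct_substances <- function(cohort, patient_id = NULL) {
  sets <- split(cohort$prescriptions$drug, cohort$prescriptions$patient_id)
  sets <- lapply(sets, unique)
  all_ids <- cohort$patients$patient_id
  out <- stats::setNames(vector("list", length(all_ids)), all_ids)
  for (id in all_ids) out[[id]] <- sets[[id]] %||% character()
  if (!is.null(patient_id)) {
    if (!patient_id %in% all_ids) stop("No such patient: ", patient_id)
    return(out[[patient_id]])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Category registrations per patient
#'
#' Concurrent use of several substances from the same category results in a
#' single registration per patient (e.g. "uses >= 1 antidepressants").
#'
#' @inheritParams distinct_substances
#' @return character vector of categories present, or a named list of them.
#' @export
category_registrations <- function(cohort, patient_id = NULL) {
  sets <- split(cohort$prescriptions$category, cohort$prescriptions$patient_id)
  sets <- lapply(sets, unique)
  all_ids <- cohort$patients$patient_id
  out <- stats::setNames(vector("list", length(all_ids)), all_ids)
  for (id in all_ids) out[[id]] <- sets[[id]] %||% character()
  if (!is.null(patient_id)) {
    if (!patient_id %in% all_ids) stop("No such patient: ", patient_id)
    return(out[[patient_id]])
  }
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort '%s': %d patients (%d excluded by age < 65)\n",
              x$label, nrow(x$patients), x$excluded_count))
  cat(sprintf("  %d prescription rows, %d distinct substances\n",
              nrow(x$prescriptions), length(unique(x$prescriptions$drug))))
  if (nrow(x$patients)) {
    cat(sprintf("  age %d-%d (mean %.1f), %.1f%% male\n",
                min(x$patients$age), max(x$patients$age),
                mean(x$patients$age),
                100 * mean(x$patients$gender == "M")))
  }
  invisible(x)
}

#' Write a cohort in the interchange CSV format
#'
#' Inverse of [read_cohort()]; drug-free patients get a single row with an
#' empty `drug_name`. Output is deterministic (stable row order), so two
#' writes of the same cohort are byte-identical.
#'
#' @param cohort a `cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  pat <- cohort$patients
  rx <- cohort$prescriptions
  rows <- merge(pat, rx, by = "patient_id", all.x = TRUE, sort = FALSE)
  rows <- rows[order(match(rows$patient_id, pat$patient_id), rows$drug), ]
  out <- data.frame(
    patient_id = rows$patient_id,
    age = rows$age,
    gender = rows$gender,
    drug_name = ifelse(is.na(rows$drug), "", rows$drug),
    atc = ifelse(is.na(rows$atc), "", rows$atc),
    as_needed = ifelse(is.na(rows$as_needed), "",
                       as.character(as.integer(rows$as_needed))),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}
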