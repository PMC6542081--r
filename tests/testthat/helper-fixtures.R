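# Shared fixture builders: tiny cohorts written through the real CSV
# interface so every test also exercises the reader.

cohort_csv_header <- "patient_id,age,gender,drug_name,atc,as_needed"

write_cohort_file <- function(rows) {
  path <- tempfile(fileext = ".csv")
  writeLines(c(cohort_csv_header, rows), path)
  path
}

# drug_lists: named list patient_id -> character vector of drug names
# (possibly with duplicates to emulate regular + PRN rows)
toy_cohort <- function(drug_lists, ages = NULL, genders = NULL,
                       registry = default_registry(), label = "toy") {
  ids <- names(drug_lists)
  if (is.null(ages)) ages <- rep(84L, length(ids))
  if (is.null(genders)) genders <- rep("F", length(ids))
  rows <- character()
  for (i in seq_along(ids)) {
    drugs <- drug_lists[[i]]
    if (!length(drugs)) {
      rows <- c(rows, sprintf("%s,%d,%s,,,", ids[i], ages[i], genders[i]))
    } else {
      prn <- as.integer(duplicated(drugs)) # second entry of a dup = PRN row
      rows <- c(rows, sprintf("%s,%d,%s,%s,,%d", ids[i], ages[i],
                              genders[i], drugs, prn))
    }
  }
  path <- tempfile(fileext = ".csv")
  writeLines(c(cohort_csv_header, rows), path)
  on.exit(unlink(path))
  read_cohort(path, registry, label = label)
}

# A random cohort drawn directly from the registry (uniform drug choice),
# independent of the synthetic-data module's sampling design.
random_toy_cohort <- function(n, seed, max_drugs = 6,
                              registry = default_registry()) {
  set.seed(seed)
  drug_lists <- lapply(seq_len(n), function(i) {
    k <- sample(0:max_drugs, 1)
    sample(registry$name, k)
  })
  names(drug_lists) <- sprintf("R%03d", seq_len(n))
  ages <- sample(65:99, n, replace = TRUE)
  genders <- sample(c("F", "M"), n, replace = TRUE)
  toy_cohort(drug_lists, ages, genders, registry)
}
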