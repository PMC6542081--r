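# The drug registry: canonical substance names, level-5 ATC codes, PIPS
# flags (long-acting benzodiazepine, anticholinergic) and the published
# per-drug prevalence counts used as default synthetic sampling weights.

# name, atc5, long_acting_benzo, anticholinergic, n_2000, n_2016
REGISTRY_TABLE <- list(
  # antidepressants (N06A)
  c("clomipramine",    "N06AA04", 0, 1,  1,   0),
  c("doxepin",         "N06AA12", 0, 0,  2,   0),
  c("nortriptyline",   "N06AA10", 0, 1,  6,   0),
  c("paroxetine",      "N06AB05", 0, 0, 16,   0),
  c("amitriptyline",   "N06AA09", 0, 1,  8,   2),
  c("citalopram",      "N06AB04", 0, 0, 51,  25),
  c("mianserin",       "N06AX03", 0, 0, 15,  10),
  c("sertraline",      "N06AB06", 0, 0,  8,  15),
  c("bupropion",       "N06AX12", 0, 0,  0,   4),
  c("escitalopram",    "N06AB10", 0, 0,  0,  57),
  c("mirtazapine",     "N06AX11", 0, 0,  0,  89),
  c("moclobemide",     "N06AG02", 0, 0,  0,   1),
  c("venlafaxine",     "N06AX16", 0, 0,  0,  11),
  # antipsychotics (N05A)
  c("chlorpromazine",  "N05AA01", 0, 1,  7,   0),
  c("flupentixol",     "N05AF01", 0, 0,  3,   0),
  c("fluphenazine",    "N05AB02", 0, 0,  1,   0),
  c("melperone",       "N05AD03", 0, 0,  5,   0),
  c("perphenazine",    "N05AB03", 0, 0,  3,   0),
  c("sertindole",      "N05AE03", 0, 0,  1,   0),
  c("chlorprothixene", "N05AF03", 0, 1,  2,   3),
  c("haloperidol",     "N05AD01", 0, 0, 14,  27),
  c("levomepromazine", "N05AA02", 0, 1, 18,   4),
  c("lithium",         "N05AN01", 0, 0,  2,   1),
  c("olanzapine",      "N05AH03", 0, 0,  7,  13),
  c("risperidone",     "N05AX08", 0, 0, 33,   8),
  c("prochlorperazine","N05AB04", 0, 1,  2,   1),
  c("zuclopenthixol",  "N05AF05", 0, 0,  4,   2),
  c("clozapine",       "N05AH02", 0, 0,  0,   4),
  c("quetiapine",      "N05AH04", 0, 0,  0,  72),
  # anxiolytics-hypnotics (N05B / N05C)
  c("buspirone",       "N05BE01", 0, 0,  1,   0),
  c("flunitrazepam",   "N05CD03", 1, 0,  5,   0),
  c("diazepam",        "N05BA01", 1, 0, 14,  33),
  c("oxazepam",        "N05BA04", 0, 0, 40, 164),
  c("hydroxyzine",     "N05BB01", 0, 1,  3,   3),
  c("nitrazepam",      "N05CD02", 1, 0, 11,   2),
  c("zolpidem",        "N05CF02", 0, 0,  2,   5),
  c("zopiclone",       "N05CF01", 0, 0, 34, 113),
  c("clomethiazole",   "N05CM02", 0, 0,  0,  20),
  c("melatonin",       "N05CH01", 0, 0,  0,   6),
  c("midazolam",       "N05CD08", 0, 0,  0,  19),
  # antiepileptics (N03A)
  c("phenobarbital",   "N03AA02", 0, 0,  3,   0),
  c("phenytoin",       "N03AB02", 0, 0,  4,   0),
  c("gabapentin",      "N03AX12", 0, 0,  1,   8),
  c("carbamazepine",   "N03AF01", 0, 0, 23,   6),
  c("clonazepam",      "N03AE01", 0, 0,  2,   1),
  c("valproic acid",   "N03AG01", 0, 0,  2,   9),
  c("lamotrigine",     "N03AX09", 0, 0,  0,   4),
  c("levetiracetam",   "N03AX14", 0, 0,  0,  17),
  c("pregabalin",      "N03AX16", 0, 0,  0,   5)
)

new_registry <- function(df) {
  df$name <- tolower(trimws(df$name))
  if (anyDuplicated(df$name)) {
    stop("Duplicate drug name(s) in registry: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "),
         call. = FALSE)
  }
  df$atc <- validate_atc(df$atc)
  if (any(nchar(df$atc) != 7L)) {
    stop("Registry ATC codes must be level-5 (7 characters)", call. = FALSE)
  }
  df$long_acting_benzo <- as.logical(df$long_acting_benzo)
  df$anticholinergic <- as.logical(df$anticholinergic)
  df$category <- atc_category(df$atc)
  if (anyNA(df$category)) {
    stop("Registry contains non-psychotropic ATC code(s): ",
         paste(df$atc[is.na(df$category)], collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("drug_registry", "data.frame")
  df
}

#' Default psychotropic drug registry
#'
#' The 49 psychotropic substances of the audited nursing-home cohorts, each
#' with its WHO level-5 ATC code, the two PIPS flags (long-acting
#' benzodiazepine; anticholinergic effects) and the published per-drug
#' patient counts at the two audit timepoints (`n_2000`, `n_2016`), which
#' serve as default prevalence weights for the synthetic-cohort generator.
#'
#' @return a `drug_registry` data.frame with columns `name`, `atc`,
#'   `long_acting_benzo`, `anticholinergic`, `n_2000`, `n_2016`, `category`.
#' @export
#' @examples
#' reg <- default_registry()
#' table(reg$category)
default_registry <- function() {
  df <- as.data.frame(do.call(rbind, REGISTRY_TABLE), stringsAsFactors = FALSE)
  names(df) <- c("name", "atc", "long_acting_benzo", "anticholinergic",
                 "n_2000", "n_2016")
  df$long_acting_benzo <- df$long_acting_benzo == "1"
  df$anticholinergic <- df$anticholinergic == "1"
  df$n_2000 <- as.numeric(df$n_2000)
  df$n_2016 <- as.numeric(df$n_2016)
  new_registry(df)
}

#' Read a drug registry from a delimited file
#'
#' Expected header: `name, atc, long_acting_benzo, anticholinergic` with the
#' flags coded 0/1. All entries must carry level-5 ATC codes with a
#' psychotropic prefix.
#'
#' @param path file path.
#' @return a `drug_registry` data.frame.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("Registry file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", strip.white = TRUE)
  need <- c("name", "atc", "long_acting_benzo", "anticholinergic")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("Registry file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$long_acting_benzo %in% c("0", "1")) ||
      !all(df$anticholinergic %in% c("0", "1"))) {
    stop("Registry flags must be coded 0/1", call. = FALSE)
  }
  df$long_acting_benzo <- df$long_acting_benzo == "1"
  df$anticholinergic <- df$anticholinergic == "1"
  df$n_2000 <- NA_real_
  df$n_2016 <- NA_real_
  new_registry(df)
}

#' Write a registry in the interchange format
#'
#' @param registry a `drug_registry`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  out <- data.frame(name = registry$name, atc = registry$atc,
                    long_acting_benzo = as.integer(registry$long_acting_benzo),
                    anticholinergic = as.integer(registry$anticholinergic))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

# Resolve drug names (case-insensitively) to registry row indices.
# Unknown names error with the nearest registry names, or are skipped with a
# message when skip_unknown = TRUE (returning NA for those positions).
lookup_drug <- function(registry, name, skip_unknown = FALSE) {
  key <- tolower(trimws(name))
  idx <- match(key, registry$name)
  if (anyNA(idx[!is.na(key) & key != ""])) {
    unknown <- unique(key[is.na(idx) & !is.na(key) & key != ""])
    nearest <- vapply(unknown, function(u) {
      d <- utils::adist(u, registry$name)
      paste(registry$name[order(d)][1:3], collapse = ", ")
    }, character(1))
    msg <- paste0("Unknown drug name(s): ",
                  paste(sprintf("'%s' (nearest: %s)", unknown, nearest),
                        collapse = "; "))
    if (!skip_unknown) stop(msg, call. = FALSE)
    message("Skipping unresolved drugs. ", msg)
  }
  idx
}

#' PIPS flag of a drug
#'
#' Potentially inappropriate psychotropic substances (PIPS) are, by
#' definition, long-acting benzodiazepines and psychotropics with
#' anticholinergic effects. Returns which rule (if any) lists each drug.
#'
#' @param drug character vector of drug names (case-insensitive).
#' @param registry a `drug_registry`; defaults to [default_registry()].
#' @return character vector over `{"long_acting_benzodiazepine",
#'   "anticholinergic", "none"}`.
#' @export
#' @examples
#' pips_flag(c("diazepam", "zopiclone", "levomepromazine"))
pips_flag <- function(drug, registry = default_registry()) {
  idx <- lookup_drug(registry, drug)
  ifelse(registry$long_acting_benzo[idx], "long_acting_benzodiazepine",
         ifelse(registry$anticholinergic[idx], "anticholinergic", "none"))
}

#' @export
print.drug_registry <- function(x, ...) {
  cat(sprintf("Drug registry: %d psychotropic substances\n", nrow(x)))
  cat(sprintf("  PIPS-listed: %d long-acting benzodiazepines, %d anticholinergic\n",
              sum(x$long_acting_benzo), sum(x$anticholinergic)))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("  ... and %d more rows\n", nrow(x) - 5))
  invisible(x)
}
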