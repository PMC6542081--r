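# ATC code handling and psychotropic category mapping.
#
# The Anatomical Therapeutic Chemical (ATC) classification is hierarchical:
# level 1 = anatomical main group (1 letter), level 2 = therapeutic subgroup
# (+2 digits), level 3 = pharmacological subgroup (+1 letter), level 4 =
# chemical subgroup (+1 letter), level 5 = chemical substance (+2 digits).
# Valid code lengths are therefore 1, 3, 4, 5 and 7 characters, and every
# truncation to a shallower level is a prefix of the full code.

ATC_PATTERN <- "^[A-Za-z]([0-9]{2}([A-Za-z]([A-Za-z]([0-9]{2})?)?)?)?$"

# character widths of ATC levels 1..5
ATC_LEVEL_WIDTH <- c(1L, 3L, 4L, 5L, 7L)

#' The four psychotropic categories used by the audit
#'
#' Antidepressants (N06A), antipsychotics (N05A), anxiolytics-hypnotics
#' (N05B and N05C, collapsed into one category on the assumption of
#' comparable adverse effects in frail elderly patients) and antiepileptics
#' (N03A).
#'
#' @return character vector of the four category identifiers.
#' @export
psychotropic_categories <- function() {
  c("antidepressant", "antipsychotic", "anxiolytic_hypnotic", "antiepileptic")
}

#' Validate ATC codes
#'
#' Checks each code against the ATC syntax (letter, 2 digits, letter, letter,
#' 2 digits; any level-boundary prefix thereof) and returns the codes
#' uppercased. Malformed codes raise an error naming the offending strings.
#'
#' @param code character vector of ATC codes.
#' @return uppercase codes, invisibly usable downstream.
#' @export
#' @examples
#' validate_atc("n05ba04") # "N05BA04"
validate_atc <- function(code) {
  if (!is.character(code)) stop("ATC codes must be character strings")
  ok <- !is.na(code) & grepl(ATC_PATTERN, code)
  if (!all(ok)) {
    stop("Malformed ATC code(s): ",
         paste(unique(code[!ok]), collapse = ", "), call. = FALSE)
  }
  toupper(code)
}

#' Is a string a syntactically valid ATC code?
#'
#' @param code character vector.
#' @return logical vector.
#' @export
atc_valid <- function(code) {
  !is.na(code) & grepl(ATC_PATTERN, code)
}

#' Truncate ATC codes to a shallower level
#'
#' @param code character vector of valid ATC codes.
#' @param level target level 1-5; codes already shallower than `level` are
#'   returned unchanged.
#' @return truncated uppercase codes.
#' @export
#' @examples
#' atc_truncate("N05BA04", 3) # "N05B"
atc_truncate <- function(code, level = 3) {
  stopifnot(level %in% 1:5)
  code <- validate_atc(code)
  width <- ATC_LEVEL_WIDTH[level]
  substr(code, 1L, pmin(nchar(code), width))
}

#' Psychotropic category of an ATC code
#'
#' Maps a code to one of the audit's four categories by its pharmacological
#' subgroup prefix: N06A antidepressants, N05A antipsychotics, N05B
#' anxiolytics and N05C hypnotics (both mapped to the collapsed
#' anxiolytic-hypnotic category), N03A antiepileptics. Any other prefix,
#' including codes too short to carry a level-3 subgroup, yields `NA`.
#'
#' @param atc character vector of valid ATC codes (any level >= 3).
#' @return character vector over [psychotropic_categories()] or `NA`.
#' @export
#' @examples
#' atc_category("N05B")    # anxiolytic_hypnotic
#' atc_category("C07AB02") # NA
atc_category <- function(atc) {
  atc <- validate_atc(atc)
  lvl3 <- substr(atc, 1L, 4L)
  out <- rep(NA_character_, length(atc))
  out[lvl3 == "N06A"] <- "antidepressant"
  out[lvl3 == "N05A"] <- "antipsychotic"
  out[lvl3 %in% c("N05B", "N05C")] <- "anxiolytic_hypnotic"
  out[lvl3 == "N03A"] <- "antiepileptic"
  out[nchar(atc) < 4L] <- NA_character_
  out
}
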