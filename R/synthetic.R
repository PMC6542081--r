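# Seeded synthetic-cohort generator and the interaction knowledge-base
# fixture. The generator emulates a nursing-home point-prevalence audit:
# ages from a normal distribution truncated at 65, a configurable
# per-patient distribution of the number of distinct psychotropics, and
# drugs sampled without replacement with probability proportional to
# per-drug prevalence weights.

# Per-patient distinct-psychotropic count distributions (support 0..6),
# calibrated to the published threshold prevalences (>=1 / >=2 / >=3 =
# 59.6/24.4/6.2% in 2000 and 80.5/56.0/29.6% in 2016), the reported ranges
# (2-4 and 2-6 among polypharmacy patients) and the mean counts per person
# (0.91 and 1.84).
COUNT_PMF_2000 <- c(0.404, 0.352, 0.182, 0.054, 0.008, 0, 0)
COUNT_PMF_2016 <- c(0.195, 0.245, 0.264, 0.162, 0.098, 0.027, 0.009)

#' Synthetic cohort configuration
#'
#' Defaults come from the two audit timepoints: 386 patients, 26.4% male,
#' age 84.6 +/- 7.2 for the 2000-style cohort; 416 patients, 33.9% male,
#' age 84.3 +/- 8.1 for the 2016-style cohort. Drug weights default to the
#' published per-drug patient counts for the chosen year, and the
#' per-patient count distribution to a calibration reproducing the
#' published >= 1 / >= 2 / >= 3 substance prevalences and mean count.
#'
#' @param year `"2000"` or `"2016"`, selecting the preset.
#' @param n_patients cohort size.
#' @param male_fraction probability a patient is male.
#' @param age_mean,age_sd normal age parameters (years); ages are
#'   rejection-sampled above 64.5 and rounded to integer years.
#' @param count_pmf probability vector over 0..6 distinct psychotropics.
#' @param drug_weights named non-negative vector of relative prevalences
#'   (names must be registry drug names).
#' @param prn_fraction probability a prescription is marked as-needed.
#' @param seed integer RNG seed; generation is deterministic given the
#'   seed.
#' @param label cohort label.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(year = c("2000", "2016"),
                          n_patients = NULL, male_fraction = NULL,
                          age_mean = NULL, age_sd = NULL,
                          count_pmf = NULL, drug_weights = NULL,
                          prn_fraction = 0.3, seed = 1L, label = NULL) {
  year <- match.arg(year)
  preset <- if (year == "2000") {
    list(n = 386L, male = 0.264, mean = 84.6, sd = 7.2,
         pmf = COUNT_PMF_2000, wcol = "n_2000")
  } else {
    list(n = 416L, male = 0.339, mean = 84.3, sd = 8.1,
         pmf = COUNT_PMF_2016, wcol = "n_2016")
  }
  if (is.null(drug_weights)) {
    reg <- default_registry()
    drug_weights <- stats::setNames(reg[[preset$wcol]], reg$name)
  }
  cfg <- list(
    year = year,
    n_patients = as.integer(n_patients %||% preset$n),
    male_fraction = male_fraction %||% preset$male,
    age_mean = age_mean %||% preset$mean,
    age_sd = age_sd %||% preset$sd,
    count_pmf = count_pmf %||% preset$pmf,
    drug_weights = drug_weights,
    prn_fraction = prn_fraction,
    seed = as.integer(seed),
    label = label %||% paste0("synthetic-", year))
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  pmf <- cfg$count_pmf
  if (length(pmf) != 7 || any(pmf < 0) || abs(sum(pmf) - 1) > 1e-8) {
    stop("count_pmf must be a length-7 probability vector over 0..6",
         call. = FALSE)
  }
  w <- cfg$drug_weights
  if (is.null(names(w)) || any(w < 0) || !any(w > 0)) {
    stop("drug_weights must be a named non-negative vector with a positive entry",
         call. = FALSE)
  }
  max_support <- max(which(pmf > 0)) - 1L
  if (max_support > sum(w > 0)) {
    stop("count_pmf support exceeds the number of drugs with positive weight",
         call. = FALSE)
  }
  if (cfg$n_patients < 0 || cfg$male_fraction < 0 || cfg$male_fraction > 1 ||
      cfg$prn_fraction < 0 || cfg$prn_fraction > 1 || cfg$age_sd <= 0) {
    stop("Invalid cohort configuration", call. = FALSE)
  }
  invisible(cfg)
}

# Inclusion probabilities for a fixed-size probability-proportional-to-size
# draw: k * w / sum(w), iteratively capped at 1 with the surplus
# redistributed over the uncapped units so that the probabilities sum to k.
inclusion_probs <- function(weights, k) {
  stopifnot(k <= sum(weights > 0))
  pi <- rep(0, length(weights))
  active <- weights > 0
  repeat {
    pi[active] <- (k - sum(!active & weights > 0)) *
      weights[active] / sum(weights[active])
    over <- active & pi > 1
    if (!any(over)) break
    pi[over] <- 1
    active <- active & !over
  }
  pi[weights > 0 & !active] <- 1
  pi
}

# Systematic PPS sampling of exactly k units with the given inclusion
# probabilities (which sum to k); unit order is randomised so joint
# inclusions are not tied to registry order. Marginal inclusion
# probabilities are exact.
sample_pps <- function(weights, k) {
  if (k == 0L) return(integer())
  pi <- inclusion_probs(weights, k)
  ord <- sample.int(length(pi))
  p <- pi[ord]
  cum <- cumsum(p)
  u <- stats::runif(1)
  prev <- c(0, cum[-length(cum)])
  sel <- which(floor(cum - u + 1e-12) > floor(prev - u + 1e-12))
  # guard against float drift at the last interval boundary
  if (length(sel) > k) sel <- sel[seq_len(k)]
  if (length(sel) < k) {
    extra <- setdiff(order(p, decreasing = TRUE), sel)
    sel <- c(sel, extra[seq_len(k - length(sel))])
  }
  ord[sel]
}

#' Expected per-drug prevalence under a configuration
#'
#' The exact marginal probability that each drug is included in a random
#' patient's chart: the count distribution mixed over the fixed-size
#' inclusion probabilities of the proportional sampling design. This is the
#' "configured prevalence" that observed synthetic prevalences converge to.
#'
#' @param config a `cohort_config`.
#' @return named numeric vector of inclusion probabilities per drug.
#' @export
expected_drug_prevalence <- function(config) {
  w <- config$drug_weights
  pmf <- config$count_pmf
  out <- rep(0, length(w))
  for (k in seq_along(pmf) - 1L) {
    if (pmf[k + 1L] > 0 && k > 0) {
      out <- out + pmf[k + 1L] * inclusion_probs(w, k)
    }
  }
  stats::setNames(out, names(w))
}

#' Generate a synthetic cohort
#'
#' Deterministic given `config$seed`. Ages are drawn from the configured
#' normal distribution, rejection-sampled above 64.5 and rounded, so every
#' generated patient passes the age >= 65 inclusion filter. Each patient
#' receives a distinct-psychotropic count from `count_pmf`, then that many
#' distinct drugs by proportional-to-weight sampling without replacement;
#' each prescription is independently marked as-needed with probability
#' `prn_fraction`.
#'
#' @param config a `cohort_config`.
#' @param registry a `drug_registry`; drugs in `drug_weights` must resolve
#'   in it.
#' @return a `cohort` with `excluded_count = 0`.
#' @export
generate_cohort <- function(config, registry = default_registry()) {
  validate_config(config)
  w <- config$drug_weights
  idx <- lookup_drug(registry, names(w))
  n <- config$n_patients

  with_seed(config$seed, {
    ages <- integer(0)
    while (length(ages) < n) {
      draw <- stats::rnorm(max(2L * (n - length(ages)), 10L),
                           config$age_mean, config$age_sd)
      draw <- draw[draw >= 64.5]
      ages <- c(ages, as.integer(round(draw)))
    }
    ages <- ages[seq_len(n)]
    gender <- ifelse(stats::runif(n) < config$male_fraction, "M", "F")
    counts <- sample(0:6, n, replace = TRUE, prob = config$count_pmf)

    ids <- sprintf("P%04d", seq_len(n))
    rx_list <- vector("list", n)
    for (i in seq_len(n)) {
      k <- counts[i]
      if (k == 0L) next
      picked <- sample_pps(w, k)
      drugs <- sort(names(w)[picked])
      rx_list[[i]] <- data.frame(
        patient_id = ids[i],
        drug = drugs,
        as_needed = stats::runif(k) < config$prn_fraction,
        stringsAsFactors = FALSE)
    }
    rx <- do.call(rbind, rx_list)
    if (is.null(rx)) {
      rx <- data.frame(patient_id = character(), drug = character(),
                       as_needed = logical(), stringsAsFactors = FALSE)
    }
    ridx <- match(rx$drug, registry$name)
    rx <- data.frame(patient_id = rx$patient_id, drug = rx$drug,
                     atc = registry$atc[ridx],
                     category = registry$category[ridx],
                     as_needed = rx$as_needed, stringsAsFactors = FALSE)
    patients <- data.frame(patient_id = ids, age = ages, gender = gender,
                           stringsAsFactors = FALSE)
    new_cohort(config$label, patients, rx, 0L, registry)
  })
}

# Substance pairs of the published first-ranked interaction table, with
# their printed mechanism, recommended-action, documentation and severity
# annotations. Raw tokens "adjust dose" and "extensive" appear so the
# collapsing rules are exercised by the fixture.
KB_FIXTURE <- list(
  c("haloperidol", "citalopram", "pharmacodynamic", "avoid",
    "theoretical", "severe", "QT-prolongation"),
  c("levomepromazine", "haloperidol", "pharmacodynamic", "avoid",
    "theoretical", "severe", "QT-prolongation"),
  c("citalopram", "risperidone", "pharmacodynamic", "informative",
    "case", "severe", "Priapism/QT-prolongation"),
  c("citalopram", "levomepromazine", "pharmacodynamic", "informative",
    "theoretical", "severe", "QT-prolongation"),
  c("citalopram", "zopiclone", "pharmacodynamic", "informative",
    "theoretical", "moderate", "Sedation"),
  c("zopiclone", "carbamazepine", "pharmacodynamic", "informative",
    "theoretical", "mild", "Sedation"),
  c("carbamazepine", "olanzapine", "pharmacokinetic", "adjust dose",
    "study", "moderate", "Olanzapine exposure reduced"),
  c("carbamazepine", "risperidone", "pharmacokinetic", "monitor",
    "study", "moderate", "Risperidone exposure reduced"),
  c("carbamazepine", "nortriptyline", "pharmacokinetic", "monitor",
    "study", "moderate", "Nortriptyline exposure reduced"),
  c("valproic acid", "carbamazepine", "pharmacokinetic", "adjust dose",
    "extensive", "moderate", "Carbamazepine-epoxide increased"),
  c("mirtazapine", "oxazepam", "pharmacodynamic", "monitor",
    "theoretical", "moderate", "Sedation"),
  c("mirtazapine", "diazepam", "pharmacodynamic", "monitor",
    "study", "moderate", "CNS depression"),
  c("mirtazapine", "olanzapine", "pharmacodynamic", "monitor",
    "case", "moderate", "Sedation"),
  c("mirtazapine", "escitalopram", "pharmacodynamic", "monitor",
    "theoretical", "severe", "Serotonin syndrome"),
  c("escitalopram", "oxazepam", "pharmacodynamic", "informative",
    "theoretical", "moderate", "Sedation")
)

#' Interaction knowledge-base fixture
#'
#' A small knowledge base encoding the substance pairs of the published
#' first-ranked interaction classification, for tests and demonstrations.
#' A stand-in for a subscription interaction database, which cannot be
#' redistributed.
#'
#' @return an `interaction_kb`.
#' @export
kb_fixture <- function() {
  df <- as.data.frame(do.call(rbind, KB_FIXTURE), stringsAsFactors = FALSE)
  names(df) <- KB_COLUMNS
  new_kb(df, source = "fixture")
}

#' Write the knowledge-base fixture to a file
#'
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_kb_fixture <- function(path) {
  df <- as.data.frame(do.call(rbind, KB_FIXTURE), stringsAsFactors = FALSE)
  names(df) <- KB_COLUMNS
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, eol = "\n")
  invisible(path)
}
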