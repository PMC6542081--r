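# Two-cohort comparison statistics and the three-step logistic regression
# procedure with multicollinearity diagnostics.

#' Compare two proportions
#'
#' Builds the 2x2 table (events / non-events in each cohort) and applies
#' Pearson's chi-square test without continuity correction, switching to
#' Fisher's exact test (two-sided) when any expected cell count is below 5.
#' Significance is flagged at p < 0.01, the audit's threshold.
#'
#' @param count_a,denom_a,count_b,denom_b non-negative integers,
#'   `count <= denom`, denominators positive.
#' @param label optional row label.
#' @return a `proportion_comparison` list: counts, one-decimal percentages,
#'   `test_used` (`"chi_square"` or `"fisher_exact"`), `p_value`,
#'   `significant`.
#' @export
#' @examples
#' compare_proportions(24, 386, 123, 416) # 6.2% vs 29.6%, p < 0.001
compare_proportions <- function(count_a, denom_a, count_b, denom_b,
                                label = NULL) {
  if (denom_a <= 0 || denom_b <= 0) {
    stop("Undefined comparison: zero denominator", call. = FALSE)
  }
  if (count_a > denom_a || count_b > denom_b || count_a < 0 || count_b < 0) {
    stop("Counts must satisfy 0 <= count <= denom", call. = FALSE)
  }
  tab <- matrix(c(count_a, denom_a - count_a,
                  count_b, denom_b - count_b),
                nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    test_used <- "fisher_exact"
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  } else {
    test_used <- "chi_square"
    p <- stats::chisq.test(tab, correct = FALSE)$p.value
  }
  structure(list(label = label,
                 count_a = count_a, denom_a = denom_a,
                 count_b = count_b, denom_b = denom_b,
                 percent_a = pct(count_a, denom_a),
                 percent_b = pct(count_b, denom_b),
                 test_used = test_used, p_value = p,
                 significant = p < 0.01),
            class = "proportion_comparison")
}

#' @export
print.proportion_comparison <- function(x, ...) {
  cat(sprintf("%s%d/%d (%.1f%%) vs %d/%d (%.1f%%): %s p = %.4g%s\n",
              if (is.null(x$label)) "" else paste0(x$label, ": "),
              x$count_a, x$denom_a, x$percent_a,
              x$count_b, x$denom_b, x$percent_b,
              x$test_used, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Mann-Whitney U-test
#'
#' Two-sided rank-sum test for comparing continuous variables (age, number
#' of psychotropics or interactions) between cohorts. Exact p-values are
#' used for small untied samples; otherwise the normal approximation with
#' tie correction.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return two-sided p-value.
#' @export
mann_whitney <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) {
    stop("Both samples must be non-empty", call. = FALSE)
  }
  suppressWarnings(stats::wilcox.test(sample_a, sample_b,
                                      alternative = "two.sided"))$p.value
}

#' Multicollinearity diagnostics
#'
#' Variance inflation factor and tolerance for each predictor, from the
#' auxiliary linear regression of that predictor on all the others:
#' tolerance = 1 - R^2, VIF = 1 / tolerance.
#'
#' @param data data.frame of numeric predictor columns.
#' @return data.frame with `predictor`, `vif`, `tolerance`.
#' @export
vif_tolerance <- function(data) {
  preds <- names(data)
  stopifnot(length(preds) >= 2)
  out <- lapply(preds, function(p) {
    fit <- stats::lm(stats::reformulate(setdiff(preds, p), response = p),
                     data = data)
    r2 <- summary(fit)$r.squared
    tol <- 1 - r2
    data.frame(predictor = p, vif = 1 / tol, tolerance = tol,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Wald OR table for one glm fit, with perfect-separation screening: a
# predictor whose Wald SE explodes has its estimates suppressed and flagged.
or_table <- function(fit, separation_warned = FALSE) {
  sm <- summary(fit)$coefficients
  rows <- rownames(sm)[-1]
  est <- sm[-1, "Estimate"]
  se <- sm[-1, "Std. Error"]
  p <- sm[-1, "Pr(>|z|)"]
  suppress <- separation_warned & se > 50
  data.frame(
    predictor = rows,
    or = ifelse(suppress, NA_real_, exp(est)),
    ci_low = ifelse(suppress, NA_real_, exp(est - 1.959964 * se)),
    ci_high = ifelse(suppress, NA_real_, exp(est + 1.959964 * se)),
    p_value = ifelse(suppress, NA_real_, p),
    separation = suppress,
    stringsAsFactors = FALSE)
}

fit_logistic <- function(formula, data) {
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, data = data, family = stats::binomial()),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg) ||
          grepl("algorithm did not converge", msg)) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  list(fit = fit, separation = warned)
}

#' Three-step logistic regression procedure
#'
#' Step 1 fits a univariate logistic model per predictor; step 2 fits the
#' fully adjusted model with all predictors; step 3 refits a final model
#' over the predictors with p < 0.25 in at least one of the first two
#' steps. Odds ratios carry Wald 95% confidence intervals and p-values.
#' Multicollinearity is screened by [vif_tolerance()]. Predictors showing
#' perfect separation are flagged and their estimates suppressed.
#'
#' @param data data.frame containing the outcome and predictors.
#' @param outcome name of the 0/1 outcome column.
#' @param predictors character vector of predictor column names (binary
#'   predictors coded 0/1; age and counts continuous).
#' @param selection_p screening threshold for step 3 (default 0.25).
#' @return a `logistic_report`: `$step1`, `$step2`, `$step3` OR tables,
#'   `$selected` predictor names, `$vif`, `$n`, `$n_events`.
#' @export
logistic_three_step <- function(data, outcome, predictors,
                                selection_p = 0.25) {
  stopifnot(outcome %in% names(data), all(predictors %in% names(data)))
  y <- data[[outcome]]
  if (length(unique(y[!is.na(y)])) < 2) {
    stop("Degenerate model: outcome has a single class", call. = FALSE)
  }
  for (p in predictors) {
    v <- data[[p]]
    if (!is.numeric(v)) stop("Predictor not numeric: ", p, call. = FALSE)
  }
  constant <- predictors[vapply(predictors, function(p)
    length(unique(data[[p]])) < 2, logical(1))]
  if (length(constant)) {
    message("Dropping constant predictor(s): ",
            paste(constant, collapse = ", "))
    predictors <- setdiff(predictors, constant)
  }
  if (!length(predictors)) stop("No usable predictors", call. = FALSE)

  step1 <- do.call(rbind, lapply(predictors, function(p) {
    f <- fit_logistic(stats::reformulate(p, response = outcome), data)
    or_table(f$fit, f$separation)
  }))
  f2 <- fit_logistic(stats::reformulate(predictors, response = outcome),
                     data)
  step2 <- or_table(f2$fit, f2$separation)

  p1 <- stats::setNames(step1$p_value, step1$predictor)
  p2 <- stats::setNames(step2$p_value, step2$predictor)
  selected <- predictors[
    pmin(p1[predictors], p2[predictors], na.rm = TRUE) < selection_p]
  selected <- selected[!is.na(selected)]

  step3 <- if (length(selected)) {
    f3 <- fit_logistic(stats::reformulate(selected, response = outcome),
                       data)
    or_table(f3$fit, f3$separation)
  } else {
    step1[0, ]
  }

  structure(list(step1 = step1, step2 = step2, step3 = step3,
                 selected = selected,
                 vif = vif_tolerance(data[predictors]),
                 n = nrow(data), n_events = sum(y == 1),
                 selection_p = selection_p),
            class = "logistic_report")
}

#' @export
print.logistic_report <- function(x, ...) {
  cat(sprintf(
    "Three-step logistic regression: n = %d, events = %d\n", x$n, x$n_events))
  cat(sprintf("Step 3 predictors (p < %.2f in step 1 or 2): %s\n",
              x$selection_p,
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "(none)"))
  fmt <- function(tab) {
    data.frame(predictor = tab$predictor,
               `OR (95% CI)` = sprintf("%.2f (%.2f-%.2f)", tab$or,
                                       tab$ci_low, tab$ci_high),
               p = signif(tab$p_value, 3), check.names = FALSE)
  }
  cat("Unadjusted (step 1):\n"); print(fmt(x$step1), row.names = FALSE)
  cat("Final (step 3):\n")
  if (nrow(x$step3)) print(fmt(x$step3), row.names = FALSE)
  cat("Max VIF:", round_half_up(max(x$vif$vif), 2), "\n")
  invisible(x)
}

#' Predictors of having interactions in a cohort
#'
#' Runs the three-step procedure on the audit's standard question: among
#' patients with two or more concurrent psychotropics, which of gender
#' (male = 1), age, number of psychotropics and the four category-use flags
#' predict having at least one matched interaction?
#'
#' @param cohort a `cohort`.
#' @param kb an `interaction_kb`.
#' @param min_substances population filter: minimum distinct psychotropics
#'   (default 2).
#' @return a `logistic_report` (see [logistic_three_step()]); the modelling
#'   data frame is attached as attribute `"model_data"`.
#' @export
logistic_procedure <- function(cohort, kb, min_substances = 2) {
  prof <- indicator_profiles(cohort)
  pi <- match_interactions(cohort, kb)
  prof$has_pi <- as.integer(prof$patient_id %in% pi$first_ranked$patient_id)
  pop <- prof[prof$n_substances >= min_substances, , drop = FALSE]
  if (!nrow(pop)) stop("Empty population after filter", call. = FALSE)
  dat <- data.frame(
    has_pi = pop$has_pi,
    gender = as.integer(pop$gender == "M"),
    age = as.numeric(pop$age),
    n_psychotropics = as.numeric(pop$n_substances),
    antidepressant = as.integer(pop$antidepressant),
    antipsychotic = as.integer(pop$antipsychotic),
    anxiolytic_hypnotic = as.integer(pop$anxiolytic_hypnotic),
    antiepileptic = as.integer(pop$antiepileptic))
  rep <- logistic_three_step(
    dat, "has_pi",
    c("gender", "age", "n_psychotropics", "antidepressant", "antipsychotic",
      "anxiolytic_hypnotic", "antiepileptic"))
  attr(rep, "model_data") <- dat
  rep
}
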