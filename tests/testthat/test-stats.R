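test_that("proportion comparison reproduces printed percentages and switches tests", {
  cmp <- compare_proportions(24, 386, 123, 416)
  expect_equal(cmp$percent_a, 6.2)
  expect_equal(cmp$percent_b, 29.6)
  expect_equal(cmp$test_used, "chi_square")
  expect_lt(cmp$p_value, 0.001)
  expect_true(cmp$significant)

  same <- compare_proportions(10, 100, 10, 100)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  small <- compare_proportions(1, 10, 9, 12)
  expect_equal(small$test_used, "fisher_exact")

  expect_error(compare_proportions(1, 0, 1, 10), "zero denominator")
  expect_error(compare_proportions(11, 10, 1, 10), "count <= denom")
})

test_that("Fisher p equals exhaustive hypergeometric tail summation", {
  cases <- list(c(1, 10, 9, 12), c(0, 5, 4, 6), c(2, 12, 8, 13),
                c(3, 8, 3, 8))
  for (cs in cases) {
    cmp <- compare_proportions(cs[1], cs[2], cs[3], cs[4])
    expect_equal(cmp$test_used, "fisher_exact")
    oracle <- oracle_fisher_p(cs[1], cs[2] - cs[1], cs[3], cs[4] - cs[3])
    expect_equal(cmp$p_value, oracle, tolerance = 1e-10)
  }
})

test_that("proportion comparison is symmetric and chi-square tracks Fisher on large tables", {
  set.seed(5)
  for (i in 1:20) {
    da <- sample(4000:6000, 1); db <- sample(4000:6000, 1)
    ca <- rbinom(1, da, 0.5); cb <- rbinom(1, db, 0.5)
    ab <- compare_proportions(ca, da, cb, db)
    ba <- compare_proportions(cb, db, ca, da)
    expect_equal(ab$p_value, ba$p_value)
    expect_equal(ab$percent_a, ba$percent_b)
    # expected cells in the thousands: the exact and asymptotic tests agree
    # (the gap between them shrinks like 1/sqrt(N) under the null)
    fish <- stats::fisher.test(matrix(c(ca, da - ca, cb, db - cb), 2,
                                      byrow = TRUE))$p.value
    expect_lt(abs(ab$p_value - fish), 0.02)
  }
})

test_that("Mann-Whitney p matches exhaustive rank-assignment enumeration", {
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(mann_whitney(c(1, 2, 3), c(101, 102, 103)),
               oracle_mw_p(c(1, 2, 3), c(101, 102, 103)))
  set.seed(9)
  for (i in 1:25) {
    nx <- sample(2:4, 1); ny <- sample(2:4, 1)
    x <- sample(1:100, nx); y <- setdiff(sample(1:100, ny + nx), x)[1:ny]
    expect_equal(mann_whitney(x, y), oracle_mw_p(x, y), tolerance = 1e-10)
  }
  expect_error(mann_whitney(numeric(), 1:3), "non-empty")
})

test_that("VIF and tolerance come from auxiliary regressions", {
  set.seed(21)
  d <- data.frame(a = rnorm(500), b = rnorm(500), c = rnorm(500))
  vt <- vif_tolerance(d)
  expect_true(all(abs(vt$vif - 1) < 0.05))
  expect_true(all(abs(vt$tolerance - 1) < 0.05))
  # a collinear predictor inflates
  d$d <- d$a + rnorm(500, sd = 0.1)
  vt2 <- vif_tolerance(d)
  expect_gt(vt2$vif[vt2$predictor == "d"], 10)
  expect_equal(vt2$tolerance, 1 / vt2$vif)
})

test_that("three-step selection keeps exactly the predictors with p < 0.25 in step 1 or 2", {
  set.seed(33)
  n <- 400
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rbinom(n, 1, 0.4))
  d$y <- rbinom(n, 1, plogis(-0.5 + 1.2 * d$x1))
  rep <- logistic_three_step(d, "y", c("x1", "x2", "x3"))
  p1 <- setNames(rep$step1$p_value, rep$step1$predictor)
  p2 <- setNames(rep$step2$p_value, rep$step2$predictor)
  should <- names(p1)[pmin(p1, p2[names(p1)]) < 0.25]
  expect_setequal(rep$selected, should)
  expect_true(all(rep$step3$predictor %in% rep$step1$predictor))
  # every CI contains its OR
  for (tab in list(rep$step1, rep$step2, rep$step3)) {
    ok <- !is.na(tab$or)
    expect_true(all(tab$ci_low[ok] <= tab$or[ok] & tab$or[ok] <= tab$ci_high[ok]))
  }
  expect_equal(rep$n, n)
})

test_that("degenerate outcomes error and perfect separation is suppressed", {
  d <- data.frame(y = rep(1, 50), x = rnorm(50))
  expect_error(logistic_three_step(d, "y", "x"), "single class")
  set.seed(4)
  d2 <- data.frame(x = c(rnorm(30, -3), rnorm(30, 3)), z = rnorm(60))
  d2$y <- as.integer(d2$x > 0)
  rep <- logistic_three_step(d2, "y", c("x", "z"))
  sep_row <- rep$step2[rep$step2$predictor == "x", ]
  expect_true(sep_row$separation)
  expect_true(is.na(sep_row$or))
})

test_that("logistic_procedure models interactions among multi-psychotropic patients", {
  cfg <- cohort_config("2016", seed = 12)
  co <- generate_cohort(cfg)
  rep <- logistic_procedure(co, kb_fixture())
  expect_s3_class(rep, "logistic_report")
  dat <- attr(rep, "model_data")
  expect_true(all(dat$n_psychotropics >= 2))
  expect_true(all(rep$step1$predictor %in%
                    c("gender", "age", "n_psychotropics", "antidepressant",
                      "antipsychotic", "anxiolytic_hypnotic", "antiepileptic")))
  expect_true(all(dat$has_pi %in% 0:1))
  # VIF below the audit's multicollinearity concern threshold
  expect_true(all(rep$vif$vif < 2.5))
})
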