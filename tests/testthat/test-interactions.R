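kb <- kb_fixture()

test_that("knowledge base loads from file and validates vocabularies", {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_kb_fixture(path)
  loaded <- read_kb(path)
  expect_gte(nrow(loaded), 10)
  expect_equal(loaded$pair, kb$pair)

  hdr <- "drug_a,drug_b,mechanism,action,documentation,severity,description"
  writeLines(c(hdr, "a,b,pharmacodynamic,sometimes,case,mild,x"), path)
  expect_error(read_kb(path), "Unknown action token 'sometimes'.*row 1")

  writeLines(c(hdr, "a,b,pharmacodynamic,avoid,case,mild,x",
               "B,A,pharmacokinetic,monitor,study,severe,y"), path)
  expect_error(read_kb(path), "Duplicate unordered pair")

  writeLines(c(hdr, "a,a,pharmacodynamic,avoid,case,mild,x"), path)
  expect_error(read_kb(path), "distinct substances")

  writeLines(c(hdr, "a,b,magic,avoid,case,mild,x"), path)
  expect_error(read_kb(path), "Unknown mechanism")
})

test_that("collapsing merges monitor/adjust-dose and study/extensive, fixing the rest", {
  expect_equal(collapse_levels("adjust dose", "case", "mild")$action,
               "monitor_or_adjust")
  expect_equal(collapse_levels("monitor", "case", "mild")$action,
               "monitor_or_adjust")
  expect_equal(collapse_levels("avoid", "extensive", "mild")$documentation,
               "study")
  out <- collapse_levels("avoid", "theoretical", "mild")
  expect_equal(unlist(out, use.names = FALSE),
               c("avoid", "theoretical", "mild"))
  # surjective and order-preserving on each scale
  acts <- collapse_levels(c("informative", "monitor", "adjust dose", "avoid"),
                          rep("case", 4), rep("mild", 4))$action
  expect_equal(acts, c("informative", "monitor_or_adjust",
                       "monitor_or_adjust", "avoid"))
  ords <- rank_key(acts, rep("case", 4), rep("mild", 4))[, "action"]
  expect_true(all(diff(ords) >= 0))
})

test_that("rank keys compare lexicographically: action > documentation > severity", {
  cmp <- function(a, b) { # 1 if a outranks b
    d <- a - b
    nz <- which(d != 0)
    if (!length(nz)) 0 else unname(sign(d[nz[1]]))
  }
  k <- function(...) drop(rank_key(...))
  expect_equal(cmp(k("avoid", "theoretical", "mild"),
                   k("monitor_or_adjust", "study", "severe")), 1)
  expect_equal(cmp(k("monitor_or_adjust", "study", "mild"),
                   k("monitor_or_adjust", "case", "severe")), 1)
  expect_equal(cmp(k("informative", "case", "moderate"),
                   k("informative", "case", "moderate")), 0)
  expect_error(rank_key("adjust dose", "case", "mild"), "collapsed")
})

test_that("matching finds knowledge-base pairs and selects the first-ranked one", {
  co <- toy_cohort(list(
    A = c("haloperidol", "citalopram", "mirtazapine", "oxazepam"),
    B = "citalopram",
    C = c("zopiclone", "quetiapine")))
  pi <- match_interactions(co, kb)
  mA <- pi$matches[pi$matches$patient_id == "A", ]
  expect_setequal(mA$pair, c("citalopram|haloperidol", "mirtazapine|oxazepam"))
  fr <- pi$first_ranked[pi$first_ranked$patient_id == "A", ]
  expect_equal(fr$pair, "citalopram|haloperidol")
  expect_equal(fr$action, "avoid")
  expect_false(fr$tie)
  # single drug and unmatched pair: no first-ranked entry
  expect_false(any(pi$first_ranked$patient_id %in% c("B", "C")))
})

test_that("ties on the full triple pick the alphabetically first pair and are recorded", {
  hdr <- "drug_a,drug_b,mechanism,action,documentation,severity,description"
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  writeLines(c(hdr,
               "zopiclone,oxazepam,pharmacodynamic,monitor,case,mild,x",
               "citalopram,oxazepam,pharmacodynamic,adjust dose,case,mild,y"),
             path)
  tie_kb <- read_kb(path)
  co <- toy_cohort(list(A = c("zopiclone", "oxazepam", "citalopram")))
  fr <- match_interactions(co, tie_kb)$first_ranked
  expect_equal(fr$pair, "citalopram|oxazepam")
  expect_true(fr$tie)
})

test_that("first-ranked selection equals brute-force maximisation on random patients", {
  set.seed(101)
  reg <- default_registry()
  for (i in 1:300) {
    drugs <- sample(reg$name, sample(2:6, 1))
    lst <- list(drugs); names(lst) <- "A"
    co <- toy_cohort(lst)
    pi <- match_interactions(co, kb)
    oracle <- oracle_first_ranked(drugs, kb)
    if (is.null(oracle)) {
      expect_equal(nrow(pi$first_ranked), 0)
    } else {
      expect_equal(pi$first_ranked$pair[1], oracle$pair)
    }
    expect_equal(nrow(pi$matches), oracle_match_count(drugs, kb))
    expect_lte(nrow(pi$matches), choose(length(drugs), 2))
  }
})

test_that("mechanism summary matches a hand tally on a small fixture", {
  co <- toy_cohort(list(
    P1 = c("haloperidol", "citalopram"),            # avoid/theoretical/severe PD
    P2 = c("mirtazapine", "oxazepam"),              # monitor/theoretical/moderate PD
    P3 = c("mirtazapine", "oxazepam", "zopiclone"), # same first-ranked as P2
    P4 = c("valproic acid", "carbamazepine"),       # adjust/study/moderate PK
    P5 = c("escitalopram", "oxazepam"),             # informative/theoretical/moderate PD
    P6 = "quetiapine"))
  ms <- mechanism_summary(co, kb)
  get <- function(section, label) ms[ms$section == section & ms$label == label, ]
  expect_equal(get("interactions", "Patients with interactions")$count, 5)
  expect_equal(get("mechanism", "Pharmacodynamic")$count, 4)
  expect_equal(get("mechanism", "Pharmacodynamic")$pct, 80.0)
  expect_equal(get("mechanism", "Pharmacokinetic")$count, 1)
  expect_equal(get("action", "Avoid")$count, 1)
  expect_equal(get("action", "Monitor or adjust dose")$count, 3) # P2, P3, P4
  expect_equal(get("documentation", "Study")$count, 1)
  expect_equal(get("severity", "Severe")$count, 1)
  # two most frequent substances among pharmacodynamic first-ranked pairs:
  # oxazepam in 3 of 4, mirtazapine in 2 of 4
  pd <- get("mechanism", "Pharmacodynamic")
  expect_equal(pd$first_drug, "oxazepam")
  expect_equal(pd$first_pct, 75.0)
  expect_equal(pd$second_drug, "mirtazapine")
  expect_equal(pd$second_pct, 50.0)
})
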