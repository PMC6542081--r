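test_that("polypharmacy is >= 3 distinct substances after level-5 dedup", {
  co <- toy_cohort(list(
    A = c("oxazepam", "zopiclone", "mirtazapine"),
    B = c("oxazepam", "zopiclone"),
    C = c("oxazepam", "oxazepam", "zopiclone"))) # regular + PRN oxazepam
  expect_true(polypharmacy_flag(co, "A"))
  expect_false(polypharmacy_flag(co, "B"))
  expect_false(polypharmacy_flag(co, "C"))
})

test_that("PICP rules: same-category pairs, antiepileptic pair reported only, anticholinergic crosses categories", {
  co <- toy_cohort(list(
    A = c("oxazepam", "zopiclone"),
    B = c("carbamazepine", "valproic acid"),
    C = c("amitriptyline", "levomepromazine"), # antidepressant + antipsychotic
    D = c("citalopram", "oxazepam")))
  rA <- picp_rules(co, "A")
  expect_equal(as.character(rA), "2+_anxiolytics_hypnotics")
  expect_true(attr(rA, "picp"))

  rB <- picp_rules(co, "B")
  expect_equal(as.character(rB), "2+_antiepileptics")
  expect_false(attr(rB, "picp")) # reported but excluded from the flag

  rC <- picp_rules(co, "C")
  expect_equal(as.character(rC), "2+_anticholinergic")
  expect_true(attr(rC, "picp"))

  rD <- picp_rules(co, "D")
  expect_length(rD, 0)
  expect_false(attr(rD, "picp"))

  prof <- indicator_profiles(co)
  expect_true(all(prof$n_substances[prof$picp] >= 2))
})

test_that("PIPS hits list flagged substances in registry order", {
  co <- toy_cohort(list(
    A = c("diazepam", "zopiclone"),
    B = "escitalopram",
    C = c("hydroxyzine", "nitrazepam")))
  expect_equal(pips_hits(co, "A"), "diazepam")
  expect_equal(pips_hits(co, "B"), character())
  # registry lists benzodiazepines before the anxiolytic anticholinergics
  expect_equal(pips_hits(co, "C"), c("hydroxyzine", "nitrazepam"))
  prof <- indicator_profiles(co)
  expect_equal(prof$pips, c(TRUE, FALSE, TRUE))
})

test_that("indicator table counts thresholds with row-count denominators", {
  co <- toy_cohort(list(A = "oxazepam", B = "citalopram", C = "zopiclone"))
  tab <- cohort_indicator_table(co)
  get <- function(section, label) tab[tab$section == section & tab$label == label, ]
  expect_equal(get("1_or_more", "One or more drugs")$count, 3)
  expect_equal(get("2_or_more", "Two or more drugs")$count, 0)
  expect_equal(get("1_or_more", "Anxiolytics-hypnotics")$count, 2)
  expect_equal(get("1_or_more", "Anxiolytics-hypnotics")$denom, 3)
  expect_equal(get("1_or_more", "Anxiolytics-hypnotics")$pct, 66.7)
})

test_that("empty cohorts give zero counts and NA percentages without division", {
  p <- write_cohort_file(character())
  co <- read_cohort(p)
  unlink(p)
  tab <- cohort_indicator_table(co)
  expect_true(all(tab$count == 0))
  expect_true(all(is.na(tab$pct)))
  comb <- combination_table(co)
  expect_true(all(comb$count == 0))
})

test_that("indicator table equals an independent nested-loop recount", {
  co <- random_toy_cohort(20, seed = 42)
  tab <- cohort_indicator_table(co)
  sections <- c("1_or_more" = 1L, "2_or_more" = 2L, "3_or_more" = 3L)
  for (sec in names(sections)) {
    row <- tab[tab$section == sec, ][1, ]
    expect_equal(row$count, oracle_threshold_counts(co, sections[[sec]]))
    for (cc in psychotropic_categories()) {
      lab <- c(antidepressant = "Antidepressants",
               antipsychotic = "Antipsychotics",
               anxiolytic_hypnotic = "Anxiolytics-hypnotics",
               antiepileptic = "Antiepileptics")[[cc]]
      crow <- tab[tab$section == sec & tab$label == lab, ]
      expect_equal(crow$count,
                   oracle_category_count_in_threshold(co, sections[[sec]], cc))
    }
  }
})

test_that("threshold counts are monotone on random cohorts", {
  for (seed in c(3, 7, 19)) {
    co <- random_toy_cohort(30, seed = seed)
    tab <- cohort_indicator_table(co)
    heads <- tab[!duplicated(tab$section), ]
    counts <- heads$count[match(c("1_or_more", "2_or_more", "3_or_more"),
                                heads$section)]
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("combination table uses family-count denominators", {
  co <- toy_cohort(list(
    A = c("citalopram", "oxazepam"),           # antidep + anx combination
    B = c("oxazepam", "zopiclone"),            # PICP (anx pair)
    C = c("diazepam", "nitrazepam"),           # PIPS x2, no PICP category pair?
    D = "citalopram"))
  # C: diazepam + nitrazepam are both anxiolytic-hypnotics -> also PICP
  tab <- combination_table(co)
  comb <- tab[tab$label == "Combination of categories", ]
  expect_equal(comb$count, 1) # only A spans two categories
  pair <- tab[tab$label == "Antidepressants + anxiolytics-hypnotics", ]
  expect_equal(pair$count, 1)
  expect_equal(pair$denom, 1)

  picp <- tab[tab$label == "Potentially inappropriate combinations (PICP)", ]
  expect_equal(picp$count, 2) # B and C
  anx_rule <- tab[tab$label == "Two or more anxiolytics-hypnotics", ]
  expect_equal(anx_rule$denom, 2)
  expect_equal(anx_rule$count, 2)

  pips <- tab[tab$label == "Potentially inappropriate substances (PIPS)", ]
  expect_equal(pips$count, 1) # only C
  dia <- tab[grepl("^diazepam", tab$label), ]
  expect_equal(dia$count, 1)
  expect_equal(dia$denom, 1)
})

test_that("percentages print half-up at one decimal", {
  expect_equal(pct(24, 386), 6.2)
  expect_equal(pct(123, 416), 29.6)
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(2.345, 2), 2.35)
  expect_true(is.na(pct(0, 0)))
})
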