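test_that("joining requires a report in all three tables", {
  demo <- demo_records(c("1", "2"))
  drug <- drug_records("1", "alpha")          # report 2 missing from DRUG
  reac <- reac_records(c("1", "2"), c("Dysgeusia", "Nausea"))
  ta <- build_table_a(demo, drug, reac)
  expect_equal(ta$reports$primary_id, "1")
})

test_that("taste/smell flags follow SMQ membership case-insensitively", {
  demo <- demo_records("1")
  drug <- drug_records("1", "alpha")
  reac <- reac_records(c("1", "1"), c("DYSGEUSIA", "Nausea"))
  ta <- build_table_a(demo, drug, reac)
  expect_true(ta$reports$has_taste)
  expect_false(ta$reports$has_smell)
  expect_true(ta$reports$has_tsd)
})

test_that("per-report flags match hand enumeration on the ten-report fixture", {
  ta <- fixture_table_a()
  r <- ta$reports[order(as.integer(ta$reports$primary_id)), ]
  expect_equal(r$has_taste, c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE,
                              TRUE, FALSE, FALSE))
  expect_equal(r$has_smell, c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
                              TRUE, FALSE, FALSE))
  expect_equal(r$has_tsd, r$has_taste | r$has_smell)
  expect_false(any(duplicated(ta$drug_pairs)))
  expect_false(any(duplicated(ta$pt_pairs)))
})

test_that("report counts partition taste-only / smell-only / both", {
  ta <- fixture_table_a()
  # exposure = every drug: 4 taste-only (1,2,3,5), 2 smell-only (6,7), 1 both (8)
  counts <- count_tsd_reports(ta, c("alpha", "beta", "gamma"))
  expect_equal(counts$n_tsd_any, 7L)
  expect_equal(counts$n_taste_only, 4L)
  expect_equal(counts$n_smell_only, 2L)
  expect_equal(counts$n_both, 1L)
  expect_equal(counts$n_taste_any, 5L)
  expect_equal(counts$n_smell_any, 3L)
  # exposure matching nothing
  zero <- count_tsd_reports(ta, "nonexistent")
  expect_equal(zero$n_tsd_any, 0L)
  expect_equal(zero$n_exposed, 0L)
})

test_that("partition identity holds on random databases", {
  for (seed in 1:6) {
    rec <- random_records(40, seed)
    ta <- build_table_a(rec$demo, rec$drug, rec$reac)
    counts <- count_tsd_reports(ta, c("alpha", "delta"))
    expect_equal(counts$n_taste_only + counts$n_smell_only + counts$n_both,
                 counts$n_tsd_any)
    expect_equal(counts$n_taste_any, counts$n_taste_only + counts$n_both)
    expect_equal(counts$n_smell_any, counts$n_smell_only + counts$n_both)
  }
})

test_that("counts on synthetic data equal the generator's bookkeeping", {
  cfg <- synthetic_config(n_reports = 1000, seed = 31)
  sim <- simulate_faers(cfg)
  ta <- build_table_a(deduplicate(sim$demo), deduplicate(sim$drug),
                      deduplicate(sim$reac))
  counts <- count_tsd_reports(ta, cfg$drugs$name)
  led <- sim$ledger$reports
  exposed <- led$exposed_any
  expect_equal(counts$n_exposed, sum(exposed))
  expect_equal(counts$n_tsd_any, sum(led$has_tsd & exposed))
  expect_equal(counts$n_both, sum(led$has_taste & led$has_smell & exposed))
})

test_that("Table B applies the age, unit, and gender filters", {
  demo <- demo_records(
    primary_id = as.character(1:6),
    age_value = c(62, 250, 5, 70, 45, 30),
    age_unit = c("years", "years", "months", "years", "years", "years"),
    gender = c("female", "male", "male", "male", "unknown", "female")
  )
  drug <- drug_records(as.character(c(1:5)), "alpha")  # report 6 unexposed
  reac <- reac_records(c("1", "4"), c("Dysgeusia", "Nausea"))
  tb <- build_table_b(demo, drug, reac, l01_drugs = "alpha")
  # kept: 1 (62y F) and 4 (70y M); dropped: 250y, months, unknown, unexposed
  expect_equal(sort(tb$primary_id), c("1", "4"))
  expect_equal(tb$tsd[tb$primary_id == "1"], TRUE)
  expect_equal(tb$tsd[tb$primary_id == "4"], FALSE)
})

test_that("decade-coded ages convert to years", {
  demo <- demo_records("1", age_value = 7, age_unit = "decades")
  drug <- drug_records("1", "alpha")
  reac <- reac_records("1", "Nausea")
  tb <- build_table_b(demo, drug, reac, "alpha")
  expect_equal(tb$age_years, 70)
})

test_that("Table B from files equals the generator's eligibility ledger", {
  cfg <- synthetic_config(n_reports = 2000, seed = 13)
  sim <- simulate_faers(cfg)
  tb <- build_table_b(deduplicate(sim$demo), deduplicate(sim$drug),
                      deduplicate(sim$reac), cfg$drugs$name)
  truth <- ledger_table_b(sim)
  o1 <- tb[order(tb$primary_id), ]; rownames(o1) <- NULL
  o2 <- truth[order(truth$primary_id), ]; rownames(o2) <- NULL
  expect_equal(o1, o2)
})
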