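test_that("a fixed seed reproduces the database exactly", {
  cfg <- synthetic_config(n_reports = 500, seed = 5)
  s1 <- simulate_faers(cfg)
  s2 <- simulate_faers(cfg)
  expect_identical(s1$demo, s2$demo)
  expect_identical(s1$drug, s2$drug)
  expect_identical(s1$reac, s2$reac)
  expect_identical(s1$ledger$events, s2$ledger$events)
  # ledger-only runs draw from the same stream
  s3 <- simulate_faers(cfg, tables = FALSE)
  expect_identical(s1$ledger, s3$ledger)
  expect_error(write_faers(s3, tempfile()), "tables = TRUE")
})

test_that("duplicate cases are re-emitted and removed again by dedup", {
  cfg <- synthetic_config(n_reports = 1000, duplicate_fraction = 0.1, seed = 6)
  sim <- simulate_faers(cfg)
  expect_equal(nrow(sim$demo), 1100)
  dd <- deduplicate(sim$demo)
  expect_equal(nrow(dd), 1000)
  expect_setequal(dd$primary_id, sim$ledger$reports$primary_id)
})

test_that("ledger tables equal pipeline recomputation across configs and drugs", {
  for (seed in c(3, 17, 29)) {
    panel <- default_drug_panel()[c(1, 2, 5, 6, 8), ]  # keeps both signal drugs
    cfg <- synthetic_config(n_reports = 800, drugs = panel, seed = seed)
    sim <- simulate_faers(cfg)
    ta <- build_table_a(deduplicate(sim$demo), deduplicate(sim$drug),
                        deduplicate(sim$reac))
    for (d in panel$name) {
      led <- ledger_contingency(sim, d, smq_terms())
      rec <- make_contingency(ta, d, smq_terms())
      expect_identical(unclass(led), unclass(rec))
    }
  }
})

test_that("the ledger handles empty event sets and unknown drugs", {
  sim <- simulate_faers(synthetic_config(n_reports = 200, seed = 8), tables = FALSE)
  t <- ledger_contingency(sim, "sunitinib", character())
  expect_equal(t$a + t$c, 0)
  expect_error(ledger_contingency(sim, "no such drug", "Dysgeusia"),
               "unknown drug")
})

test_that("null configurations yield lnROR estimates centred on zero", {
  panel <- data.frame(name = paste("null", letters[1:6]),
                      atc_code = paste0("L01A", LETTERS[1:6], "1"),
                      exposure_prob = 0.05, stringsAsFactors = FALSE)
  cfg <- synthetic_config(n_reports = 30000, drugs = panel,
                          injected_signals = list(),
                          background_tsd_rate = 0.03, age_effect_ror = 1,
                          seed = 9)
  sim <- simulate_faers(cfg, tables = FALSE)
  lnrors <- vapply(panel$name, function(d) {
    ror(haldane_correct(ledger_contingency(sim, d, smq_terms())))$ln_ror
  }, numeric(1))
  expect_lt(abs(mean(lnrors)), 0.15)
  expect_lt(max(abs(lnrors)), 0.5)
})

test_that("configuration validation rejects bad inputs", {
  expect_error(synthetic_config(n_reports = 0))
  expect_error(
    synthetic_config(injected_signals = list(paracetamol = c(Dysgeusia = 2))),
    "unknown drug"
  )
  expect_error(
    synthetic_config(injected_signals = list(sunitinib = c(`No such PT` = 2))),
    "unknown PT"
  )
  expect_error(
    synthetic_config(injected_signals = list(sunitinib = c(Dysgeusia = -1))),
    "> 0"
  )
  # an odds tilt that pushes a PT probability past 0.99 names the PT
  expect_error(
    synthetic_config(
      pt_marginals = c(stats::setNames(rep(0.001, 13), setdiff(smq_terms(), "Dysgeusia")),
                       Dysgeusia = 0.5, Nausea = 0.05),
      injected_signals = list(sunitinib = c(Dysgeusia = 1000))
    ),
    "infeasible tilt"
  )
})

test_that("injected odds tilts reproduce the target ROR at scale", {
  cfg <- synthetic_config(
    n_reports = 150000,
    drugs = data.frame(name = "probe", atc_code = "L01EX99",
                       exposure_prob = 0.1, stringsAsFactors = FALSE),
    injected_signals = list(probe = c(Dysgeusia = 3)),
    age_effect_ror = 1, seed = 10
  )
  sim <- simulate_faers(cfg, tables = FALSE)
  rt <- ror_test(ledger_contingency(sim, "probe", "Dysgeusia"))
  expect_true(rt$conf_int[["low"]] <= 3 && 3 <= rt$conf_int[["high"]])
})
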