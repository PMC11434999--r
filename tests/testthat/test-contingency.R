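test_that("Haldane correction adds exactly 0.5 to every cell, once", {
  expect_error(contingency_2x2(0, 0, 0, 0), "positive total")
  t <- haldane_correct(contingency_2x2(3, 1, 1, 5))
  expect_equal(unlist(t[c("a", "b", "c", "d")]), c(a = 3.5, b = 1.5, c = 1.5, d = 5.5))
  expect_true(t$corrected)
  expect_error(haldane_correct(t), "already")
  # symmetric corrected table has ROR exactly 1
  sym <- haldane_correct(contingency_2x2(0, 0, 1, 1))
  expect_equal(ror(contingency_2x2(0.5, 0.5, 0.5, 0.5, corrected = TRUE))$ror, 1)
})

test_that("the ROR formula reproduces published demographic tables", {
  age <- contingency_2x2(4561, 387134, 8077, 946863)
  expect_equal(ror(age)$ror, 1.381, tolerance = 1e-3)
  gender <- contingency_2x2(5391, 565885, 7164, 744229)
  expect_equal(ror(gender)$ror, 0.990, tolerance = 1e-3)
  # a*d = b*c gives exactly 1
  expect_equal(ror(contingency_2x2(2, 4, 3, 6))$ror, 1)
  expect_equal(ror(contingency_2x2(2, 4, 3, 6))$ln_ror, 0)
})

test_that("ROR on an uncorrected zero-denominator table instructs correction", {
  expect_error(ror(contingency_2x2(1, 0, 2, 3)), "haldane_correct")
})

test_that("Fisher exact p matches hand enumeration and fisher.test", {
  expect_equal(fisher_p(contingency_2x2(2, 0, 0, 2)), 1 / 3)
  expect_equal(fisher_p(contingency_2x2(1, 1, 1, 1)), 1)
  expect_equal(fisher_p(contingency_2x2(50, 10, 10, 50)),
               oracle_fisher_p(50, 10, 10, 50), tolerance = 1e-12)
  set.seed(4)
  for (i in 1:25) {
    t <- sample(0:30, 4, TRUE)
    if (sum(t) == 0) next
    expect_equal(
      fisher_p(t[1], t[2], t[3], t[4]),
      stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
      tolerance = 1e-12
    )
  }
  expect_error(fisher_p(contingency_2x2(1.5, 1, 1, 1 + 0.5, corrected = TRUE)),
               "raw integer")
  expect_error(fisher_p(1.2, 1, 1, 1), "integer")
})

test_that("transposing exposure rows inverts the ROR and keeps p", {
  set.seed(8)
  for (i in 1:20) {
    t <- sample(1:40, 4, TRUE)
    fwd <- contingency_2x2(t[1], t[2], t[3], t[4])
    rev <- contingency_2x2(t[3], t[4], t[1], t[2])
    expect_equal(ror(fwd)$ror, 1 / ror(rev)$ror)
    expect_equal(fisher_p(fwd), fisher_p(rev), tolerance = 1e-12)
  }
})

test_that("the Haldane correction tames extreme tables and is bounded", {
  # zero-cell tables: infinite/undefined raw odds ratio becomes finite
  expect_true(is.finite(ror(haldane_correct(contingency_2x2(5, 0, 2, 9)))$ror))
  expect_gt(ror(haldane_correct(contingency_2x2(5, 0, 2, 9)))$ror, 1)
  # when the concordant cells dominate their same-column cells
  # (a >= c and d >= b, the shape of a strong signal), the correction
  # can only pull the odds ratio down, never inflate it
  set.seed(9)
  done <- 0
  while (done < 20) {
    t <- sample(1:30, 4, TRUE)
    if (!(t[1] >= t[3] && t[4] >= t[2])) next
    raw <- ror(contingency_2x2(t[1], t[2], t[3], t[4]))$ror
    cor <- ror(haldane_correct(contingency_2x2(t[1], t[2], t[3], t[4])))$ror
    expect_lte(cor, raw)
    done <- done + 1
  }
  # and the relative perturbation vanishes for large cells
  big <- contingency_2x2(4561, 387134, 8077, 946863)
  expect_equal(ror(haldane_correct(big))$ror, ror(big)$ror, tolerance = 1e-3)
})

test_that("-log10 p is capped at 308 and validated", {
  expect_equal(neg_log10_p(0.01), 2)
  expect_equal(neg_log10_p(1), 0)
  expect_equal(neg_log10_p(1e-400), 308)  # underflows to 0
  expect_equal(neg_log10_p(0), 308)
  expect_error(neg_log10_p(1.2), "0, 1")
  expect_error(neg_log10_p(-0.1), "0, 1")
})

test_that("Wald intervals reproduce published bounds and log symmetry", {
  ci <- wald_ci(contingency_2x2(4561, 387134, 8077, 946863))
  expect_equal(unname(ci), c(1.332, 1.432), tolerance = 1e-3)
  ci2 <- wald_ci(contingency_2x2(5391, 565885, 7164, 744229))
  expect_equal(unname(ci2), c(0.955, 1.025), tolerance = 1e-3)
  sym <- wald_ci(contingency_2x2(6, 6, 6, 6))
  expect_equal(log(sym[["low"]]), -log(sym[["high"]]))
  expect_error(wald_ci(contingency_2x2(0, 5, 5, 5)), "haldane_correct")
})

test_that("ror_test combines corrected ROR/CI with raw-count p", {
  t <- contingency_2x2(3, 1, 1, 5)
  rt <- ror_test(t)
  expect_s3_class(rt, "ror_test")
  expect_equal(rt$ror, ror(haldane_correct(t))$ror)
  expect_equal(rt$p, fisher_p(t))
  expect_equal(rt$n_event, 3)
  expect_equal(unname(coef(rt)), rt$ln_ror)
  expect_equal(confint(rt), rt$conf_int)
  expect_lt(rt$conf_int[["low"]], rt$ror)
  expect_gt(rt$conf_int[["high"]], rt$ror)
  expect_error(ror_test(haldane_correct(t)), "uncorrected")
})
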