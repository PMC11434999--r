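# A compact Table A where drug/PT co-occurrence is fully controlled:
# each report gets one drug and one PT.
pairs_table_a <- function(drug_of_report, pt_of_report) {
  ids <- as.character(seq_along(drug_of_report))
  build_table_a(
    demo_records(ids),
    drug_records(ids, drug_of_report),
    reac_records(ids, pt_of_report)
  )
}

test_that("lnROR matrix cells are Haldane-corrected single-PT lnRORs", {
  set.seed(101)
  drugs <- sample(c("alpha", "beta", "other"), 200, TRUE, prob = c(.2, .2, .6))
  pts <- sample(c("Dysgeusia", "Anosmia", "Nausea"), 200, TRUE)
  ta <- pairs_table_a(drugs, pts)
  m <- build_lnror_matrix(ta, c("alpha", "beta"), pt_min_reports = 1)
  expect_s3_class(m, "lnror_matrix")
  for (d in rownames(m)) for (p in colnames(m)) {
    t <- haldane_correct(make_contingency(ta, d, p))
    expect_equal(m[d, p], ror(t)$ln_ror)
  }
  expect_true(all(is.finite(m)))
  # a drug never co-reported with a PT gets a finite negative cell
  ta2 <- pairs_table_a(c("alpha", "other", "other"),
                       c("Nausea", "Dysgeusia", "Dysgeusia"))
  m2 <- build_lnror_matrix(ta2, "alpha", pt_min_reports = 1)
  expect_lt(m2["alpha", "Dysgeusia"], 0)
})

test_that("PT columns are filtered by database-wide report counts", {
  drugs <- rep("alpha", 10)
  pts <- c(rep("Dysgeusia", 6), rep("Anosmia", 3), "Hyposmia")
  ta <- pairs_table_a(drugs, pts)
  m <- build_lnror_matrix(ta, "alpha", pt_min_reports = 3)
  expect_setequal(colnames(m), c("Dysgeusia", "Anosmia"))
  expect_equal(unname(attr(m, "pt_counts")["Dysgeusia"]), 6L)
  expect_error(build_lnror_matrix(ta, "alpha", pt_min_reports = 100),
               "empty")
})

test_that("identical profiles merge first, at height zero", {
  x <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(1, 2, 3), d = c(9, 0, 1))
  cl <- ward_cluster(x, k = 2)
  merges <- hclust_merges(cl$hclust)
  expect_equal(merge_key(merges[[1]]$sets), "1|3")  # rows a and c
  expect_equal(merges[[1]]$height, 0)
  expect_equal(cl$assignment[["a"]], cl$assignment[["c"]])
})

test_that("k is validated and k = 1 yields one cluster", {
  x <- matrix(rnorm(12), 4)
  expect_error(ward_cluster(x, k = 5), "between 1")
  expect_equal(unname(ward_cluster(x, k = 1)$assignment), rep(1L, 4))
})

test_that("the merge sequence equals brute-force minimum-variance search", {
  set.seed(42)
  for (i in 1:40) {
    n <- sample(3:7, 1)
    x <- matrix(rnorm(n * sample(2:5, 1)), n)
    cl <- ward_cluster(x, k = 1)
    got <- hclust_merges(cl$hclust)
    want <- oracle_ward_merges(x)
    for (s in seq_along(want)) {
      expect_equal(merge_key(got[[s]]$sets), merge_key(want[[s]]$sets))
      # heights carry the same objective: h = sqrt(2 * delta SS)
      expect_equal(got[[s]]$height, sqrt(2 * want[[s]]$delta_ss),
                   tolerance = 1e-8)
    }
    expect_true(all(diff(cl$hclust$height) >= -1e-12))
  }
})

test_that("clustering is invariant to row order up to relabeling", {
  set.seed(7)
  x <- matrix(rnorm(6 * 4), 6, dimnames = list(letters[1:6], NULL))
  perm <- sample(6)
  a1 <- ward_cluster(x, k = 3)$assignment
  a2 <- ward_cluster(x[perm, ], k = 3)$assignment[rownames(x)]
  expect_equal(rand_index(a1, a2), 1)
})

test_that("correlation-matrix PCA matches a direct eigendecomposition", {
  set.seed(11)
  for (i in 1:10) {
    x <- matrix(rnorm(20 * 7), 20)
    colnames(x) <- paste0("pt", 1:7)
    p <- lnror_pca(x)
    e <- eigen(cor(x), symmetric = TRUE)
    expect_equal(p$eigenvalues, e$values, tolerance = 1e-8)
    for (j in 1:7) {
      v <- e$vectors[, j]
      s <- sign(sum(v * p$loadings[, j]))
      expect_equal(unname(p$loadings[, j]), s * v, tolerance = 1e-8)
    }
    expect_equal(sum(p$explained_fraction), 1)
    # reconstruction: scores %*% t(loadings) returns the standardized data
    expect_equal(p$scores %*% t(p$loadings), scale(x),
                 ignore_attr = TRUE, tolerance = 1e-8)
  }
})

test_that("two perfectly correlated columns load equally on the top component", {
  set.seed(12)
  base <- rnorm(30)
  x <- cbind(a = base, b = base, c = rnorm(30))
  p <- lnror_pca(x)
  expect_gte(p$explained_fraction[1], 1 / 3)
  expect_equal(abs(p$loadings["a", 1]), abs(p$loadings["b", 1]),
               tolerance = 1e-10)
  expect_error(lnror_pca(cbind(x, d = rep(1, 30))), "degenerate")
})

test_that("PCA is invariant to row order", {
  set.seed(13)
  x <- matrix(rnorm(15 * 4), 15, dimnames = list(paste0("d", 1:15), paste0("p", 1:4)))
  perm <- sample(15)
  p1 <- lnror_pca(x)
  p2 <- lnror_pca(x[perm, ])
  expect_equal(abs(p1$loadings), abs(p2$loadings), tolerance = 1e-10)
  expect_equal(abs(p1$scores[perm, ]), abs(p2$scores), tolerance = 1e-10)
})

test_that("component interpretation is a Pearson correlation table", {
  set.seed(15)
  x <- matrix(rnorm(25 * 4), 25, dimnames = list(NULL, paste0("pt", 1:4)))
  p <- lnror_pca(x)
  tab <- interpret_components(p, x, components = 1:2)
  expect_equal(nrow(tab), 8)
  for (i in seq_len(nrow(tab))) {
    # textbook formula
    s1 <- p$scores[, tab$component[i]]; s2 <- x[, tab$pt[i]]
    r <- sum((s1 - mean(s1)) * (s2 - mean(s2))) /
      sqrt(sum((s1 - mean(s1))^2) * sum((s2 - mean(s2))^2))
    expect_equal(tab$r[i], r, tolerance = 1e-12)
  }
  # a column equal to the scores has correlation exactly 1
  y <- cbind(x, exact = p$scores[, 1])
  tab2 <- interpret_components(p, y, components = 1)
  expect_equal(tab2$r[tab2$pt == "exact"], 1, tolerance = 1e-12)
})

test_that("the PC1 regression returns exact fits for constructed data", {
  set.seed(16)
  x <- matrix(rnorm(12 * 5), 12, dimnames = list(paste0("d", 1:12), paste0("p", 1:5)))
  p <- lnror_pca(x)
  # overall lnROR constructed from PC1 itself: slope 1/2, R^2 = 1
  overall <- stats::setNames(p$scores[, 1] / 2, rownames(x))
  # summary.lm warns about the (intentionally) perfect fit
  fit <- suppressWarnings(regress_pc1_on_lnror(p, overall))
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # R^2 identity on noisy data
  noisy <- stats::setNames(p$scores[, 1] + rnorm(12), rownames(x))
  f2 <- regress_pc1_on_lnror(p, noisy)
  y <- p$scores[, 1]
  pred <- f2$intercept + f2$slope * noisy[rownames(x)]
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  expect_equal(f2$r_squared, unname(r2), tolerance = 1e-12)
  expect_error(regress_pc1_on_lnror(p, stats::setNames(1:3, paste0("d", 1:3))),
               "cover")
  expect_error(
    regress_pc1_on_lnror(lnror_pca(x[1:2, , drop = FALSE]),
                         stats::setNames(1:2, paste0("d", 1:2))),
    "at least 3"
  )
})
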