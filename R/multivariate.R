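#' Build the signal-drug x PT lnROR matrix
#'
#' For each signal drug and each sufficiently reported taste/smell PT, the
#' cell is the natural-log reporting odds ratio of the drug against that
#' single PT, from the Haldane-corrected 2x2 over the full Table A
#' background. PT columns are restricted to SMQ terms whose database-wide
#' report count (over all drugs) reaches `pt_min_reports`; with the
#' default threshold of 3000 on a full FAERS snapshot this retains the
#' seven terms dysgeusia, ageusia, taste disorder, anosmia, parosmia,
#' hypogeusia, and hyposmia. The correction guarantees every cell is
#' finite, so the matrix has no missing values.
#'
#' @param table_a A [build_table_a()] result.
#' @param drugs Non-empty character vector of (signal) drug names: the
#'   matrix rows.
#' @param pt_min_reports Minimum database-wide report count for a PT
#'   column; default 3000.
#' @param smq SMQ vocabulary, see [smq_taste_smell()].
#' @return A numeric matrix of class `lnror_matrix` (drugs x PTs) with
#'   attributes `pt_counts` (database-wide report counts of the retained
#'   PTs) and `pt_category` (taste/smell).
#' @export
build_lnror_matrix <- function(table_a, drugs, pt_min_reports = 3000,
                               smq = smq_taste_smell()) {
  stopifnot(length(drugs) > 0L)
  drugs <- normalize_drug_name(drugs)
  pt_low <- tolower(table_a$pt_pairs$pt_name)
  db_counts <- vapply(tolower(smq$pt), function(p) {
    length(unique(table_a$pt_pairs$primary_id[pt_low == p]))
  }, integer(1))
  keep <- db_counts >= pt_min_reports
  if (!any(keep)) {
    stop("no PT reaches pt_min_reports = ", pt_min_reports,
         "; the lnROR matrix would be empty")
  }
  pts <- smq$pt[keep]

  ids <- table_a$reports$primary_id
  N <- length(ids)
  event_flags <- lapply(pts, function(p) ids %in% .event_ids(table_a, p))
  n_event <- vapply(event_flags, sum, integer(1))

  m <- matrix(NA_real_, length(drugs), length(pts),
              dimnames = list(drugs, pts))
  for (i in seq_along(drugs)) {
    exposed <- ids %in% .exposed_ids(table_a, drugs[i])
    n_drug <- sum(exposed)
    for (j in seq_along(pts)) {
      a <- sum(exposed & event_flags[[j]])
      b <- n_drug - a
      cc <- n_event[j] - a
      d <- N - n_drug - cc
      m[i, j] <- log(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5)))
    }
  }
  structure(m,
            pt_counts = stats::setNames(db_counts[keep], pts),
            pt_category = stats::setNames(smq$category[keep], pts),
            class = c("lnror_matrix", "matrix", "array"))
}

#' Ward hierarchical clustering of lnROR profiles
#'
#' Agglomerative clustering of drug side-effect profiles with Ward's
#' minimum-variance criterion on Euclidean distances (the classical
#' Ward.D2 formulation: each merge minimizes the increase in total
#' within-cluster sum of squares), cut at `k` clusters. Rows are not
#' re-standardized by default: lnROR cells already share a scale.
#'
#' @param m A numeric matrix (e.g. [build_lnror_matrix()] result).
#' @param k Number of clusters, `1 <= k <= nrow(m)`.
#' @param scale_rows Standardize rows before clustering (off by default).
#' @return An object of class `ward_clustering`: a list with `hclust` (the
#'   [stats::hclust()] tree, method `ward.D2`), `k`, and `assignment`, a
#'   named integer vector of cluster ids.
#' @export
ward_cluster <- function(m, k = 3, scale_rows = FALSE) {
  m <- as.matrix(m)
  if (k < 1 || k > nrow(m)) {
    stop("k must lie between 1 and the number of rows (", nrow(m), ")")
  }
  if (scale_rows) m <- t(scale(t(m)))
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "ward.D2")
  structure(
    list(hclust = hc, k = as.integer(k),
         assignment = stats::cutree(hc, k = k)),
    class = "ward_clustering"
  )
}

#' @export
print.ward_clustering <- function(x, ...) {
  cat(sprintf("Ward (minimum-variance) clustering of %d profiles, k = %d\n",
              length(x$assignment), x$k))
  print(table(cluster = x$assignment))
  invisible(x)
}

#' @export
plot.ward_clustering <- function(x, ...) {
  plot(x$hclust, xlab = "", sub = "", main = "Ward clustering of lnROR profiles", ...)
  if (x$k > 1) stats::rect.hclust(x$hclust, k = x$k)
  invisible(x)
}

#' Export a dendrogram as newick text
#'
#' @param x A `ward_clustering` result.
#' @param path Optional file to write to.
#' @return The newick string, invisibly if `path` is given.
#' @export
dendrogram_newick <- function(x, path = NULL) {
  stopifnot(inherits(x, "ward_clustering"))
  phy <- ape::as.phylo(x$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Correlation-matrix principal component analysis of lnROR profiles
#'
#' PCA on the column-correlation matrix (i.e., columns centred and scaled
#' to unit variance), components ordered by decreasing eigenvalue. Signs
#' are fixed deterministically: each component is oriented so that its
#' largest-magnitude loading is positive, or, when `orient` is supplied,
#' so that the first component's scores correlate positively with it.
#'
#' @param m A numeric matrix (drugs x PTs); every column must have nonzero
#'   variance.
#' @param orient Optional numeric vector (one value per row of `m`, e.g.
#'   the overall per-drug lnROR) used to orient the first component.
#' @return An object of class `lnror_pca`: a list with `loadings` (PT x
#'   component), `scores` (drug x component), `sdev`, `eigenvalues`, and
#'   `explained_fraction` (sums to 1 over all components).
#' @export
lnror_pca <- function(m, orient = NULL) {
  m <- as.matrix(m)
  v <- apply(m, 2, stats::var)
  if (any(v == 0)) {
    stop("degenerate (constant) column(s): ",
         paste(colnames(m)[v == 0], collapse = ", "))
  }
  pr <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  loadings <- pr$rotation
  scores <- pr$x
  for (j in seq_len(ncol(loadings))) {
    flip <- if (j == 1L && !is.null(orient)) {
      stats::cor(scores[, 1L], orient) < 0
    } else {
      loadings[which.max(abs(loadings[, j])), j] < 0
    }
    if (isTRUE(flip)) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  eig <- pr$sdev^2
  structure(
    list(loadings = loadings, scores = scores, sdev = pr$sdev,
         eigenvalues = eig, explained_fraction = eig / sum(eig)),
    class = "lnror_pca"
  )
}

#' @export
print.lnror_pca <- function(x, ...) {
  cat(sprintf("Correlation-matrix PCA: %d profiles x %d terms\n",
              nrow(x$scores), nrow(x$loadings)))
  ef <- round(100 * x$explained_fraction, 2)
  cat("  explained variance (%):", paste(ef, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.lnror_pca <- function(object, ...) {
  m <- rbind(
    `Standard deviation` = object$sdev,
    `Proportion of Variance` = object$explained_fraction,
    `Cumulative Proportion` = cumsum(object$explained_fraction)
  )
  colnames(m) <- colnames(object$loadings)
  m
}

#' @export
plot.lnror_pca <- function(x, components = c(1, 2), ...) {
  i <- components[1]; j <- components[2]
  graphics::plot(x$scores[, i], x$scores[, j], pch = 16, col = "grey40",
                 xlab = sprintf("PC%d (%.1f%%)", i, 100 * x$explained_fraction[i]),
                 ylab = sprintf("PC%d (%.1f%%)", j, 100 * x$explained_fraction[j]),
                 ...)
  sc <- max(abs(x$scores[, c(i, j)])) * 0.8
  graphics::arrows(0, 0, sc * x$loadings[, i], sc * x$loadings[, j],
                   length = 0.06, col = "firebrick")
  graphics::text(sc * x$loadings[, i], sc * x$loadings[, j],
                 labels = rownames(x$loadings), cex = 0.7, col = "firebrick",
                 pos = 3)
  invisible(x)
}

#' Correlate principal components with PT lnROR columns
#'
#' Pearson correlation (with two-sided p-values) of each selected
#' component's scores against each PT's lnROR column, the standard reading
#' aid for naming components ("taste vs smell contrast", etc.).
#'
#' @param p A [lnror_pca()] result.
#' @param m The lnROR matrix the PCA was fitted on.
#' @param components Integer vector of component indices; default 1:3.
#' @return A data frame with columns `component`, `pt`, `r`, `p_value`.
#' @export
interpret_components <- function(p, m, components = 1:3) {
  m <- as.matrix(m)
  rows <- lapply(components, function(cmp) {
    res <- lapply(colnames(m), function(pt) {
      ct <- stats::cor.test(p$scores[, cmp], m[, pt])
      data.frame(component = cmp, pt = pt,
                 r = unname(ct$estimate), p_value = ct$p.value,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regress the first principal component on overall lnROR
#'
#' Ordinary least squares of the PC1 score on the per-drug lnROR of the
#' combined taste-and-smell event, quantifying how much of the leading
#' profile axis is overall risk.
#'
#' @param p A [lnror_pca()] result.
#' @param overall_lnror Named numeric vector of per-drug lnROR for the
#'   combined event; names must cover the PCA's drugs.
#' @return A list with `slope`, `intercept`, `r_squared`, `p_value`, and
#'   the underlying `lm` fit.
#' @export
regress_pc1_on_lnror <- function(p, overall_lnror) {
  drugs <- rownames(p$scores)
  if (is.null(names(overall_lnror)) || !all(drugs %in% names(overall_lnror))) {
    stop("overall_lnror must be named and cover every drug in the PCA")
  }
  if (length(drugs) < 3) stop("need at least 3 drugs for the regression")
  x <- overall_lnror[drugs]
  y <- p$scores[, 1L]
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = s$r.squared,
    p_value = unname(s$coefficients[2L, 4L]),
    fit = fit
  )
}
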