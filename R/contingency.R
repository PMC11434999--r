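#' 2x2 contingency table for disproportionality analysis
#'
#' The four cells follow the standard spontaneous-report layout:
#' `a` = reports with the suspected drug *and* the event, `b` = reports
#' with the drug without the event, `c` = all other reports with the
#' event, `d` = all other reports without the event. The reporting odds
#' ratio is `(a/b)/(c/d) = a*d/(b*c)`.
#'
#' @param a,b,c,d Non-negative cell counts (integers before correction).
#' @param corrected Whether the Haldane continuity correction has been
#'   applied (every cell incremented by 0.5).
#' @return An object of class `contingency_2x2`.
#' @seealso [haldane_correct()], [ror_test()]
#' @export
contingency_2x2 <- function(a, b, c, d, corrected = FALSE) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop("contingency cells must be finite and non-negative")
  }
  if (sum(cells) <= 0) stop("contingency table must have a positive total")
  if (!corrected && any(cells != round(cells))) {
    stop("uncorrected contingency cells must be integers")
  }
  if (corrected && any(cells < 0.5)) {
    stop("a corrected table must have every cell >= 0.5")
  }
  structure(list(a = a, b = b, c = c, d = d, corrected = corrected),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("drug", "other"), c("event", "no event")))
  cat(sprintf("2x2 contingency table%s\n",
              if (x$corrected) " (Haldane-corrected)" else ""))
  print(m)
  invisible(x)
}

#' @export
as.matrix.contingency_2x2 <- function(x, ...) {
  matrix(c(x$a, x$c, x$b, x$d), 2, 2,
         dimnames = list(c("drug", "other"), c("event", "no event")))
}

#' Haldane continuity correction
#'
#' Adds 0.5 to every cell of an uncorrected 2x2 table so that the odds
#' ratio and its Wald interval remain finite in the presence of zero
#' cells. Applying the correction twice is an error.
#'
#' @param t A `contingency_2x2` with `corrected = FALSE`.
#' @return The corrected `contingency_2x2`.
#' @export
haldane_correct <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  if (t$corrected) stop("table is already Haldane-corrected")
  contingency_2x2(t$a + 0.5, t$b + 0.5, t$c + 0.5, t$d + 0.5, corrected = TRUE)
}

#' Reporting odds ratio of a 2x2 table
#'
#' @param t A `contingency_2x2`. For uncorrected tables `b*c` must be
#'   positive (apply [haldane_correct()] otherwise); correction guarantees
#'   a finite ratio.
#' @return A list with `ror` and `ln_ror` (natural log).
#' @examples
#' ror(contingency_2x2(4561, 387134, 8077, 946863))
#' @export
ror <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  if (t$b * t$c == 0) {
    stop("b*c = 0: the ROR is undefined on this uncorrected table; ",
         "apply haldane_correct() first")
  }
  r <- (t$a * t$d) / (t$b * t$c)
  list(ror = r, ln_ror = log(r))
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Conditional exact test: with margins fixed, the two-sided p-value is the
#' sum of the hypergeometric point probabilities of all tables no more
#' probable than the observed one. As in common implementations, "no more
#' probable" admits a relative tolerance of 1e-7 so that exact
#' probability ties (e.g., the mirror table of a symmetric configuration)
#' are included despite floating-point rounding. The test operates on raw
#' integer counts; Haldane-corrected tables are rejected.
#'
#' @param t A `contingency_2x2` with integer counts, or the cell `a` when
#'   `b`, `c`, `d` are given.
#' @param b,c,d Optional cell counts (vectorized) when `t` is numeric `a`.
#' @return The p-value(s) in (0, 1].
#' @examples
#' fisher_p(contingency_2x2(2, 0, 0, 2))  # 1/3
#' @export
fisher_p <- function(t, b = NULL, c = NULL, d = NULL) {
  if (inherits(t, "contingency_2x2")) {
    if (t$corrected) stop("Fisher's exact test requires raw integer counts")
    return(.fisher_p_vec(t$a, t$b, t$c, t$d))
  }
  .fisher_p_vec(t, b, c, d)
}

.fisher_p_vec <- function(a, b, c, d) {
  if (any(c(a, b, c, d) != round(c(a, b, c, d))) || any(c(a, b, c, d) < 0)) {
    stop("Fisher's exact test requires non-negative integer counts")
  }
  n <- length(a)
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- .fisher_p1(a[i], b[i], c[i], d[i])
  out
}

.fisher_p1 <- function(a, b, c, d) {
  m <- a + b      # drug-exposed reports
  n2 <- c + d     # other reports
  k <- a + c      # event reports
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  support <- lo:hi
  p <- stats::dhyper(support, m, n2, k)
  p_obs <- p[a - lo + 1L]
  pv <- sum(p[p <= p_obs * (1 + 1e-7)])
  min(pv, 1)
}

#' Capped negative common logarithm of a p-value
#'
#' `-log10(p)` capped at 308; p-values that underflow to zero (below the
#' smallest representable double, ~1e-308) map to the cap.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Values in \[0, 308\].
#' @export
neg_log10_p <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  out <- rep(308, length(p))
  pos <- p > 0
  out[pos] <- pmin(-log10(p[pos]), 308)
  out
}

#' Wald confidence interval for the reporting odds ratio
#'
#' `exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` with `z` the standard
#' normal quantile of the level. All cells must be positive; for tables
#' with zero cells apply [haldane_correct()] first.
#'
#' @param t A `contingency_2x2` with all cells > 0.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @examples
#' wald_ci(contingency_2x2(4561, 387134, 8077, 946863))
#' @export
wald_ci <- function(t, level = 0.95) {
  stopifnot(inherits(t, "contingency_2x2"), level > 0, level < 1)
  if (min(t$a, t$b, t$c, t$d) <= 0) {
    stop("Wald interval needs all cells > 0; apply haldane_correct() first")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  ln <- log((t$a * t$d) / (t$b * t$c))
  se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  ci <- exp(ln + c(-1, 1) * z * se)
  names(ci) <- c("low", "high")
  ci
}

#' Disproportionality test for one 2x2 table
#'
#' The package's core estimator: reporting odds ratio with Wald confidence
#' interval (from Haldane-corrected counts by default, which keeps both
#' finite for zero cells) and a two-sided Fisher exact p-value (always from
#' the raw integer counts, where the conditional test is defined).
#'
#' @param t An uncorrected `contingency_2x2`.
#' @param level Confidence level for the Wald interval.
#' @param correction `"haldane"` (default) to compute ROR and CI from the
#'   corrected table, or `"none"` to use raw counts (all cells must then be
#'   positive).
#' @param entity Optional label (drug, class, or stratum name).
#' @return An object of class `ror_test`: a list with `entity`, `n_event`
#'   (raw `a`), `counts`, `ror`, `ln_ror`, `p`, `neg_log10_p`, `conf_int`,
#'   `level`, `correction`.
#' @examples
#' ror_test(contingency_2x2(4561, 387134, 8077, 946863), correction = "none")
#' @export
ror_test <- function(t, level = 0.95, correction = c("haldane", "none"),
                     entity = NA_character_) {
  stopifnot(inherits(t, "contingency_2x2"))
  if (t$corrected) stop("ror_test() expects an uncorrected table")
  correction <- match.arg(correction)
  tc <- if (correction == "haldane") haldane_correct(t) else t
  est <- ror(tc)
  ci <- wald_ci(tc, level = level)
  p <- fisher_p(t)
  structure(
    list(
      entity = entity,
      n_event = t$a,
      counts = c(a = t$a, b = t$b, c = t$c, d = t$d),
      ror = est$ror,
      ln_ror = est$ln_ror,
      p = p,
      neg_log10_p = neg_log10_p(p),
      conf_int = ci,
      level = level,
      correction = correction
    ),
    class = "ror_test"
  )
}

#' @export
print.ror_test <- function(x, digits = 4, ...) {
  lab <- if (is.na(x$entity)) "" else paste0(" for ", x$entity)
  cat(sprintf("Reporting odds ratio disproportionality test%s\n", lab))
  cat(sprintf("  counts: a=%g b=%g c=%g d=%g (%s)\n",
              x$counts["a"], x$counts["b"], x$counts["c"], x$counts["d"],
              if (x$correction == "haldane") "ROR/CI Haldane-corrected"
              else "uncorrected"))
  cat(sprintf("  ROR = %s  (%.0f%% CI %s-%s)\n",
              format(x$ror, digits = digits), 100 * x$level,
              format(x$conf_int[["low"]], digits = digits),
              format(x$conf_int[["high"]], digits = digits)))
  cat(sprintf("  Fisher exact p = %s  (-log10 p = %s)\n",
              format.pval(x$p, digits = digits),
              format(x$neg_log10_p, digits = digits)))
  invisible(x)
}

#' @export
coef.ror_test <- function(object, ...) c(ln_ror = object$ln_ror)

#' @export
confint.ror_test <- function(object, parm, level, ...) object$conf_int
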