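#' Build the drug-event 2x2 contingency table from Table A
#'
#' Counts distinct reports: `a` = reports mentioning any drug of `drugs`
#' with at least one event PT, `b` = exposed reports without, `c`/`d` = all
#' remaining reports with/without the event. The total `a+b+c+d` equals the
#' number of distinct reports in Table A, so the background is the entire
#' database, not just the drug class under study.
#'
#' @param table_a A [build_table_a()] result.
#' @param drugs Drug name or character vector (a set is treated as "any-of"
#'   exposure, e.g. an ATC class).
#' @param event_pts Character vector of PT names (case-insensitive); may be
#'   empty, giving `a = c = 0`.
#' @return An uncorrected `contingency_2x2`.
#' @export
make_contingency <- function(table_a, drugs, event_pts) {
  ids <- table_a$reports$primary_id
  exposed <- ids %in% .exposed_ids(table_a, drugs)
  event <- ids %in% .event_ids(table_a, event_pts)
  contingency_2x2(
    a = sum(exposed & event),
    b = sum(exposed & !event),
    c = sum(!exposed & event),
    d = sum(!exposed & !event)
  )
}

#' Screen every drug for disproportionate event reporting
#'
#' Fits the reporting-odds-ratio disproportionality test
#' (see [ror_test()]) for every distinct drug in Table A against a fixed
#' event PT set. The ROR and its Wald interval come from Haldane-corrected
#' counts; the two-sided Fisher exact p-value from raw counts. A drug is
#' flagged as a signal when `p < p_cutoff`, `ROR > ror_cutoff`, and its
#' event report count `a` is at least `min_events`.
#'
#' @param table_a A [build_table_a()] result.
#' @param event_pts Character vector of event PT names (default: the 14
#'   taste and smell disorder terms).
#' @param drugs Optional character vector restricting which drugs are
#'   screened; default all distinct drugs in Table A.
#' @param p_cutoff,ror_cutoff,min_events Signal criteria; defaults 0.05, 1,
#'   and 100 event reports.
#' @param level Confidence level for the Wald intervals.
#' @return An object of class `disprop_screen` (a data frame) with one row
#'   per drug and columns `entity`, `n_event`, `ror`, `ln_ror`, `p`,
#'   `neg_log10_p`, `ci_low`, `ci_high`, `signal`, sorted by decreasing
#'   `ln_ror`. The criteria are stored in `attr(, "criteria")`.
#' @seealso [signal_drugs()], [plot.disprop_screen()]
#' @export
disproportionality <- function(table_a, event_pts = smq_terms(),
                               drugs = NULL,
                               p_cutoff = 0.05, ror_cutoff = 1,
                               min_events = 100, level = 0.95) {
  stopifnot(p_cutoff > 0, ror_cutoff > 0, min_events >= 0)
  ids <- table_a$reports$primary_id
  pairs <- table_a$drug_pairs
  if (!is.null(drugs)) {
    pairs <- pairs[pairs$generic_name %in% normalize_drug_name(drugs), , drop = FALSE]
  }
  all_drugs <- sort(unique(pairs$generic_name))
  N <- length(ids)
  event <- ids %in% .event_ids(table_a, event_pts)
  n_event_total <- sum(event)

  # per-drug exposed and exposed-with-event counts over distinct reports
  ev_by_id <- event[match(pairs$primary_id, ids)]
  f <- factor(pairs$generic_name, levels = all_drugs)
  n_drug <- as.integer(table(f))
  a <- as.integer(round(tapply(ev_by_id, f, sum, default = 0)))
  b <- n_drug - a
  cc <- n_event_total - a
  d <- N - n_drug - cc

  z <- stats::qnorm(1 - (1 - level) / 2)
  ah <- a + 0.5; bh <- b + 0.5; ch <- cc + 0.5; dh <- d + 0.5
  ln_ror <- log((ah * dh) / (bh * ch))
  se <- sqrt(1 / ah + 1 / bh + 1 / ch + 1 / dh)
  p <- fisher_p(a, b, cc, d)

  out <- data.frame(
    entity = all_drugs,
    n_event = a,
    ror = exp(ln_ror),
    ln_ror = ln_ror,
    p = p,
    neg_log10_p = neg_log10_p(p),
    ci_low = exp(ln_ror - z * se),
    ci_high = exp(ln_ror + z * se),
    stringsAsFactors = FALSE
  )
  out$signal <- out$p < p_cutoff & out$ror > ror_cutoff & out$n_event >= min_events
  out <- out[order(-out$ln_ror, out$entity), , drop = FALSE]
  rownames(out) <- NULL
  structure(
    out,
    criteria = list(p_cutoff = p_cutoff, ror_cutoff = ror_cutoff,
                    min_events = min_events, level = level),
    event_pts = event_pts,
    n_reports = N,
    class = c("disprop_screen", "data.frame")
  )
}

#' Signal drugs of a disproportionality screen
#'
#' @param x A `disprop_screen` result.
#' @return Character vector of flagged drug names.
#' @export
signal_drugs <- function(x) {
  stopifnot(inherits(x, "disprop_screen"))
  x$entity[x$signal]
}

#' @export
print.disprop_screen <- function(x, n = 10, ...) {
  cr <- attr(x, "criteria")
  cat(sprintf("Disproportionality screen: %d drugs over %d reports\n",
              nrow(x), attr(x, "n_reports")))
  cat(sprintf("  signal criteria: p < %g, ROR > %g, >= %g event reports\n",
              cr$p_cutoff, cr$ror_cutoff, cr$min_events))
  cat(sprintf("  signals: %d\n", sum(x$signal)))
  top <- utils::head(as.data.frame(x)[x$signal, , drop = FALSE], n)
  if (nrow(top)) {
    cat("  top signals by lnROR:\n")
    print(top, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.disprop_screen <- function(object, ...) {
  cr <- attr(object, "criteria")
  structure(
    list(
      n_drugs = nrow(object),
      n_reports = attr(object, "n_reports"),
      n_signals = sum(object$signal),
      criteria = cr,
      signals = as.data.frame(object)[object$signal, , drop = FALSE]
    ),
    class = "summary.disprop_screen"
  )
}

#' @export
print.summary.disprop_screen <- function(x, ...) {
  cat(sprintf("%d drugs screened over %d reports; %d signal(s)\n",
              x$n_drugs, x$n_reports, x$n_signals))
  if (nrow(x$signals)) print(x$signals, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.disprop_screen <- function(object, ...) {
  stats::setNames(object$ln_ror, object$entity)
}

#' @export
confint.disprop_screen <- function(object, parm, level, ...) {
  m <- cbind(low = object$ci_low, high = object$ci_high)
  rownames(m) <- object$entity
  m
}

#' Volcano plot of a disproportionality screen
#'
#' Scatter of effect size (lnROR) against significance (-log10 p); signal
#' drugs are highlighted and labelled.
#'
#' @param x A `disprop_screen` result.
#' @param label_signals Label flagged drugs with their names.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.disprop_screen <- function(x, label_signals = TRUE, ...) {
  cr <- attr(x, "criteria")
  col <- ifelse(x$signal, "firebrick", "grey60")
  graphics::plot(
    x$ln_ror, x$neg_log10_p, col = col, pch = 16,
    xlab = "lnROR", ylab = expression(-log[10] ~ italic(p)), ...
  )
  graphics::abline(h = -log10(cr$p_cutoff), lty = 3)
  graphics::abline(v = log(cr$ror_cutoff), lty = 3)
  if (label_signals && any(x$signal)) {
    graphics::text(x$ln_ror[x$signal], x$neg_log10_p[x$signal],
                   labels = x$entity[x$signal], pos = 4, cex = 0.6)
  }
  invisible(x)
}
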