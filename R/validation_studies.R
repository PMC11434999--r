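# Replicated simulation studies validating the estimator against the
# generator's known truth. These define the package's reference study
# conditions; the methods vignette discusses the choices.

#' Confidence-interval coverage study for an injected drug-event ROR
#'
#' Repeatedly simulates a database with a single drug carrying an injected
#' odds-scale association with dysgeusia (the most-reported taste term)
#' and no age effect (so the population odds ratio equals the target
#' exactly), then checks whether the Haldane-corrected Wald interval from
#' the realized 2x2 covers the target.
#'
#' @param n_replicates Number of seeded replicates (default 100).
#' @param n_reports Reports per replicate (default 200000).
#' @param target_ror Injected ROR (default 4).
#' @param exposure_prob Marginal exposure probability of the probe drug.
#' @param seed Base seed; replicate r uses `seed * 1000 + r`.
#' @return A list with `covered` (count), `n_replicates`, `estimates`
#'   (per-replicate RORs), and `n_reports`.
#' @export
ror_recovery_study <- function(n_replicates = 100, n_reports = 200000,
                               target_ror = 4, exposure_prob = 0.08,
                               seed = 1) {
  covered <- 0L
  estimates <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- synthetic_config(
      n_reports = n_reports,
      drugs = data.frame(name = "probe drug", atc_code = "L01EX99",
                         exposure_prob = exposure_prob,
                         stringsAsFactors = FALSE),
      injected_signals = list("probe drug" = c(Dysgeusia = target_ror)),
      age_effect_ror = 1,
      seed = seed * 1000L + r
    )
    sim <- simulate_faers(cfg, tables = FALSE)
    rt <- ror_test(ledger_contingency(sim, "probe drug", "Dysgeusia"))
    estimates[r] <- rt$ror
    if (rt$conf_int[["low"]] <= target_ror &&
        target_ror <= rt$conf_int[["high"]]) {
      covered <- covered + 1L
    }
  }
  list(covered = covered, n_replicates = n_replicates,
       estimates = estimates, n_reports = n_reports)
}

#' Null-calibration study for the signal criteria
#'
#' Simulates databases with no injected associations (all drug-event RORs
#' equal to 1) and measures the fraction of eligible drugs (those reaching
#' the event-count threshold) flagged by the default signal criteria
#' (p < 0.05, ROR > 1, >= 100 event reports). Because the criteria require
#' ROR > 1, the expected null rate is about half the two-sided test size.
#'
#' @param n_replicates Number of seeded replicates (default 50).
#' @param n_reports Reports per replicate (default 150000; with eight
#'   panel drugs at 8% exposure this keeps null drugs near the 100-event
#'   eligibility threshold).
#' @param seed Base seed; replicate r uses `seed * 1000 + 500 + r`.
#' @return A list with `flagged`, `eligible` (totals over replicates),
#'   `fraction`, and `n_replicates`.
#' @export
null_signal_study <- function(n_replicates = 50, n_reports = 150000,
                              seed = 1) {
  panel <- data.frame(
    name = paste("null drug", letters[1:8]),
    atc_code = paste0("L01E", LETTERS[1:8], "9"),
    exposure_prob = 0.08, stringsAsFactors = FALSE
  )
  flagged <- 0L
  eligible <- 0L
  for (r in seq_len(n_replicates)) {
    cfg <- synthetic_config(
      n_reports = n_reports, drugs = panel, injected_signals = list(),
      seed = seed * 1000L + 500L + r
    )
    sim <- simulate_faers(cfg, tables = FALSE)
    sc <- disproportionality(as_table_a(sim))
    drugs <- sc[sc$entity %in% panel$name, , drop = FALSE]
    el <- drugs[drugs$n_event >= 100, , drop = FALSE]
    eligible <- eligible + nrow(el)
    flagged <- flagged + sum(el$signal)
  }
  list(flagged = flagged, eligible = eligible,
       fraction = if (eligible > 0) flagged / eligible else NA_real_,
       n_replicates = n_replicates)
}

#' Planted-profile recovery study for clustering and PCA
#'
#' Simulates a database with three drug archetypes -- uniformly elevated
#' across the seven analysis PTs, taste-only elevated, and baseline --
#' separated by `separation` lnROR units (three drugs each), builds the
#' lnROR matrix through the standard pipeline, clusters it with Ward's
#' method at k = 3, and correlates the principal components with the PT
#' columns. The PT-count threshold is scaled to the synthetic database so
#' that exactly the seven sufficiently reported terms survive, as on a
#' full-size snapshot.
#'
#' @param n_reports Reports (default 200000).
#' @param separation Archetype separation in lnROR units (default 2.5).
#' @param seed Seed for the single replicate.
#' @return A list with `rand_index` (clustering vs planted partition),
#'   `assignment`, `truth`, `contrast_component` (index of the component
#'   whose correlations best separate taste from smell PTs),
#'   `taste_r`/`smell_r` (its correlations), `matrix`, and `pca`.
#' @export
planted_profile_study <- function(n_reports = 200000, separation = 2.5,
                                  seed = 1) {
  smq <- smq_taste_smell()
  analysis_pts <- c("Dysgeusia", "Ageusia", "Taste disorder", "Hypogeusia",
                    "Anosmia", "Parosmia", "Hyposmia")
  taste_pts <- intersect(analysis_pts, smq$pt[smq$category == "taste"])
  r <- exp(separation)
  panel <- data.frame(
    name = c(paste("uniform", c("one", "two", "three")),
             paste("tasteonly", c("one", "two", "three")),
             paste("baseline", c("one", "two", "three"))),
    atc_code = paste0("L01E", LETTERS[1:9], "8"),
    exposure_prob = 0.05, stringsAsFactors = FALSE
  )
  truth <- rep(1:3, each = 3)
  names(truth) <- panel$name
  uni <- stats::setNames(rep(r, length(analysis_pts)), analysis_pts)
  tst <- stats::setNames(rep(r, length(taste_pts)), taste_pts)
  signals <- c(
    stats::setNames(rep(list(uni), 3), panel$name[1:3]),
    stats::setNames(rep(list(tst), 3), panel$name[4:6])
  )
  cfg <- synthetic_config(
    n_reports = n_reports, drugs = panel, background_tsd_rate = 0.03,
    injected_signals = signals, age_effect_ror = 1, seed = seed
  )
  sim <- simulate_faers(cfg, tables = FALSE)
  ta <- as_table_a(sim)
  # threshold scaled to database size: keeps the 7 analysis PTs, drops
  # the rarer SMQ terms (mirroring the full-database 3000-report cut)
  m <- build_lnror_matrix(ta, panel$name, pt_min_reports = 60, smq = smq)
  cl <- ward_cluster(m, k = 3)
  p <- lnror_pca(m)
  interp <- interpret_components(p, m, components = seq_len(min(3, ncol(m))))
  taste_cols <- colnames(m) %in% taste_pts
  contrast <- vapply(unique(interp$component), function(cmp) {
    rr <- interp$r[interp$component == cmp]
    mean(rr[taste_cols]) - mean(rr[!taste_cols])
  }, numeric(1))
  best <- unique(interp$component)[which.max(abs(contrast))]
  rr <- interp$r[interp$component == best]
  if (mean(rr[taste_cols]) < 0) rr <- -rr  # orientation-free contrast
  list(
    rand_index = .rand_index(cl$assignment[names(truth)], truth),
    assignment = cl$assignment, truth = truth,
    contrast_component = best,
    taste_r = stats::setNames(rr[taste_cols], colnames(m)[taste_cols]),
    smell_r = stats::setNames(rr[!taste_cols], colnames(m)[!taste_cols]),
    matrix = m, pca = p
  )
}

# plain (unadjusted) Rand index between two partitions
.rand_index <- function(x, y) {
  n <- length(x)
  tab <- table(x, y)
  s <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  (choose(n, 2) + 2 * s - a - b) / choose(n, 2)
}
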