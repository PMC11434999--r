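#' Build the combined analysis table (Table A)
#'
#' Inner-joins deduplicated DEMO, DRUG, and REAC tables on `primary_id`: a
#' report must be present in all three tables to enter the analysis. The
#' result stores the unique report-drug and report-PT pairs plus per-report
#' taste/smell flags computed against an SMQ term set by exact
#' case-insensitive PT-name match.
#'
#' @param demo,drug,reac Deduplicated record tables (see [deduplicate()]).
#' @param smq SMQ vocabulary data frame, see [smq_taste_smell()].
#' @return An object of class `faers_table_a`: a list with
#'   * `reports`: one row per `primary_id` with logical `has_taste`,
#'     `has_smell`, `has_tsd` (`has_taste | has_smell`);
#'   * `drug_pairs`: unique (`primary_id`, `generic_name`) rows;
#'   * `pt_pairs`: unique (`primary_id`, `pt_name`) rows.
#' @export
build_table_a <- function(demo, drug, reac, smq = smq_taste_smell()) {
  ids <- intersect(intersect(unique(demo$primary_id), unique(drug$primary_id)),
                   unique(reac$primary_id))
  drug_pairs <- unique(drug[drug$primary_id %in% ids,
                            c("primary_id", "generic_name")])
  pt_pairs <- unique(reac[reac$primary_id %in% ids, c("primary_id", "pt_name")])
  rownames(drug_pairs) <- rownames(pt_pairs) <- NULL

  taste <- tolower(smq$pt[smq$category == "taste"])
  smell <- tolower(smq$pt[smq$category == "smell"])
  pt_low <- tolower(pt_pairs$pt_name)
  taste_ids <- unique(pt_pairs$primary_id[pt_low %in% taste])
  smell_ids <- unique(pt_pairs$primary_id[pt_low %in% smell])

  reports <- data.frame(
    primary_id = ids,
    has_taste = ids %in% taste_ids,
    has_smell = ids %in% smell_ids,
    stringsAsFactors = FALSE
  )
  reports$has_tsd <- reports$has_taste | reports$has_smell
  structure(
    list(reports = reports, drug_pairs = drug_pairs, pt_pairs = pt_pairs),
    class = "faers_table_a"
  )
}

#' @export
print.faers_table_a <- function(x, ...) {
  cat("FAERS analysis table (Table A)\n")
  cat(sprintf("  reports: %d  drug mentions: %d  reaction mentions: %d\n",
              nrow(x$reports), nrow(x$drug_pairs), nrow(x$pt_pairs)))
  cat(sprintf("  distinct drugs: %d  distinct PTs: %d\n",
              length(unique(x$drug_pairs$generic_name)),
              length(unique(x$pt_pairs$pt_name))))
  cat(sprintf("  taste/smell reports: %d (%.2f%%)\n",
              sum(x$reports$has_tsd),
              100 * mean(x$reports$has_tsd)))
  invisible(x)
}

# primary ids of reports mentioning any of `drugs` (normalized names)
.exposed_ids <- function(table_a, drugs) {
  drugs <- normalize_drug_name(drugs)
  unique(table_a$drug_pairs$primary_id[table_a$drug_pairs$generic_name %in% drugs])
}

# primary ids of reports mentioning any PT of `event_pts` (case-insensitive)
.event_ids <- function(table_a, event_pts) {
  pts <- tolower(event_pts)
  unique(table_a$pt_pairs$primary_id[tolower(table_a$pt_pairs$pt_name) %in% pts])
}

#' Count taste and smell disorder reports among exposed reports
#'
#' A report counts as an adverse-reaction report if it carries at least one
#' taste or smell disorder PT. Counts partition exposed taste/smell reports
#' into taste-only, smell-only, and both.
#'
#' @param table_a A [build_table_a()] result.
#' @param exposure Non-empty character vector of drug names defining the
#'   exposed population (e.g., all ATC L01 antineoplastic agents).
#' @return An object of class `tsd_counts`: a list with `n_exposed`,
#'   `n_tsd_any`, `n_taste_any`, `n_taste_only`, `n_smell_any`,
#'   `n_smell_only`, `n_both`, and `proportions` (of `n_tsd_any`).
#' @export
count_tsd_reports <- function(table_a, exposure) {
  stopifnot(length(exposure) > 0L)
  ids <- .exposed_ids(table_a, exposure)
  r <- table_a$reports[table_a$reports$primary_id %in% ids, , drop = FALSE]
  n_both <- sum(r$has_taste & r$has_smell)
  counts <- list(
    n_exposed = nrow(r),
    n_tsd_any = sum(r$has_tsd),
    n_taste_any = sum(r$has_taste),
    n_taste_only = sum(r$has_taste & !r$has_smell),
    n_smell_any = sum(r$has_smell),
    n_smell_only = sum(r$has_smell & !r$has_taste),
    n_both = n_both
  )
  denom <- max(counts$n_tsd_any, 1L)
  counts$proportions <- vapply(
    counts[c("n_taste_any", "n_taste_only", "n_smell_any", "n_smell_only", "n_both")],
    function(k) 100 * k / denom, numeric(1)
  )
  structure(counts, class = "tsd_counts")
}

#' @export
print.tsd_counts <- function(x, ...) {
  cat("Taste and smell disorder report counts\n")
  cat(sprintf("  exposed reports:       %d\n", x$n_exposed))
  cat(sprintf("  taste or smell (any):  %d\n", x$n_tsd_any))
  p <- x$proportions
  cat(sprintf("  taste (any):           %d (%.1f%%)\n", x$n_taste_any, p["n_taste_any"]))
  cat(sprintf("  taste only:            %d (%.1f%%)\n", x$n_taste_only, p["n_taste_only"]))
  cat(sprintf("  smell (any):           %d (%.1f%%)\n", x$n_smell_any, p["n_smell_any"]))
  cat(sprintf("  smell only:            %d (%.1f%%)\n", x$n_smell_only, p["n_smell_only"]))
  cat(sprintf("  both:                  %d (%.1f%%)\n", x$n_both, p["n_both"]))
  invisible(x)
}

#' Build the demographic outcome table (Table B)
#'
#' One row per exposed report with a clean age in years and a known gender.
#' Rows are restricted to reports mentioning at least one drug of the
#' exposure set; age is taken only from records whose unit is years
#' (decade-coded entries are multiplied by 10), records with other units or
#' missing/out-of-range ages (outside \[0, 120\]) are removed, as are
#' records with missing or unknown gender. The outcome flag `tsd` is true
#' if any of the report's REAC rows carries a taste or smell PT.
#'
#' @param demo,drug,reac Deduplicated record tables.
#' @param l01_drugs Character vector of exposure drug names (typically the
#'   antineoplastic agents of [atc_l01_map()]).
#' @param smq SMQ vocabulary, see [smq_taste_smell()].
#' @return A data frame of class `faers_table_b` with columns `primary_id`,
#'   `age_years`, `gender` (`"male"`/`"female"`), `tsd` (logical).
#' @export
build_table_b <- function(demo, drug, reac, l01_drugs, smq = smq_taste_smell()) {
  stopifnot(length(l01_drugs) > 0L)
  l01 <- normalize_drug_name(l01_drugs)
  exposed <- unique(drug$primary_id[drug$generic_name %in% l01])
  d <- demo[demo$primary_id %in% exposed, , drop = FALSE]
  d <- d[!duplicated(d$primary_id), , drop = FALSE]

  age_years <- rep(NA_real_, nrow(d))
  yr <- !is.na(d$age_unit) & d$age_unit == "years"
  dec <- !is.na(d$age_unit) & d$age_unit == "decades"
  age_years[yr] <- d$age_value[yr]
  age_years[dec] <- 10 * d$age_value[dec]
  keep <- !is.na(age_years) & age_years >= 0 & age_years <= 120 &
    !is.na(d$gender) & d$gender %in% c("male", "female")
  d <- d[keep, , drop = FALSE]
  age_years <- age_years[keep]

  tsd_ids <- unique(reac$primary_id[
    tolower(reac$pt_name) %in% tolower(smq$pt)
  ])
  out <- data.frame(
    primary_id = d$primary_id,
    age_years = age_years,
    gender = d$gender,
    tsd = d$primary_id %in% tsd_ids,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("faers_table_b", "data.frame")
  out
}
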