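#' Default antineoplastic drug panel for the synthetic generator
#'
#' Eight agents spanning the seven L01 subclasses with realistic marginal
#' exposure probabilities for a spontaneous-report database.
#'
#' @return A data frame with columns `name`, `atc_code`, `exposure_prob`.
#' @export
default_drug_panel <- function() {
  data.frame(
    name = c("capecitabine", "cyclophosphamide", "paclitaxel", "doxorubicin",
             "sunitinib", "erlotinib", "pembrolizumab", "vismodegib"),
    atc_code = c("L01BC06", "L01AA01", "L01CD01", "L01DB01",
                 "L01EX01", "L01EB02", "L01FF02", "L01XJ01"),
    exposure_prob = c(0.02, 0.02, 0.02, 0.015, 0.015, 0.015, 0.02, 0.005),
    stringsAsFactors = FALSE
  )
}

.default_filler_pts <- function() {
  stats::setNames(rep(0.03, 20), c(
    "Nausea", "Vomiting", "Diarrhoea", "Fatigue", "Headache", "Dizziness",
    "Rash", "Pyrexia", "Anaemia", "Neutropenia", "Thrombocytopenia",
    "Decreased appetite", "Constipation", "Dyspnoea", "Pain",
    "Oedema peripheral", "Pruritus", "Cough", "Insomnia", "Arthralgia"
  ))
}

.default_background_drugs <- function() {
  c("paracetamol", "omeprazole", "metformin", "amlodipine", "atorvastatin",
    "levothyroxine", "lisinopril", "aspirin")
}

#' Configuration for the synthetic spontaneous-report generator
#'
#' Defines the generative model of [simulate_faers()]: per report an age
#' (3-component normal mixture, integer years in \[0, 120\]), a gender, an
#' independent Bernoulli exposure per panel drug plus one background
#' (non-antineoplastic) drug, and an independent Bernoulli occurrence per
#' PT. Associations are injected on the odds scale: a report exposed to a
#' drug with an injected signal has that PT's event odds multiplied by the
#' target ROR, so the population odds ratio equals the target exactly;
#' likewise the event odds of every taste/smell PT are multiplied by
#' `age_effect_ror` for reports aged 70 or older. Dirty data is emulated by
#' re-emitting a fraction of cases as stale earlier case versions and by
#' corrupting a fraction of ages (non-year units, out-of-range values,
#' missing values) and genders (unknown codes).
#'
#' Default rates emulate an oncology-flavoured pharmacovigilance snapshot:
#' taste/smell PT baselines proportional to the SMQ reference record
#' counts scaled to a combined rate of ~0.94%, ~29% of patients aged 70+,
#' 57% female, and two planted signal drugs (sunitinib, all 14 terms at
#' ROR 2.5; vismodegib, the 7 taste terms at ROR 4).
#'
#' @param n_reports Number of reports (cases) to generate.
#' @param drugs Data frame with columns `name`, `atc_code`,
#'   `exposure_prob`; see [default_drug_panel()].
#' @param background_tsd_rate Combined baseline probability mass of the 14
#'   taste/smell PTs in an unexposed, under-70 report.
#' @param pt_marginals Named vector of per-PT baseline probabilities
#'   (taste/smell terms and filler terms); default derived from
#'   `background_tsd_rate` and the SMQ reference record counts plus 20
#'   filler PTs at 0.03 each.
#' @param injected_signals Named list: drug name -> named vector of target
#'   RORs per PT (all > 0).
#' @param age_distribution List with `mean`, `sd`, `weight` of the normal
#'   mixture (years).
#' @param age_effect_ror Target odds multiplier for taste/smell PTs in
#'   reports aged >= 70 (1 = no age effect).
#' @param gender_split Probability that a report is female.
#' @param duplicate_fraction Fraction of cases re-emitted with a stale
#'   lower case version (removed again by [deduplicate()]).
#' @param invalid_age_fraction Fraction of reports with a corrupted age
#'   (non-year unit, out-of-range value, or missing).
#' @param unknown_gender_fraction Fraction of reports with unknown gender.
#' @param decade_fraction Fraction of valid ages encoded in decades.
#' @param background_drugs Character vector of non-study drugs; each
#'   report mentions exactly one.
#' @param seed Integer seed; a fixed seed makes the output byte-identical.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reports = 200000,
                             drugs = default_drug_panel(),
                             background_tsd_rate = 0.0094,
                             pt_marginals = NULL,
                             injected_signals = NULL,
                             age_distribution = list(
                               mean = c(42, 62, 76),
                               sd = c(15, 9, 7),
                               weight = c(0.35, 0.40, 0.25)
                             ),
                             age_effect_ror = 1.381,
                             gender_split = 0.57,
                             duplicate_fraction = 0.05,
                             invalid_age_fraction = 0.05,
                             unknown_gender_fraction = 0.02,
                             decade_fraction = 0.01,
                             background_drugs = .default_background_drugs(),
                             seed = 1L) {
  smq <- smq_taste_smell()
  if (is.null(pt_marginals)) {
    w <- pmax(smq$reference_records, 0.05)  # floor so no PT has probability 0
    smq_p <- background_tsd_rate * w / sum(w)
    pt_marginals <- c(stats::setNames(smq_p, smq$pt), .default_filler_pts())
  }
  if (is.null(injected_signals)) {
    injected_signals <- list(
      sunitinib = stats::setNames(rep(2.5, 14), smq$pt),
      vismodegib = stats::setNames(rep(4, 7), smq$pt[smq$category == "taste"])
    )
  }
  drugs$name <- normalize_drug_name(drugs$name)
  stopifnot(
    n_reports >= 1,
    is.data.frame(drugs),
    all(c("name", "atc_code", "exposure_prob") %in% names(drugs)),
    !anyDuplicated(drugs$name),
    all(drugs$exposure_prob > 0 & drugs$exposure_prob < 1),
    all(pt_marginals >= 0 & pt_marginals < 1),
    !is.null(names(pt_marginals)), !anyDuplicated(names(pt_marginals)),
    all(smq$pt %in% names(pt_marginals)),
    age_effect_ror > 0, gender_split > 0, gender_split < 1,
    duplicate_fraction >= 0, duplicate_fraction < 1,
    invalid_age_fraction >= 0, invalid_age_fraction < 1,
    unknown_gender_fraction >= 0, unknown_gender_fraction < 1,
    decade_fraction >= 0, decade_fraction < 1,
    length(background_drugs) >= 1,
    length(age_distribution$mean) == length(age_distribution$sd),
    length(age_distribution$mean) == length(age_distribution$weight)
  )
  names(injected_signals) <- normalize_drug_name(names(injected_signals))
  for (d in names(injected_signals)) {
    sig <- injected_signals[[d]]
    if (!d %in% drugs$name) stop("injected signal for unknown drug: ", d)
    if (any(sig <= 0)) stop("injected RORs must be > 0 (drug ", d, ")")
    bad <- setdiff(names(sig), names(pt_marginals))
    if (length(bad)) {
      stop("injected signal for drug ", d, " names unknown PT(s): ",
           paste(bad, collapse = ", "))
    }
  }
  # feasibility: no single injected tilt (with the age tilt) may push an
  # event probability past 0.99
  for (d in names(injected_signals)) {
    for (pt in names(injected_signals[[d]])) {
      odds <- pt_marginals[[pt]] / (1 - pt_marginals[[pt]])
      if (pt %in% smq$pt) odds <- odds * max(1, age_effect_ror)
      odds <- odds * injected_signals[[d]][[pt]]
      if (odds / (1 + odds) > 0.99) {
        stop("infeasible tilt: drug '", d, "' pushes PT '", pt,
             "' past probability 0.99")
      }
    }
  }
  structure(
    list(
      n_reports = as.integer(n_reports), drugs = drugs,
      background_tsd_rate = background_tsd_rate, pt_marginals = pt_marginals,
      injected_signals = injected_signals, age_distribution = age_distribution,
      age_effect_ror = age_effect_ror, gender_split = gender_split,
      duplicate_fraction = duplicate_fraction,
      invalid_age_fraction = invalid_age_fraction,
      unknown_gender_fraction = unknown_gender_fraction,
      decade_fraction = decade_fraction,
      background_drugs = normalize_drug_name(background_drugs),
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Generate a synthetic FAERS-like database with a ground-truth ledger
#'
#' Draws reports from the generative model of [synthetic_config()] and
#' returns normalized DEMO/DRUG/REAC record tables (the same shape
#' [read_faers_table()] produces) together with a ground-truth ledger:
#' the realized per-report exposure and event indicator matrices plus
#' per-report eligibility flags, from which any drug-event 2x2 or the true
#' demographic table can be recomputed exactly.
#'
#' @param config A [synthetic_config()].
#' @param tables Materialize the DEMO/DRUG/REAC record tables (default).
#'   `FALSE` skips them and returns the ledger only, which is much faster
#'   for replicated simulation studies that measure realized counts
#'   through [ledger_contingency()]; the random stream is unaffected.
#' @return An object of class `synthetic_faers`: a list with `demo`,
#'   `drug`, `reac` (record data frames including stale duplicate case
#'   versions), `ledger`, and `config`. The ledger holds `reports` (one
#'   row per true case: identifiers, true/recorded age, `elderly`,
#'   recorded gender, `eligible_demo`, `exposed_any`, taste/smell flags),
#'   `exposure` (n x drugs logical matrix), `background` (the per-report
#'   background drug), and `events` (n x PTs logical matrix).
#' @seealso [write_faers()], [as_table_a()], [ledger_contingency()]
#' @export
simulate_faers <- function(config = synthetic_config(), tables = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_reports
  smq <- smq_taste_smell()
  pts <- names(config$pt_marginals)
  P <- length(pts)
  smq_col <- pts %in% smq$pt

  # age: integer years from a truncated normal mixture
  ad <- config$age_distribution
  age <- rep(NA_real_, n)
  todo <- seq_len(n)
  while (length(todo)) {
    comp <- sample.int(length(ad$mean), length(todo), replace = TRUE,
                       prob = ad$weight)
    draw <- round(stats::rnorm(length(todo), ad$mean[comp], ad$sd[comp]))
    ok <- draw >= 0 & draw <= 120
    age[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  elderly <- age >= 70
  gender <- ifelse(stats::runif(n) < config$gender_split, "female", "male")

  # exposures: independent Bernoulli per panel drug + one background drug
  D <- nrow(config$drugs)
  exposure <- matrix(
    stats::runif(n * D) < rep(config$drugs$exposure_prob, each = n),
    nrow = n, dimnames = list(NULL, config$drugs$name)
  )
  background <- sample(config$background_drugs, n, replace = TRUE)

  # event log-odds: baseline + per-drug injected tilts + age tilt on SMQ PTs
  eta <- matrix(stats::qlogis(config$pt_marginals), n, P, byrow = TRUE,
                dimnames = list(NULL, pts))
  for (d in names(config$injected_signals)) {
    sig <- config$injected_signals[[d]]
    j <- match(names(sig), pts)
    rows <- exposure[, d]
    if (any(rows)) {
      eta[rows, j] <- sweep(eta[rows, j, drop = FALSE], 2, log(sig), "+")
    }
  }
  if (config$age_effect_ror != 1 && any(elderly)) {
    eta[elderly, smq_col] <- eta[elderly, smq_col] + log(config$age_effect_ror)
  }
  events <- matrix(stats::runif(n * P), n, P) < stats::plogis(eta)
  dimnames(events) <- list(NULL, pts)
  # every report carries at least one reaction (as in real extracts)
  none <- which(rowSums(events) == 0L)
  if (length(none)) {
    j <- sample(which(!smq_col), length(none), replace = TRUE)
    events[cbind(none, j)] <- TRUE
  }

  taste_col <- pts %in% smq$pt[smq$category == "taste"]
  smell_col <- pts %in% smq$pt[smq$category == "smell"]
  has_taste <- rowSums(events[, taste_col, drop = FALSE]) > 0L
  has_smell <- rowSums(events[, smell_col, drop = FALSE]) > 0L

  # dirty demographics
  recorded_value <- age
  recorded_unit <- rep("years", n)
  n_inv <- floor(config$invalid_age_fraction * n)
  inv <- sample.int(n, n_inv)
  third <- split(inv, rep_len(1:3, n_inv))
  if (length(third$`1`)) {  # non-year units
    u <- sample(c("months", "weeks", "days"), length(third$`1`), replace = TRUE)
    recorded_unit[third$`1`] <- u
    recorded_value[third$`1`] <- age[third$`1`] *
      c(months = 12, weeks = 52, days = 365)[u]
  }
  if (length(third$`2`)) {  # out-of-range years
    recorded_value[third$`2`] <- sample(121:199, length(third$`2`), replace = TRUE)
  }
  if (length(third$`3`)) {  # missing
    recorded_value[third$`3`] <- NA_real_
    recorded_unit[third$`3`] <- NA_character_
  }
  valid <- setdiff(seq_len(n), inv)
  n_dec <- floor(config$decade_fraction * n)
  dec <- valid[sample.int(length(valid), min(n_dec, length(valid)))]
  recorded_unit[dec] <- "decades"
  recorded_value[dec] <- floor(age[dec] / 10)

  recorded_gender <- gender
  n_unk <- floor(config$unknown_gender_fraction * n)
  unk <- sample.int(n, n_unk)
  recorded_gender[unk] <- "unknown"

  age_recorded <- rep(NA_real_, n)
  age_recorded[recorded_unit %in% "years"] <-
    recorded_value[recorded_unit %in% "years"]
  age_recorded[recorded_unit %in% "decades"] <-
    10 * recorded_value[recorded_unit %in% "decades"]
  valid_age <- !is.na(age_recorded) & age_recorded >= 0 & age_recorded <= 120
  eligible_demo <- valid_age & recorded_gender %in% c("male", "female")

  case_id <- as.character(10000000L + seq_len(n))
  n_dup <- floor(config$duplicate_fraction * n)
  dup <- sort(sample.int(n, n_dup))
  version <- rep(1L, n)
  version[dup] <- 2L
  primary_id <- paste0(case_id, version)

  demo <- drug <- reac <- NULL
  if (tables) {
  demo <- data.frame(
    primary_id = primary_id, case_id = case_id, case_version = version,
    age_value = recorded_value, age_unit = recorded_unit,
    gender = recorded_gender, stringsAsFactors = FALSE
  )
  exp_idx <- which(exposure, arr.ind = TRUE)
  drug <- rbind(
    data.frame(primary_id = primary_id, generic_name = background,
               stringsAsFactors = FALSE),
    data.frame(primary_id = primary_id[exp_idx[, 1L]],
               generic_name = config$drugs$name[exp_idx[, 2L]],
               stringsAsFactors = FALSE)
  )
  ev_idx <- which(events, arr.ind = TRUE)
  reac <- data.frame(
    primary_id = primary_id[ev_idx[, 1L]], pt_name = pts[ev_idx[, 2L]],
    stringsAsFactors = FALSE
  )

  if (n_dup) {  # stale earlier versions, same content, superseded at dedup
    stale_id <- paste0(case_id[dup], 1L)
    demo <- rbind(demo, within(demo[dup, ], {
      primary_id <- stale_id; case_version <- 1L
    }))
    sd_rows <- drug[drug$primary_id %in% primary_id[dup], ]
    sd_rows$primary_id <- stale_id[match(sd_rows$primary_id, primary_id[dup])]
    drug <- rbind(drug, sd_rows)
    sr_rows <- reac[reac$primary_id %in% primary_id[dup], ]
    sr_rows$primary_id <- stale_id[match(sr_rows$primary_id, primary_id[dup])]
    reac <- rbind(reac, sr_rows)
  }
  o <- order(drug$primary_id, drug$generic_name)
  drug <- drug[o, ]
  o <- order(reac$primary_id, reac$pt_name)
  reac <- reac[o, ]
  rownames(demo) <- rownames(drug) <- rownames(reac) <- NULL
  class(demo) <- c("faers_demo", "data.frame")
  class(drug) <- c("faers_drug", "data.frame")
  class(reac) <- c("faers_reac", "data.frame")
  }

  ledger <- list(
    reports = data.frame(
      primary_id = primary_id, case_id = case_id,
      age_true = age, age_recorded = age_recorded, elderly = elderly,
      gender = recorded_gender, valid_age = valid_age,
      eligible_demo = eligible_demo,
      exposed_any = rowSums(exposure) > 0L,
      has_taste = has_taste, has_smell = has_smell,
      has_tsd = has_taste | has_smell,
      stringsAsFactors = FALSE
    ),
    exposure = exposure, background = background, events = events, pts = pts
  )
  structure(list(demo = demo, drug = drug, reac = reac,
                 ledger = ledger, config = config),
            class = "synthetic_faers")
}

#' @export
print.synthetic_faers <- function(x, ...) {
  cat(sprintf("Synthetic spontaneous-report database: %d cases (seed %d)\n",
              x$config$n_reports, x$config$seed))
  if (!is.null(x$demo)) {
    cat(sprintf("  DEMO rows: %d  DRUG rows: %d  REAC rows: %d\n",
                nrow(x$demo), nrow(x$drug), nrow(x$reac)))
  }
  cat(sprintf("  taste/smell reports: %d  eligible demographics: %d\n",
              sum(x$ledger$reports$has_tsd),
              sum(x$ledger$reports$eligible_demo)))
  invisible(x)
}

#' Exact realized 2x2 table from the generator's ledger
#'
#' The ground-truth contingency table for a drug against an event PT set,
#' counted over all true cases; by construction it equals the table the
#' analysis pipeline recomputes from the emitted files after
#' deduplication and joining.
#'
#' @param sim A [simulate_faers()] result.
#' @param drug A panel or background drug name.
#' @param event_pts Character vector of PT names (may be empty: `a=c=0`).
#' @return An uncorrected `contingency_2x2`.
#' @export
ledger_contingency <- function(sim, drug, event_pts) {
  stopifnot(inherits(sim, "synthetic_faers"))
  drug <- normalize_drug_name(drug)
  led <- sim$ledger
  if (drug %in% colnames(led$exposure)) {
    exposed <- led$exposure[, drug]
  } else if (drug %in% sim$config$background_drugs) {
    exposed <- led$background == drug
  } else {
    stop("unknown drug: ", drug)
  }
  j <- which(tolower(led$pts) %in% tolower(event_pts))
  event <- if (length(j)) rowSums(led$events[, j, drop = FALSE]) > 0L
           else rep(FALSE, nrow(led$events))
  contingency_2x2(
    a = sum(exposed & event), b = sum(exposed & !event),
    c = sum(!exposed & event), d = sum(!exposed & !event)
  )
}

#' In-memory Table A of a synthetic database
#'
#' Builds the `faers_table_a` object directly from the ledger's indicator
#' matrices, bypassing file round trips. Identical (tested) to running
#' [read_faers_table()] + [deduplicate()] + [build_table_a()] on the files
#' written by [write_faers()].
#'
#' @param sim A [simulate_faers()] result.
#' @return A `faers_table_a` object.
#' @export
as_table_a <- function(sim) {
  stopifnot(inherits(sim, "synthetic_faers"))
  led <- sim$ledger
  r <- led$reports
  reports <- data.frame(
    primary_id = r$primary_id, has_taste = r$has_taste,
    has_smell = r$has_smell, has_tsd = r$has_tsd, stringsAsFactors = FALSE
  )
  exp_idx <- which(led$exposure, arr.ind = TRUE)
  drug_pairs <- rbind(
    data.frame(primary_id = r$primary_id, generic_name = led$background,
               stringsAsFactors = FALSE),
    data.frame(primary_id = r$primary_id[exp_idx[, 1L]],
               generic_name = colnames(led$exposure)[exp_idx[, 2L]],
               stringsAsFactors = FALSE)
  )
  ev_idx <- which(led$events, arr.ind = TRUE)
  pt_pairs <- data.frame(
    primary_id = r$primary_id[ev_idx[, 1L]], pt_name = led$pts[ev_idx[, 2L]],
    stringsAsFactors = FALSE
  )
  o <- order(drug_pairs$primary_id, drug_pairs$generic_name)
  drug_pairs <- drug_pairs[o, ]
  o <- order(pt_pairs$primary_id, pt_pairs$pt_name)
  pt_pairs <- pt_pairs[o, ]
  rownames(drug_pairs) <- rownames(pt_pairs) <- NULL
  structure(list(reports = reports, drug_pairs = drug_pairs,
                 pt_pairs = pt_pairs),
            class = "faers_table_a")
}

#' Ground-truth demographic table of a synthetic database
#'
#' The Table-B rows the generator knows to be eligible: exposed to at
#' least one panel drug, valid recorded age in years, known gender.
#'
#' @param sim A [simulate_faers()] result.
#' @return A `faers_table_b` data frame.
#' @export
ledger_table_b <- function(sim) {
  stopifnot(inherits(sim, "synthetic_faers"))
  r <- sim$ledger$reports
  keep <- r$eligible_demo & r$exposed_any
  out <- data.frame(
    primary_id = r$primary_id[keep], age_years = r$age_recorded[keep],
    gender = r$gender[keep], tsd = r$has_tsd[keep], stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("faers_table_b", "data.frame")
  out
}

.unit_code <- c(years = "YR", decades = "DEC", months = "MON",
                weeks = "WK", days = "DY", hours = "HR")
.gender_code <- c(male = "M", female = "F", unknown = "UNK")

#' Write a synthetic database in the FAERS dollar-delimited dialect
#'
#' Emits `DEMO.txt`, `DRUG.txt`, and `REAC.txt` (including the stale
#' duplicate case versions) that round-trip through
#' [read_faers_table()].
#'
#' @param sim A [simulate_faers()] result.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_faers <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_faers"))
  if (is.null(sim$demo)) {
    stop("this simulation was run with tables = FALSE; re-run simulate_faers() ",
         "with tables = TRUE to write files")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    DEMO = file.path(dir, "DEMO.txt"),
    DRUG = file.path(dir, "DRUG.txt"),
    REAC = file.path(dir, "REAC.txt")
  )
  demo_out <- data.frame(
    primaryid = sim$demo$primary_id, caseid = sim$demo$case_id,
    caseversion = sim$demo$case_version,
    age = ifelse(is.na(sim$demo$age_value), "",
                 format(sim$demo$age_value, trim = TRUE, scientific = FALSE)),
    age_cod = ifelse(is.na(sim$demo$age_unit), "",
                     .unit_code[sim$demo$age_unit]),
    sex = .gender_code[sim$demo$gender],
    stringsAsFactors = FALSE
  )
  drug_out <- data.frame(
    primaryid = sim$drug$primary_id,
    drug_seq = seq_len(nrow(sim$drug)),
    drugname = toupper(sim$drug$generic_name),
    stringsAsFactors = FALSE
  )
  reac_out <- data.frame(
    primaryid = sim$reac$primary_id, pt = sim$reac$pt_name,
    stringsAsFactors = FALSE
  )
  for (x in list(list(demo_out, paths[["DEMO"]]),
                 list(drug_out, paths[["DRUG"]]),
                 list(reac_out, paths[["REAC"]]))) {
    utils::write.table(x[[1L]], x[[2L]], sep = "$", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(paths)
}
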