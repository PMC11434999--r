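# Programmatic fixtures: tiny record tables and dollar-delimited files.

demo_records <- function(primary_id, case_id = primary_id,
                         case_version = 1L, age_value = 50,
                         age_unit = "years", gender = "female") {
  out <- data.frame(
    primary_id = as.character(primary_id), case_id = as.character(case_id),
    case_version = as.integer(case_version), age_value = as.numeric(age_value),
    age_unit = age_unit, gender = gender, stringsAsFactors = FALSE
  )
  class(out) <- c("faers_demo", "data.frame")
  out
}

drug_records <- function(primary_id, generic_name) {
  out <- data.frame(
    primary_id = as.character(primary_id),
    generic_name = normalize_drug_name(generic_name), stringsAsFactors = FALSE
  )
  class(out) <- c("faers_drug", "data.frame")
  out
}

reac_records <- function(primary_id, pt_name) {
  out <- data.frame(
    primary_id = as.character(primary_id), pt_name = pt_name,
    pt_code = NA_integer_, stringsAsFactors = FALSE
  )
  class(out) <- c("faers_reac", "data.frame")
  out
}

# A ten-report database: reports 1-4 mention drug "alpha" (3 with
# dysgeusia, one clean); report 5 has dysgeusia without alpha; reports
# 6-7 smell-only; report 8 both taste and smell; 9-10 clean background.
fixture_table_a <- function() {
  ids <- as.character(1:10)
  demo <- demo_records(ids)
  drug <- drug_records(
    c("1", "2", "3", "4", "5", "6", "7", "8", "9", "10"),
    c("alpha", "alpha", "alpha", "alpha", "beta", "beta", "gamma",
      "gamma", "beta", "gamma")
  )
  reac <- reac_records(
    c("1", "2", "3", "4", "5", "6", "7", "8", "8", "9", "10"),
    c("Dysgeusia", "Dysgeusia", "Dysgeusia", "Nausea", "Dysgeusia",
      "Anosmia", "Parosmia", "Ageusia", "Hyposmia", "Nausea", "Fatigue")
  )
  build_table_a(demo, drug, reac)
}

# Write records as a dollar-delimited file; returns the path.
write_dollar_file <- function(lines, path = tempfile(fileext = ".txt")) {
  writeLines(lines, path)
  path
}

# Random record fixture for property tests.
random_records <- function(n_reports = 30, seed = 1) {
  set.seed(seed)
  ids <- as.character(seq_len(n_reports))
  pts <- c("Dysgeusia", "Ageusia", "Anosmia", "Parosmia", "Nausea", "Rash")
  drugs <- c("alpha", "beta", "gamma", "delta")
  demo <- demo_records(ids, age_value = sample(20:90, n_reports, TRUE))
  drug <- drug_records(
    sample(ids, n_reports * 2, TRUE), sample(drugs, n_reports * 2, TRUE)
  )
  reac <- reac_records(
    sample(ids, n_reports * 2, TRUE), sample(pts, n_reports * 2, TRUE)
  )
  list(demo = deduplicate(demo), drug = deduplicate(drug),
       reac = deduplicate(reac))
}
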