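#' Normalize a drug name
#'
#' Case-folds, trims leading/trailing whitespace, and collapses internal
#' whitespace runs to a single space. No fuzzy matching or spelling
#' correction is attempted: the reader assumes vendor-curated generic names.
#'
#' @param x Character vector of drug names.
#' @return Character vector of normalized names.
#' @examples
#' normalize_drug_name("  Trastuzumab   Deruxtecan ")
#' @export
normalize_drug_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# column synonyms accepted per schema; first match wins
.faers_schema <- list(
  DEMO = list(
    primary_id   = c("primaryid", "primary_id", "isr"),
    case_id      = c("caseid", "case_id", "case"),
    case_version = c("caseversion", "case_version"),
    age_value    = c("age"),
    age_unit     = c("age_cod", "age_code", "agecod"),
    gender       = c("sex", "gndr_cod", "gender")
  ),
  DRUG = list(
    primary_id   = c("primaryid", "primary_id", "isr"),
    generic_name = c("drugname", "drug_name", "prod_ai")
  ),
  REAC = list(
    primary_id = c("primaryid", "primary_id", "isr"),
    pt_name    = c("pt", "pt_name"),
    pt_code    = c("pt_code", "ptcode")  # optional
  )
)

.faers_optional <- list(DEMO = character(), DRUG = character(), REAC = "pt_code")

.age_unit_map <- c(
  YR = "years", YEAR = "years", DEC = "decades", MON = "months",
  WK = "weeks", DY = "days", HR = "hours"
)

.gender_map <- c(M = "male", F = "female", UNK = "unknown", NS = "unknown")

#' Read a FAERS-dialect quarterly extract table
#'
#' Reads one of the dollar-sign-delimited ASCII tables of a FAERS quarterly
#' extract (DEMO, DRUG, or REAC) into a normalized record data frame.
#' Column names are matched case-insensitively and common synonyms are
#' accepted (e.g. `SEX`/`GNDR_COD`, `DRUGNAME`/`PROD_AI`). Unparseable
#' numeric fields become `NA` rather than errors; age-unit codes are mapped
#' to `years`/`decades`/`months`/`weeks`/`days`/`hours` and gender codes to
#' `male`/`female`/`unknown`.
#'
#' @param path Path to the file; the first line must be a header naming at
#'   least the schema's required columns.
#' @param schema One of `"DEMO"`, `"DRUG"`, `"REAC"`.
#' @return A data frame of records with class `faers_demo`, `faers_drug`,
#'   or `faers_reac`:
#'   * DEMO: `primary_id`, `case_id`, `case_version` (integer),
#'     `age_value` (numeric), `age_unit`, `gender`.
#'   * DRUG: `primary_id`, `generic_name` (normalized; empty names dropped
#'     with a warning).
#'   * REAC: `primary_id`, `pt_name` (trimmed, case preserved), `pt_code`
#'     (integer, `NA` when the file has no code column).
#' @seealso [deduplicate()], [build_table_a()]
#' @export
read_faers_table <- function(path, schema = c("DEMO", "DRUG", "REAC")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(
    path, sep = "$", quote = "", header = TRUE,
    colClasses = "character", check.names = FALSE,
    stringsAsFactors = FALSE, blank.lines.skip = TRUE
  )
  spec <- .faers_schema[[schema]]
  optional <- .faers_optional[[schema]]
  lower <- tolower(trimws(names(raw)))
  cols <- lapply(names(spec), function(field) {
    hit <- which(lower %in% spec[[field]])
    if (!length(hit)) {
      if (field %in% optional) return(NULL)
      stop(sprintf("%s file %s is missing required column '%s'",
                   schema, path, spec[[field]][1L]))
    }
    raw[[hit[1L]]]
  })
  names(cols) <- names(spec)
  n <- nrow(raw)
  if (n == 0L) warning(schema, " file ", path, " has no data rows")

  out <- switch(schema,
    DEMO = data.frame(
      primary_id = trimws(cols$primary_id),
      case_id = trimws(cols$case_id),
      case_version = .as_int(cols$case_version, default = 0L),
      age_value = suppressWarnings(as.numeric(cols$age_value)),
      age_unit = unname(.age_unit_map[toupper(trimws(cols$age_unit))]),
      gender = {
        g <- unname(.gender_map[toupper(trimws(cols$gender))])
        if (n) g[is.na(g) & !nzchar(trimws(cols$gender))] <- NA_character_
        g
      },
      stringsAsFactors = FALSE
    ),
    DRUG = data.frame(
      primary_id = trimws(cols$primary_id),
      generic_name = normalize_drug_name(cols$generic_name),
      stringsAsFactors = FALSE
    ),
    REAC = data.frame(
      primary_id = trimws(cols$primary_id),
      pt_name = gsub("[[:space:]]+", " ", trimws(cols$pt_name)),
      pt_code = if (is.null(cols$pt_code)) rep(NA_integer_, n) else .as_int(cols$pt_code),
      stringsAsFactors = FALSE
    )
  )
  if (schema == "DRUG" && any(!nzchar(out$generic_name))) {
    warning("dropping ", sum(!nzchar(out$generic_name)),
            " DRUG row(s) with empty drug name")
    out <- out[nzchar(out$generic_name), , drop = FALSE]
  }
  if (schema == "REAC" && any(!nzchar(out$pt_name))) {
    warning("dropping ", sum(!nzchar(out$pt_name)),
            " REAC row(s) with empty PT name")
    out <- out[nzchar(out$pt_name), , drop = FALSE]
  }
  bad_id <- !nzchar(out$primary_id)
  if (any(bad_id)) {
    warning("dropping ", sum(bad_id), " ", schema, " row(s) with empty primary id")
    out <- out[!bad_id, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c(paste0("faers_", tolower(schema)), "data.frame")
  out
}

.as_int <- function(x, default = NA_integer_) {
  v <- suppressWarnings(as.integer(x))
  if (!is.na(default)) v[is.na(v)] <- default
  v
}

#' Deduplicate FAERS record tables
#'
#' DEMO tables keep exactly one record per `case_id`: the one with the
#' highest `case_version` (later versions supersede earlier submissions of
#' the same case); ties are broken by the lexicographically highest
#' `primary_id`. DRUG and REAC tables collapse exact-duplicate rows to one.
#' Deduplication is idempotent.
#'
#' @param records A `faers_demo`, `faers_drug`, or `faers_reac` data frame
#'   from [read_faers_table()] (or the same shape).
#' @param ... Unused.
#' @return The deduplicated records, same class as the input.
#' @export
deduplicate <- function(records, ...) UseMethod("deduplicate")

#' @rdname deduplicate
#' @export
deduplicate.faers_demo <- function(records, ...) {
  if (!nrow(records)) return(records)
  o <- order(records$case_id, records$case_version, records$primary_id)
  x <- records[o, , drop = FALSE]
  keep <- !duplicated(x$case_id, fromLast = TRUE)  # last = highest version/id
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname deduplicate
#' @export
deduplicate.faers_drug <- function(records, ...) {
  out <- unique(records)
  rownames(out) <- NULL
  out
}

#' @rdname deduplicate
#' @export
deduplicate.faers_reac <- function(records, ...) {
  out <- unique(records)
  rownames(out) <- NULL
  out
}
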