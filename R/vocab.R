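#' Taste and smell disorders SMQ term set
#'
#' The 14 MedDRA preferred terms (PTs) of the standardized MedDRA query
#' "Taste and smell disorders" (SMQ 20000046, MedDRA v25.0), split into the
#' seven taste-related and seven smell-related terms, excluding congenital
#' anosmia (a congenital condition, not a drug effect). The
#' `reference_records` column carries the number of FAERS records per PT in
#' a May 2022 snapshot; it is used only as a relative frequency profile by
#' the synthetic report generator ([synthetic_config()]) and for
#' documentation.
#'
#' @return A data frame with columns `pt` (preferred term), `pt_code`
#'   (MedDRA numeric code), `category` (`"taste"` or `"smell"`), and
#'   `reference_records` (integer).
#' @examples
#' smq <- smq_taste_smell()
#' table(smq$category)
#' @export
smq_taste_smell <- function() {
  data.frame(
    pt = c(
      "Dysgeusia", "Ageusia", "Taste disorder", "Hypogeusia",
      "Hallucination, gustatory", "Hypergeusia", "Gustometry abnormal",
      "Anosmia", "Parosmia", "Hyposmia", "Hallucination, olfactory",
      "Olfactory nerve disorder", "Olfactory test abnormal",
      "Olfactory dysfunction"
    ),
    pt_code = c(
      10013911L, 10001480L, 10082490L, 10020989L,
      10019071L, 10069147L, 10064480L,
      10002653L, 10034018L, 10050515L, 10019072L,
      10056388L, 10062927L, 10086567L
    ),
    category = rep(c("taste", "smell"), each = 7L),
    reference_records = c(
      220220L, 70503L, 34849L, 6926L, 157L, 184L, 11L,
      30875L, 22325L, 3547L, 1371L, 320L, 9L, 0L
    ),
    stringsAsFactors = FALSE
  )
}

#' Extract taste or smell PT names from an SMQ table
#'
#' @param smq An SMQ data frame as returned by [smq_taste_smell()].
#' @param category `"taste"`, `"smell"`, or `"all"`.
#' @return Character vector of preferred-term names.
#' @export
smq_terms <- function(smq = smq_taste_smell(), category = c("all", "taste", "smell")) {
  category <- match.arg(category)
  if (category == "all") smq$pt else smq$pt[smq$category == category]
}

#' ATC L01 antineoplastic drug-class map
#'
#' A bundled reference map from generic drug name to WHO ATC code for a
#' broad set of L01 antineoplastic agents, partitioned into the seven
#' level-3 classes: alkylating agents (L01A), antimetabolites (L01B), plant
#' alkaloids and other natural products (L01C), cytotoxic antibiotics and
#' related substances (L01D), protein kinase inhibitors (L01E), monoclonal
#' antibodies and antibody drug conjugates (L01F), and other antineoplastic
#' agents (L01X). The bundled file is a curated subset, not a complete ATC
#' release; supply your own file (same columns) for production runs.
#'
#' @param path Optional path to a CSV with columns `drug` and `atc_code`.
#'   Defaults to the map shipped with the package.
#' @return A data frame with columns `drug` (normalized name), `atc_code`,
#'   and `atc_class` (the 4-character L01 subclass).
#' @examples
#' map <- atc_l01_map()
#' table(map$atc_class)
#' @export
atc_l01_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "atc_l01_reference.csv", package = "rorsignal")
  }
  stopifnot(file.exists(path))
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("drug", "atc_code")
  missing <- setdiff(required, names(map))
  if (length(missing)) {
    stop("ATC map is missing required column(s): ", paste(missing, collapse = ", "))
  }
  map$drug <- normalize_drug_name(map$drug)
  map$atc_class <- substr(map$atc_code, 1L, 4L)
  bad <- !map$atc_class %in% atc_l01_classes()
  if (any(bad)) {
    stop(
      "ATC codes outside L01A-L01X: ",
      paste(unique(map$atc_code[bad]), collapse = ", ")
    )
  }
  if (anyDuplicated(map$drug)) {
    stop("duplicated drug names in ATC map: ",
         paste(unique(map$drug[duplicated(map$drug)]), collapse = ", "))
  }
  map[, c("drug", "atc_code", "atc_class")]
}

#' The seven ATC L01 subclasses
#'
#' @return Character vector `c("L01A", ..., "L01X")`.
#' @export
atc_l01_classes <- function() {
  c("L01A", "L01B", "L01C", "L01D", "L01E", "L01F", "L01X")
}
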