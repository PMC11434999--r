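#' Fraction of signal drugs per ATC class
#'
#' For each of the seven L01 subclasses, the number of signal drugs, the
#' number of mapped drugs, and the percentage of signal drugs in the class
#' (reported to 2 decimals). Classes with no mapped drugs report `NA`.
#'
#' @param signals Character vector of signal drug names (must be a subset
#'   of the mapped drugs; unmapped names raise an error).
#' @param map An ATC class map, see [atc_l01_map()].
#' @return A data frame with columns `atc_class`, `n_signal`, `n_total`,
#'   `percent`.
#' @examples
#' map <- data.frame(drug = c("x", "y", "z"),
#'                   atc_code = c("L01EX01", "L01EX02", "L01AA01"))
#' map$atc_class <- substr(map$atc_code, 1, 4)
#' class_signal_fraction(c("x"), map)
#' @export
class_signal_fraction <- function(signals, map) {
  signals <- normalize_drug_name(signals)
  unmapped <- setdiff(signals, map$drug)
  if (length(unmapped)) {
    stop("signal drug(s) not in the ATC map: ", paste(unmapped, collapse = ", "))
  }
  classes <- atc_l01_classes()
  cls <- factor(map$atc_class, levels = classes)
  n_total <- as.integer(table(cls))
  n_signal <- as.integer(table(cls[map$drug %in% signals]))
  percent <- ifelse(n_total > 0, round(100 * n_signal / n_total, 2), NA_real_)
  data.frame(
    atc_class = classes, n_signal = n_signal, n_total = n_total,
    percent = percent, stringsAsFactors = FALSE
  )
}

#' Class-level disproportionality test
#'
#' Treats exposure to any drug of an ATC class as the "suspected drug" row
#' of the 2x2 table and runs the standard ROR / Fisher / Wald analysis
#' against the full Table A background. A report exposed to drugs of
#' several classes counts as exposed in each class's table.
#'
#' @param table_a A [build_table_a()] result.
#' @param cls One of the seven L01 subclasses, e.g. `"L01E"`.
#' @param map An ATC class map, see [atc_l01_map()].
#' @param event_pts Event PT set (default: all 14 taste/smell terms).
#' @param level Confidence level.
#' @return A [ror_test()] object labelled with the class.
#' @export
class_association <- function(table_a, cls, map, event_pts = smq_terms(),
                              level = 0.95) {
  stopifnot(cls %in% atc_l01_classes())
  drugs <- map$drug[map$atc_class == cls]
  drugs <- drugs[drugs %in% table_a$drug_pairs$generic_name]
  if (!length(drugs)) {
    stop("undefined association: no drugs of class ", cls, " occur in Table A")
  }
  t <- make_contingency(table_a, drugs, event_pts)
  ror_test(t, level = level, correction = "haldane", entity = cls)
}

#' Class-level disproportionality for all seven L01 subclasses
#'
#' @inheritParams class_association
#' @return A data frame with one row per class present in Table A:
#'   `entity`, `n_event`, `ror`, `ln_ror`, `p`, `neg_log10_p`, `ci_low`,
#'   `ci_high`.
#' @export
class_associations <- function(table_a, map, event_pts = smq_terms(),
                               level = 0.95) {
  present <- intersect(
    atc_l01_classes(),
    unique(map$atc_class[map$drug %in% table_a$drug_pairs$generic_name])
  )
  rows <- lapply(present, function(cl) {
    rt <- class_association(table_a, cl, map, event_pts, level)
    data.frame(
      entity = cl, n_event = rt$n_event, ror = rt$ror, ln_ror = rt$ln_ror,
      p = rt$p, neg_log10_p = rt$neg_log10_p,
      ci_low = rt$conf_int[["low"]], ci_high = rt$conf_int[["high"]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
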