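#' Dichotomize Table B into two strata
#'
#' Splits the demographic outcome table into two exhaustive, mutually
#' exclusive groups and cross-tabulates them against the taste/smell
#' outcome. For age, group 1 is `age >= cutoff` ("70 years of age or
#' older" by default); for gender, group 1 is male, group 2 female.
#'
#' @param table_b A [build_table_b()] result.
#' @param variable `"age"` or `"gender"`.
#' @param cutoff Age cutoff in years, in (0, 120]; default 70.
#' @return An object of class `stratum_split`: a list with `variable`,
#'   `labels` (group names), and `counts`, a 2x2 integer matrix with rows =
#'   groups and columns = `c("tsd", "no_tsd")`.
#' @export
dichotomize <- function(table_b, variable = c("age", "gender"), cutoff = 70) {
  variable <- match.arg(variable)
  if (variable == "age") {
    stopifnot(cutoff > 0, cutoff <= 120)
    g1 <- table_b$age_years >= cutoff
    labels <- c(sprintf("age>=%g", cutoff), sprintf("age<%g", cutoff))
  } else {
    g1 <- table_b$gender == "male"
    labels <- c("male", "female")
  }
  counts <- matrix(
    c(sum(g1 & table_b$tsd), sum(g1 & !table_b$tsd),
      sum(!g1 & table_b$tsd), sum(!g1 & !table_b$tsd)),
    nrow = 2, byrow = TRUE,
    dimnames = list(labels, c("tsd", "no_tsd"))
  )
  structure(list(variable = variable, labels = labels, counts = counts),
            class = "stratum_split")
}

#' @export
print.stratum_split <- function(x, ...) {
  cat(sprintf("Stratum split on %s\n", x$variable))
  print(x$counts)
  invisible(x)
}

#' Disproportionality test for a demographic stratum split
#'
#' Runs the same ROR / Fisher exact / Wald machinery used for drugs on the
#' stratum 2x2 (group 1 plays the role of the exposure). By default raw
#' counts are used (no continuity correction): demographic tables have
#' large cells and the uncorrected ratio reproduces published two-level
#' demographic tables.
#'
#' @param split A [dichotomize()] result.
#' @param level Confidence level for the Wald interval.
#' @param correction `"none"` (default) or `"haldane"`.
#' @return A [ror_test()] object labelled with the group-1 stratum.
#' @examples
#' # age >= 70 vs < 70 cross-tabulated against taste/smell outcome
#' s <- structure(list(variable = "age", labels = c("age>=70", "age<70"),
#'   counts = matrix(c(4561, 387134, 8077, 946863), 2, byrow = TRUE,
#'                   dimnames = list(c("age>=70", "age<70"), c("tsd", "no_tsd")))),
#'   class = "stratum_split")
#' stratum_association(s)
#' @export
stratum_association <- function(split, level = 0.95,
                                correction = c("none", "haldane")) {
  stopifnot(inherits(split, "stratum_split"))
  correction <- match.arg(correction)
  k <- split$counts
  if (any(rowSums(k) == 0) || any(colSums(k) == 0)) {
    stop("undefined association: a zero marginal in the ", split$variable,
         " split")
  }
  t <- contingency_2x2(k[1, 1], k[1, 2], k[2, 1], k[2, 2])
  ror_test(t, level = level, correction = correction, entity = split$labels[1])
}
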