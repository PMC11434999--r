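#' Default pipeline configuration
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param input Either `NULL` (generate synthetic input) or a list with
#'   paths `demo`, `drug`, `reac` to FAERS-dialect files.
#' @param synthetic A [synthetic_config()] used when `input` is `NULL`.
#' @param atc_map_path Optional path to a drug->ATC CSV; default the
#'   bundled reference map for file input, or the synthetic panel.
#' @param p_cutoff,ror_cutoff,min_events Signal criteria (see
#'   [disproportionality()]).
#' @param age_cutoff Elderly age cutoff in years.
#' @param pt_min_reports PT report-count threshold for the lnROR matrix.
#' @param k Number of Ward clusters.
#' @param level Confidence level.
#' @param seed Integer seed (forwarded to the synthetic generator).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            input = NULL,
                            synthetic = synthetic_config(),
                            atc_map_path = NULL,
                            p_cutoff = 0.05, ror_cutoff = 1, min_events = 100,
                            age_cutoff = 70, pt_min_reports = 3000,
                            k = 3, level = 0.95, seed = NULL) {
  stopifnot(p_cutoff > 0, ror_cutoff > 0, min_events >= 0,
            age_cutoff > 0, age_cutoff <= 120, pt_min_reports >= 0, k >= 1)
  if (!is.null(input)) {
    stopifnot(all(c("demo", "drug", "reac") %in% names(input)))
    missing <- !vapply(input[c("demo", "drug", "reac")], file.exists, logical(1))
    if (any(missing)) {
      stop("input file(s) not found: ",
           paste(unlist(input)[missing], collapse = ", "))
    }
  }
  if (!is.null(seed) && is.null(input)) synthetic$seed <- as.integer(seed)
  structure(
    list(out_dir = out_dir, input = input, synthetic = synthetic,
         atc_map_path = atc_map_path, p_cutoff = p_cutoff,
         ror_cutoff = ror_cutoff, min_events = min_events,
         age_cutoff = age_cutoff, pt_min_reports = pt_min_reports,
         k = k, level = level, seed = seed),
    class = "pipeline_config"
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full disproportionality pipeline
#'
#' Executes ingestion (or synthetic generation), deduplication and
#' joining, taste/smell report counting, the per-drug disproportionality
#' screen, the demographic (age/gender) analysis, the ATC-class analysis,
#' and the lnROR-profile characterization (Ward clustering + PCA + PC1
#' regression), writing every stage output as CSV/JSON plus a run manifest
#' that suffices to reproduce the run.
#'
#' @param config A [pipeline_config()].
#' @return The manifest list, invisibly; all artifacts are written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  smq <- smq_taste_smell()

  if (is.null(config$input)) {
    sim <- .stage("simulate", simulate_faers(config$synthetic))
    input_dir <- out("input")
    .stage("simulate", write_faers(sim, input_dir))
    paths <- list(demo = file.path(input_dir, "DEMO.txt"),
                  drug = file.path(input_dir, "DRUG.txt"),
                  reac = file.path(input_dir, "REAC.txt"))
    atc_map <- sim$config$drugs[, c("name", "atc_code")]
    names(atc_map) <- c("drug", "atc_code")
    atc_map$atc_class <- substr(atc_map$atc_code, 1, 4)
  } else {
    paths <- config$input
    atc_map <- atc_l01_map(config$atc_map_path)
  }

  demo <- .stage("ingest", read_faers_table(paths$demo, "DEMO"))
  drug <- .stage("ingest", read_faers_table(paths$drug, "DRUG"))
  reac <- .stage("ingest", read_faers_table(paths$reac, "REAC"))
  demo_d <- deduplicate(demo); drug_d <- deduplicate(drug)
  reac_d <- deduplicate(reac)
  table_a <- .stage("join", build_table_a(demo_d, drug_d, reac_d, smq))

  l01 <- atc_map$drug
  counts <- .stage("counts", count_tsd_reports(table_a, l01))
  jsonlite::write_json(unclass(counts), out("tsd_counts.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  screen <- .stage("screen", disproportionality(
    table_a, smq_terms(smq),
    p_cutoff = config$p_cutoff, ror_cutoff = config$ror_cutoff,
    min_events = config$min_events, level = config$level
  ))
  utils::write.csv(as.data.frame(screen), out("screen.csv"), row.names = FALSE)

  table_b <- .stage("demographics",
                    build_table_b(demo_d, drug_d, reac_d, l01, smq))
  demog <- .stage("demographics", {
    rows <- lapply(list(
      dichotomize(table_b, "age", cutoff = config$age_cutoff),
      dichotomize(table_b, "gender")
    ), function(s) {
      rt <- stratum_association(s, level = config$level)
      data.frame(group = s$labels[1], n_tsd = s$counts[1, 1],
                 n_no_tsd = s$counts[1, 2], ref_tsd = s$counts[2, 1],
                 ref_no_tsd = s$counts[2, 2], ror = rt$ror, p = rt$p,
                 ci_low = rt$conf_int[["low"]], ci_high = rt$conf_int[["high"]],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  utils::write.csv(demog, out("demographics.csv"), row.names = FALSE)

  sig <- intersect(signal_drugs(screen), atc_map$drug)
  cls_frac <- .stage("classes", class_signal_fraction(sig, atc_map))
  utils::write.csv(cls_frac, out("class_signal_fraction.csv"), row.names = FALSE)
  cls_assoc <- .stage("classes",
                      class_associations(table_a, atc_map, smq_terms(smq),
                                         level = config$level))
  utils::write.csv(cls_assoc, out("class_association.csv"), row.names = FALSE)

  profile <- NULL
  if (length(sig) >= max(2, config$k)) {
    m <- .stage("profile", build_lnror_matrix(
      table_a, sig, pt_min_reports = config$pt_min_reports, smq = smq
    ))
    utils::write.csv(as.data.frame(unclass(m)), out("lnror_matrix.csv"))
    cl <- .stage("profile", ward_cluster(m, k = config$k))
    utils::write.csv(
      data.frame(drug = names(cl$assignment), cluster = cl$assignment),
      out("clusters.csv"), row.names = FALSE
    )
    dendrogram_newick(cl, out("dendrogram.nwk"))
    overall <- stats::setNames(screen$ln_ror, screen$entity)[rownames(m)]
    pca <- .stage("profile", lnror_pca(m, orient = overall))
    utils::write.csv(as.data.frame(pca$loadings), out("pca_loadings.csv"))
    utils::write.csv(as.data.frame(pca$scores), out("pca_scores.csv"))
    interp <- .stage("profile", interpret_components(
      pca, m, components = seq_len(min(3, ncol(pca$loadings)))
    ))
    utils::write.csv(interp, out("pc_interpretation.csv"), row.names = FALSE)
    reg <- .stage("profile", regress_pc1_on_lnror(pca, overall))
    jsonlite::write_json(
      reg[c("slope", "intercept", "r_squared", "p_value")],
      out("pc1_regression.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    profile <- list(n_drugs = nrow(m), n_pts = ncol(m),
                    explained_fraction = pca$explained_fraction)
  } else if (config$k > length(sig) && length(sig) >= 2) {
    stop("pipeline stage 'profile' failed: k = ", config$k,
         " exceeds the number of signal drugs (", length(sig), ")")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("rorsignal")),
    seed = if (is.null(config$input)) config$synthetic$seed else config$seed,
    input = if (is.null(config$input)) "synthetic" else unlist(paths),
    thresholds = config[c("p_cutoff", "ror_cutoff", "min_events",
                          "age_cutoff", "pt_min_reports", "k", "level")],
    rows = list(
      demo = nrow(demo), drug = nrow(drug), reac = nrow(reac),
      demo_dedup = nrow(demo_d), drug_dedup = nrow(drug_d),
      reac_dedup = nrow(reac_d),
      table_a_reports = nrow(table_a$reports), table_b = nrow(table_b)
    ),
    counts = unclass(counts)[c("n_exposed", "n_tsd_any", "n_taste_only",
                               "n_smell_only", "n_both")],
    n_signals = sum(screen$signal),
    profile = profile
  )
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
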