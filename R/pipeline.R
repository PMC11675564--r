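#' Simulate a cohort and write it to disk
#'
#' Convenience wrapper: generate a cohort under `config` and write the
#' samples/mothers/LOQ CSVs plus a reproducibility manifest into
#' `out_dir`.
#'
#' @param config An [scfa_sim_config()] or a path to a YAML/JSON config.
#' @param out_dir Output directory.
#' @param seed Integer master seed.
#' @return The cohort, invisibly.
#' @export
simulate_to_dir <- function(config = scfa_sim_config(), out_dir, seed = 1) {
  if (is.character(config)) config <- read_sim_config(config)
  cohort <- simulate_scfa_cohort(config, seed = seed)
  paths <- write_cohort(cohort, out_dir)
  manifest <- list(
    tool = "scfapanel", version = as.character(utils::packageVersion("scfapanel")),
    stage = "simulate", seed = as.integer(seed),
    n_mothers = nrow(cohort$mothers), n_samples = nrow(cohort$samples),
    analytes = cohort$analytes, timepoints = cohort$timepoints,
    file_md5 = as.list(tools::md5sum(paths))
  )
  names(manifest$file_md5) <- basename(paths)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(cohort)
}

#' Run the full SCFA analysis pipeline
#'
#' Orchestrates ingest -> QC -> prevalence filter -> half-LOQ imputation ->
#' composition metrics -> association battery -> correlation
#' difference-in-differences screen, writing result CSVs, figures and a
#' reproducibility manifest to `out_dir`.
#'
#' @param data Either a directory containing the cohort CSVs (see
#'   [read_cohort()]) or an `scfa_cohort` object.
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output and just returns the results.
#' @param seed Master seed; the permutation stream is derived from it.
#' @param n_perm Permutations for the correlation screen.
#' @param min_detect Prevalence-filter detection threshold.
#' @param unadjusted,clr Include the sensitivity blocks in the association
#'   battery.
#' @param bh Append Benjamini-Hochberg columns (off by default; raw
#'   p-values are the primary output).
#' @param figures Write PNG figures?
#' @return A list with the analysis table, QC report, dropped analytes,
#'   `associations` (`scfa_assoc`) and `didiff` (`scfa_didiff`).
#' @export
run_scfa_pipeline <- function(data, out_dir = NULL, seed = 1, n_perm = 9999,
                              min_detect = 2, unadjusted = FALSE,
                              clr = FALSE, bh = FALSE, figures = TRUE) {
  cohort <- if (is.character(data)) read_cohort(data) else data
  stopifnot(inherits(cohort, "scfa_cohort"))
  input_md5 <- if (is.character(data)) {
    files <- file.path(data, c("samples.csv", "mothers.csv", "loq.csv"))
    as.list(stats::setNames(tools::md5sum(files[file.exists(files)]),
                            basename(files[file.exists(files)])))
  } else NULL

  cohort <- apply_qc(cohort)
  cohort <- prevalence_filter(cohort, min_detected_samples = min_detect)
  analysis <- impute_half_loq(cohort)
  analysis <- add_profile_metrics(analysis)
  assoc <- scfa_associations(analysis, unadjusted = unadjusted, clr = clr,
                             bh = bh)
  didiff <- scfa_didiff(analysis, n_perm = n_perm, seed = seed, bh = bh)

  out <- list(analysis = analysis, qc_report = cohort$qc_report,
              dropped_analytes = cohort$dropped_analytes,
              associations = assoc, didiff = didiff)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cohort$qc_report, file.path(out_dir, "qc_report.csv"),
                     row.names = FALSE)
    utils::write.csv(assoc$results, file.path(out_dir, "associations.csv"),
                     row.names = FALSE)
    dd <- didiff$results
    dd$seed <- seed
    utils::write.csv(dd, file.path(out_dir, "didiff.csv"), row.names = FALSE)
    if (figures) .write_figures(out, out_dir)
    manifest <- list(
      tool = "scfapanel",
      version = as.character(utils::packageVersion("scfapanel")),
      stage = "analyze", seed = as.integer(seed), n_perm = as.integer(n_perm),
      min_detect = min_detect, unadjusted = unadjusted, clr = clr, bh = bh,
      input_md5 = input_md5,
      qc = cohort$qc_report,
      dropped_analytes = cohort$dropped_analytes,
      n_analysis_rows = nrow(analysis),
      n_analytes = length(attr(analysis, "analytes")),
      n_association_models = nrow(assoc$results),
      n_didiff_pairs = nrow(didiff$results)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(out)
}

.write_figures <- function(out, out_dir) {
  a <- attr(out$analysis, "analytes")
  tps <- attr(out$analysis, "timepoints")
  png1 <- function(file, w, h, expr) {
    grDevices::png(file.path(out_dir, file), width = w, height = h,
                   res = 110)
    on.exit(grDevices::dev.off())
    force(expr)
  }
  png1("fig_total_shannon.png", 900, 700,
       plot(out$associations, responses = c("total", "shannon"),
            strata = tps))
  png1("fig_analytes.png", 1300, 800,
       plot(out$associations, responses = a, strata = tps))
  png1("fig_change.png", 1300, 500,
       plot(out$associations, responses = a, strata = "change"))
  png1("fig_didiff_heatmap.png", 900, 850, plot(out$didiff))
  invisible(NULL)
}
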