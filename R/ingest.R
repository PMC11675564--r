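#' Remove QC-failed samples from a cohort
#'
#' Drops every sample flagged `qc_pass = FALSE`. Mothers who lose one
#' timepoint are retained with their remaining timepoint; per-timepoint
#' retained/excluded counts are attached as `$qc_report`. Idempotent.
#'
#' @param cohort An `scfa_cohort`.
#' @return The filtered cohort with a `qc_report` data frame
#'   (`timepoint`, `n_retained`, `n_excluded`).
#' @export
apply_qc <- function(cohort) {
  stopifnot(inherits(cohort, "scfa_cohort"))
  s <- cohort$samples
  report <- data.frame(
    timepoint = cohort$timepoints,
    n_retained = vapply(cohort$timepoints, function(t)
      sum(s$timepoint == t & s$qc_pass), integer(1)),
    n_excluded = vapply(cohort$timepoints, function(t)
      sum(s$timepoint == t & !s$qc_pass), integer(1)),
    row.names = NULL
  )
  cohort$samples <- s[s$qc_pass, , drop = FALSE]
  rownames(cohort$samples) <- NULL
  cohort$qc_report <- report
  cohort
}

#' Drop analytes detected in too few samples
#'
#' An analyte is "detected" in a sample when its concentration is present
#' (not the below-LOQ marker) and at least the analyte's LOQ. Analytes
#' detected in fewer than `min_detected_samples` samples — counted over all
#' rows of the table passed in, both timepoints pooled — are removed. The
#' default threshold of 2 removes any analyte seen in at most one sample.
#'
#' @param cohort An `scfa_cohort` (normally after [apply_qc()]).
#' @param loq Named LOQ vector; defaults to the cohort's own.
#' @param min_detected_samples Minimum detection count to retain an analyte.
#' @return The reduced cohort; dropped analytes are recorded in
#'   `$dropped_analytes`.
#' @export
prevalence_filter <- function(cohort, loq = cohort$loq,
                              min_detected_samples = 2) {
  stopifnot(inherits(cohort, "scfa_cohort"), min_detected_samples >= 1)
  .check_loq(cohort$analytes, loq)
  counts <- vapply(cohort$analytes, function(a) {
    x <- cohort$samples[[a]]
    sum(!is.na(x) & x >= loq[[a]])
  }, integer(1))
  drop <- names(counts)[counts < min_detected_samples]
  keep <- setdiff(cohort$analytes, drop)
  if (length(keep) == 0)
    stop("prevalence filter removed every analyte; nothing left to analyze")
  cohort$samples <- cohort$samples[, setdiff(names(cohort$samples), drop),
                                   drop = FALSE]
  cohort$analytes <- keep
  cohort$loq <- loq[keep]
  cohort$dropped_analytes <- c(cohort$dropped_analytes, drop)
  cohort$detection_counts <- counts
  cohort
}

#' Impute below-LOQ concentrations at half the LOQ
#'
#' Replaces every missing (below-LOQ) concentration with half the analyte's
#' limit of quantitation, leaving observed values untouched, and returns a
#' fully numeric analysis table: one row per retained sample with analyte
#' columns, the mother's group label and covariates. Samples flagged as QC
#' failures are excluded (with a warning if any were still present).
#'
#' @param cohort An `scfa_cohort`, normally after [apply_qc()] and
#'   [prevalence_filter()].
#' @param loq Named LOQ vector covering every analyte in the cohort.
#' @return A data frame of class `scfa_analysis` with attributes
#'   `analytes`, `timepoints`, `loq` and `n_imputed`.
#' @export
impute_half_loq <- function(cohort, loq = cohort$loq) {
  stopifnot(inherits(cohort, "scfa_cohort"))
  .check_loq(cohort$analytes, loq)
  s <- cohort$samples
  if (any(!s$qc_pass)) {
    warning("dropping ", sum(!s$qc_pass), " QC-failed sample(s); ",
            "run apply_qc() first to record them")
    s <- s[s$qc_pass, , drop = FALSE]
  }
  n_imputed <- 0L
  for (a in cohort$analytes) {
    miss <- is.na(s[[a]])
    s[[a]][miss] <- loq[[a]] / 2
    n_imputed <- n_imputed + sum(miss)
  }
  tab <- merge(s, cohort$mothers, by = "mother_id", sort = FALSE)
  tab <- tab[order(match(tab$timepoint, cohort$timepoints), tab$mother_id), ]
  rownames(tab) <- NULL
  structure(tab, analytes = cohort$analytes, timepoints = cohort$timepoints,
            loq = loq[cohort$analytes], n_imputed = n_imputed,
            class = c("scfa_analysis", "data.frame"))
}

.check_loq <- function(analytes, loq) {
  missing <- setdiff(analytes, names(loq))
  if (length(missing))
    stop("no LOQ entry for analyte(s): ", paste(missing, collapse = ", "))
  if (any(loq[analytes] <= 0)) stop("all LOQ values must be > 0")
  invisible(TRUE)
}

#' Analyte names of an analysis table or cohort
#' @param x An `scfa_analysis` or `scfa_cohort`.
#' @return Character vector of analyte names.
#' @export
analytes <- function(x) {
  if (inherits(x, "scfa_cohort")) x$analytes else attr(x, "analytes")
}

#' Timepoint labels of an analysis table or cohort
#' @param x An `scfa_analysis` or `scfa_cohort`.
#' @return Character vector of timepoint labels.
#' @export
timepoints <- function(x) {
  if (inherits(x, "scfa_cohort")) x$timepoints else attr(x, "timepoints")
}
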