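#' Default SCFA panel used by the cohort simulator
#'
#' Seven short-chain fatty acids commonly assayed in maternal plasma. The
#' last, hexanoate, is typically near or below the assay limit of
#' quantitation (LOQ) and is the default "rare" analyte.
#'
#' @return Character vector of analyte names.
#' @export
default_analytes <- function() {
  c("acetate", "propionate", "butyrate", "valerate",
    "isobutyrate", "isovalerate", "hexanoate")
}

# Typical plasma concentrations (uM) used to seed default log-means.
# Acetate dominates the panel by an order of magnitude; the minor acids sit
# around or below 1 uM.
.default_panel_conc <- c(
  acetate = 40, propionate = 4.5, butyrate = 1.5, valerate = 0.35,
  isobutyrate = 1.2, isovalerate = 1.3, hexanoate = 0.5
)

.groups <- c("control", "case")

#' Default covariate distribution parameters
#'
#' Baseline socio-demographic distributions for the simulated mothers:
#' normal BMI with group-specific means, age uniform over the cohort range,
#' ordered categorical household income (5 levels) and education (3 levels),
#' and a Bernoulli first-fetus sex.
#'
#' @return Named list of per-covariate parameter lists.
#' @export
default_covariate_params <- function() {
  list(
    bmi = list(mean = c(control = 25.68, case = 25.93),
               sd = c(control = 5.77, case = 5.75)),
    age = list(min = 19.51, max = 38.39),
    income = list(
      levels = c("lt20k", "20to39k", "40to74k", "75to99k", "ge100k"),
      probs = c(4, 29, 15, 15, 64) / 127
    ),
    fetus_sex = list(levels = c("female", "male"), p_male = 68 / 127),
    education = list(
      levels = c("less_than_hs", "hs_grad", "more_than_hs"),
      probs = c(2, 11, 114) / 127
    )
  )
}

#' Simulation configuration for a two-timepoint SCFA cohort
#'
#' Builds and validates the parameter set that drives
#' [simulate_scfa_cohort()]. Defaults emulate a pregnancy case-control
#' design: 63 control and 64 case mothers sampled at gestational weeks 20
#' and 28 (254 samples), log-normal analyte concentrations with LOQ
#' censoring, three week-20 samples flagged as QC failures, and a rare
#' analyte (hexanoate) detected in exactly one sample.
#'
#' @param n_case,n_ctrl Numbers of case and control mothers.
#' @param analytes Ordered character vector of analyte names.
#' @param timepoints Ordered character vector of gestational-week labels.
#' @param log_mean Numeric array `[analyte, group, timepoint]` of
#'   log-concentration means (groups ordered control, case). Defaults to a
#'   plausible plasma panel with no group or time effect.
#' @param log_sd Named numeric vector of per-analyte log-scale SDs.
#' @param within_subject_rho Per-analyte correlation of a mother's
#'   log-concentrations across the two timepoints (recycled if scalar).
#' @param analyte_corr Between-analyte correlation matrices of
#'   log-concentrations: a single matrix (recycled) or a nested list
#'   `analyte_corr[[group]][[timepoint]]`. Each must be symmetric with unit
#'   diagonal and positive semi-definite.
#' @param loq Named positive vector of per-analyte limits of quantitation in
#'   concentration units; values generated below the LOQ are censored.
#' @param n_low_quality Named integer vector per timepoint: number of
#'   samples to flag as QC failures (default 3 at the first timepoint).
#' @param rare_analyte Optional analyte forced to be detected (above LOQ) in
#'   exactly one sample cohort-wide; `NULL` disables.
#' @param covariate_params See [default_covariate_params()].
#'
#' @return An object of class `scfa_sim_config`.
#' @seealso [simulate_scfa_cohort()], [null_config()], [set_mean_shift()],
#'   [set_pair_correlation()]
#' @export
scfa_sim_config <- function(n_case = 64, n_ctrl = 63,
                            analytes = default_analytes(),
                            timepoints = c("20w", "28w"),
                            log_mean = NULL,
                            log_sd = NULL,
                            within_subject_rho = 0.5,
                            analyte_corr = NULL,
                            loq = NULL,
                            n_low_quality = NULL,
                            rare_analyte = if ("hexanoate" %in% analytes) "hexanoate" else NULL,
                            covariate_params = default_covariate_params()) {
  k <- length(analytes)
  if (is.null(log_sd)) log_sd <- rep(0.45, k)
  log_sd <- rep_len(log_sd, k)
  names(log_sd) <- analytes

  if (is.null(log_mean)) {
    base <- ifelse(analytes %in% names(.default_panel_conc),
                   log(.default_panel_conc[analytes]), 0)
    log_mean <- array(rep(base, times = 2 * length(timepoints)),
                      dim = c(k, 2, length(timepoints)),
                      dimnames = list(analytes, .groups, timepoints))
  } else {
    log_mean <- .coerce_log_mean(log_mean, analytes, timepoints)
  }

  within_subject_rho <- rep_len(within_subject_rho, k)
  names(within_subject_rho) <- analytes

  if (is.null(analyte_corr)) {
    analyte_corr <- matrix(0.35, k, k, dimnames = list(analytes, analytes))
    diag(analyte_corr) <- 1
  }
  analyte_corr <- .coerce_analyte_corr(analyte_corr, .groups, timepoints)

  if (is.null(loq)) {
    # ~2% of draws fall below a 2-SD LOQ; gives the imputation rule work to do
    loq <- exp(log_mean[, "control", 1] - 2 * log_sd)
  }
  loq <- rep_len(loq, k)
  names(loq) <- analytes

  if (is.null(n_low_quality)) {
    n_low_quality <- stats::setNames(c(3L, rep(0L, length(timepoints) - 1L)),
                                     timepoints)
  }

  cfg <- structure(list(
    n_case = as.integer(n_case), n_ctrl = as.integer(n_ctrl),
    analytes = analytes, timepoints = timepoints,
    log_mean = log_mean, log_sd = log_sd,
    within_subject_rho = within_subject_rho,
    analyte_corr = analyte_corr, loq = loq,
    n_low_quality = n_low_quality, rare_analyte = rare_analyte,
    covariate_params = covariate_params
  ), class = "scfa_sim_config")
  validate_sim_config(cfg)
  cfg
}

.coerce_log_mean <- function(log_mean, analytes, timepoints) {
  k <- length(analytes); tn <- length(timepoints)
  if (is.null(dim(log_mean))) {
    if (!is.null(names(log_mean))) log_mean <- log_mean[analytes]
    log_mean <- array(rep(rep_len(unname(log_mean), k), times = 2 * tn),
                      dim = c(k, 2, tn))
  }
  stopifnot(all(dim(log_mean) == c(k, 2, tn)))
  dimnames(log_mean) <- list(analytes, .groups, timepoints)
  log_mean
}

.coerce_analyte_corr <- function(analyte_corr, groups, timepoints) {
  if (is.matrix(analyte_corr)) {
    m <- analyte_corr
    analyte_corr <- lapply(groups, function(g) {
      stats::setNames(lapply(timepoints, function(t) m), timepoints)
    })
    names(analyte_corr) <- groups
  }
  analyte_corr
}

#' Validate a simulation configuration
#'
#' Checks sample counts, correlation-matrix symmetry, unit diagonals and
#' positive semi-definiteness, SD/LOQ positivity, and that categorical
#' probability vectors sum to one (tolerance 1e-9). Called by
#' [scfa_sim_config()] and again by [simulate_scfa_cohort()].
#'
#' @param config An `scfa_sim_config`.
#' @return `config`, invisibly; errors describe the offending field.
#' @export
validate_sim_config <- function(config) {
  with(config, {
    if (n_case < 0 || n_ctrl < 0 || n_case + n_ctrl < 1)
      stop("need n_case >= 0, n_ctrl >= 0 and at least one mother")
    if (any(log_sd <= 0)) stop("all log_sd must be > 0")
    if (any(loq <= 0)) stop("all loq must be > 0")
    if (any(abs(within_subject_rho) > 1))
      stop("|within_subject_rho| must be <= 1")
    for (g in names(analyte_corr)) for (t in names(analyte_corr[[g]])) {
      m <- analyte_corr[[g]][[t]]
      lab <- sprintf("analyte_corr[%s, %s]", g, t)
      if (!isTRUE(all.equal(m, t(m), tolerance = 1e-12)))
        stop(lab, " is not symmetric")
      if (max(abs(diag(m) - 1)) > 1e-12)
        stop(lab, " does not have a unit diagonal")
      ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8)
        stop(lab, " is not positive semi-definite")
    }
    if (!is.null(rare_analyte) && !rare_analyte %in% analytes)
      stop("rare_analyte '", rare_analyte, "' is not in the analyte list")
    if (any(n_low_quality < 0)) stop("n_low_quality must be non-negative")
    for (nm in c("income", "education")) {
      p <- covariate_params[[nm]]$probs
      if (abs(sum(p) - 1) > 1e-9)
        stop(nm, " probabilities must sum to 1")
    }
  })
  invisible(config)
}

#' Remove all group effects from a configuration
#'
#' Returns a copy of `config` in which the case group's log-means and
#' analyte correlation matrices are replaced by the control group's at every
#' timepoint, so cases and controls are drawn from identical distributions.
#' Used as the null generator for type-I-error studies. Idempotent.
#'
#' @param config An `scfa_sim_config`.
#' @return An `scfa_sim_config` with no case-control effect.
#' @export
null_config <- function(config) {
  validate_sim_config(config)
  config$log_mean[, "case", ] <- config$log_mean[, "control", ]
  config$analyte_corr[["case"]] <- config$analyte_corr[["control"]]
  config
}

#' Inject a case-control mean shift
#'
#' Adds `shift` to the case group's log-mean for one analyte at one
#' timepoint (control unchanged). `shift` is on the log scale; passing
#' `config$log_sd[analyte]` injects a one-SD effect.
#'
#' @param config An `scfa_sim_config`.
#' @param analyte,timepoint Which cell to shift.
#' @param shift Additive shift of the case log-mean.
#' @return The modified configuration.
#' @export
set_mean_shift <- function(config, analyte, timepoint, shift) {
  stopifnot(analyte %in% config$analytes, timepoint %in% config$timepoints)
  config$log_mean[analyte, "case", timepoint] <-
    config$log_mean[analyte, "case", timepoint] + shift
  config
}

#' Set the correlation of one analyte pair
#'
#' Overwrites a single entry (symmetrically) of the between-analyte
#' correlation matrix for the given group and timepoint. Used to inject
#' group- or time-specific correlation dynamics; validation (including
#' positive semi-definiteness) is re-run on the result.
#'
#' @param config An `scfa_sim_config`.
#' @param analyte1,analyte2 The pair.
#' @param group `"case"` or `"control"`.
#' @param timepoint Timepoint label.
#' @param r New correlation in `[-1, 1]`.
#' @return The modified configuration.
#' @export
set_pair_correlation <- function(config, analyte1, analyte2, group, timepoint, r) {
  stopifnot(analyte1 %in% config$analytes, analyte2 %in% config$analytes,
            group %in% .groups, timepoint %in% config$timepoints,
            abs(r) <= 1)
  m <- config$analyte_corr[[group]][[timepoint]]
  m[analyte1, analyte2] <- r
  m[analyte2, analyte1] <- r
  config$analyte_corr[[group]][[timepoint]] <- m
  validate_sim_config(config)
  config
}

#' @export
print.scfa_sim_config <- function(x, ...) {
  cat("SCFA cohort simulation configuration\n")
  cat(sprintf("  mothers: %d control + %d case\n", x$n_ctrl, x$n_case))
  cat(sprintf("  timepoints: %s\n", paste(x$timepoints, collapse = ", ")))
  cat(sprintf("  analytes (%d): %s\n", length(x$analytes),
              paste(x$analytes, collapse = ", ")))
  if (!is.null(x$rare_analyte))
    cat(sprintf("  rare analyte: %s (detected in one sample)\n", x$rare_analyte))
  cat(sprintf("  QC failures: %s\n",
              paste(sprintf("%s=%d", names(x$n_low_quality), x$n_low_quality),
                    collapse = ", ")))
  invisible(x)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Keys mirror the arguments of [scfa_sim_config()]; absent keys take the
#' defaults. `log_mean` may be given as a single named vector (applied to
#' every group and timepoint) and `analyte_corr` as a single matrix.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `scfa_sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- names(formals(scfa_sim_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$analyte_corr)) raw$analyte_corr <- as.matrix(raw$analyte_corr)
  if (!is.null(raw$log_mean) && !is.null(names(raw$log_mean)))
    raw$log_mean <- unlist(raw$log_mean)
  do.call(scfa_sim_config, raw)
}
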