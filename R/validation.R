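#' Type-I-error study of the association battery
#'
#' Simulates `n_rep` cohorts from a null configuration (no group effect of
#' any kind), runs the covariate-adjusted association battery on each, and
#' tabulates per-response rejection rates at level `alpha`. Under the null
#' the two-sided p-values are uniform, so rates should sit near `alpha` up
#' to binomial Monte-Carlo error.
#'
#' @param n_rep Number of simulated cohorts.
#' @param alpha Nominal level.
#' @param seed Master seed; replicate `i` uses `seed + i`.
#' @param config Generator configuration; forced through [null_config()].
#' @return A list: `rates` (data frame response, stratum, rate), `pooled`
#'   (overall rejection rate), and `p_values` (replicate x model matrix).
#' @export
type1_assoc_study <- function(n_rep = 200, alpha = 0.05, seed = 1000,
                              config = scfa_sim_config()) {
  config <- null_config(config)
  pmat <- NULL
  labels <- NULL
  for (i in seq_len(n_rep)) {
    co <- simulate_scfa_cohort(config, seed = seed + i)
    co <- prevalence_filter(apply_qc(co))
    an <- add_profile_metrics(impute_half_loq(co))
    res <- scfa_associations(an)$results
    if (is.null(pmat)) {
      labels <- paste0(res$response, "@", res$stratum)
      pmat <- matrix(NA_real_, n_rep, nrow(res), dimnames = list(NULL, labels))
    }
    pmat[i, ] <- res$p_value
  }
  rej <- colMeans(pmat < alpha)
  rates <- data.frame(
    response = sub("@.*$", "", labels), stratum = sub("^.*@", "", labels),
    rate = unname(rej), stringsAsFactors = FALSE)
  list(rates = rates, pooled = mean(pmat < alpha), p_values = pmat)
}

#' Type-I-error study of the correlation permutation test
#'
#' Simulates `n_rep` null cohorts (identical correlation dynamics in both
#' groups) and runs the difference-in-differences permutation test for one
#' analyte pair on each, returning the permutation p-values. Their
#' distribution should be valid: `P(p <= a) <= a` up to Monte-Carlo error.
#'
#' @param n_rep Number of simulated cohorts.
#' @param n_perm Permutations per test.
#' @param seed Master seed; replicate `i` uses `seed + i`.
#' @param pair Analyte pair to test.
#' @param config Generator configuration; forced through [null_config()].
#' @return Numeric vector of `n_rep` permutation p-values.
#' @export
type1_didiff_study <- function(n_rep = 300, n_perm = 499, seed = 2000,
                               pair = c("acetate", "propionate"),
                               config = scfa_sim_config()) {
  config <- null_config(config)
  vapply(seq_len(n_rep), function(i) {
    co <- simulate_scfa_cohort(config, seed = seed + i)
    co <- prevalence_filter(apply_qc(co))
    an <- impute_half_loq(co)
    didiff_test(an, pair, n_perm = n_perm, seed = seed + n_rep + i)$p_value
  }, numeric(1))
}

#' Recovery study for an injected case-control mean shift
#'
#' Adds a `shift_sd`-SD shift (on the log scale) to the case group's mean
#' for one analyte at one timepoint, simulates large cohorts, fits the
#' adjusted association model, and compares the mean estimate to the
#' analytic raw-scale truth
#' `exp(mu + sigma^2/2) * (exp(shift_sd * sigma) - 1)` of the log-normal
#' group-mean difference.
#'
#' @param n_rep Number of replicates.
#' @param n_per_group Mothers per group in each replicate.
#' @param analyte,timepoint Where the shift is injected.
#' @param shift_sd Shift size in units of the analyte's log-scale SD.
#' @param seed Master seed.
#' @return A list: `truth`, `mean_estimate`, `ratio`
#'   (`mean_estimate / truth`) and the per-replicate estimates.
#' @export
mean_shift_recovery_study <- function(n_rep = 100, n_per_group = 1000,
                                      analyte = "acetate",
                                      timepoint = "28w", shift_sd = 1,
                                      seed = 3000) {
  base <- scfa_sim_config(n_case = n_per_group, n_ctrl = n_per_group)
  sigma <- base$log_sd[[analyte]]
  cfg <- set_mean_shift(base, analyte, timepoint, shift_sd * sigma)
  mu <- base$log_mean[analyte, "control", timepoint]
  truth <- exp(mu + sigma^2 / 2) * (exp(shift_sd * sigma) - 1)
  est <- vapply(seq_len(n_rep), function(i) {
    co <- simulate_scfa_cohort(cfg, seed = seed + i)
    co <- prevalence_filter(apply_qc(co))
    an <- impute_half_loq(co)
    fit_association(build_design(an, analyte, timepoint))$estimate
  }, numeric(1))
  list(truth = truth, mean_estimate = mean(est),
       ratio = mean(est) / truth, estimates = est)
}

#' Power study for an injected correlation-dynamics difference
#'
#' Injects opposite-direction temporal changes of one pair's correlation
#' (it rises by `delta` from the first to the second timepoint in controls
#' and falls by `delta` in cases, a difference-in-differences of
#' `-2 * delta`), simulates cohorts, runs the full pairwise screen, and
#' reports how often the injected pair attains the smallest permutation
#' p-value of all pairs (ties counted as attaining it).
#'
#' @param n_rep Number of replicates.
#' @param n_per_group Mothers per group.
#' @param pair The analyte pair carrying the injected dynamics.
#' @param delta Correlation change magnitude per group.
#' @param n_perm Permutations per screen.
#' @param seed Master seed.
#' @return A list: `hit_rate` plus the per-replicate p-value matrix.
#' @export
didiff_power_study <- function(n_rep = 50, n_per_group = 750,
                               pair = c("isovalerate", "isobutyrate"),
                               delta = 0.2, n_perm = 199, seed = 4000) {
  cfg <- scfa_sim_config(n_case = n_per_group, n_ctrl = n_per_group)
  r0 <- cfg$analyte_corr[["control"]][[cfg$timepoints[1]]][pair[1], pair[2]]
  tp2 <- cfg$timepoints[2]
  cfg <- set_pair_correlation(cfg, pair[1], pair[2], "control", tp2,
                              r0 + delta)
  cfg <- set_pair_correlation(cfg, pair[1], pair[2], "case", tp2,
                              r0 - delta)
  hits <- logical(n_rep)
  pmats <- list()
  for (i in seq_len(n_rep)) {
    co <- simulate_scfa_cohort(cfg, seed = seed + i)
    co <- prevalence_filter(apply_qc(co))
    an <- impute_half_loq(co)
    res <- scfa_didiff(an, n_perm = n_perm, seed = seed + n_rep + i)$results
    target <- (res$analyte_j == pair[1] & res$analyte_k == pair[2]) |
      (res$analyte_j == pair[2] & res$analyte_k == pair[1])
    hits[i] <- res$p_value[target] <= min(res$p_value)
    pmats[[i]] <- res$p_value
  }
  list(hit_rate = mean(hits), hits = hits,
       p_values = do.call(rbind, pmats))
}
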