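#' Simulate a two-timepoint SCFA cohort
#'
#' Draws a full synthetic cohort under `config`: per mother, log-scale
#' concentrations of all analytes at all timepoints are multivariate normal
#' with the configured between-analyte correlation matrix at each
#' (group, timepoint) and the configured per-analyte within-subject
#' correlation across timepoints; concentrations are the exponentials.
#' Values below an analyte's limit of quantitation are censored to the
#' missing marker (`NA`), `n_low_quality[t]` randomly chosen samples at
#' timepoint `t` are flagged as QC failures, and the optional rare analyte
#' is forced to be detected in exactly one sample cohort-wide. Identical
#' `(config, seed)` pairs yield identical cohorts.
#'
#' The joint log-scale covariance for a group couples the two timepoints
#' through `sqrt(rho_j * rho_k) * sd_j * sd_k * Rbar[j, k]`, where `Rbar`
#' averages the group's two between-analyte correlation matrices; when the
#' two timepoints share a matrix this is an exact Kronecker structure and
#' within-timepoint correlations equal the configured matrices. The
#' assembled covariance is eigen-checked and a configuration error is
#' raised if it is not positive semi-definite.
#'
#' @param config An [scfa_sim_config()].
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class `scfa_cohort`: a list with `samples` (one row
#'   per mother and timepoint, one column per analyte, `NA` marking
#'   below-LOQ values, plus `qc_pass`), `mothers` (group label and
#'   covariates), `loq`, `analytes`, `timepoints`.
#' @export
simulate_scfa_cohort <- function(config = scfa_sim_config(), seed = 1) {
  validate_sim_config(config)
  tps <- config$timepoints
  n <- config$n_ctrl + config$n_case
  for (t in names(config$n_low_quality)) {
    if (config$n_low_quality[[t]] > n)
      stop("n_low_quality[", t, "] exceeds the ", n, " samples at that timepoint")
  }
  set.seed(as.integer(seed))

  mothers <- .draw_mothers(config)
  samples <- .draw_samples(config, mothers)

  # censor below-LOQ values to the missing marker
  for (a in config$analytes) {
    samples[[a]][samples[[a]] < config$loq[[a]]] <- NA_real_
  }

  if (!is.null(config$rare_analyte)) {
    a <- config$rare_analyte
    keep <- sample.int(nrow(samples), 1L)
    v <- samples[[a]][keep]
    samples[[a]] <- NA_real_
    samples[[a]][keep] <- max(v, 1.5 * config$loq[[a]], na.rm = TRUE)
  }

  samples$qc_pass <- TRUE
  for (t in tps) {
    n_bad <- config$n_low_quality[[t]]
    if (is.null(n_bad) || n_bad == 0) next
    idx <- which(samples$timepoint == t)
    samples$qc_pass[sample(idx, n_bad)] <- FALSE
  }

  structure(list(samples = samples, mothers = mothers,
                 loq = config$loq, analytes = config$analytes,
                 timepoints = tps, config = config, seed = as.integer(seed)),
            class = "scfa_cohort")
}

.draw_mothers <- function(config) {
  n <- config$n_ctrl + config$n_case
  cp <- config$covariate_params
  group <- factor(rep(.groups, c(config$n_ctrl, config$n_case)),
                  levels = .groups)
  bmi <- stats::rnorm(n, cp$bmi$mean[as.character(group)],
                      cp$bmi$sd[as.character(group)])
  age <- stats::runif(n, cp$age$min, cp$age$max)
  income <- factor(sample(cp$income$levels, n, replace = TRUE,
                          prob = cp$income$probs),
                   levels = cp$income$levels)
  fetus_sex <- factor(ifelse(stats::runif(n) < cp$fetus_sex$p_male,
                             "male", "female"),
                      levels = cp$fetus_sex$levels)
  education <- factor(sample(cp$education$levels, n, replace = TRUE,
                             prob = cp$education$probs),
                      levels = cp$education$levels)
  data.frame(mother_id = sprintf("M%04d", seq_len(n)), group = group,
             bmi = bmi, age = age, income = income,
             fetus_sex = fetus_sex, education = education,
             stringsAsFactors = FALSE)
}

# joint covariance of (t1 analytes, t2 analytes, ...) log-concentrations
.joint_covariance <- function(config, group) {
  k <- length(config$analytes)
  tps <- config$timepoints
  tn <- length(tps)
  sd <- config$log_sd
  rho <- config$within_subject_rho
  rmats <- config$analyte_corr[[group]]
  sigma <- matrix(0, k * tn, k * tn)
  for (i in seq_len(tn)) for (j in seq_len(tn)) {
    ri <- (i - 1) * k + seq_len(k)
    rj <- (j - 1) * k + seq_len(k)
    if (i == j) {
      block <- diag(sd) %*% rmats[[tps[i]]] %*% diag(sd)
    } else {
      if (any(rho < 0))
        stop("negative within_subject_rho is not supported by the joint ",
             "covariance construction")
      rbar <- (rmats[[tps[i]]] + rmats[[tps[j]]]) / 2
      block <- outer(sqrt(rho) * sd, sqrt(rho) * sd) * rbar
    }
    sigma[ri, rj] <- block
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("joint log-scale covariance for group '", group,
         "' is not positive semi-definite; weaken within_subject_rho or the ",
         "analyte correlations")
  sigma
}

.draw_samples <- function(config, mothers) {
  k <- length(config$analytes)
  tps <- config$timepoints
  out <- list()
  for (g in .groups) {
    ids <- mothers$mother_id[mothers$group == g]
    n_g <- length(ids)
    if (n_g == 0) next
    mu <- as.vector(config$log_mean[, g, ])
    sigma <- .joint_covariance(config, g)
    z <- MASS::mvrnorm(n_g, mu = mu, Sigma = sigma)
    z <- matrix(z, nrow = n_g)  # keep matrix shape when n_g == 1
    for (i in seq_along(tps)) {
      conc <- exp(z[, (i - 1) * k + seq_len(k), drop = FALSE])
      colnames(conc) <- config$analytes
      out[[length(out) + 1L]] <- data.frame(
        mother_id = ids, timepoint = tps[i], conc,
        stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  samples <- do.call(rbind, out)
  samples <- samples[order(match(samples$timepoint, tps), samples$mother_id), ]
  rownames(samples) <- NULL
  samples
}

#' @export
print.scfa_cohort <- function(x, ...) {
  cat("SCFA cohort\n")
  tab <- table(x$mothers$group)
  cat(sprintf("  mothers: %d (%s)\n", nrow(x$mothers),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  samples: %d across timepoints %s\n", nrow(x$samples),
              paste(x$timepoints, collapse = ", ")))
  cat(sprintf("  analytes (%d): %s\n", length(x$analytes),
              paste(x$analytes, collapse = ", ")))
  n_missing <- sum(is.na(as.matrix(x$samples[x$analytes])))
  cat(sprintf("  below-LOQ/missing cells: %d; QC failures: %d\n",
              n_missing, sum(!x$samples$qc_pass)))
  if (!is.null(x$dropped_analytes))
    cat("  dropped analytes:", paste(x$dropped_analytes, collapse = ", "), "\n")
  invisible(x)
}
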