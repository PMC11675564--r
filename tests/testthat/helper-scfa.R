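# Shared fixtures and independent oracles for the test suite.

# A compact simulation config: no rare analyte, no QC failures, and an
# effectively disabled LOQ unless asked for, so tests control censoring.
small_config <- function(n_case = 10, n_ctrl = 10,
                         analytes = c("acetate", "propionate", "butyrate",
                                      "valerate", "isobutyrate", "isovalerate"),
                         loq = 1e-8, n_low_quality = NULL, ...) {
  cfg <- scfa_sim_config(
    n_case = n_case, n_ctrl = n_ctrl, analytes = analytes,
    loq = rep(loq, length(analytes)), rare_analyte = NULL, ...)
  if (is.null(n_low_quality)) {
    cfg$n_low_quality[] <- 0L
  } else {
    cfg$n_low_quality <- n_low_quality
  }
  cfg
}

# Build an scfa_analysis table directly from two concentration matrices
# (mothers x analytes, one per timepoint) and a group vector; covariates are
# held constant so they play no role.
toy_analysis <- function(x1, x2, group,
                         analytes = colnames(x1),
                         tps = c("20w", "28w")) {
  stopifnot(nrow(x1) == nrow(x2), length(group) == nrow(x1))
  n <- nrow(x1)
  ids <- sprintf("M%03d", seq_len(n))
  cp <- default_covariate_params()
  one_tp <- function(x, tp) {
    df <- data.frame(mother_id = ids, timepoint = tp,
                     stringsAsFactors = FALSE)
    for (j in seq_along(analytes)) df[[analytes[j]]] <- x[, j]
    df$qc_pass <- TRUE
    df$group <- factor(group, levels = c("control", "case"))
    df$bmi <- 25
    df$age <- 30
    df$income <- factor("ge100k", levels = cp$income$levels)
    df$fetus_sex <- factor("female", levels = cp$fetus_sex$levels)
    df$education <- factor("more_than_hs", levels = cp$education$levels)
    df
  }
  out <- rbind(one_tp(x1, tps[1]), one_tp(x2, tps[2]))
  structure(out, analytes = analytes, timepoints = tps,
            loq = stats::setNames(rep(1e-8, length(analytes)), analytes),
            n_imputed = 0L, class = c("scfa_analysis", "data.frame"))
}

# Independent ordinary-least-squares oracle: solves the normal equations
# directly and derives the t-test of one coefficient from first principles.
ne_oracle <- function(X, y, col = "groupcase") {
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  rdf <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / rdf
  se <- sqrt(diag(xtx_inv) * sigma2)
  est <- unname(beta[col, 1])
  se_col <- unname(se[col])
  tval <- est / se_col
  list(estimate = est, se = se_col,
       p_value = 2 * stats::pt(abs(tval), rdf, lower.tail = FALSE))
}

# Exhaustive permutation oracle: exact two-sided p of the correlation
# difference-in-differences over every assignment of case labels.
exact_didiff_p <- function(analysis, pair) {
  a <- attr(analysis, "analytes")
  tps <- attr(analysis, "timepoints")
  t1 <- analysis[analysis$timepoint == tps[1], ]
  t2 <- analysis[analysis$timepoint == tps[2], ]
  t2 <- t2[match(t1$mother_id, t2$mother_id), ]
  x1 <- as.matrix(t1[pair]); x2 <- as.matrix(t2[pair])
  n <- nrow(x1)
  n_case <- sum(t1$group == "case")
  stat <- function(case_idx) {
    is_case <- seq_len(n) %in% case_idx
    d <- function(idx) stats::cor(x2[idx, 1], x2[idx, 2]) -
      stats::cor(x1[idx, 1], x1[idx, 2])
    d(which(is_case)) - d(which(!is_case))
  }
  obs <- stat(which(t1$group == "case"))
  all_d <- apply(utils::combn(n, n_case), 2, stat)
  list(obs = obs, p_exact = mean(abs(all_d) >= abs(obs) - 1e-12),
       n_assignments = ncol(utils::combn(n, n_case)))
}

# Pearson correlation from the covariance definition, written out by hand.
cor_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxy / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
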