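sim_analysis <- function(seed = 1, cfg = scfa_sim_config()) {
  co <- prevalence_filter(apply_qc(simulate_scfa_cohort(cfg, seed = seed)))
  add_profile_metrics(impute_half_loq(co))
}

test_that("fit_association agrees with the normal-equations oracle", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(20:44, 1)
    an <- sim_analysis(seed = i,
                       cfg = small_config(n_case = ceiling(n / 2),
                                          n_ctrl = floor(n / 2)))
    # randomise continuous covariates so each instance is a fresh matrix
    an$bmi <- rnorm(nrow(an), 25, 4)
    an$age <- runif(nrow(an), 20, 40)
    adj <- sample(c(TRUE, FALSE), 1)
    des <- suppressWarnings(build_design(an, "acetate", "20w",
                                         adjusted = adj))
    got <- fit_association(des)
    ora <- ne_oracle(des$X, des$y)
    expect_equal(got$estimate, ora$estimate, tolerance = 1e-10)
    expect_equal(got$se, ora$se, tolerance = 1e-10)
    expect_equal(got$p_value, ora$p_value, tolerance = 1e-10)
  }
})

test_that("a noise-free group effect is recovered exactly", {
  an <- sim_analysis(seed = 2, cfg = small_config(n_case = 8, n_ctrl = 8))
  an$synthetic <- 2 * (an$group == "case")
  des <- build_design(an, "synthetic", "20w", adjusted = FALSE)
  expect_equal(ncol(des$X), 2L)  # intercept + case indicator only
  # lm flags the zero-residual fit; the point estimate is still exact
  got <- suppressWarnings(fit_association(des))
  expect_equal(got$estimate, 2, tolerance = 1e-10)
  expect_lt(got$p_value, 1e-10)
})

test_that("a constant response is flagged degenerate rather than fit", {
  an <- sim_analysis(seed = 3, cfg = small_config(n_case = 6, n_ctrl = 6))
  an$flat <- 1.25
  got <- fit_association(build_design(an, "flat", "20w", adjusted = FALSE))
  expect_equal(got$status, "degenerate")
  expect_equal(got$estimate, 0)
  expect_true(is.na(got$se) && is.na(got$p_value))
})

test_that("swapping case and control labels negates the estimate only", {
  an <- sim_analysis(seed = 4, cfg = small_config(n_case = 15, n_ctrl = 12))
  a <- fit_association(build_design(an, "butyrate", "28w"))
  swapped <- an
  swapped$group <- factor(ifelse(an$group == "case", "control", "case"),
                          levels = levels(an$group))
  b <- fit_association(build_design(swapped, "butyrate", "28w"))
  expect_equal(b$estimate, -a$estimate, tolerance = 1e-10)
  expect_equal(b$p_value, a$p_value, tolerance = 1e-10)
})

test_that("single-level categorical covariates collapse with a warning", {
  an <- sim_analysis(seed = 5, cfg = small_config(n_case = 10, n_ctrl = 10))
  an$income <- factor("ge100k", levels = levels(an$income))
  expect_warning(des <- build_design(an, "acetate", "20w"), "income")
  expect_false(any(grepl("income", colnames(des$X))))
  expect_equal(fit_association(des)$status, "ok")
})

test_that("temporal change subtracts the first timepoint from the second", {
  x1 <- cbind(a = c(1, 2, 4), b = c(10, 10, 10))
  x2 <- cbind(a = c(3, 1, 8), b = c(12, 9, 10))
  an <- toy_analysis(x1, x2, c("control", "case", "case"))
  ch <- temporal_change(an)
  expect_equal(ch$a, c(2, -1, 4))
  expect_equal(ch$b, c(2, -1, 0))
  expect_equal(attr(ch, "n_excluded"), 0L)
  # a mother missing one timepoint drops out and is counted
  an2 <- an[!(an$mother_id == "M002" & an$timepoint == "28w"), ]
  attr(an2, "analytes") <- attr(an, "analytes")
  attr(an2, "timepoints") <- attr(an, "timepoints")
  class(an2) <- class(an)
  ch2 <- temporal_change(an2)
  expect_equal(nrow(ch2), 2L)
  expect_equal(attr(ch2, "n_excluded"), 1L)
})

test_that("the study-design change table keeps mothers with both timepoints", {
  an <- sim_analysis(seed = 6)
  ch <- temporal_change(an)
  expect_equal(nrow(ch), 124L)
  expect_equal(attr(ch, "n_excluded"), 3L)
})

test_that("the battery enumerates the analysis plan", {
  an <- sim_analysis(seed = 7)
  k <- length(analytes(an))
  base <- scfa_associations(an)
  # (total, shannon, K analytes) x 2 timepoints + K temporal changes
  expect_equal(nrow(base$results), 2 * (k + 2) + k)
  expect_true(all(base$results$adjusted))
  expect_true(all(base$results$status == "ok"))
  expect_true(all(base$results$p_value >= 0 & base$results$p_value <= 1))
  full <- scfa_associations(an, unadjusted = TRUE, clr = TRUE, bh = TRUE)
  expect_equal(nrow(full$results), 2 * (2 * (k + 2) + k) + 2 * k)
  expect_true("p_bh" %in% names(full$results))
  expect_true(all(full$results$p_bh >= full$results$p_value - 1e-12))
  # per-timepoint analyte rows alone
  sub <- base$results[base$results$response %in% analytes(an) &
                        base$results$stratum != "change", ]
  expect_equal(nrow(sub), 12L)
})

test_that("adjusted and unadjusted estimates agree when covariates are noise", {
  # covariates are generated independently of group and response, so
  # adjustment should not move the estimate materially
  an <- sim_analysis(seed = 8, cfg = small_config(n_case = 400, n_ctrl = 400))
  res <- scfa_associations(an, unadjusted = TRUE)$results
  for (tp in c("20w", "28w")) {
    adj <- res[res$response == "acetate" & res$stratum == tp & res$adjusted, ]
    una <- res[res$response == "acetate" & res$stratum == tp & !res$adjusted, ]
    expect_lt(abs(adj$estimate - una$estimate), 2 * una$se)
  }
})

test_that("unknown strata and responses are named in errors", {
  an <- sim_analysis(seed = 9, cfg = small_config(n_case = 5, n_ctrl = 5))
  expect_error(build_design(an, "acetate", "32w"), "32w")
  expect_error(build_design(an, "nonexistent", "20w"), "nonexistent")
})
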