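sim_analysis_dd <- function(seed = 1, cfg = scfa_sim_config()) {
  co <- prevalence_filter(apply_qc(simulate_scfa_cohort(cfg, seed = seed)))
  impute_half_loq(co)
}

test_that("the correlation panel matches the covariance-definition oracle", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  x1 <- cbind(a = x, b = y)
  set.seed(21)
  x2 <- cbind(a = rnorm(5, 10), b = rnorm(5, 10))
  # 5 control mothers carry the hand-computed vectors; cases are filler
  xc1 <- cbind(a = rnorm(5, 5), b = rnorm(5, 5))
  xc2 <- cbind(a = rnorm(5, 5), b = rnorm(5, 5))
  an <- toy_analysis(rbind(x1, xc1), rbind(x2, xc2),
                     rep(c("control", "case"), each = 5))
  panel <- correlation_panel(an)
  expect_s3_class(panel, "scfa_corr_panel")
  expect_equal(panel$r$control[["20w"]]["a", "b"], cor_oracle(x, y),
               tolerance = 1e-12)
  for (g in c("control", "case")) for (tp in c("20w", "28w")) {
    m <- panel$r[[g]][[tp]]
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), c(1, 1))
    expect_true(all(abs(m) <= 1 + 1e-12))
  }
})

test_that("perfectly dependent columns give correlation +1 and -1", {
  set.seed(22)
  v <- rnorm(6)
  x1 <- cbind(a = v, b = v, c = -v + 3)
  x2 <- cbind(a = v + 1, b = rnorm(6), c = rnorm(6))
  an <- toy_analysis(rbind(x1, x1 + rnorm(18, sd = 0.1)),
                     rbind(x2, x2 + rnorm(18, sd = 0.1)),
                     rep(c("control", "case"), each = 6))
  panel <- correlation_panel(an)
  expect_equal(panel$r$control[["20w"]]["a", "b"], 1, tolerance = 1e-12)
  expect_equal(panel$r$control[["20w"]]["a", "c"], -1, tolerance = 1e-12)
})

test_that("the didiff statistic is pure arithmetic on the panel", {
  mk <- function(r) matrix(c(1, r, r, 1), 2, dimnames = list(c("a", "b"),
                                                             c("a", "b")))
  panel <- structure(list(
    r = list(control = list("20w" = mk(0.3), "28w" = mk(0.3)),
             case = list("20w" = mk(0.3), "28w" = mk(0.3))),
    n = c(control = 10, case = 10),
    analytes = c("a", "b"), timepoints = c("20w", "28w")),
    class = "scfa_corr_panel")
  expect_equal(didiff_statistic(panel, c("a", "b")), 0)
  panel$r$case[["28w"]] <- mk(1); panel$r$case[["20w"]] <- mk(0)
  panel$r$control[["28w"]] <- mk(0); panel$r$control[["20w"]] <- mk(0)
  expect_equal(didiff_statistic(panel, c("a", "b")), 1)
  expect_equal(didiff_statistic(panel, c("b", "a")), 1)  # pair order
  expect_error(didiff_statistic(panel, c("a", "zz")), "zz")
})

test_that("group-label exchange negates the didiff statistic", {
  an <- sim_analysis_dd(seed = 23)
  panel <- correlation_panel(an)
  swapped <- an
  swapped$group <- factor(ifelse(an$group == "case", "control", "case"),
                          levels = levels(an$group))
  panel2 <- correlation_panel(swapped)
  for (pair in list(c("acetate", "butyrate"), c("valerate", "isovalerate"))) {
    expect_equal(didiff_statistic(panel2, pair),
                 -didiff_statistic(panel, pair), tolerance = 1e-12)
  }
})

test_that("the permutation p-value respects its floor and determinism", {
  # large opposite-direction correlation change: the observed statistic
  # should beat every random relabelling
  cfg <- small_config(n_case = 30, n_ctrl = 30)
  cfg <- set_pair_correlation(cfg, "isovalerate", "isobutyrate",
                              "control", "28w", 0.9)
  cfg <- set_pair_correlation(cfg, "isovalerate", "isobutyrate",
                              "case", "28w", -0.4)
  an <- sim_analysis_dd(seed = 24, cfg = cfg)
  res <- didiff_test(an, c("isovalerate", "isobutyrate"),
                     n_perm = 999, seed = 31)
  expect_equal(res$p_value, 1 / 1000)
  res2 <- didiff_test(an, c("isovalerate", "isobutyrate"),
                      n_perm = 999, seed = 31)
  expect_identical(res, res2)
  res3 <- didiff_test(an, c("isovalerate", "isobutyrate"),
                      n_perm = 999, seed = 32)
  expect_equal(res3$didiff, res$didiff)  # statistic is permutation-free
})

test_that("Monte-Carlo permutation agrees with exhaustive enumeration", {
  cfg <- small_config(n_case = 4, n_ctrl = 4)
  an <- sim_analysis_dd(seed = 25, cfg = cfg)
  pair <- c("acetate", "propionate")
  ora <- exact_didiff_p(an, pair)
  expect_equal(ora$n_assignments, 70L)
  n_perm <- 50000
  res <- didiff_test(an, pair, n_perm = n_perm, seed = 33)
  expect_equal(res$didiff, ora$obs, tolerance = 1e-12)
  mc_se <- sqrt(ora$p_exact * (1 - ora$p_exact) / n_perm)
  expect_lt(abs(res$p_value - ora$p_exact), 3 * mc_se + 2 / (n_perm + 1))
})

test_that("the full screen covers every pair deterministically", {
  an <- sim_analysis_dd(seed = 26)
  scr <- scfa_didiff(an, n_perm = 99, seed = 7)
  expect_equal(nrow(scr$results), choose(6, 2))
  expect_true(all(scr$results$p_value >= 1 / 100 &
                    scr$results$p_value <= 1))
  expect_true(all(abs(scr$results$delta_case) <= 2))
  expect_true(all(abs(scr$results$didiff) <= 4))
  scr2 <- scfa_didiff(an, n_perm = 99, seed = 7)
  expect_identical(scr$results, scr2$results)
  # screen and single-pair test agree on the statistic
  one <- didiff_test(an, c("acetate", "butyrate"), n_perm = 9, seed = 1)
  row <- scr$results[scr$results$analyte_j == "acetate" &
                       scr$results$analyte_k == "butyrate", ]
  expect_equal(one$didiff, row$didiff, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected with informative errors", {
  cfg <- small_config(n_case = 2, n_ctrl = 5)
  an <- sim_analysis_dd(seed = 27, cfg = cfg)
  expect_error(correlation_panel(an), "at least 3")
  an2 <- sim_analysis_dd(seed = 28, cfg = small_config(n_case = 5, n_ctrl = 5))
  an2$acetate <- 1.0
  expect_error(correlation_panel(an2), "acetate")
  expect_error(scfa_didiff(an2, n_perm = 9), "acetate")
})
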