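test_that("default design produces one sample per mother per timepoint", {
  co <- simulate_scfa_cohort(scfa_sim_config(), seed = 11)
  expect_equal(nrow(co$samples), 254)
  expect_equal(nrow(co$mothers), 127)
  expect_equal(sum(co$mothers$group == "case"), 64)
  expect_equal(sum(co$mothers$group == "control"), 63)
  key <- paste(co$samples$mother_id, co$samples$timepoint)
  expect_equal(anyDuplicated(key), 0L)
  expect_true(all(co$samples$mother_id %in% co$mothers$mother_id))
})

test_that("a config with no cases yields only control records", {
  cfg <- small_config(n_case = 0, n_ctrl = 5)
  co <- simulate_scfa_cohort(cfg, seed = 3)
  expect_equal(nrow(co$samples), 10)
  grp <- co$mothers$group[match(co$samples$mother_id, co$mothers$mother_id)]
  expect_true(all(grp == "control"))
})

test_that("generation is seed-deterministic", {
  cfg <- scfa_sim_config()
  a <- simulate_scfa_cohort(cfg, seed = 7)
  b <- simulate_scfa_cohort(cfg, seed = 7)
  c <- simulate_scfa_cohort(cfg, seed = 8)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_false(identical(a$samples, c$samples))
})

test_that("no emitted concentration falls below its analyte's LOQ", {
  co <- simulate_scfa_cohort(scfa_sim_config(), seed = 5)
  for (a in co$analytes) {
    v <- co$samples[[a]]
    expect_true(all(is.na(v) | v >= co$loq[[a]]), label = a)
  }
})

test_that("the rare analyte is detected in exactly one sample cohort-wide", {
  co <- simulate_scfa_cohort(scfa_sim_config(), seed = 9)
  v <- co$samples$hexanoate
  expect_equal(sum(!is.na(v)), 1L)
  expect_gte(v[!is.na(v)], co$loq[["hexanoate"]])
})

test_that("QC failures land at the configured timepoints in the configured numbers", {
  co <- simulate_scfa_cohort(scfa_sim_config(), seed = 2)
  bad <- co$samples[!co$samples$qc_pass, ]
  expect_equal(nrow(bad), 3L)
  expect_true(all(bad$timepoint == "20w"))
})

test_that("null_config equalises the groups and is idempotent", {
  cfg <- set_mean_shift(scfa_sim_config(), "acetate", "28w", 0.7)
  cfg <- set_pair_correlation(cfg, "acetate", "butyrate", "case", "28w", 0.6)
  nul <- null_config(cfg)
  expect_equal(nul$log_mean[, "case", ], nul$log_mean[, "control", ])
  expect_identical(nul$analyte_corr$case, nul$analyte_corr$control)
  expect_identical(null_config(nul), nul)
})

test_that("invalid configurations are rejected with informative errors", {
  bad_corr <- matrix(0.99, 3, 3); diag(bad_corr) <- 1
  bad_corr[1, 2] <- bad_corr[2, 1] <- -0.99
  expect_error(
    scfa_sim_config(analytes = c("a", "b", "c"), analyte_corr = bad_corr,
                    rare_analyte = NULL),
    "positive semi-definite")
  cfg <- small_config(n_case = 2, n_ctrl = 2)
  cfg$n_low_quality <- c("20w" = 10L, "28w" = 0L)
  expect_error(simulate_scfa_cohort(cfg, seed = 1), "exceeds")
  expect_error(scfa_sim_config(n_case = 0, n_ctrl = 0), "at least one")
  expect_error(scfa_sim_config(log_sd = -1), "log_sd")
})

test_that("large-sample moments recover the configured distribution", {
  cfg <- small_config(n_case = 2000, n_ctrl = 2000,
                      analytes = c("acetate", "propionate", "butyrate",
                                   "valerate"))
  co <- simulate_scfa_cohort(cfg, seed = 42)
  an <- impute_half_loq(apply_qc(co))
  for (g in c("control", "case")) for (tp in cfg$timepoints) {
    rows <- an[an$timepoint == tp & an$group == g, ]
    lx <- log(as.matrix(rows[cfg$analytes]))
    n_g <- nrow(rows)
    for (a in cfg$analytes) {
      se <- cfg$log_sd[[a]] / sqrt(n_g)
      expect_lt(abs(mean(lx[, a]) - cfg$log_mean[a, g, tp]), 3 * se)
    }
    emp <- cor(lx)
    expect_lt(max(abs(emp - cfg$analyte_corr[[g]][[tp]])), 0.05)
  }
})

test_that("within-subject correlation across timepoints is honoured", {
  cfg <- small_config(n_case = 2000, n_ctrl = 0,
                      analytes = c("acetate", "propionate"),
                      within_subject_rho = 0.6)
  co <- simulate_scfa_cohort(cfg, seed = 13)
  an <- impute_half_loq(apply_qc(co))
  t1 <- an[an$timepoint == "20w", ]
  t2 <- an[an$timepoint == "28w", ]
  t2 <- t2[match(t1$mother_id, t2$mother_id), ]
  r <- cor(log(t1$acetate), log(t2$acetate))
  expect_lt(abs(r - 0.6), 0.05)
})
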