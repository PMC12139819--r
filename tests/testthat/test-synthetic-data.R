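small_cfg <- function(...) {
  args <- list(n_genotypes = 10L, n_gardens = 5L, n_blocks = 1L,
               n_years = 1L,
               re_sd_cond = c(genotype = 0.2, garden = 0.2),
               re_sd_zi = c(genotype = 0.2, garden = 0.2))
  do.call(sim_config, utils::modifyList(args, list(...)))
}

test_that("generation is deterministic in (config, seed)", {
  cfg <- small_cfg()
  g1 <- simulate_genotypes(cfg, seed = 3)
  g2 <- simulate_genotypes(cfg, seed = 3)
  expect_identical(g1, g2)
  s1 <- simulate_trial(cfg, seed = 3)
  s2 <- simulate_trial(cfg, seed = 3)
  expect_identical(s1$data$observations, s2$data$observations)
  # and the CSVs are byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_sim_csvs(s1, d1); write_sim_csvs(s2, d2)
  for (f in c("measurements.csv", "genotypes.csv", "gardens.csv",
              "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("PC axes realize the configured climate correlations", {
  # exact affine limit
  cfg1 <- small_cfg(target_cor_pc1_home = -1)
  g <- simulate_genotypes(cfg1, seed = 2)$genotypes
  expect_equal(cor(g$pc1, g$home_mcmt), -1, tolerance = 1e-12)
  # default target is hit essentially exactly by construction
  cfg <- sim_config()
  gd <- simulate_genotypes(cfg, seed = 1)$genotypes
  expect_equal(cor(gd$pc1, gd$home_mcmt), -0.69, tolerance = 1e-10)
  expect_lt(abs(cor(gd$pc2, gd$home_mcmt) - -0.22), 1e-10)
  expect_lt(abs(cor(gd$pc3, gd$home_mcmt) - -0.40), 1e-10)
  expect_true(all(gd$ancestry_q >= 0 & gd$ancestry_q <= 1))
  expect_true(all(gd$home_mcmt >= -23.9 & gd$home_mcmt <= -3.8))
  expect_error(sim_config(target_cor_pc1_home = -0.9995), "infeasible")
})

test_that("the zero-inflation intercept calibration hits the target", {
  cfg <- sim_config()
  sim <- simulate_trial(cfg, seed = 1)
  zf <- mean(sim$data$observations$growth_increment_cm == 0)
  expect_lt(abs(zf - 0.27), 0.02)
  # structural zeros coincide with mortality
  obs <- sim$data$observations
  expect_identical(obs$growth_increment_cm == 0, obs$survived == 0L)
  # uncalibrated extreme intercept: essentially no zeros
  cfg0 <- small_cfg(beta_zi = c("(Intercept)" = -30),
                    calibrate_zi_intercept = FALSE)
  sim0 <- simulate_trial(cfg0, seed = 1)
  expect_lt(mean(sim0$data$observations$growth_increment_cm == 0), 0.01)
})

test_that("generated trials pass QC untouched", {
  sim <- simulate_trial(small_cfg(), seed = 5)
  qc <- apply_qc_filters(sim$data)
  expect_true(all(qc$qc_report == 0))
  expect_equal(nrow(qc$observations), nrow(sim$data$observations))
})

test_that("garden climates anchor both extremes of the range", {
  cfg <- sim_config()
  sim <- simulate_trial(cfg, seed = 4)
  gm <- sim$data$gardens$garden_mcmt
  expect_gte(min(gm), -16.5)
  expect_lte(max(gm), 9.8)
  expect_lt(min(gm), -15)   # a garden near the cold anchor
  expect_gt(max(gm), 8.3)   # and one near the warm anchor
})

test_that("noiseless data identify the conditional coefficients", {
  bc <- c("(Intercept)" = 4.5, gmt = 0.25, gmt2 = -0.7, hmt = 0.08,
          pc1 = -0.3, "pc1:gmt" = -0.25)
  cfg <- small_cfg(sigma_resid = 1e-6, beta_cond = bc,
                   re_sd_cond = c(genotype = 0, garden = 0),
                   re_sd_zi = c(genotype = 0, garden = 0),
                   beta_zi = c("(Intercept)" = -30),
                   calibrate_zi_intercept = FALSE)
  sim <- simulate_trial(cfg, seed = 6)
  des <- build_design(apply_qc_filters(sim$data),
                      model_spec("full",
                                 random_terms = c("genotype", "garden")))
  fit <- suppressWarnings(fit_zig(des))
  truth <- sim$truth$params$beta_cond
  expect_lt(max(abs(fit$params$beta_cond - truth)), 1e-4)
})

test_that("the generator's score is centred at the truth", {
  # model/generator consistency: E[score at truth] = 0. The conditional
  # fixed-effect score has a closed form given the realized random
  # effects; average over replicates and compare with its Monte Carlo SE.
  cfg <- small_cfg()
  R <- 40
  sc <- matrix(NA_real_, R, 2)
  for (r in seq_len(R)) {
    sim <- simulate_trial(cfg, seed = 1000 + r)
    des <- build_design(apply_qc_filters(sim$data),
                        model_spec("full",
                                   random_terms = c("genotype", "garden")),
                        scaling = sim$truth$scaling)
    tr <- sim$truth
    b <- list(cond = lapply(tr$re_cond, identity),
              zi = lapply(tr$re_zi, identity))
    eta_c <- drop(des$X_cond %*% tr$params$beta_cond) +
      as.numeric(des$Z$genotype %*% tr$re_cond$genotype[des$levels$genotype]) +
      as.numeric(des$Z$garden %*% tr$re_cond$garden[des$levels$garden])
    eta_z <- drop(des$X_zi %*% tr$params$beta_zi) +
      as.numeric(des$Z$genotype %*% tr$re_zi$genotype[des$levels$genotype]) +
      as.numeric(des$Z$garden %*% tr$re_zi$garden[des$levels$garden])
    d <- zignorm:::zig_obs_derivs(eta_c, eta_z, des$y, des$is_zero,
                                  tr$params$sigma_resid)
    sc[r, 1] <- sum(d$gc * des$X_cond[, "gmt"])
    sc[r, 2] <- sum(d$gz * des$X_zi[, "gmt2"])
  }
  for (j in 1:2) {
    se <- sd(sc[, j]) / sqrt(R)
    expect_lt(abs(mean(sc[, j])), 4 * se)
  }
})

test_that("recovery experiments summarize estimates against truth", {
  cfg <- small_cfg()
  rec <- recovery_experiment(cfg, n_reps = 2, seeds = c(11, 12),
                             spec = model_spec(
                               "full", random_terms = c("genotype",
                                                        "garden")))
  expect_true(all(c("parameter", "truth", "mean_estimate", "bias",
                    "empirical_sd", "mean_se", "coverage") %in%
                    names(rec$table)))
  expect_true(rec$coverage_defined)
  rec1 <- recovery_experiment(cfg, n_reps = 1, seeds = 13,
                              spec = model_spec(
                                "full", random_terms = c("genotype",
                                                         "garden")))
  expect_false(rec1$coverage_defined)
  expect_true(all(is.na(rec1$table$coverage)))
})
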