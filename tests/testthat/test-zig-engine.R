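# Engine tests: joint likelihood values, Laplace vs independent oracles,
# fitting in closed-form-checkable regimes, and Wald tests.

test_that("joint log-likelihood matches hand-computed mixture values", {
  # single zero observation, p = 0.5, mu = 0, sigma = 1
  des <- toy_two_col_design(y = c(0, 0), x = c(0, 0))
  p <- zig_params(beta_cond = c("(Intercept)" = 0, x = 0),
                  beta_zi = c("(Intercept)" = 0, x = 0), sigma_resid = 1,
                  re_sd_cond = c(group = 0), re_sd_zi = c(group = 0))
  got <- zig_joint_loglik(p, list(cond = list(), zi = list()), des)
  expect_equal(got, 2 * log(0.5 + 0.5 * dnorm(0)), tolerance = 1e-12)
  expect_equal(log(0.5 + 0.5 * dnorm(0)), -0.35743, tolerance = 1e-4)

  # p -> 0 limit: collapses to the plain Gaussian log-likelihood
  set.seed(1)
  y <- abs(rnorm(12)) + 0.2
  des <- toy_two_col_design(y)
  p <- zig_params(beta_cond = c("(Intercept)" = 0.5, x = 0.2),
                  beta_zi = c("(Intercept)" = -30, x = 0), sigma_resid = 0.8,
                  re_sd_cond = c(group = 0), re_sd_zi = c(group = 0))
  mu <- 0.5 + 0.2 * des$X_cond[, "x"]
  expect_equal(zig_joint_loglik(p, list(cond = list(), zi = list()), des),
               sum(dnorm(y, mu, 0.8, log = TRUE)), tolerance = 1e-9)
})

test_that("Laplace equals the closed-form Gaussian marginal", {
  # conditional-only instance: 20 observations in 2 groups
  set.seed(7)
  des <- toy_two_col_design(y = abs(rnorm(20, 2, 0.5)) + 0.1,
                            groups = rep(c("a", "b"), each = 10))
  beta <- stats::setNames(c(2, 0.2), colnames(des$X_cond))
  bz <- stats::setNames(c(-30, 0), colnames(des$X_zi))
  p <- zig_params(beta, bz, sigma_resid = 0.6,
                  re_sd_cond = c(group = 0.4),
                  re_sd_zi = c(group = 0))
  lap <- laplace_marginal_loglik(p, des)
  ref <- mvn_marginal_loglik(p, des)
  expect_equal(lap$value, ref, tolerance = 1e-8)
  # conditional modes present for every level
  expect_length(lap$b_hat$cond$group, 2)
  # vanishing random-effect SD approaches the fixed-effects likelihood
  p0 <- zig_params(beta, bz, 0.6, re_sd_cond = c(group = 1e-8),
                   re_sd_zi = c(group = 0))
  fe <- sum(zignorm:::.zig_obs_loglik(drop(des$X_cond %*% beta),
                                      drop(des$X_zi %*% bz), des$y,
                                      des$is_zero, 0.6))
  expect_equal(laplace_marginal_loglik(p0, des)$value, fe,
               tolerance = 1e-4)
})

test_that("brute-force quadrature equals the closed form and the
           fixed-effect limit", {
  td <- make_small_trial(n_geno = 3, n_gard = 6, zero_frac = 0, seed = 5)
  des <- build_design(td, model_spec("climate_only",
                                     random_terms = "genotype"))
  beta <- stats::setNames(c(2, .2, -.3, .1, -.1, .05, .02, .01, .03),
                          colnames(des$X_cond))
  bz <- stats::setNames(c(-30, rep(0, 8)), colnames(des$X_zi))
  p <- zig_params(beta, bz, 0.6, re_sd_cond = c(genotype = 0.4),
                  re_sd_zi = c(genotype = 0))
  expect_equal(brute_force_marginal_loglik(p, des),
               mvn_marginal_loglik(p, des), tolerance = 1e-8)
  # zero SDs: no integration at all
  p0 <- zig_params(beta, bz, 0.6, re_sd_cond = c(genotype = 0),
                   re_sd_zi = c(genotype = 0))
  fe <- sum(zignorm:::.zig_obs_loglik(drop(des$X_cond %*% beta),
                                      drop(des$X_zi %*% bz), des$y,
                                      des$is_zero, 0.6))
  expect_equal(brute_force_marginal_loglik(p0, des), fe, tolerance = 1e-10)
  # guards
  big <- make_small_trial(n_geno = 8, n_gard = 4)
  desb <- build_design(big, model_spec("climate_only",
                                       random_terms = "genotype"))
  pb <- zig_params(stats::setNames(rep(0, 9), colnames(desb$X_cond)),
                   stats::setNames(rep(0, 9), colnames(desb$X_zi)), 1,
                   re_sd_cond = c(genotype = 0.3),
                   re_sd_zi = c(genotype = 0))
  expect_error(brute_force_marginal_loglik(pb, desb), "6 levels")
})

test_that("Laplace tracks the quadrature oracle on a mixed instance", {
  des <- make_toy_design(seed = 9)
  beta <- stats::setNames(c(1.5, 0.4), colnames(des$X_cond))
  bz <- stats::setNames(c(-1, 0.6), colnames(des$X_zi))
  p <- zig_params(beta, bz, 0.5, re_sd_cond = c(group = 0.25),
                  re_sd_zi = c(group = 0))
  lap <- laplace_marginal_loglik(p, des)$value
  bf <- brute_force_marginal_loglik(p, des)
  expect_lt(abs(lap - bf), 5e-3)
})

test_that("Laplace underestimates on a Bernoulli-heavy instance", {
  # zero-inflation random effects make the integrand sub-Gaussian, so
  # the Laplace value sits at or below the quadrature value
  td <- make_small_trial(n_geno = 3, n_gard = 10, zero_frac = 0.3,
                         seed = 11)
  des <- build_design(td, model_spec("climate_only",
                                     random_terms = "genotype"))
  beta <- stats::setNames(c(1.8, .2, -.3, .1, -.1, .05, .02, .01, .03),
                          colnames(des$X_cond))
  bz <- stats::setNames(c(-0.8, -.3, 0, .5, rep(0, 5)),
                        colnames(des$X_zi))
  p <- zig_params(beta, bz, 0.6, re_sd_cond = c(genotype = 0.35),
                  re_sd_zi = c(genotype = 0.45))
  lap <- laplace_marginal_loglik(p, des)$value
  bf <- brute_force_marginal_loglik(p, des)
  expect_lte(lap, bf + 1e-3)
})

test_that("likelihood is invariant to row order and level labels", {
  des <- make_toy_design(n_per = 8, n_lev = 3, seed = 4)
  beta <- stats::setNames(c(1.5, 0.4), colnames(des$X_cond))
  bz <- stats::setNames(c(-1, 0.6), colnames(des$X_zi))
  p <- zig_params(beta, bz, 0.5, re_sd_cond = c(group = 0.3),
                  re_sd_zi = c(group = 0))
  v1 <- laplace_marginal_loglik(p, des)$value
  set.seed(1)
  ord <- sample(length(des$y))
  des2 <- des
  des2$y <- des$y[ord]; des2$is_zero <- des$is_zero[ord]
  des2$X_cond <- des$X_cond[ord, ]; des2$X_zi <- des$X_zi[ord, ]
  des2$Z$group <- des$Z$group[ord, ]
  expect_equal(laplace_marginal_loglik(p, des2)$value, v1,
               tolerance = 1e-9)
  # relabel levels (permute columns of Z)
  des3 <- des
  perm <- c(3, 1, 2)
  des3$Z$group <- des$Z$group[, perm]
  expect_equal(laplace_marginal_loglik(p, des3)$value, v1,
               tolerance = 1e-9)
})

test_that("with no random effects and no zeros the fit is OLS", {
  td <- make_small_trial(n_geno = 5, n_gard = 8, zero_frac = 0, seed = 3)
  des <- build_design(td, model_spec("climate_only",
                                     random_terms = "genotype"))
  fit <- suppressWarnings(fit_zig(des))
  ols <- stats::lm.fit(des$X_cond, des$y)$coefficients
  expect_lt(max(abs(fit$params$beta_cond - ols)), 1e-5)
  expect_lt(fit$params$re_sd_cond[["genotype"]], 1e-3)
  expect_true("cond.genotype" %in% fit$boundary_terms)
})

test_that("fits agree with glmmTMB on a moderate instance", {
  skip_if_not_installed("glmmTMB")
  set.seed(11)
  cfg <- sim_config(n_genotypes = 15L, n_gardens = 8L, n_blocks = 1L,
                    n_years = 1L,
                    re_sd_cond = c(genotype = 0.3, garden = 0.3),
                    re_sd_zi = c(genotype = 0.3, garden = 0.3))
  sim <- simulate_trial(cfg, seed = 4)
  des <- build_design(apply_qc_filters(sim$data),
                      model_spec("climate_only",
                                 random_terms = c("genotype", "garden")))
  fit <- fit_zig(des)
  df <- as.data.frame(des$X_cond[, -1])
  names(df) <- gsub("[:()]", "_", colnames(des$X_cond)[-1])
  df$y <- des$y
  df$genotype <- des$obs_keys$genotype_id
  df$garden <- des$obs_keys$garden_id
  ff <- stats::reformulate(c(names(df)[1:8], "(1|genotype)", "(1|garden)"),
                           response = "y")
  zf <- stats::reformulate(c(names(df)[1:8], "(1|genotype)", "(1|garden)"))
  m <- glmmTMB::glmmTMB(ff, ziformula = zf, data = df,
                        family = stats::gaussian())
  expect_equal(fit$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-4)
  expect_equal(unname(fit$params$beta_cond),
               unname(glmmTMB::fixef(m)$cond), tolerance = 1e-2)
  expect_equal(fit$params$sigma_resid, glmmTMB::sigma(m),
               tolerance = 1e-3)
  # Wald SEs from the joint-precision Schur complement match too
  se_tmb <- sqrt(diag(stats::vcov(m)$cond))
  se_our <- sqrt(diag(fit$vcov_fixed))[seq_len(9)]
  expect_equal(unname(se_our), unname(se_tmb), tolerance = 0.05)
})

test_that("degenerate responses are handled with warnings", {
  td <- make_small_trial(n_geno = 3, n_gard = 4, zero_frac = 0, seed = 2)
  td$observations$growth_increment_cm <- 0
  td$observations$survived <- 0L
  des <- build_design(td, model_spec("climate_only",
                                     random_terms = "genotype"))
  expect_warning(fit <- fit_zig(des), "all responses are zero")
  expect_false(fit$converged)
  expect_true(stats::plogis(fit$params$beta_zi[["(Intercept)"]]) > 0.999)
})

test_that("Wald tests reproduce chi-square arithmetic", {
  fit <- make_fake_fit(c("(Intercept)" = 2, gmt = 0),
                       c("(Intercept)" = -1))
  k <- length(fit$params$beta_cond)
  vc <- diag(rep(1, 2 * k))
  rownames(vc) <- colnames(vc) <- c(paste0("cond.", names(fit$params$beta_cond)),
                                    paste0("zi.", names(fit$params$beta_zi)))
  fit$vcov_fixed <- vc
  wt <- wald_tests(fit)
  r1 <- wt[wt$part == "cond" & wt$term == "(Intercept)", ]
  expect_equal(r1$chisq, 4)
  expect_equal(r1$df, 1L)
  expect_equal(r1$p, stats::pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(r1$p, 0.0455, tolerance = 1e-3)
  r0 <- wt[wt$part == "cond" & wt$term == "gmt", ]
  expect_equal(r0$chisq, 0)
  expect_equal(r0$p, 1)
})

test_that("optimizer never reports an objective better than its best", {
  des <- make_toy_design(n_per = 10, n_lev = 4, seed = 6)
  fit <- fit_zig(des)
  expect_true(fit$converged)
  expect_lte(-fit$loglik, min(fit$convergence_log$objective) + 1e-6)
})

test_that("fits serialize to JSON and reload for prediction", {
  des <- make_toy_design(n_per = 10, n_lev = 4, seed = 8)
  td <- make_small_trial(n_geno = 4, n_gard = 6, zero_frac = 0.25, seed = 9)
  dd <- build_design(td, model_spec("climate_only",
                                    random_terms = "genotype"))
  fit <- fit_zig(dd)
  f <- withr::local_tempfile(fileext = ".json")
  write_zig_fit(fit, f)
  fit2 <- read_zig_fit(f)
  expect_equal(fit2$params$beta_cond, fit$params$beta_cond)
  expect_equal(fit2$vcov_fixed, fit$vcov_fixed)
  expect_equal(fit2$re_modes$cond$genotype, fit$re_modes$cond$genotype)
  nd <- data.frame(garden_mcmt = -5, home_mcmt = -12, pc1 = 0, pc2 = 0,
                   pc3 = 0)
  expect_equal(predict_components(fit2, nd), predict_components(fit, nd))
})
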