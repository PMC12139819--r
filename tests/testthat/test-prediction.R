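test_that("component predictions satisfy the mixture identities", {
  # all-zero coefficients: eta 0, growth 0, p = 0.5
  fit0 <- make_fake_fit(c("(Intercept)" = 0), c("(Intercept)" = 0))
  nd <- data.frame(garden_mcmt = -3, home_mcmt = -10, pc1 = 1, pc2 = -1,
                   pc3 = 0)
  pr <- predict_components(fit0, nd)
  expect_equal(pr$eta_cond, 0)
  expect_equal(pr$growth_response, 0)
  expect_equal(pr$p_mortality, 0.5)
  # zero mortality: overall equals the growth response exactly
  fit <- make_fake_fit(c("(Intercept)" = 2, gmt = 0.3),
                       c("(Intercept)" = -30))
  pr <- predict_components(fit, nd)
  expect_equal(pr$overall, pr$growth_response, tolerance = 1e-12)
  # hand-computed dot product across all 18 columns
  set.seed(20)
  bc <- stats::setNames(rnorm(18), zignorm:::design_colnames("full"))
  fith <- make_fake_fit(bc, c("(Intercept)" = -1))
  nd2 <- data.frame(garden_mcmt = -4.2, home_mcmt = -11.7, pc1 = 0.8,
                    pc2 = -0.4, pc3 = 1.1)
  g <- nd2$garden_mcmt; h <- nd2$home_mcmt
  xrow <- c(1, g, h, g^2, h^2, g*h, g^2*h^2, g^2*h, g*h^2, nd2$pc1,
            nd2$pc2, nd2$pc3, nd2$pc1*g, nd2$pc2*g, nd2$pc3*g,
            nd2$pc1*g^2, nd2$pc2*g^2, nd2$pc3*g^2)
  expect_equal(predict_components(fith, nd2)$eta_cond, sum(bc * xrow),
               tolerance = 1e-12)
})

test_that("lognormal-mean back-transform applies the variance correction", {
  fit <- make_fake_fit(c("(Intercept)" = 2), c("(Intercept)" = -2),
                       sigma = 0.6)
  nd <- data.frame(garden_mcmt = 0, home_mcmt = -10, pc1 = 0, pc2 = 0,
                   pc3 = 0)
  naive <- predict_components(fit, nd, transform = "naive")
  lnm <- predict_components(fit, nd, transform = "lognormal_mean")
  expect_equal(naive$growth_response, exp(2) - 1)
  expect_equal(lnm$growth_response, exp(2 + 0.36 / 2) - 1)
})

test_that("reaction norms use an inclusive equally spaced grid", {
  fit <- make_fake_fit(c("(Intercept)" = 4, gmt = 0.05, gmt2 = -0.002),
                       c("(Intercept)" = -2))
  geno <- list(home_mcmt = -12, pc1 = 0, pc2 = 0, pc3 = 0)
  rn <- reaction_norm(fit, geno)
  expect_equal(nrow(rn), 100)
  expect_equal(rn$mcmt[1], -23.9)
  expect_equal(rn$mcmt[100], 9.8)
  expect_equal(diff(rn$mcmt)[1], 33.7 / 99, tolerance = 1e-12)
  expect_true(all(rn$p_mortality >= 0 & rn$p_mortality <= 1))
  expect_true(all(rn$overall <= rn$growth_response + 1e-12))
})

test_that("the growth optimum sits at the parabola vertex", {
  b1 <- 0.06; b2 <- -0.004
  fit <- make_fake_fit(c("(Intercept)" = 2, gmt = b1, gmt2 = b2),
                       c("(Intercept)" = -30))
  geno <- list(home_mcmt = -12, pc1 = 0, pc2 = 0, pc3 = 0)
  rn <- reaction_norm(fit, geno)
  vertex <- -b1 / (2 * b2)
  step <- 33.7 / 99
  expect_lt(abs(attr(rn, "t_opt_growth") - vertex), step + 1e-9)
  # with no mortality the overall optimum coincides
  expect_equal(attr(rn, "t_opt_overall"), attr(rn, "t_opt_growth"))
  # grid refinement moves the optimum by at most one coarse step
  rn2 <- reaction_norm(fit, geno, n_points = 200)
  expect_lt(abs(attr(rn2, "t_opt_growth") - attr(rn, "t_opt_growth")),
            step + 1e-9)
})

test_that("a convex zero-inflation logit yields U-shaped mortality", {
  fit <- make_fake_fit(c("(Intercept)" = 2),
                       c("(Intercept)" = -2, gmt = 0.02, gmt2 = 0.012))
  geno <- list(home_mcmt = -12, pc1 = 0, pc2 = 0, pc3 = 0)
  rn <- reaction_norm(fit, geno)
  k <- which.min(rn$p_mortality)
  expect_gt(k, 1); expect_lt(k, 100)
  expect_true(all(diff(rn$p_mortality[1:k]) <= 1e-12))
  expect_true(all(diff(rn$p_mortality[k:100]) >= -1e-12))
})

test_that("transfer distance re-indexes without changing predictions", {
  fit <- make_fake_fit(c("(Intercept)" = 2, gmt = 0.06, gmt2 = -0.004),
                       c("(Intercept)" = -2))
  geno <- list(home_mcmt = -10, pc1 = 0, pc2 = 0, pc3 = 0)
  rn <- reaction_norm(fit, geno)
  tv <- transfer_distance_view(rn)
  expect_equal(tv$transfer_distance, rn$mcmt + 10)
  expect_true(all(diff(tv$transfer_distance) > 0))
  expect_equal(tv$overall, rn$overall)
  # optimum warmer than home shows as a positive transfer distance
  expect_gt(attr(rn, "t_opt_growth"), -10)
  expect_equal(tv$transfer_distance[which.max(tv$growth_response)],
               attr(rn, "t_opt_growth") + 10)
})

test_that("random-effect lookups add known modes and ignore new levels", {
  fit <- make_fake_fit(c("(Intercept)" = 2), c("(Intercept)" = -2))
  fit$re_modes$cond$genotype <- c(G1 = 0.5, G2 = -0.5)
  fit$re_modes$zi$genotype <- c(G1 = 0.2, G2 = 0)
  nd <- data.frame(garden_mcmt = 0, home_mcmt = -10, pc1 = 0, pc2 = 0,
                   pc3 = 0, genotype_id = c("G1", "G9"))
  pr0 <- predict_components(fit, nd, include_random_effects = FALSE)
  pr1 <- predict_components(fit, nd, include_random_effects = TRUE)
  expect_equal(pr1$eta_cond[1], pr0$eta_cond[1] + 0.5)
  expect_equal(pr1$eta_cond[2], pr0$eta_cond[2])   # unseen: zero deviation
  expect_equal(pr0$eta_cond, c(2, 2))
})

test_that("out-of-range requests warn but still predict", {
  fit <- make_fake_fit(c("(Intercept)" = 2), c("(Intercept)" = -2))
  nd <- data.frame(garden_mcmt = c(-30, 0), home_mcmt = -10, pc1 = 0,
                   pc2 = 0, pc3 = 0)
  expect_warning(pr <- predict_components(fit, nd,
                                          extrapolation_bounds = c(-20, 12)),
                 "extrapolation")
  expect_equal(nrow(pr), 2)
  expect_identical(attr(pr, "extrapolated"), c(TRUE, FALSE))
})
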