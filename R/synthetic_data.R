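# Synthetic multi-garden clonal trials with known truth: the generator's
# defaults emulate the structure of the motivating hybrid-zone trial
# network (45 clonal genotypes of mixed species ancestry, 17 gardens x 2
# blocks x 2 years, garden winter temperatures spanning -16.5 to 9.8 C,
# home climates -23.9 to -3.8 C, leading genomic PC tracking home climate
# at r = -0.69, and ~27% structural zeros from mortality concentrated at
# the temperature extremes).

# run expr with a local RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Configuration of a synthetic trial
#'
#' True fixed effects are given per named design column (see
#' [build_design()] for the naming scheme) and act on the RMS-scaled
#' covariates; unnamed columns are zero. The zero-inflation intercept is
#' calibrated at generation time so that the expected structural-zero
#' fraction equals `target_zero_fraction`. PC axes are constructed to
#' realize the target correlations with home climate exactly (via
#' orthogonalized noise), mirroring the observed coupling of genetic
#' structure and climate of origin.
#'
#' @param n_genotypes,n_gardens,n_blocks,n_years design dimensions.
#' @param garden_mcmt_range,home_mcmt_range climate ranges, degrees C.
#' @param target_cor_pc1_home,target_cor_pc2_home,target_cor_pc3_home
#'   Pearson correlations of the PC axes with home MCMT; magnitude above
#'   0.999 (other than exactly 1) is rejected as infeasible.
#' @param target_zero_fraction expected share of structural zeros.
#' @param beta_cond,beta_zi named true fixed effects (scaled-design units);
#'   the `(Intercept)` of `beta_zi` is a starting value replaced by the
#'   calibrated intercept.
#' @param re_sd_cond,re_sd_zi named true random-intercept SDs.
#' @param sigma_resid residual SD of log growth.
#' @param year_jitter_sd half-width of the per-year uniform jitter of
#'   garden MCMT, degrees C.
#' @param sampling_zero_rate probability that a surviving tree records a
#'   growth of exactly 0 (a sampling zero); default 0 (mortality is the
#'   only source of zeros).
#' @param calibrate_zi_intercept when `TRUE` (default) the zero-inflation
#'   intercept is shifted so the expected structural-zero fraction equals
#'   `target_zero_fraction`; when `FALSE` the `beta_zi` intercept is used
#'   as given.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genotypes = 45L, n_gardens = 17L, n_blocks = 2L,
                       n_years = 2L,
                       garden_mcmt_range = c(-16.5, 9.8),
                       home_mcmt_range = c(-23.9, -3.8),
                       target_cor_pc1_home = -0.69,
                       target_cor_pc2_home = -0.22,
                       target_cor_pc3_home = -0.40,
                       target_zero_fraction = 0.27,
                       beta_cond = c("(Intercept)" = 4.2, gmt = 0.25,
                                     gmt2 = -0.7, hmt = 0.08, hmt2 = -0.05,
                                     "gmt:hmt" = 0.05, pc1 = -0.3,
                                     pc3 = 0.2, "pc1:gmt" = -0.25,
                                     "pc3:gmt" = 0.1, "pc1:gmt2" = 0.1),
                       beta_zi = c("(Intercept)" = -2.0, gmt = -0.5,
                                   gmt2 = 1.2, pc1 = 0.2),
                       re_sd_cond = c(genotype = 0.25, garden = 0.4,
                                      block_in_garden = 0.15, year = 0.2,
                                      individual = 0.3),
                       re_sd_zi = c(genotype = 0.3, garden = 0.4,
                                    block_in_garden = 0.2, year = 0.2,
                                    individual = 0),
                       sigma_resid = 0.5,
                       year_jitter_sd = 0.5,
                       sampling_zero_rate = 0,
                       calibrate_zi_intercept = TRUE) {
  stopifnot(garden_mcmt_range[1] < garden_mcmt_range[2],
            home_mcmt_range[1] < home_mcmt_range[2],
            target_zero_fraction > 0, target_zero_fraction < 1,
            all(re_sd_cond >= 0), all(re_sd_zi >= 0), sigma_resid >= 0,
            sampling_zero_rate >= 0, sampling_zero_rate < 1)
  for (r in c(target_cor_pc1_home, target_cor_pc2_home, target_cor_pc3_home))
    if (abs(r) > 0.999 && abs(r) != 1)
      stop("infeasible target correlation: ", r)
  structure(list(
    n_genotypes = as.integer(n_genotypes), n_gardens = as.integer(n_gardens),
    n_blocks = as.integer(n_blocks), n_years = as.integer(n_years),
    garden_mcmt_range = garden_mcmt_range, home_mcmt_range = home_mcmt_range,
    target_cor_pc1_home = target_cor_pc1_home,
    target_cor_pc2_home = target_cor_pc2_home,
    target_cor_pc3_home = target_cor_pc3_home,
    target_zero_fraction = target_zero_fraction,
    beta_cond = beta_cond, beta_zi = beta_zi,
    re_sd_cond = re_sd_cond, re_sd_zi = re_sd_zi,
    sigma_resid = sigma_resid, year_jitter_sd = year_jitter_sd,
    sampling_zero_rate = sampling_zero_rate,
    calibrate_zi_intercept = isTRUE(calibrate_zi_intercept)),
    class = "sim_config")
}

# y with exact sample correlation rho to x, built from noise orthogonalized
# against x, then rescaled to the requested marginal SD
.calibrated_cor <- function(x, rho, out_sd, noise) {
  xs <- (x - mean(x)) / stats::sd(x)
  if (abs(rho) == 1) return(sign(rho) * xs * out_sd)
  e <- stats::residuals(stats::lm.fit(cbind(1, xs), noise))
  es <- (e - mean(e)) / stats::sd(e)
  y <- rho * xs + sqrt(1 - rho^2) * es
  y / stats::sd(y) * out_sd
}

#' Simulate admixture-structured genotypes
#'
#' Ancestry proportions are drawn from a mixture of near-parental (both
#' species) and intermediate hybrid components; home MCMT increases with
#' the warm-species ancestry share plus noise; PC axes are constructed to
#' hit the configured correlations with home MCMT exactly.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed (RNG state is restored afterwards).
#' @return list with `genotypes` (data frame in the genotype-table schema)
#'   and `truth` (construction internals).
#' @export
simulate_genotypes <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(seed, {
    n <- cfg$n_genotypes
    comp <- sample(c("bals", "hyb", "tricho"), n, replace = TRUE,
                   prob = c(0.3, 0.4, 0.3))
    q <- numeric(n)
    q[comp == "bals"] <- stats::rbeta(sum(comp == "bals"), 1, 12)
    q[comp == "tricho"] <- 1 - stats::rbeta(sum(comp == "tricho"), 1, 12)
    q[comp == "hyb"] <- stats::runif(sum(comp == "hyb"), 0.05, 0.95)
    hr <- cfg$home_mcmt_range
    home <- hr[1] + q * diff(hr) + stats::rnorm(n, 0, 1.5)
    home <- pmin(pmax(home, hr[1]), hr[2])
    pc1 <- .calibrated_cor(home, cfg$target_cor_pc1_home, 30,
                           stats::rnorm(n))
    pc2 <- .calibrated_cor(home, cfg$target_cor_pc2_home, 15,
                           stats::rnorm(n))
    pc3 <- .calibrated_cor(home, cfg$target_cor_pc3_home, 10,
                           stats::rnorm(n))
    genotypes <- data.frame(
      genotype_id = sprintf("G%02d", seq_len(n)),
      home_mcmt = home, pc1 = pc1, pc2 = pc2, pc3 = pc3, ancestry_q = q,
      latitude = 61 - q * 12 + stats::rnorm(n, 0, 1),
      longitude = -148 + q * 22 + stats::rnorm(n, 0, 2))
    list(genotypes = genotypes,
         truth = list(component = comp, seed = seed))
  })
}

#' Simulate a complete multi-garden trial with known truth
#'
#' Garden MCMT values are quasi-evenly spaced over the configured range
#' (anchoring both climatic extremes, as extreme gardens anchor response
#' curves in real trial networks) with a small uniform per-year jitter.
#' Each genotype is planted once per block per garden and measured every
#' year. For each observation the full-model design row is built, random
#' intercepts are drawn per level, and a structural zero (death) occurs
#' with the zero-inflation probability — the zero-inflation intercept
#' having been calibrated so the expected zero fraction matches the
#' configuration. Surviving trees get `growth = exp(eta + eps) - 1` with
#' `eps ~ N(0, sigma^2)` truncated so log growth stays non-negative
#' (sampled by inversion; under the default parameters the truncated mass
#' is negligible).
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return list with `data` (a `trial_dataset`) and `truth` (a `sim_truth`:
#'   the exact [zig_params()] used on the realized scaled design, the
#'   scaling divisors, all random-effect draws and the genotype latents).
#' @export
simulate_trial <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  gen <- simulate_genotypes(cfg, seed)
  .with_seed(seed + 1000003L, {
    gr <- cfg$garden_mcmt_range
    garden_ids <- sprintf("S%02d", seq_len(cfg$n_gardens))
    base_mcmt <- seq(gr[1], gr[2], length.out = cfg$n_gardens)
    years <- 2020L + seq_len(cfg$n_years)
    gardens <- expand.grid(garden_id = garden_ids, year = years,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    gardens$garden_mcmt <- pmin(pmax(
      base_mcmt[match(gardens$garden_id, garden_ids)] +
        stats::runif(nrow(gardens), -cfg$year_jitter_sd, cfg$year_jitter_sd),
      gr[1]), gr[2])

    skel <- expand.grid(genotype_id = gen$genotypes$genotype_id,
                        garden_id = garden_ids,
                        block_id = sprintf("B%d", seq_len(cfg$n_blocks)),
                        year = years,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    skel$individual_id <- paste(skel$genotype_id, skel$garden_id,
                                skel$block_id, sep = ".")
    gi <- match(skel$genotype_id, gen$genotypes$genotype_id)
    gk <- match(paste(skel$garden_id, skel$year),
                paste(gardens$garden_id, gardens$year))
    cov <- data.frame(garden_mcmt = gardens$garden_mcmt[gk],
                      home_mcmt = gen$genotypes$home_mcmt[gi],
                      pc1 = gen$genotypes$pc1[gi],
                      pc2 = gen$genotypes$pc2[gi],
                      pc3 = gen$genotypes$pc3[gi])
    scaling <- lapply(cov, function(x) scale_no_center(x)$divisor)
    X <- design_row_matrix(scaling, "full", cov$garden_mcmt, cov$home_mcmt,
                           cov$pc1, cov$pc2, cov$pc3)
    full_cols <- colnames(X)
    bc <- stats::setNames(rep(0, length(full_cols)), full_cols)
    bc[names(cfg$beta_cond)] <- cfg$beta_cond
    bz <- stats::setNames(rep(0, length(full_cols)), full_cols)
    bz[names(cfg$beta_zi)] <- cfg$beta_zi

    groups <- list(genotype = skel$genotype_id, garden = skel$garden_id,
                   block_in_garden = paste(skel$garden_id, skel$block_id,
                                           sep = ":"),
                   year = as.character(skel$year),
                   individual = skel$individual_id)
    draw_re <- function(sds) {
      lapply(names(groups), function(term) {
        lv <- unique(groups[[term]])
        sd_t <- if (term %in% names(sds)) sds[[term]] else 0
        stats::setNames(stats::rnorm(length(lv), 0, sd_t), lv)
      }) |> stats::setNames(names(groups))
    }
    u_c <- draw_re(cfg$re_sd_cond)
    u_z <- draw_re(cfg$re_sd_zi)
    re_sum <- function(u) Reduce(`+`, lapply(names(groups), function(term)
      unname(u[[term]][groups[[term]]])))

    eta_c <- drop(X %*% bc) + re_sum(u_c)
    eta_z0 <- drop(X %*% bz) + re_sum(u_z)
    shift <- if (isTRUE(cfg$calibrate_zi_intercept)) {
      stats::uniroot(function(cst)
        mean(stats::plogis(eta_z0 + cst)) - cfg$target_zero_fraction,
        c(-60, 60), tol = 1e-10)$root
    } else 0
    bz[["(Intercept)"]] <- bz[["(Intercept)"]] + shift
    eta_z <- eta_z0 + shift

    dead <- stats::runif(nrow(skel)) < stats::plogis(eta_z)
    # log growth of survivors: Normal(eta, sigma^2) truncated below at 0,
    # sampled by inversion (safe even when the untruncated mass at y < 0
    # is large)
    plo <- stats::pnorm(0, eta_c, cfg$sigma_resid)
    u <- plo + stats::runif(nrow(skel)) * (1 - plo)
    y <- stats::qnorm(pmin(u, 1 - 1e-16), eta_c, cfg$sigma_resid)
    y <- pmax(y, 0)
    growth <- ifelse(dead, 0, exp(y) - 1)
    survived <- !dead
    if (cfg$sampling_zero_rate > 0) {
      samp0 <- survived & stats::runif(nrow(skel)) < cfg$sampling_zero_rate
      growth[samp0] <- 0
    }

    measurements <- data.frame(
      individual_id = skel$individual_id, genotype_id = skel$genotype_id,
      garden_id = skel$garden_id, block_id = skel$block_id,
      year = skel$year, growth_increment_cm = growth,
      survived = as.integer(survived))
    data <- trial_dataset(measurements, gen$genotypes, gardens)
    truth <- structure(list(
      params = zig_params(beta_cond = bc, beta_zi = bz,
                          sigma_resid = max(cfg$sigma_resid, 1e-8),
                          re_sd_cond = cfg$re_sd_cond,
                          re_sd_zi = cfg$re_sd_zi),
      scaling = scaling, re_cond = u_c, re_zi = u_z,
      zi_intercept_shift = shift, genotype_truth = gen$truth,
      config = cfg, seed = seed), class = "sim_truth")
    list(data = data, truth = truth)
  })
}

#' Write the simulated trial as its three input CSV files plus truth JSON
#'
#' Output is byte-identical for identical (config, seed).
#'
#' @param sim result of [simulate_trial()].
#' @param dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
write_sim_csvs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("measurements.csv", "genotypes.csv",
                            "gardens.csv", "truth.json"))
  utils::write.csv(sim$data$observations, paths[1], row.names = FALSE)
  utils::write.csv(sim$data$genotypes, paths[2], row.names = FALSE)
  utils::write.csv(sim$data$gardens, paths[3], row.names = FALSE)
  tr <- sim$truth
  jsonlite::write_json(list(
    beta_cond = as.list(tr$params$beta_cond),
    beta_zi = as.list(tr$params$beta_zi),
    sigma_resid = tr$params$sigma_resid,
    re_sd_cond = as.list(tr$params$re_sd_cond),
    re_sd_zi = as.list(tr$params$re_sd_zi),
    scaling = tr$scaling, zi_intercept_shift = tr$zi_intercept_shift,
    seed = tr$seed), paths[4], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Parameter-recovery experiment
#'
#' Repeats simulate / fit cycles and summarizes, per fixed-effect
#' parameter, the mean estimate, bias, empirical SD of the estimates, mean
#' Wald SE, and the coverage of nominal 95% Wald intervals. Replicates
#' whose fit fails or does not converge are excluded and counted; more than
#' 20% failures aborts with diagnostics.
#'
#' @param cfg a [sim_config()].
#' @param n_reps number of replicates.
#' @param seeds integer vector of per-replicate seeds (default
#'   `seq_len(n_reps)`).
#' @param spec the [model_spec()] to fit (default full model with the
#'   generator's random terms).
#' @param control a [zig_control()].
#' @return list with `table` (per-parameter summary data frame including
#'   `bias_cv`, the control-variate bias estimate against an exactly
#'   unbiased oracle that knows the realized random effects), `n_ok`,
#'   `n_failed`, `coverage_defined` (FALSE when `n_reps` is 1) and
#'   `pooled_coverage` (the 95% Wald coverage pooled over all fixed
#'   effects and replicates).
#' @export
recovery_experiment <- function(cfg, n_reps, seeds = seq_len(n_reps),
                                spec = model_spec("full"),
                                control = zig_control()) {
  stopifnot(inherits(cfg, "sim_config"), length(seeds) == n_reps)
  est <- se <- truth_mat <- oracle_mat <- NULL
  n_failed <- 0L
  fail_msgs <- character()
  for (i in seq_len(n_reps)) {
    res <- tryCatch({
      sim <- simulate_trial(cfg, seeds[i])
      des <- build_design(apply_qc_filters(sim$data), spec)
      fit <- fit_zig(des, control)
      if (!fit$converged) stop("outer optimizer did not converge")
      tr <- c(sim$truth$params$beta_cond, sim$truth$params$beta_zi)
      names(tr) <- c(paste0("cond.", names(sim$truth$params$beta_cond)),
                     paste0("zi.", names(sim$truth$params$beta_zi)))
      wt <- wald_tests(fit)
      nm <- paste0(wt$part, ".", wt$term)
      # oracle conditional estimator: GLS on the survivors at the TRUE
      # variance components. Linear in the responses, hence exactly
      # unbiased, and it shrinks group effects like the ML fit does, so
      # est - oracle isolates the estimator's bias with far smaller
      # Monte Carlo error than est - truth (a control variate).
      alive <- !des$is_zero
      Xa <- des$X_cond[alive, , drop = FALSE]
      V <- diag(sim$truth$params$sigma_resid^2, sum(alive))
      for (term in names(des$Z)) {
        sd_t <- sim$truth$params$re_sd_cond[[term]]
        if (isTRUE(sd_t > 0)) {
          Za <- des$Z[[term]][alive, , drop = FALSE]
          V <- V + sd_t^2 * as.matrix(Matrix::tcrossprod(Za))
        }
      }
      R <- chol(V)
      wX <- backsolve(R, Xa, transpose = TRUE)
      wy <- backsolve(R, des$y[alive], transpose = TRUE)
      oracle <- stats::lm.fit(wX, wy)$coefficients
      names(oracle) <- colnames(des$X_cond)  # backsolve drops dimnames
      orc <- stats::setNames(rep(NA_real_, length(nm)), nm)
      orc[paste0("cond.", names(oracle))] <- oracle
      list(est = stats::setNames(wt$estimate, nm),
           se = stats::setNames(wt$se, nm), truth = tr[nm], oracle = orc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      fail_msgs <- c(fail_msgs, conditionMessage(res))
      next
    }
    est <- rbind(est, res$est)
    se <- rbind(se, res$se)
    truth_mat <- rbind(truth_mat, res$truth)
    oracle_mat <- rbind(oracle_mat, res$oracle)
  }
  n_ok <- n_reps - n_failed
  if (n_failed > 0.2 * n_reps)
    stop("more than 20% of replicates failed (", n_failed, "/", n_reps,
         "); first messages: ",
         paste(utils::head(unique(fail_msgs), 3), collapse = " | "))
  cover <- abs(est - truth_mat) <= 1.96 * se
  table <- data.frame(
    parameter = colnames(est),
    truth = colMeans(truth_mat),
    mean_estimate = colMeans(est),
    bias = colMeans(est - truth_mat),
    bias_cv = colMeans(est - oracle_mat),
    bias_cv_se = apply(est - oracle_mat, 2, stats::sd) / sqrt(n_ok),
    empirical_sd = apply(est, 2, stats::sd),
    mean_se = colMeans(se),
    coverage = if (n_ok > 1) colMeans(cover) else NA_real_,
    row.names = NULL)
  list(table = table, n_ok = n_ok, n_failed = n_failed,
       coverage_defined = n_ok > 1,
       pooled_coverage = if (n_ok > 1) mean(cover) else NA_real_)
}
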