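# In-code fixtures shared across test files. Everything is generated
# programmatically; no data files.

# A small clonal trial with one block and one year: n_geno x n_gard
# observations, optional structural zeros.
make_small_trial <- function(n_geno = 4, n_gard = 5, zero_frac = 0,
                             seed = 7, sigma = 0.5) {
  set.seed(seed)
  skel <- expand.grid(genotype_id = sprintf("g%d", seq_len(n_geno)),
                      garden_id = sprintf("A%d", seq_len(n_gard)),
                      stringsAsFactors = FALSE)
  n <- nrow(skel)
  meas <- data.frame(individual_id = sprintf("i%03d", seq_len(n)),
                     genotype_id = skel$genotype_id,
                     garden_id = skel$garden_id, block_id = "B1",
                     year = 2021L,
                     growth_increment_cm = exp(rnorm(n, 2, sigma)) - 1,
                     survived = 1L)
  if (zero_frac > 0) {
    k <- which(runif(n) < zero_frac)
    meas$growth_increment_cm[k] <- 0
    meas$survived[k] <- 0L
  }
  geno <- data.frame(genotype_id = sprintf("g%d", seq_len(n_geno)),
                     home_mcmt = seq(-20, -6, length.out = n_geno),
                     pc1 = rnorm(n_geno), pc2 = rnorm(n_geno),
                     pc3 = rnorm(n_geno), ancestry_q = runif(n_geno))
  gard <- data.frame(garden_id = sprintf("A%d", seq_len(n_gard)),
                     year = 2021L,
                     garden_mcmt = seq(-15, 8, length.out = n_gard))
  apply_qc_filters(trial_dataset(meas, geno, gard))
}

# Minimal hand-built design: one grouping factor, X = [1, x] in both
# parts, conditional random intercept only (no zi random effect). Used by
# the engine-oracle comparisons where a quadrature refit must stay cheap.
make_toy_design <- function(n_per = 15, n_lev = 6, seed = 9, sdc = 0.25,
                            beta_c = c(1.5, 0.4), beta_z = c(-1.0, 0.6),
                            sigma = 0.5) {
  set.seed(seed)
  n <- n_per * n_lev
  grp <- rep(sprintf("L%d", seq_len(n_lev)), each = n_per)
  x <- runif(n, -1, 1)
  X <- cbind("(Intercept)" = 1, x = x)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(factor(grp)),
                            x = 1, dims = c(n, n_lev),
                            dimnames = list(NULL,
                                            sprintf("L%d", seq_len(n_lev))))
  uc <- rnorm(n_lev, 0, sdc)
  eta_c <- drop(X %*% beta_c) + as.numeric(Z %*% uc)
  eta_z <- drop(X %*% beta_z)
  dead <- runif(n) < plogis(eta_z)
  y <- ifelse(dead, 0, eta_c + rnorm(n, 0, sigma))
  y[!dead & y < 0] <- 0.01
  structure(list(y = y, is_zero = y == 0, X_cond = X, X_zi = X,
                 Z = list(group = Z),
                 levels = list(group = colnames(Z)), scaling = list(),
                 spec = model_spec("full", "genotype",
                                   zi_random_terms = character())),
            class = "zig_design")
}

# A synthetic fitted model with hand-set coefficients, identity scaling
# and no random-effect modes; exercises prediction and projection without
# an actual fit.
make_fake_fit <- function(beta_cond, beta_zi, sigma = 0.5,
                          variant = "full") {
  cols <- zignorm:::design_colnames(variant)
  bc <- stats::setNames(rep(0, length(cols)), cols)
  bc[names(beta_cond)] <- beta_cond
  bz <- stats::setNames(rep(0, length(cols)), cols)
  bz[names(beta_zi)] <- beta_zi
  scaling <- list(garden_mcmt = 1, home_mcmt = 1, pc1 = 1, pc2 = 1, pc3 = 1)
  structure(list(
    params = zig_params(bc, bz, sigma,
                        re_sd_cond = c(genotype = 0),
                        re_sd_zi = c(genotype = 0)),
    vcov_fixed = NULL,
    re_modes = list(cond = list(), zi = list()),
    loglik = NA_real_, converged = TRUE, boundary_terms = character(),
    convergence_log = data.frame(), n_obs = 0L, scaling = scaling,
    spec = model_spec(variant), levels = list(), zi_enabled = TRUE),
    class = "fitted_zig")
}

# Closed-form marginal log-likelihood of the conditional-only model:
# y ~ MVN(X beta, sigma^2 I + sum_t sd_t^2 Z_t Z_t'), plus the log(1 - p)
# terms of the pinned zero-inflation part.
mvn_marginal_loglik <- function(params, design) {
  stopifnot(all(!design$is_zero))
  S <- params$sigma_resid^2 * diag(length(design$y))
  for (term in names(design$Z)) {
    sd_t <- params$re_sd_cond[[term]]
    if (isTRUE(sd_t > 0)) {
      Zt <- as.matrix(design$Z[[term]])
      S <- S + sd_t^2 * Zt %*% t(Zt)
    }
  }
  r <- design$y - drop(design$X_cond %*% params$beta_cond)
  R <- chol(S)
  gauss <- -0.5 * length(r) * log(2 * pi) - sum(log(diag(R))) -
    0.5 * sum(backsolve(R, r, transpose = TRUE)^2)
  p_log1m <- stats::plogis(drop(design$X_zi %*% params$beta_zi),
                           log.p = TRUE, lower.tail = FALSE)
  gauss + sum(p_log1m)
}

# Two-column design (intercept + slope, both parts) over arbitrary
# grouping labels; handy for hand-computed likelihood values.
toy_two_col_design <- function(y, x = NULL, groups = NULL) {
  n <- length(y)
  if (is.null(x)) x <- seq(-1, 1, length.out = n)
  X <- cbind("(Intercept)" = 1, x = x)
  if (is.null(groups)) groups <- rep("L1", n)
  f <- factor(groups)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(f), x = 1,
                            dims = c(n, nlevels(f)),
                            dimnames = list(NULL, levels(f)))
  structure(list(y = y, is_zero = y == 0, X_cond = X, X_zi = X,
                 Z = list(group = Z), levels = list(group = levels(f)),
                 scaling = list(), spec = model_spec("full", "genotype")),
            class = "zig_design")
}
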