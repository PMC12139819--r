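# Observation-level zero-inflated Gaussian log-likelihood and its first and
# second derivatives with respect to the two linear predictors.
#
# Conditional part: y | survive ~ Normal(eta_c, sigma^2) on the log scale.
# Zero-inflation part: structural-zero probability p = plogis(eta_z).
# Density convention for a zero observation mixes the point mass with the
# Gaussian density evaluated at zero:
#   y  = 0: f = p + (1 - p) * dnorm(0; eta_c, sigma)
#   y != 0: f = (1 - p) * dnorm(y; eta_c, sigma)
# This matches the numerical convention of zero-inflated continuous families
# in widely used mixed-model software, so fits are comparable across tools.

# Returns list of vectors: l, gc, gz (gradients wrt eta_c, eta_z) and
# hcc, hzz, hcz (second derivatives). All length n.
zig_obs_derivs <- function(eta_c, eta_z, y, is_zero, sigma) {
  n <- length(y)
  l <- gc <- gz <- hcc <- hzz <- hcz <- numeric(n)
  s2 <- sigma^2

  log_p <- stats::plogis(eta_z, log.p = TRUE)
  log_1mp <- stats::plogis(eta_z, log.p = TRUE, lower.tail = FALSE)
  p <- exp(log_p)

  pos <- !is_zero
  if (any(pos)) {
    l[pos] <- log_1mp[pos] + stats::dnorm(y[pos], eta_c[pos], sigma, log = TRUE)
    gc[pos] <- (y[pos] - eta_c[pos]) / s2
    hcc[pos] <- -1 / s2
    gz[pos] <- -p[pos]
    hzz[pos] <- -p[pos] * (1 - p[pos])
    hcz[pos] <- 0
  }
  z <- is_zero
  if (any(z)) {
    mu <- eta_c[z]
    lphi0 <- stats::dnorm(0, mu, sigma, log = TRUE)
    phi0 <- exp(lphi0)
    a <- pmax(log_p[z], log_1mp[z] + lphi0)
    lf <- a + log(exp(log_p[z] - a) + exp(log_1mp[z] + lphi0 - a))
    l[z] <- lf
    w <- exp(log_1mp[z] + lphi0 - lf)        # posterior weight of the
    pz <- p[z]                                # Gaussian (sampling) branch
    gc[z] <- -w * mu / s2
    hcc[z] <- w * (1 - w) * mu^2 / s2^2 - w / s2
    dz <- (1 - pz) * (1 - w) * (1 - phi0)
    gz[z] <- dz
    hzz[z] <- (1 - 2 * pz) * dz - dz^2
    hcz[z] <- (1 - pz) * (1 - w) * (mu / s2) * (phi0 + w * (1 - phi0))
  }
  list(l = l, gc = gc, gz = gz, hcc = hcc, hzz = hzz, hcz = hcz)
}

#' Joint log-likelihood of data and random effects
#'
#' Evaluates the zero-inflated Gaussian joint log-density: the sum of
#' per-observation mixture log-likelihood terms (see Details) plus the
#' Gaussian log-prior of the random-intercept vectors of both model parts.
#' This is the integrand (on the log scale) of the marginal likelihood that
#' [laplace_marginal_loglik()] and [brute_force_marginal_loglik()]
#' approximate.
#'
#' @details For observation i with structural-zero probability
#' `p_i = plogis(eta_zi)` and conditional mean `mu_i`:
#' zero observations contribute `log(p_i + (1 - p_i) dnorm(0, mu_i, sigma))`
#' and positive observations `log(1 - p_i) + dnorm(y_i, mu_i, sigma, log)`.
#'
#' @param params a [zig_params()] object.
#' @param b named list of random-effect vectors: `cond` and `zi`, each a
#'   list by grouping factor with one value per level (missing entries are
#'   taken as zero).
#' @param design a `zig_design` from [build_design()].
#' @return scalar joint log-likelihood.
#' @export
zig_joint_loglik <- function(params, b, design) {
  stopifnot(inherits(params, "zig_params"), inherits(design, "zig_design"))
  eta <- .zig_linear_predictors(params, b, design)
  if (any(!is.finite(eta$cond)) || any(!is.finite(eta$zi)))
    stop("non-finite linear predictor")
  d <- zig_obs_derivs(eta$cond, eta$zi, design$y, design$is_zero,
                      params$sigma_resid)
  lp <- 0
  for (part in c("cond", "zi")) {
    sds <- params[[paste0("re_sd_", part)]]
    for (term in names(design$Z)) {
      sd_t <- if (term %in% names(sds)) sds[[term]] else 0
      u <- b[[part]][[term]]
      if (is.null(u)) u <- numeric(ncol(design$Z[[term]]))
      if (sd_t > 0) {
        lp <- lp + sum(stats::dnorm(u, 0, sd_t, log = TRUE))
      } else if (any(u != 0)) {
        stop("nonzero random effects supplied for a term with zero SD (",
             part, ":", term, ")")
      }
    }
  }
  sum(d$l) + lp
}

.zig_linear_predictors <- function(params, b, design) {
  eta_c <- drop(design$X_cond %*% params$beta_cond)
  eta_z <- drop(design$X_zi %*% params$beta_zi)
  for (term in names(design$Z)) {
    uc <- b$cond[[term]]
    if (!is.null(uc)) eta_c <- eta_c + drop(design$Z[[term]] %*% uc)
    uz <- b$zi[[term]]
    if (!is.null(uz)) eta_z <- eta_z + drop(design$Z[[term]] %*% uz)
  }
  list(cond = eta_c, zi = eta_z)
}

#' Parameter container for the zero-inflated Gaussian mixed model
#'
#' @param beta_cond named fixed-effect vector of the conditional (growth)
#'   part; names must match the design columns.
#' @param beta_zi named fixed-effect vector of the zero-inflation
#'   (mortality) part, on the logit scale.
#' @param sigma_resid residual SD of the conditional part (log scale).
#' @param re_sd_cond,re_sd_zi named non-negative random-intercept SDs per
#'   grouping factor (a missing name means that term is absent / SD zero).
#' @return A `zig_params` object.
#' @export
zig_params <- function(beta_cond, beta_zi, sigma_resid,
                       re_sd_cond = numeric(), re_sd_zi = numeric()) {
  stopifnot(sigma_resid > 0, all(re_sd_cond >= 0), all(re_sd_zi >= 0))
  structure(list(beta_cond = beta_cond, beta_zi = beta_zi,
                 sigma_resid = sigma_resid,
                 re_sd_cond = re_sd_cond, re_sd_zi = re_sd_zi),
            class = "zig_params")
}

# Third derivatives of the observation log-likelihood with respect to the
# two linear predictors, needed by the analytic gradient of the Laplace
# objective (the log-determinant term differentiates the curvature).
# Naming: Tccc = d^3 l / d eta_c^3, Tccz = d^3 l / d eta_c^2 d eta_z, etc.
#
# For zero observations everything is assembled from ratios R_* = f_*/f of
# derivatives of the mixture density f = p + (1-p) phi0, which are stable
# in the posterior weight w = (1-p) phi0 / f.
zig_obs_third_derivs <- function(eta_c, eta_z, y, is_zero, sigma) {
  n <- length(y)
  Tccc <- Tccz <- Tczz <- Tzzz <- numeric(n)
  s2 <- sigma^2
  p <- stats::plogis(eta_z)
  q <- stats::plogis(eta_z, lower.tail = FALSE)

  pos <- !is_zero
  if (any(pos)) Tzzz[pos] <- -p[pos] * q[pos] * (1 - 2 * p[pos])

  z <- is_zero
  if (any(z)) {
    mu <- eta_c[z]
    log_p <- stats::plogis(eta_z[z], log.p = TRUE)
    log_q <- stats::plogis(eta_z[z], log.p = TRUE, lower.tail = FALSE)
    lphi0 <- stats::dnorm(0, mu, sigma, log = TRUE)
    phi0 <- exp(lphi0)
    a <- pmax(log_p, log_q + lphi0)
    lf <- a + log(exp(log_p - a) + exp(log_q + lphi0 - a))
    w <- exp(log_q + lphi0 - lf)
    pz <- p[z]; qz <- q[z]
    one_phi <- 1 - phi0

    Rm <- -w * mu / s2
    Rz <- qz * (1 - w) * one_phi
    Rmm <- w * (mu^2 / s2^2 - 1 / s2)
    Rzz <- qz * (1 - w) * (1 - 2 * pz) * one_phi
    Rmz <- pz * w * mu / s2
    Rmmm <- w * (-mu^3 / s2^3 + 3 * mu / s2^2)
    Rmmz <- -pz * w * (mu^2 / s2^2 - 1 / s2)
    Rmzz <- (1 - 2 * pz) * Rmz
    Rzzz <- qz * (1 - w) * (1 - 6 * pz * qz) * one_phi

    Tccc[z] <- Rmmm - 3 * Rmm * Rm + 2 * Rm^3
    Tccz[z] <- Rmmz - (Rmm * Rz + 2 * Rmz * Rm) + 2 * Rm^2 * Rz
    Tczz[z] <- Rmzz - (2 * Rmz * Rz + Rzz * Rm) + 2 * Rm * Rz^2
    Tzzz[z] <- Rzzz - 3 * Rzz * Rz + 2 * Rz^3
  }
  list(ccc = Tccc, ccz = Tccz, czz = Tczz, zzz = Tzzz)
}

# Derivatives with respect to log sigma of the observation log-likelihood
# and of its first and second eta-derivatives; completes the analytic
# gradient of the Laplace objective in the residual-SD coordinate.
zig_obs_sigma_derivs <- function(eta_c, eta_z, y, is_zero, sigma) {
  n <- length(y)
  dl <- dgc <- dgz <- dhcc <- dhcz <- dhzz <- numeric(n)
  s2 <- sigma^2
  pos <- !is_zero
  if (any(pos)) {
    r <- (y[pos] - eta_c[pos])
    dl[pos] <- r^2 / s2 - 1
    dgc[pos] <- -2 * r / s2
    dhcc[pos] <- 2 / s2
  }
  z <- is_zero
  if (any(z)) {
    mu <- eta_c[z]
    log_p <- stats::plogis(eta_z[z], log.p = TRUE)
    log_q <- stats::plogis(eta_z[z], log.p = TRUE, lower.tail = FALSE)
    pz <- exp(log_p); qz <- exp(log_q)
    lphi0 <- stats::dnorm(0, mu, sigma, log = TRUE)
    phi0 <- exp(lphi0)
    a <- pmax(log_p, log_q + lphi0)
    lf <- a + log(exp(log_p - a) + exp(log_q + lphi0 - a))
    w <- exp(log_q + lphi0 - lf)
    c1 <- mu^2 / s2 - 1
    gc <- -w * mu / s2
    gz <- qz * (1 - w) * (1 - phi0)
    hcz <- qz * (1 - w) * (mu / s2) * (phi0 + w * (1 - phi0))
    dl[z] <- w * c1
    dgc[z] <- gc * ((1 - w) * c1 - 2)
    dgz[z] <- -qz * (1 - w) * c1 * (w * (1 - phi0) + phi0)
    dhcc[z] <- (1 - 2 * w) * w * (1 - w) * c1 * mu^2 / s2^2 -
      4 * w * (1 - w) * mu^2 / s2^2 - w * (1 - w) * c1 / s2 + 2 * w / s2
    dhzz[z] <- (1 - 2 * pz - 2 * gz) * dgz[z]
    dhcz[z] <- hcz * ((1 - 2 * w) * c1 - 2)
  }
  list(dl = dl, dgc = dgc, dgz = dgz, dhcc = dhcc, dhcz = dhcz, dhzz = dhzz)
}
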