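# Dense Gauss-Hermite quadrature oracle for the marginal likelihood on tiny
# instances. Used to validate the Laplace approximation; never used to fit.

#' Gauss-Hermite nodes and weights
#'
#' Golub-Welsch construction for the weight function `exp(-x^2)`: nodes are
#' eigenvalues of the symmetric tridiagonal Jacobi matrix with off-diagonal
#' `sqrt(i/2)`, weights come from the first components of its eigenvectors.
#'
#' @param n number of nodes.
#' @return list with `nodes` (ascending) and `weights`.
#' @export
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

# log-likelihood only (no derivatives); vectorized over observations
.zig_obs_loglik <- function(eta_c, eta_z, y, is_zero, sigma) {
  log_p <- stats::plogis(eta_z, log.p = TRUE)
  log_1mp <- stats::plogis(eta_z, log.p = TRUE, lower.tail = FALSE)
  out <- numeric(length(eta_c))
  pos <- !is_zero
  if (any(pos))
    out[pos] <- log_1mp[pos] +
      stats::dnorm(y[pos], eta_c[pos], sigma, log = TRUE)
  if (any(is_zero)) {
    lphi0 <- stats::dnorm(0, eta_c[is_zero], sigma, log = TRUE)
    a <- pmax(log_p[is_zero], log_1mp[is_zero] + lphi0)
    out[is_zero] <- a + log(exp(log_p[is_zero] - a) +
                              exp(log_1mp[is_zero] + lphi0 - a))
  }
  out
}

.logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# Adaptive GH integral of exp(Q(u)) over R^q, centred at mode uhat with
# curvature H (negative Hessian of Q at the mode). qfun(U) takes a q x m
# matrix of points and returns the m values Q(u). Chunked over node points.
.adaptive_ghq <- function(uhat, H, qfun, n_nodes, chunk = 20000L) {
  q <- length(uhat)
  gh <- gauss_hermite(n_nodes)
  R <- chol(as.matrix(H))
  Cmat <- backsolve(R, diag(q))          # C C^T = H^{-1}
  ld_half <- sum(log(diag(R)))
  idx <- do.call(expand.grid, rep(list(seq_len(n_nodes)), q))
  npts <- nrow(idx)
  pieces <- numeric(0)
  for (start in seq(1L, npts, by = chunk)) {
    sel <- start:min(start + chunk - 1L, npts)
    X <- matrix(gh$nodes[as.matrix(idx[sel, , drop = FALSE])],
                nrow = length(sel), ncol = q)
    logw <- rowSums(matrix(log(gh$weights)[as.matrix(idx[sel, , drop = FALSE])],
                           nrow = length(sel), ncol = q))
    U <- uhat + sqrt(2) * (Cmat %*% t(X))
    qv <- qfun(U)
    pieces <- c(pieces, .logsumexp(logw + qv + rowSums(X^2)))
  }
  (q / 2) * log(2) - ld_half + .logsumexp(pieces)
}

#' Brute-force marginal log-likelihood by dense Gauss-Hermite quadrature
#'
#' Independent oracle for [laplace_marginal_loglik()] on tiny instances:
#' integrates the random effects of [zig_joint_loglik()] out numerically
#' with adaptive (mode- and curvature-centred) Gauss-Hermite quadrature,
#' at least 50 nodes per dimension. With a single grouping factor the
#' integral factorizes over levels and each level is a 1- or 2-dimensional
#' integral; with two crossed factors a dense product rule over all
#' dimensions is used. Guarded to at most 2 grouping factors and 6 levels
#' in total (and at most 4 product-rule dimensions), because cost grows
#' exponentially. Test machinery; never part of fitting.
#'
#' @param params a [zig_params()].
#' @param design a `zig_design`.
#' @param n_nodes Gauss-Hermite nodes per dimension (default 50).
#' @return scalar marginal log-likelihood.
#' @export
brute_force_marginal_loglik <- function(params, design, n_nodes = 50L) {
  stopifnot(inherits(params, "zig_params"), inherits(design, "zig_design"))
  if (length(design$Z) > 2L)
    stop("brute force guard: at most 2 grouping factors")
  if (sum(vapply(design$Z, ncol, integer(1))) > 6L)
    stop("brute force guard: at most 6 levels in total")
  act <- .active_terms(params, design)
  layout <- .zig_layout(design, include_beta = FALSE,
                        active_cond = act$cond, active_zi = act$zi)
  off_c <- drop(design$X_cond %*% params$beta_cond)
  off_z <- drop(design$X_zi %*% params$beta_zi)
  sigma <- params$sigma_resid
  if (layout$d == 0L)
    return(sum(.zig_obs_loglik(off_c, off_z, design$y, design$is_zero, sigma)))

  prec <- .zig_prior_prec(layout, params$re_sd_cond, params$re_sd_zi)
  prior_const <- .prior_const(layout, params$re_sd_cond, params$re_sd_zi)
  inner <- .zig_inner(layout, off_c, off_z, design$y, design$is_zero, sigma,
                      prec, tol = 1e-10, maxit = 200L)
  n <- layout$n
  active_terms_all <- union(act$cond, act$zi)

  qfun_factory <- function(rows, cols, pconst) {
    Bsub <- layout$B[c(rows, n + rows), cols, drop = FALSE]
    yr <- design$y[rows]; zr <- design$is_zero[rows]
    oc <- off_c[rows]; oz <- off_z[rows]
    pr <- prec[cols]
    nr <- length(rows)
    function(U) {
      m <- ncol(U)
      E <- as.matrix(Bsub %*% U)              # 2nr x m
      ec <- E[seq_len(nr), , drop = FALSE] + oc
      ez <- E[nr + seq_len(nr), , drop = FALSE] + oz
      ll <- .zig_obs_loglik(as.vector(ec), as.vector(ez),
                            rep(yr, times = m), rep(zr, times = m), sigma)
      colSums(matrix(ll, nrow = nr)) -
        0.5 * colSums(pr * U^2) + pconst
    }
  }

  if (length(design$Z) == 1L && length(active_terms_all) == 1L) {
    # single grouping factor: the marginal factorizes over levels
    term <- active_terms_all
    Zt <- design$Z[[term]]
    total <- 0
    for (j in seq_len(ncol(Zt))) {
      rows <- which(Zt[, j] != 0)
      cols <- which(layout$terms == term &
                      layout$lev_names == colnames(Zt)[j])
      pc_j <- sum(vapply(cols, function(cc) {
        -0.5 * log(2 * pi) + 0.5 * log(prec[cc])
      }, numeric(1)))
      qf <- qfun_factory(rows, cols, pc_j)
      Hj <- inner$H[cols, cols, drop = FALSE]
      total <- total + .adaptive_ghq(inner$z[cols], Hj, qf, n_nodes)
    }
    # observations not tied to any level of the factor (all-zero Z rows)
    loose <- which(Matrix::rowSums(Zt != 0) == 0)
    if (length(loose))
      total <- total + sum(.zig_obs_loglik(off_c[loose], off_z[loose],
                                           design$y[loose],
                                           design$is_zero[loose], sigma))
    return(total)
  }

  if (layout$d > 4L)
    stop("brute force guard: dense product rule limited to 4 dimensions ",
         "(crossed factors); got ", layout$d)
  qf <- qfun_factory(seq_len(n), seq_len(layout$d), prior_const)
  .adaptive_ghq(inner$z, inner$H, qf, n_nodes)
}
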