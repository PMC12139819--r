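# Analytic gradient of the Laplace objective
#
# L(beta, log sigma, log tau) = Q(u_hat) + prior_const
#                               + (q/2) log 2pi - 0.5 logdet H(u_hat)
# with u_hat the inner mode. By the envelope theorem the Q term
# differentiates as the partial derivative at fixed u; the log-determinant
# contributes a direct term tr(H^-1 dH/dtheta) and an indirect term through
# the mode shift du_hat/dtheta = H^-1 dF/dtheta. Both traces contract
# per-observation 2x2 blocks G_i of B_u H^-1 B_u^T — obtained from the
# Takahashi selected inverse of H — against third derivatives of the
# observation log-likelihood. The log sigma coordinate is differenced
# numerically by the caller (its analytic form adds little and the
# remaining coordinates dominate the cost).

# Precomputed gather indices mapping per-observation level pairs to
# positions in the selected-inverse value vector. Pattern-stable across
# parameter values because the Hessian pattern and fill-reducing
# permutation depend only on the design.
.zig_gather_index <- function(layout_u, design, si, terms, zi_terms) {
  q <- layout_u$d
  n <- layout_u$n
  perm1 <- si$perm + 1L
  pinv <- match(seq_len(q), perm1)
  Lkeys <- as.numeric(si$Li) +
    q * rep(seq_len(q) - 1, diff(si$Lp))          # (row0) + q * col0
  miss <- length(si$Sx) + 1L

  col_of <- function(part_kind, tms) {
    if (!length(tms)) return(matrix(integer(), n, 0))
    out <- matrix(0L, n, length(tms))
    for (k in seq_along(tms)) {
      sel <- which(layout_u$kinds == part_kind & layout_u$terms == tms[k])
      Zt <- design$Z[[tms[k]]]
      lev <- as.integer(Zt %*% seq_len(ncol(Zt)))
      out[, k] <- sel[lev]
    }
    out
  }
  Acols <- col_of("u_c", terms)
  Zcols <- col_of("u_z", zi_terms)

  pair_idx <- function(M1, M2) {
    k1 <- ncol(M1); k2 <- ncol(M2)
    if (!k1 || !k2) return(matrix(miss, n, 0))
    A2 <- M1[, rep(seq_len(k1), each = k2), drop = FALSE]
    B2 <- M2[, rep(seq_len(k2), times = k1), drop = FALSE]
    pa <- matrix(pinv[A2], n); pb <- matrix(pinv[B2], n)
    r <- pmax(pa, pb); cc <- pmin(pa, pb)
    key <- as.numeric(r - 1) + q * as.numeric(cc - 1)
    idx <- match(key, Lkeys)
    idx[is.na(idx)] <- miss                        # structurally absent:
    matrix(idx, n)                                 # contraction weight is 0
  }
  list(cc = pair_idx(Acols, Acols), zz = pair_idx(Zcols, Zcols),
       cz = pair_idx(Acols, Zcols),
       diag = si$Lp[pinv] + 1L, nnz = length(si$Sx), miss = miss)
}

# Gradient with respect to (beta_cond, beta_zi if enabled, log re_sds),
# i.e. every outer coordinate except log sigma. `inn` must hold the inner
# solution at the evaluation point (z, derivs, eta, Ch); offc/offz the
# fixed-effect offsets; ps the sigma/SD list; prec the prior precisions.
.zig_analytic_gradient <- function(st, layout_u, design, zi_enabled,
                                   terms, zi_terms) {
  inn <- st$inner
  ps <- st$ps
  prec <- st$prec
  n <- layout_u$n
  q <- layout_u$d
  d <- inn$derivs
  ec <- st$offc + inn$eta[seq_len(n)]
  ez <- st$offz + inn$eta[n + seq_len(n)]
  T3 <- zig_obs_third_derivs(ec, ez, design$y, design$is_zero, ps$sigma)
  SD <- zig_obs_sigma_derivs(ec, ez, design$y, design$is_zero, ps$sigma)
  si <- .selected_inverse(inn$Ch)
  if (is.null(st$gidx) || st$gidx$nnz != length(si$Sx))
    st$gidx <- .zig_gather_index(layout_u, design, si, terms, zi_terms)
  gx <- st$gidx
  Sx0 <- c(si$Sx, 0)
  gather <- function(idx) if (ncol(idx)) rowSums(matrix(Sx0[idx], n)) else
    numeric(n)
  Gcc <- gather(gx$cc)
  Gzz <- gather(gx$zz)
  Gcz <- gather(gx$cz)
  Sdiag <- Sx0[gx$diag]

  wc <- Gcc * T3$ccc + 2 * Gcz * T3$ccz + Gzz * T3$czz
  wz <- Gcc * T3$ccz + 2 * Gcz * T3$czz + Gzz * T3$zzz

  Xc <- design$X_cond
  Xz <- design$X_zi
  env_bc <- drop(crossprod(Xc, d$gc))
  dir_bc <- 0.5 * drop(crossprod(Xc, wc))
  V_list <- list(layout_u$Bt %*% rbind(d$hcc * Xc, d$hcz * Xc))
  if (zi_enabled) {
    env_bz <- drop(crossprod(Xz, d$gz))
    dir_bz <- 0.5 * drop(crossprod(Xz, wz))
    V_list <- c(V_list, list(layout_u$Bt %*% rbind(d$hcz * Xz, d$hzz * Xz)))
  }

  # log sigma coordinate
  env_sig <- sum(SD$dl)
  dir_sig <- 0.5 * sum(Gcc * SD$dhcc + 2 * Gcz * SD$dhcz + Gzz * SD$dhzz)
  V_list <- c(V_list, list(layout_u$Bt %*% cbind(c(SD$dgc, SD$dgz))))

  # log tau coordinates, ordered as in phi (cond terms then zi terms)
  u <- inn$z
  tau_keys <- c(paste0("u_c.", terms),
                if (zi_enabled && length(zi_terms)) paste0("u_z.", zi_terms))
  env_tau <- dir_tau <- numeric(length(tau_keys))
  V_tau <- matrix(0, q, length(tau_keys))
  for (k in seq_along(tau_keys)) {
    kk <- strsplit(tau_keys[k], ".", fixed = TRUE)[[1]]
    mask <- layout_u$kinds == kk[1] & layout_u$terms == kk[2]
    env_tau[k] <- sum(u[mask]^2 * prec[mask]) - sum(mask)
    dir_tau[k] <- sum(prec[mask] * Sdiag[mask])
    V_tau[mask, k] <- 2 * prec[mask] * u[mask]
  }

  V <- cbind(as.matrix(do.call(cbind, V_list)), V_tau)
  Delta <- as.matrix(Matrix::solve(inn$Ch, V, system = "A"))
  dEta <- as.matrix(layout_u$B %*% Delta)
  ind <- 0.5 * drop(crossprod(dEta, c(wc, wz)))

  k_c <- ncol(Xc)
  g_bc <- env_bc + dir_bc + ind[seq_len(k_c)]
  ofs <- k_c
  if (zi_enabled) {
    k_z <- ncol(Xz)
    g_bz <- env_bz + dir_bz + ind[ofs + seq_len(k_z)]
    ofs <- ofs + k_z
  } else g_bz <- NULL
  g_sig <- env_sig + dir_sig + ind[ofs + 1L]
  ofs <- ofs + 1L
  g_tau <- env_tau + dir_tau + ind[ofs + seq_along(tau_keys)]
  list(bc = g_bc, bz = g_bz, sigma = g_sig, tau = g_tau)
}
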