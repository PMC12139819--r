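#' Save / load a fitted model as JSON
#'
#' Serializes everything needed to predict without refitting: parameters,
#' the joint fixed-effect covariance, random-effect modes, scaling
#' divisors, the model specification and convergence information.
#'
#' @param fit a `fitted_zig`.
#' @param path output path.
#' @return `write_zig_fit` returns `path` invisibly; `read_zig_fit` the
#'   restored `fitted_zig`.
#' @export
write_zig_fit <- function(fit, path) {
  stopifnot(inherits(fit, "fitted_zig"))
  obj <- list(
    beta_cond = as.list(fit$params$beta_cond),
    beta_zi = as.list(fit$params$beta_zi),
    sigma_resid = fit$params$sigma_resid,
    re_sd_cond = as.list(fit$params$re_sd_cond),
    re_sd_zi = as.list(fit$params$re_sd_zi),
    vcov_fixed = list(names = rownames(fit$vcov_fixed),
                      values = fit$vcov_fixed),
    re_modes = lapply(fit$re_modes, function(part) lapply(part, as.list)),
    loglik = fit$loglik, converged = fit$converged,
    boundary_terms = fit$boundary_terms,
    n_obs = fit$n_obs, scaling = fit$scaling,
    spec = unclass(fit$spec), levels = fit$levels,
    zi_enabled = isTRUE(fit$zi_enabled),
    convergence_log = fit$convergence_log)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_zig_fit
#' @export
read_zig_fit <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  vc <- as.matrix(o$vcov_fixed$values)
  dimnames(vc) <- list(o$vcov_fixed$names, o$vcov_fixed$names)
  re_modes <- lapply(o$re_modes, function(part)
    lapply(part, function(v) unlist(v)))
  params <- zig_params(beta_cond = unlist(o$beta_cond),
                       beta_zi = unlist(o$beta_zi),
                       sigma_resid = o$sigma_resid,
                       re_sd_cond = unlist(o$re_sd_cond),
                       re_sd_zi = unlist(o$re_sd_zi))
  structure(list(params = params, vcov_fixed = vc, re_modes = re_modes,
                 loglik = o$loglik, converged = o$converged,
                 boundary_terms = o$boundary_terms,
                 convergence_log = as.data.frame(o$convergence_log),
                 n_obs = o$n_obs, scaling = as.list(o$scaling),
                 spec = model_spec(o$spec$variant,
                                   unlist(o$spec$random_terms),
                                   o$spec$zi_same_formula),
                 levels = lapply(o$levels, unlist),
                 zi_enabled = isTRUE(o$zi_enabled)),
            class = "fitted_zig")
}
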