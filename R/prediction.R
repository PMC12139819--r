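#' Predict growth, mortality and overall fitness for new covariates
#'
#' Applies a fitted zero-inflated Gaussian model to arbitrary covariate
#' combinations. Covariates are given on their raw scales and divided by
#' the training scaling factors stored in the fit. Predictions can be
#' population-level (fixed effects only, random effects set to zero: the
#' default) or can add the conditional modes of known random-effect levels;
#' levels unseen in training contribute zero deviation.
#'
#' @param fit a `fitted_zig`.
#' @param newdata data frame with columns `garden_mcmt`, `home_mcmt`,
#'   `pc1`, `pc2`, `pc3` (raw scales); optionally `genotype_id`,
#'   `garden_id`, `block_id`, `year`, `individual_id` for random-effect
#'   lookups.
#' @param include_random_effects logical; add conditional modes for known
#'   levels (default `FALSE`).
#' @param transform back-transform for the growth response:
#'   `"naive"` is `exp(eta) - 1` (plug-in inverse of `log(growth + 1)`);
#'   `"lognormal_mean"` is `exp(eta + sigma^2 / 2) - 1` (conditional mean
#'   under the lognormal error).
#' @param extrapolation_bounds optional length-2 numeric; a warning
#'   attribute is attached when `garden_mcmt` falls outside these bounds
#'   (prediction still proceeds).
#' @return data frame with `eta_cond` (predicted mean of `log(growth+1)`),
#'   `growth_response` (back-transformed growth, cm), `p_mortality`, and
#'   `overall` = `(1 - p_mortality) * growth_response`.
#' @export
predict_components <- function(fit, newdata, include_random_effects = FALSE,
                               transform = c("naive", "lognormal_mean"),
                               extrapolation_bounds = NULL) {
  stopifnot(inherits(fit, "fitted_zig"))
  transform <- match.arg(transform)
  need <- c("garden_mcmt", "home_mcmt", "pc1", "pc2", "pc3")
  miss <- setdiff(need, names(newdata))
  if (length(miss)) stop("newdata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(vapply(newdata[need], function(x) all(is.finite(x)), logical(1))))
    stop("newdata covariates must be finite")
  X <- design_row_matrix(fit$scaling, fit$spec$variant, newdata$garden_mcmt,
                         newdata$home_mcmt, newdata$pc1, newdata$pc2,
                         newdata$pc3)
  eta_c <- drop(X %*% fit$params$beta_cond)
  eta_z <- drop(X %*% fit$params$beta_zi)
  if (include_random_effects) {
    key_cols <- c(genotype = "genotype_id", garden = "garden_id",
                  year = "year", individual = "individual_id")
    for (term in names(fit$re_modes$cond)) {
      keys <- .re_level_keys(term, newdata, key_cols)
      if (is.null(keys)) next
      eta_c <- eta_c + .re_lookup(fit$re_modes$cond[[term]], keys)
      if (isTRUE(fit$zi_enabled) && !is.null(fit$re_modes$zi[[term]]))
        eta_z <- eta_z + .re_lookup(fit$re_modes$zi[[term]], keys)
    }
  }
  p <- stats::plogis(eta_z)
  growth <- switch(transform,
                   naive = exp(eta_c) - 1,
                   lognormal_mean = exp(eta_c + fit$params$sigma_resid^2 / 2) - 1)
  out <- data.frame(eta_cond = eta_c, growth_response = growth,
                    p_mortality = p, overall = (1 - p) * growth)
  if (!is.null(extrapolation_bounds)) {
    outside <- newdata$garden_mcmt < extrapolation_bounds[1] |
      newdata$garden_mcmt > extrapolation_bounds[2]
    if (any(outside)) {
      warning(sum(outside), " prediction point(s) outside the extrapolation",
              " guard [", extrapolation_bounds[1], ", ",
              extrapolation_bounds[2], "] degrees C")
      attr(out, "extrapolated") <- outside
    }
  }
  out
}

.re_level_keys <- function(term, newdata, key_cols) {
  if (term == "block_in_garden") {
    if (!all(c("garden_id", "block_id") %in% names(newdata))) return(NULL)
    return(paste(newdata$garden_id, newdata$block_id, sep = ":"))
  }
  col <- key_cols[[term]]
  if (is.null(col) || !(col %in% names(newdata))) return(NULL)
  as.character(newdata[[col]])
}

.re_lookup <- function(modes, keys) {
  v <- modes[keys]
  v[is.na(v)] <- 0  # unseen levels: zero deviation
  unname(v)
}

#' Genotype-specific reaction norm over a winter-temperature gradient
#'
#' Predicts a genotype's growth, mortality probability and overall fitness
#' proxy over an equally spaced grid of garden MCMT values, holding the
#' genotype's home climate and genomic PCs fixed. Predictions are
#' population-level (random effects zero). The optimum temperatures are the
#' grid argmaxes of the overall and growth responses; ties break toward the
#' lower temperature.
#'
#' @param fit a `fitted_zig`.
#' @param genotype one-row data frame (or list) with `home_mcmt`, `pc1`,
#'   `pc2`, `pc3` and optionally `genotype_id`, `ancestry_q`.
#' @param grid_min,grid_max gradient end points, degrees C. Defaults span
#'   the home and garden climates of the motivating trial network
#'   (-23.9 to 9.8).
#' @param n_points number of grid points (default 100), end points
#'   included.
#' @param transform growth back-transform, see [predict_components()].
#' @return A `reaction_norm`: data frame with `mcmt`, `eta_cond`,
#'   `growth_response`, `p_mortality`, `overall`; attributes
#'   `t_opt_overall`, `t_opt_growth`, `genotype_id`, `ancestry_q`.
#' @export
reaction_norm <- function(fit, genotype, grid_min = -23.9, grid_max = 9.8,
                          n_points = 100L, transform = "naive") {
  stopifnot(n_points >= 2L, grid_min < grid_max)
  grid <- seq(grid_min, grid_max, length.out = n_points)
  nd <- data.frame(garden_mcmt = grid,
                   home_mcmt = genotype$home_mcmt,
                   pc1 = genotype$pc1, pc2 = genotype$pc2,
                   pc3 = genotype$pc3)
  pr <- predict_components(fit, nd, include_random_effects = FALSE,
                           transform = transform)
  out <- cbind(data.frame(mcmt = grid), pr)
  attr(out, "t_opt_overall") <- grid[which.max(pr$overall)]
  attr(out, "t_opt_growth") <- grid[which.max(pr$growth_response)]
  attr(out, "genotype_id") <- if (!is.null(genotype$genotype_id))
    as.character(genotype$genotype_id) else NA_character_
  attr(out, "ancestry_q") <- if (!is.null(genotype$ancestry_q))
    genotype$ancestry_q else NA_real_
  attr(out, "home_mcmt") <- genotype$home_mcmt
  class(out) <- c("reaction_norm", "data.frame")
  out
}

#' Reaction norms for every genotype of a trial
#'
#' @param fit a `fitted_zig`.
#' @param genotypes data frame of genotype records (`genotype_id`,
#'   `home_mcmt`, `pc1`..`pc3`, optionally `ancestry_q`).
#' @param ... passed to [reaction_norm()].
#' @return tidy data frame stacking the per-genotype norms, with
#'   `genotype_id` and `ancestry_q` columns.
#' @export
reaction_norms <- function(fit, genotypes, ...) {
  out <- lapply(seq_len(nrow(genotypes)), function(i) {
    rn <- reaction_norm(fit, genotypes[i, ], ...)
    cbind(data.frame(genotype_id = genotypes$genotype_id[i],
                     ancestry_q = if ("ancestry_q" %in% names(genotypes))
                       genotypes$ancestry_q[i] else NA_real_),
          as.data.frame(rn))
  })
  do.call(rbind, out)
}

#' Re-index a reaction norm by transfer distance
#'
#' Transfer distance is garden MCMT minus the genotype's home MCMT: zero
#' marks a planting climate matching the climate of origin, positive values
#' warmer plantings. The predictions themselves are unchanged.
#'
#' @param norm a `reaction_norm`.
#' @param home_mcmt the genotype's home MCMT; defaults to the value stored
#'   in the norm.
#' @return the same data frame with a `transfer_distance` column prepended.
#' @export
transfer_distance_view <- function(norm, home_mcmt = attr(norm, "home_mcmt")) {
  stopifnot(inherits(norm, "reaction_norm"), is.finite(home_mcmt))
  out <- cbind(data.frame(transfer_distance = norm$mcmt - home_mcmt),
               as.data.frame(norm))
  attr(out, "t_opt_overall") <- attr(norm, "t_opt_overall") - home_mcmt
  attr(out, "t_opt_growth") <- attr(norm, "t_opt_growth") - home_mcmt
  out
}

#' Plot reaction norms coloured by species ancestry
#'
#' @param x tidy norms from [reaction_norms()].
#' @param component which prediction to draw.
#' @param ... further arguments to [graphics::matplot()].
#' @return invisibly, the matrix of plotted curves.
#' @export
plot_reaction_norms <- function(x, component = c("overall", "growth_response",
                                                 "p_mortality"), ...) {
  component <- match.arg(component)
  ids <- unique(x$genotype_id)
  grid <- sort(unique(x$mcmt))
  m <- vapply(ids, function(g)
    x[[component]][x$genotype_id == g][order(x$mcmt[x$genotype_id == g])],
    numeric(length(grid)))
  qv <- vapply(ids, function(g) x$ancestry_q[x$genotype_id == g][1], numeric(1))
  pal <- grDevices::colorRampPalette(c("#2166ac", "#66c2a5"))(101)
  cols <- pal[pmin(100, pmax(0, round(qv * 100))) + 1]
  graphics::matplot(grid, m, type = "l", lty = 1, col = cols,
                    xlab = "garden MCMT (deg C)", ylab = component, ...)
  invisible(m)
}
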