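#' Specify a growth/mortality model variant
#'
#' Three variants of the trial model are supported. The `full` variant
#' crosses garden winter temperature (MCMT) and home MCMT with their squares
#' and adds three genomic PC axes and their interactions with garden MCMT
#' and its square. `genetics_only` drops every home-MCMT term (testing
#' whether genomic structure alone carries the provenance signal);
#' `climate_only` drops every PC term (testing home climate as a proxy for
#' genotype). The zero-inflation (mortality) part uses the same fixed-effect
#' formula by default.
#'
#' @param variant one of `"full"`, `"genetics_only"`, `"climate_only"`.
#' @param random_terms grouping factors for random intercepts; any subset of
#'   `c("genotype", "garden", "block_in_garden", "year", "individual")`.
#' @param zi_same_formula logical; use the same fixed-effect columns for the
#'   zero-inflation part (default `TRUE`).
#' @param zi_random_terms grouping factors for the zero-inflation part's
#'   random intercepts; defaults to `random_terms` (the same grouping
#'   structure in both parts). May be a subset, including `character()`
#'   for a zero-inflation part with fixed effects only.
#' @return A `model_spec` object.
#' @export
model_spec <- function(variant = c("full", "genetics_only", "climate_only"),
                       random_terms = c("genotype", "garden",
                                        "block_in_garden", "year",
                                        "individual"),
                       zi_same_formula = TRUE,
                       zi_random_terms = random_terms) {
  variant <- match.arg(variant)
  allowed <- c("genotype", "garden", "block_in_garden", "year", "individual")
  random_terms <- match.arg(random_terms, allowed, several.ok = TRUE)
  if (length(random_terms) == 0L) stop("random_terms must be non-empty")
  if (length(zi_random_terms))
    zi_random_terms <- match.arg(zi_random_terms, allowed, several.ok = TRUE)
  if (!all(zi_random_terms %in% random_terms))
    stop("zi_random_terms must be a subset of random_terms")
  structure(list(variant = variant, random_terms = random_terms,
                 zi_same_formula = isTRUE(zi_same_formula),
                 zi_random_terms = zi_random_terms),
            class = "model_spec")
}

#' Serialize / restore a model specification
#'
#' @param spec a `model_spec`.
#' @param path file path for the YAML document.
#' @return `write_model_spec` returns `path` invisibly; `read_model_spec`
#'   returns the restored `model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- yaml::read_yaml(path)
  zrt <- if (is.null(x$zi_random_terms)) character() else
    unlist(x$zi_random_terms)
  model_spec(variant = x$variant, random_terms = unlist(x$random_terms),
             zi_same_formula = isTRUE(x$zi_same_formula),
             zi_random_terms = zrt)
}

#' Scale a covariate without centering
#'
#' Root-mean-square scaling as done by `scale(x, center = FALSE)`: the
#' divisor is `sqrt(sum(x^2) / (n - 1))`. The divisor is returned so scaled
#' values can be inverted exactly; model predictions for new data must reuse
#' the training divisors.
#'
#' @param values numeric vector, length >= 2, not all zero.
#' @return list with `scaled` and `divisor`.
#' @seealso [unscale()]
#' @export
scale_no_center <- function(values) {
  if (length(values) < 2L)
    stop("scale_no_center needs at least 2 values")
  if (anyNA(values) || !all(is.finite(values)))
    stop("scale_no_center: values must be finite")
  divisor <- sqrt(sum(values^2) / (length(values) - 1))
  if (divisor <= .Machine$double.eps)
    stop("scale_no_center: all-zero vector is degenerate")
  list(scaled = values / divisor, divisor = divisor)
}

#' Invert non-centered scaling
#' @param scaled scaled values.
#' @param divisor divisor recorded by [scale_no_center()].
#' @return the original-scale values.
#' @export
unscale <- function(scaled, divisor) scaled * divisor

# Stable fixed-effect column names per variant. Shorthand: gmt/hmt are the
# RMS-scaled garden and home MCMT; squares are of the scaled values.
design_colnames <- function(variant) {
  full <- c("(Intercept)", "gmt", "hmt", "gmt2", "hmt2", "gmt:hmt",
            "gmt2:hmt2", "gmt2:hmt", "gmt:hmt2", "pc1", "pc2", "pc3",
            "pc1:gmt", "pc2:gmt", "pc3:gmt", "pc1:gmt2", "pc2:gmt2",
            "pc3:gmt2")
  switch(variant,
         full = full,
         genetics_only = full[!grepl("hmt", full)],
         climate_only = full[!grepl("pc", full)])
}

# Fixed-effect design rows from raw-scale covariates, applying recorded
# divisors. All inputs are recycled to a common length.
design_row_matrix <- function(scaling, variant, garden_mcmt, home_mcmt,
                              pc1, pc2, pc3) {
  n <- max(length(garden_mcmt), length(home_mcmt), length(pc1))
  g <- rep_len(garden_mcmt, n) / scaling$garden_mcmt
  h <- rep_len(home_mcmt, n) / scaling$home_mcmt
  p1 <- rep_len(pc1, n) / scaling$pc1
  p2 <- rep_len(pc2, n) / scaling$pc2
  p3 <- rep_len(pc3, n) / scaling$pc3
  cols <- list("(Intercept)" = rep(1, n), "gmt" = g, "hmt" = h,
               "gmt2" = g^2, "hmt2" = h^2, "gmt:hmt" = g * h,
               "gmt2:hmt2" = g^2 * h^2, "gmt2:hmt" = g^2 * h,
               "gmt:hmt2" = g * h^2, "pc1" = p1, "pc2" = p2, "pc3" = p3,
               "pc1:gmt" = p1 * g, "pc2:gmt" = p2 * g, "pc3:gmt" = p3 * g,
               "pc1:gmt2" = p1 * g^2, "pc2:gmt2" = p2 * g^2,
               "pc3:gmt2" = p3 * g^2)
  keep <- design_colnames(variant)
  m <- do.call(cbind, cols[keep])
  colnames(m) <- keep
  m
}

#' Expand a trial dataset into model design matrices
#'
#' Builds the response `y = log(growth + 1)`, the structural-zero indicator,
#' the fixed-effect matrices for the conditional (growth) and zero-inflation
#' (mortality) parts, and sparse random-intercept indicator blocks for the
#' requested grouping factors. Numeric covariates are scaled by their
#' root-mean-square ([scale_no_center()]); squares and interactions are
#' formed from the scaled values and are not rescaled. Blocks are coded as
#' garden-specific levels (block "A" in two gardens is two levels),
#' implementing nesting of block within garden.
#'
#' @param data a `trial_dataset` with QC applied.
#' @param spec a `model_spec`.
#' @param scaling optional list of divisors (`garden_mcmt`, `home_mcmt`,
#'   `pc1`, `pc2`, `pc3`) from a training fit; when `NULL`, divisors are
#'   computed from `data`. Always pass training divisors when building a
#'   design for held-out data.
#' @return A `zig_design` object.
#' @export
build_design <- function(data, spec = model_spec(), scaling = NULL) {
  stopifnot(inherits(data, "trial_dataset"), inherits(spec, "model_spec"))
  obs <- data$observations
  if (nrow(obs) == 0L) stop("empty dataset")
  gi <- match(obs$genotype_id, data$genotypes$genotype_id)
  gk <- match(paste(obs$garden_id, obs$year),
              paste(data$gardens$garden_id, data$gardens$year))
  cov <- data.frame(
    garden_mcmt = data$gardens$garden_mcmt[gk],
    home_mcmt = data$genotypes$home_mcmt[gi],
    pc1 = data$genotypes$pc1[gi],
    pc2 = data$genotypes$pc2[gi],
    pc3 = data$genotypes$pc3[gi])
  need <- switch(spec$variant, climate_only = c("garden_mcmt", "home_mcmt"),
                 genetics_only = c("garden_mcmt", "pc1", "pc2", "pc3"),
                 names(cov))
  for (v in need) if (anyNA(cov[[v]]))
    stop("covariate '", v, "' has missing values; variant '", spec$variant,
         "' cannot be built")

  check_rank <- is.null(scaling)
  if (check_rank) {
    scaling <- lapply(cov, function(x) scale_no_center(x)$divisor)
  }
  X <- design_row_matrix(scaling, spec$variant, cov$garden_mcmt,
                         cov$home_mcmt, cov$pc1, cov$pc2, cov$pc3)
  if (check_rank) {
    # rank is only required of training designs; held-out designs reuse
    # a training fit's scaling and may have too few rows to be full rank
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      stop("fixed-effect design is rank deficient; collinear column(s): ",
           paste(drop_cols, collapse = ", "))
    }
  }

  groups <- list(
    genotype = obs$genotype_id,
    garden = obs$garden_id,
    block_in_garden = paste(obs$garden_id, obs$block_id, sep = ":"),
    year = as.character(obs$year),
    individual = obs$individual_id)[spec$random_terms]
  Z <- list(); levels_list <- list()
  for (term in names(groups)) {
    f <- factor(groups[[term]])
    levels_list[[term]] <- levels(f)
    Z[[term]] <- Matrix::sparseMatrix(
      i = seq_along(f), j = as.integer(f), x = 1,
      dims = c(length(f), nlevels(f)),
      dimnames = list(NULL, levels(f)))
  }

  y <- log(obs$growth_increment_cm + 1)
  structure(list(
    y = y, is_zero = obs$growth_increment_cm == 0,
    X_cond = X, X_zi = if (spec$zi_same_formula) X else X[, "(Intercept)", drop = FALSE],
    Z = Z, levels = levels_list, scaling = scaling, spec = spec,
    covariates = cov,
    obs_keys = obs[, c("individual_id", "genotype_id", "garden_id",
                       "block_id", "year")]),
    class = "zig_design")
}
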