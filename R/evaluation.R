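#' Pearson prediction ability
#'
#' Correlation between observed and predicted values, optionally after
#' removing pairs whose observed value is zero (dead trees, which the
#' zero-inflation part accounts for). An undefined correlation (fewer than
#' 3 retained pairs, or a constant vector) is reported as `NA`, never as 0.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @param exclude_zero_observed drop pairs with `observed == 0` before
#'   correlating (the convention for conditional-model evaluation).
#' @return list with `r` and `n` (pairs used).
#' @export
prediction_ability <- function(observed, predicted,
                               exclude_zero_observed = FALSE) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  keep <- is.finite(observed) & is.finite(predicted)
  if (exclude_zero_observed) keep <- keep & observed != 0
  o <- observed[keep]; p <- predicted[keep]
  if (length(o) < 3L || stats::sd(o) == 0 || stats::sd(p) == 0)
    return(list(r = NA_real_, n = length(o), undefined = TRUE))
  list(r = stats::cor(o, p), n = length(o), undefined = FALSE)
}

.subset_trial <- function(data, keep_obs) {
  out <- data
  out$observations <- data$observations[keep_obs, , drop = FALSE]
  out
}

#' Leave-one-garden-out cross-validation
#'
#' For each garden in turn, the model is trained on all other gardens
#' (covariate scaling recomputed on the training data only, so no
#' information leaks from the held-out garden) and used to predict the
#' held-out garden's observations for each year. Predictions for the unseen
#' garden and its blocks use zero random-effect deviation; with
#' `with_random_effects = TRUE` the known genotype and year modes are
#' added. Two prediction abilities are reported per garden x year x
#' variant: the conditional ability (observed zeros excluded) and the
#' overall ability (dead trees included as observed 0 and predicted
#' `(1 - p) * growth`).
#'
#' @param data a QC'd `trial_dataset`.
#' @param specs named list of [model_spec()] variants to evaluate.
#' @param control a [zig_control()].
#' @param with_random_effects logical vector; evaluate with and/or without
#'   known-level random effects.
#' @param scale `"log"` evaluates on the model scale (`log(growth + 1)`),
#'   `"response"` on back-transformed growth (cm).
#' @param transform growth back-transform for `scale = "response"`.
#' @return A `cv_result` data frame. Folds whose fit errored have `NA`
#'   correlations; folds whose fit returned but did not satisfy the
#'   convergence check still report their prediction abilities and are
#'   marked `fold_ok = FALSE`.
#' @export
leave_one_garden_out <- function(data, specs = list(full = model_spec("full")),
                                 control = zig_control(),
                                 with_random_effects = FALSE,
                                 scale = c("log", "response"),
                                 transform = "naive") {
  stopifnot(inherits(data, "trial_dataset"))
  scale <- match.arg(scale)
  if (is.null(names(specs)) || any(names(specs) == ""))
    names(specs) <- vapply(specs, function(s) s$variant, character(1))
  gardens <- sort(unique(data$observations$garden_id))
  if (length(gardens) < 3L) stop("need at least 3 gardens for cross-validation")
  rows <- list()
  for (g in gardens) {
    test_idx <- data$observations$garden_id == g
    train <- .subset_trial(data, !test_idx)
    test_obs <- data$observations[test_idx, , drop = FALSE]
    gi <- match(test_obs$genotype_id, data$genotypes$genotype_id)
    gk <- match(paste(test_obs$garden_id, test_obs$year),
                paste(data$gardens$garden_id, data$gardens$year))
    for (vn in names(specs)) {
      fit <- tryCatch(
        suppressWarnings(fit_zig(build_design(train, specs[[vn]]), control)),
        error = function(e) NULL)
      fold_ok <- !is.null(fit) && isTRUE(fit$converged)
      usable <- !is.null(fit)
      for (re in with_random_effects) {
        for (yr in sort(unique(test_obs$year))) {
          sel <- test_obs$year == yr
          row <- data.frame(garden_id = g, year = yr, variant = vn,
                            with_random_effects = re, scale = scale,
                            n_predicted = sum(sel),
                            pearson_r_conditional = NA_real_,
                            n_conditional = NA_integer_,
                            pearson_r_overall = NA_real_,
                            n_overall = NA_integer_, fold_ok = fold_ok)
          if (usable && sum(sel) >= 3L) {
            nd <- data.frame(
              garden_mcmt = data$gardens$garden_mcmt[gk[sel]],
              home_mcmt = data$genotypes$home_mcmt[gi[sel]],
              pc1 = data$genotypes$pc1[gi[sel]],
              pc2 = data$genotypes$pc2[gi[sel]],
              pc3 = data$genotypes$pc3[gi[sel]],
              genotype_id = test_obs$genotype_id[sel],
              garden_id = test_obs$garden_id[sel],
              block_id = test_obs$block_id[sel],
              year = test_obs$year[sel],
              individual_id = test_obs$individual_id[sel])
            pr <- predict_components(fit, nd, include_random_effects = re,
                                     transform = transform)
            if (scale == "log") {
              obs <- log(test_obs$growth_increment_cm[sel] + 1)
              pred_cond <- pr$eta_cond
              pred_overall <- (1 - pr$p_mortality) * pr$eta_cond
            } else {
              obs <- test_obs$growth_increment_cm[sel]
              pred_cond <- pr$growth_response
              pred_overall <- pr$overall
            }
            pc <- prediction_ability(obs, pred_cond,
                                     exclude_zero_observed = TRUE)
            po <- prediction_ability(obs, pred_overall,
                                     exclude_zero_observed = FALSE)
            row$pearson_r_conditional <- pc$r
            row$n_conditional <- pc$n
            row$pearson_r_overall <- po$r
            row$n_overall <- po$n
          }
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cv_result", "data.frame")
  out
}

#' Paired comparison of two model variants' fold scores
#'
#' Exact two-sided Wilcoxon signed-rank test on per-(garden, year) fold
#' prediction abilities, pairing folds by their keys. Zero differences are
#' dropped before ranking (the exact-conditional convention) and counted;
#' with no nonzero differences the comparison is degenerate and `p = 1` is
#' reported with a warning. A paired t-test is available as an alternative.
#'
#' @param a,b `cv_result` tables sharing (garden_id, year,
#'   with_random_effects) keys.
#' @param value which fold score to compare.
#' @param method `"wilcoxon"` (exact signed rank, default) or `"t"`.
#' @return list with `statistic`, `p`, `n_pairs` (nonzero differences),
#'   `n_zero_dropped`, `method`.
#' @export
compare_model_variants <- function(a, b,
                                   value = c("pearson_r_conditional",
                                             "pearson_r_overall"),
                                   method = c("wilcoxon", "t")) {
  value <- match.arg(value)
  method <- match.arg(method)
  key <- function(x) paste(x$garden_id, x$year, x$with_random_effects,
                           sep = "\r")
  ka <- key(a); kb <- key(b)
  shared <- intersect(ka, kb)
  if (length(shared) == 0L) stop("no shared (garden, year) keys to pair")
  va <- a[[value]][match(shared, ka)]
  vb <- b[[value]][match(shared, kb)]
  ok <- is.finite(va) & is.finite(vb)
  d <- va[ok] - vb[ok]
  nz <- d != 0
  if (sum(ok) < 5L) stop("need at least 5 paired fold scores")
  if (!any(nz)) {
    warning("all paired differences are zero; comparison is degenerate")
    return(list(statistic = NA_real_, p = 1, n_pairs = 0L,
                n_zero_dropped = sum(ok), method = method))
  }
  dn <- d[nz]
  if (method == "wilcoxon") {
    out <- .exact_signed_rank(dn)
    list(statistic = out$statistic, p = out$p, n_pairs = length(dn),
         n_zero_dropped = sum(!nz), method = "wilcoxon")
  } else {
    if (stats::sd(dn) < 1e-12) {
      list(statistic = Inf * sign(dn[1]), p = 0, n_pairs = length(dn),
           n_zero_dropped = sum(!nz), method = "t")
    } else {
      tst <- stats::t.test(dn)
      list(statistic = unname(tst$statistic), p = tst$p.value,
           n_pairs = length(dn), n_zero_dropped = sum(!nz), method = "t")
    }
  }
}

# Exact two-sided Wilcoxon signed-rank test by sign-flip enumeration,
# conditional on the observed magnitudes (ties handled with midranks).
# The null distribution of the positive-rank sum is built by dynamic
# programming over doubled midranks, so arbitrary tie patterns are exact.
.exact_signed_rank <- function(d) {
  d <- signif(d, 10)     # clear float jitter so genuine ties rank as ties
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  r2 <- as.integer(round(2 * r))
  counts <- numeric(sum(r2) + 1)
  counts[1] <- 1
  for (v in r2) {
    shifted <- c(rep(0, v), counts[seq_len(length(counts) - v)])
    counts <- counts + shifted
  }
  sums <- seq_along(counts) - 1
  e2 <- sum(r2) / 2
  dev <- abs(2 * w_obs - e2)
  p <- sum(counts[abs(sums - e2) >= dev - 1e-9]) / 2^length(d)
  list(statistic = w_obs, p = min(p, 1))
}
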