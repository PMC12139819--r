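#' Read the three trial input tables into a trial dataset
#'
#' Reads the measurement, genotype and garden CSV tables of a multi-garden
#' clonal trial and assembles them into a `trial_dataset` object without
#' applying any quality filtering. Column requirements are strict: a missing
#' required column is an error naming the column, and measurement rows whose
#' genotype or (garden, year) keys do not resolve against the metadata tables
#' raise a referential error listing the offending keys.
#'
#' Expected columns:
#' * measurements: `individual_id, genotype_id, garden_id, block_id, year,
#'   growth_increment_cm, survived` (0/1)
#' * genotypes: `genotype_id, home_mcmt, pc1, pc2, pc3, ancestry_q`
#'   (optional `latitude, longitude`)
#' * gardens: `garden_id, year, garden_mcmt` (optional `latitude, longitude`)
#'
#' @param measurements_path,genotypes_path,gardens_path paths to CSV files
#'   with header rows.
#' @return A `trial_dataset`: list with `observations` (data frame),
#'   `genotypes`, `gardens` (data frames keyed by id), and an empty
#'   `qc_report`.
#' @seealso [apply_qc_filters()], [summarize_dataset()]
#' @export
read_trial_tables <- function(measurements_path, genotypes_path, gardens_path) {
  for (p in c(measurements_path, genotypes_path, gardens_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  meas <- utils::read.csv(measurements_path, stringsAsFactors = FALSE)
  geno <- utils::read.csv(genotypes_path, stringsAsFactors = FALSE)
  gard <- utils::read.csv(gardens_path, stringsAsFactors = FALSE)
  trial_dataset(meas, geno, gard)
}

#' Assemble a trial dataset from in-memory tables
#'
#' Constructor behind [read_trial_tables()]; useful when tables are built
#' programmatically (e.g. by [simulate_trial()]).
#'
#' @param measurements,genotypes,gardens data frames with the columns
#'   documented in [read_trial_tables()].
#' @return A `trial_dataset` object (unfiltered, empty `qc_report`).
#' @export
trial_dataset <- function(measurements, genotypes, gardens) {
  need_meas <- c("individual_id", "genotype_id", "garden_id", "block_id",
                 "year", "growth_increment_cm", "survived")
  need_geno <- c("genotype_id", "home_mcmt", "pc1", "pc2", "pc3", "ancestry_q")
  need_gard <- c("garden_id", "year", "garden_mcmt")
  .check_columns(measurements, need_meas, "measurements")
  .check_columns(genotypes, need_geno, "genotypes")
  .check_columns(gardens, need_gard, "gardens")

  measurements$year <- as.integer(measurements$year)
  gardens$year <- as.integer(gardens$year)
  measurements$survived <- as.logical(measurements$survived)

  if (anyDuplicated(genotypes$genotype_id))
    stop("duplicate genotype_id in genotype table")
  gkey <- paste(gardens$garden_id, gardens$year, sep = "\r")
  if (anyDuplicated(gkey))
    stop("duplicate (garden_id, year) in garden table")
  dup <- duplicated(paste(measurements$individual_id, measurements$year,
                          sep = "\r"))
  if (any(dup))
    stop("duplicate (individual_id, year) rows in measurements: ",
         paste(utils::head(measurements$individual_id[dup], 5), collapse = ", "))

  bad_geno <- setdiff(measurements$genotype_id, genotypes$genotype_id)
  if (length(bad_geno))
    stop("measurement rows reference unknown genotype(s): ",
         paste(bad_geno, collapse = ", "))
  mkey <- paste(measurements$garden_id, measurements$year, sep = "\r")
  bad_gard <- setdiff(mkey, gkey)
  if (length(bad_gard))
    stop("measurement rows reference unknown (garden, year): ",
         paste(gsub("\r", "/", bad_gard), collapse = ", "))

  bad_q <- !is.finite(genotypes$ancestry_q) | genotypes$ancestry_q < 0 |
    genotypes$ancestry_q > 1
  if (any(bad_q))
    stop("ancestry_q outside [0, 1] for genotype(s): ",
         paste(genotypes$genotype_id[bad_q], collapse = ", "))
  if (any(!is.finite(genotypes$home_mcmt)))
    stop("non-finite home_mcmt in genotype table")
  if (any(!is.finite(gardens$garden_mcmt)))
    stop("non-finite garden_mcmt in garden table")

  structure(
    list(observations = measurements, genotypes = genotypes, gardens = gardens,
         qc_report = .empty_qc_report(), qc_applied = FALSE),
    class = "trial_dataset")
}

.check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " table is missing required column(s): ",
         paste(miss, collapse = ", "))
  invisible(TRUE)
}

.empty_qc_report <- function() {
  c(negative_removed = 0L, dead_zeroed = 0L, dead_missing_zeroed = 0L,
    live_missing_removed = 0L, excluded_genotype_removed = 0L,
    excluded_year_removed = 0L)
}

#' Apply the standard quality filters to a trial dataset
#'
#' Reproduces the screening applied to the field measurements before model
#' fitting: rows with negative growth increments (herbivory or measurement
#' error) are removed; rows of excluded genotypes (e.g. genetic outliers)
#' and excluded years are removed; trees marked dead get growth coded as
#' exactly 0 (a structural zero); live trees with missing growth are dropped
#' (the model has no missing-data mechanism), while dead trees with missing
#' growth are coded 0. Growth of exactly 0 on a live tree is retained as a
#' sampling zero. Every action is counted in `qc_report`. The operation is
#' idempotent.
#'
#' @param data a `trial_dataset`.
#' @param excluded_genotypes character vector of genotype ids to drop.
#' @param excluded_years integer vector of measurement years to drop.
#' @return The filtered `trial_dataset`, with `qc_report` counts and
#'   `qc_applied = TRUE`.
#' @export
apply_qc_filters <- function(data, excluded_genotypes = character(),
                             excluded_years = integer()) {
  stopifnot(inherits(data, "trial_dataset"))
  obs <- data$observations
  rep <- .empty_qc_report()

  keep <- !(obs$genotype_id %in% excluded_genotypes)
  rep["excluded_genotype_removed"] <- sum(!keep)
  obs <- obs[keep, , drop = FALSE]

  keep <- !(obs$year %in% as.integer(excluded_years))
  rep["excluded_year_removed"] <- sum(!keep)
  obs <- obs[keep, , drop = FALSE]

  g <- obs$growth_increment_cm
  dead <- !obs$survived

  miss_live <- is.na(g) & !dead
  rep["live_missing_removed"] <- sum(miss_live)
  obs <- obs[!miss_live, , drop = FALSE]
  g <- obs$growth_increment_cm
  dead <- !obs$survived

  # dead trees' recorded growth is ignored entirely: coded as structural 0
  miss_dead <- is.na(g) & dead
  rep["dead_missing_zeroed"] <- sum(miss_dead)
  nonzero_dead <- !is.na(g) & dead & g != 0
  rep["dead_zeroed"] <- sum(nonzero_dead)
  obs$growth_increment_cm[dead] <- 0
  g <- obs$growth_increment_cm

  neg <- g < 0  # live trees only by now
  rep["negative_removed"] <- sum(neg)
  obs <- obs[!neg, , drop = FALSE]

  out <- data
  out$observations <- obs
  out$genotypes <- data$genotypes[
    !(data$genotypes$genotype_id %in% excluded_genotypes), , drop = FALSE]
  out$qc_report <- rep
  out$qc_applied <- TRUE
  out
}

#' Summarize a quality-filtered trial dataset
#'
#' @param data a `trial_dataset` (after [apply_qc_filters()]).
#' @return A list with `n_obs`, `n_individuals`, `n_genotypes`, `n_gardens`,
#'   `zero_fraction` (share of observations with growth exactly 0),
#'   `per_garden_counts` (named integer vector), and `empty` flag.
#' @export
summarize_dataset <- function(data) {
  stopifnot(inherits(data, "trial_dataset"))
  obs <- data$observations
  if (nrow(obs) == 0L) {
    return(list(n_obs = 0L, n_individuals = 0L, n_genotypes = 0L,
                n_gardens = 0L, zero_fraction = NA_real_,
                per_garden_counts = integer(), empty = TRUE))
  }
  list(
    n_obs = nrow(obs),
    n_individuals = length(unique(obs$individual_id)),
    n_genotypes = length(unique(obs$genotype_id)),
    n_gardens = length(unique(obs$garden_id)),
    zero_fraction = mean(obs$growth_increment_cm == 0),
    per_garden_counts = table(obs$garden_id),
    empty = FALSE)
}

#' @export
print.trial_dataset <- function(x, ...) {
  s <- summarize_dataset(x)
  cat("trial_dataset:", s$n_obs, "observations of", s$n_individuals,
      "individuals;", s$n_genotypes, "genotypes across", s$n_gardens,
      "gardens\n")
  if (!s$empty)
    cat(sprintf("  zero-growth fraction: %.3f; QC %s\n", s$zero_fraction,
                if (isTRUE(x$qc_applied)) "applied" else "not applied"))
  invisible(x)
}
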