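#' Read a SNP dosage matrix from a plain matrix CSV
#'
#' First column must be `genotype_id`; remaining columns are per-variant
#' dosages (typically 0/1/2, fractional allowed after imputation). Upstream
#' variant calling, filtering and imputation are out of scope here.
#'
#' @param path CSV file path.
#' @return A `genotype_matrix`: list with `genotype_ids` and a numeric
#'   `dosages` matrix (rows = genotypes).
#' @export
read_genotype_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "genotype_id")
    stop("first column of a dosage matrix CSV must be 'genotype_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  genotype_matrix(df$genotype_id, m)
}

#' Construct a genotype dosage matrix object
#' @param genotype_ids character vector of row ids.
#' @param dosages numeric matrix, rows = genotypes, columns = variants.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(genotype_ids, dosages) {
  dosages <- as.matrix(dosages)
  if (length(genotype_ids) != nrow(dosages))
    stop("genotype_ids length must match dosage rows")
  if (anyNA(dosages))
    stop("dosage matrix contains missing values; impute upstream")
  if (nrow(dosages) < 2L || ncol(dosages) < 1L)
    stop("need at least 2 genotypes and 1 variant")
  structure(list(genotype_ids = as.character(genotype_ids), dosages = dosages),
            class = "genotype_matrix")
}

#' Principal-component scores of a genotype dosage matrix
#'
#' Covariance PCA of the column-centered, unscaled dosage matrix: scores are
#' projections of the centered dosages onto the eigenvectors of the dosage
#' covariance, ordered by decreasing eigenvalue. Eigenvector sign is fixed by
#' orienting each axis so that its largest-magnitude variant loading is
#' positive; downstream model fits are invariant to axis sign and scale.
#'
#' @param g a `genotype_matrix`.
#' @param n_axes number of leading axes to return; must not exceed
#'   `min(n_genotypes - 1, n_variants)`.
#' @return A `pc_scores` object: `genotype_ids`, `scores` (matrix with
#'   columns `pc1, pc2, ...`), and `explained_variance_fraction`.
#' @export
compute_pc_scores <- function(g, n_axes = 3L) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- nrow(g$dosages)
  p <- ncol(g$dosages)
  n_axes <- as.integer(n_axes)
  if (n_axes < 1L || n_axes > min(n - 1L, p))
    stop("n_axes must be in 1..min(n_genotypes - 1, n_variants) = ",
         min(n - 1L, p))
  x <- scale(g$dosages, center = TRUE, scale = FALSE)
  total_var <- sum(x^2) / (n - 1)
  if (total_var <= .Machine$double.eps)
    stop("dosage matrix has zero variance; PCA is degenerate")
  # thin SVD of the centered matrix == eigendecomposition of the covariance
  sv <- svd(x, nu = 0, nv = n_axes)
  v <- sv$v
  flip <- apply(v, 2, function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  v <- sweep(v, 2, flip, `*`)
  scores <- x %*% v
  colnames(scores) <- paste0("pc", seq_len(n_axes))
  evf <- (sv$d^2 / (n - 1)) / total_var
  structure(list(genotype_ids = g$genotype_ids, scores = scores,
                 explained_variance_fraction = evf[seq_len(n_axes)]),
            class = "pc_scores")
}

#' Correlation of genetic PC axes with climate of origin
#'
#' Pearson correlation of each PC axis with the genotypes' home-climate
#' winter temperature (MCMT of the provenance), a diagnostic of how strongly
#' genetic structure tracks climate (in the motivating system the leading
#' axis separates the two hybridizing species and correlates negatively
#' with home MCMT).
#'
#' @param pcs a `pc_scores` object.
#' @param genotypes data frame with `genotype_id` and `home_mcmt` columns.
#' @return data frame with `axis`, `r` (Pearson) and `n` (shared genotypes).
#' @export
structure_climate_correlation <- function(pcs, genotypes) {
  stopifnot(inherits(pcs, "pc_scores"))
  idx <- match(genotypes$genotype_id, pcs$genotype_ids)
  ok <- !is.na(idx)
  if (sum(ok) < 3L)
    stop("need at least 3 genotypes shared between PC scores and metadata")
  s <- pcs$scores[idx[ok], , drop = FALSE]
  h <- genotypes$home_mcmt[ok]
  data.frame(axis = colnames(s),
             r = apply(s, 2, function(col) stats::cor(col, h)),
             n = sum(ok), row.names = NULL)
}
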