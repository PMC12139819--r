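# Selected inverse of a sparse symmetric positive-definite matrix from its
# CHOLMOD factor: entries of H^{-1} on the (permuted, filled) pattern of
# the Cholesky factor. Used by the analytic gradient of the Laplace
# objective, which needs traces tr(H^{-1} dH) over the pattern of H.
#
# Returns list(Lp, Li, Sx, perm): the factor's column pointers / row
# indices (0-based, permuted order), the selected-inverse values on that
# pattern, and the 0-based fill-reducing permutation (H[perm+1, perm+1] =
# L L').
.selected_inverse <- function(Ch) {
  L <- methods::as(Ch, "sparseMatrix")   # lower triangular, dtCMatrix
  perm <- Ch@perm
  Sx <- .takahashi_cpp(L@p, L@i, L@x, nrow(L))
  list(Lp = L@p, Li = L@i, Sx = Sx, perm = perm)
}

# Wait-free bug check in interactive use
.selected_inverse_dense_check <- function(H) {
  Ch <- Matrix::Cholesky(H, LDL = FALSE, perm = TRUE)
  si <- .selected_inverse(Ch)
  Hi <- solve(as.matrix(H))
  n <- nrow(H)
  err <- 0
  for (j in seq_len(n)) {
    for (a in (si$Lp[j] + 1):si$Lp[j + 1]) {
      i <- si$Li[a] + 1L
      err <- max(err, abs(si$Sx[a] -
                            Hi[si$perm[i] + 1L, si$perm[j] + 1L]))
    }
  }
  err
}
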