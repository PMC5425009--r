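#' Identity-by-state similarity matrix
#'
#' Pairwise allele-sharing similarity: per site `1 - |g_i - g_j| / 2`,
#' averaged over the sites where both samples are called. The diagonal
#' is 1 and the matrix is symmetric.
#'
#' @param x A [genotype_matrix()] with at least two samples.
#' @return A samples x samples numeric matrix with values in `[0, 1]`.
#' @export
ibs_matrix <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (n_samples(x) < 2) stop("need at least two samples")
  codes <- x$codes
  ok <- !is.na(codes)
  A <- list(`0` = (codes == 0L) & ok, `1` = (codes == 1L) & ok,
            `2` = (codes == 2L) & ok)
  A <- lapply(A, function(m) { m[is.na(m)] <- FALSE; m * 1 })
  shared <- ok %*% t(ok)
  # sum over shared sites of |g_i - g_j|
  d1 <- A[["0"]] %*% t(A[["1"]]) + A[["1"]] %*% t(A[["0"]]) +
    A[["1"]] %*% t(A[["2"]]) + A[["2"]] %*% t(A[["1"]])
  d2 <- A[["0"]] %*% t(A[["2"]]) + A[["2"]] %*% t(A[["0"]])
  absdiff <- d1 + 2 * d2
  if (any(shared[upper.tri(shared)] == 0)) {
    idx <- which(shared == 0 & upper.tri(shared), arr.ind = TRUE)[1, ]
    stop("samples ", x$samples[idx[1]], " and ", x$samples[idx[2]],
         " share no non-missing site")
  }
  sim <- 1 - absdiff / (2 * shared)
  diag(sim) <- 1
  dimnames(sim) <- list(x$samples, x$samples)
  sim
}

#' Classical multidimensional scaling of a similarity matrix
#'
#' Converts similarity to distance (`d = 1 - similarity`), double-centers
#' `-d^2 / 2` and takes the top-`k` eigenpairs; coordinates are the
#' eigenvectors scaled by the square root of their eigenvalues. Components
#' with non-positive eigenvalues are zero-filled with a warning. The sign
#' of each component is fixed by making its largest-magnitude loading
#' positive, so output is stable across runs.
#'
#' @param similarity Symmetric similarity matrix (e.g. from
#'   [ibs_matrix()]).
#' @param k Number of components (default 2, the two structure covariates
#'   used in association).
#' @return An object of class `mds_result`: list with `coordinates`
#'   (samples x k, columns `C1..Ck`, centered at zero) and `eigenvalues`
#'   (length k, non-increasing).
#' @export
classical_mds <- function(similarity, k = 2) {
  if (!isSymmetric(unname(similarity), tol = 1e-8)) {
    stop("similarity matrix must be symmetric")
  }
  n <- nrow(similarity)
  if (k < 1) stop("`k` must be >= 1")
  if (k > n) stop("`k` cannot exceed the number of samples")
  d <- 1 - similarity
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d * d) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  vals <- e$values[seq_len(k)]
  coords <- matrix(0, n, k)
  pos <- which(vals > .Machine$double.eps * n)
  if (length(pos) < k) {
    warning("only ", length(pos), " positive eigenvalue(s); remaining ",
            "component(s) zero-filled")
  }
  for (j in pos) {
    v <- e$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    coords[, j] <- v * sqrt(vals[j])
  }
  dimnames(coords) <- list(rownames(similarity), paste0("C", seq_len(k)))
  structure(list(coordinates = coords, eigenvalues = vals),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat("mds_result:", nrow(x$coordinates), "samples,",
      ncol(x$coordinates), "components\n")
  cat("eigenvalues:", signif(x$eigenvalues, 4), "\n")
  invisible(x)
}
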