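#' Find the p nearest neighbours of each point
#'
#' Exact Euclidean nearest neighbours, self excluded, ordered by increasing
#' distance, distance ties broken toward the lower index. Duplicated points
#' are legitimate neighbours at distance zero.
#'
#' @param points numeric matrix, one point per row.
#' @param p neighbour count; needs `2 <= p < n` (at least the output
#'   dimension of the planar embedding).
#' @return An `n x p` integer matrix of 1-based neighbour indices.
#' @export
find_neighbors <- function(points, p) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points)
  p <- as.integer(p)
  if (p < 2L) .fail("p must be >= 2")
  if (n <= p) .fail("need more points (%d) than neighbours (%d)", n, p)
  .knn_cpp(points, p)
}

#' Solve the locally linear reconstruction weights
#'
#' Row `i` of the returned matrix minimises
#' `||V_i - sum_j W_ij V_ij||^2` over the neighbours of `i`, subject to the
#' weights summing to 1. The local Gram matrix is conditioned by adding
#' `reg * trace / p` to its diagonal, which is what makes the solve
#' well-posed when `p` exceeds the point dimension (the standard LLE
#' regularisation).
#'
#' @param points numeric matrix, one point per row.
#' @param graph neighbour index matrix from [find_neighbors()].
#' @param reg regularisation coefficient (default `1e-3`).
#' @return A sparse row-stochastic `n x n` weight matrix
#'   (`Matrix::dgCMatrix`), nonzero only at `(i, neighbour-of-i)`.
#' @export
solve_weights <- function(points, graph, reg = 1e-3) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points)
  p <- ncol(graph)
  if (nrow(graph) != n || any(graph < 1L) || any(graph > n))
    .fail("malformed neighbour graph")
  w <- .lle_weights_cpp(points, graph, reg)
  Matrix::sparseMatrix(i = rep(seq_len(n), times = p), j = as.vector(graph),
                       x = as.vector(w), dims = c(n, n))
}

#' Reconstruction error of a weight matrix
#'
#' `RE = sum_i ||V_i - sum_j W_ij V_ij||^2`, the quantity minimised by
#' [solve_weights()] and scanned by [select_neighbor_count()].
#'
#' @param points numeric matrix of points.
#' @param weights `n x n` weight matrix (sparse or dense).
#' @return A single nonnegative number.
#' @export
reconstruction_error <- function(points, weights) {
  points <- as.matrix(points)
  sum((points - as.matrix(weights %*% points))^2)
}

#' Embed to the plane from the weight matrix
#'
#' Forms `M = (I - W)' (I - W)` and extracts the eigenvectors of its two
#' smallest eigenvalues after discarding the constant mode (the exact
#' eigenvector of eigenvalue 0 guaranteed by row-stochastic weights). Each
#' eigenvector is unit-norm and supplies one coordinate axis, so the
#' embedded trajectory is centred at the origin. The sign of each
#' eigenvector is fixed so that its first nonzero coordinate is positive,
#' making repeated runs bit-identical.
#'
#' For `n <= dense_cutoff` the full symmetric eigendecomposition is used;
#' above that, a deterministic inverse subspace iteration on the sparse
#' matrix (with the constant mode deflated by a rank-one shift) computes the
#' same pair.
#'
#' @param weights row-stochastic weight matrix from [solve_weights()].
#' @param dense_cutoff problem size at which the dense path hands over to
#'   the sparse one (default 512).
#' @return A `planar_trajectory`: list with `points` (n x 2),
#'   `eigenvalues_used` (lambda2, lambda3).
#' @export
embed_2d <- function(weights, dense_cutoff = 512L) {
  n <- nrow(weights)
  rs <- Matrix::rowSums(weights)
  if (max(abs(rs - 1)) > 1e-6)
    .fail("weight rows must sum to 1 (max deviation %.3g)", max(abs(rs - 1)))
  if (n <= dense_cutoff) {
    W <- as.matrix(weights)
    IW <- diag(n) - W
    M <- crossprod(IW)
    # push the constant mode to the top of the spectrum so the two smallest
    # eigenpairs of the deflated operator are exactly (lambda2, lambda3)
    shift <- 2 * max(1, max(diag(M)))
    Md <- M + shift / n
    e <- eigen((Md + t(Md)) / 2, symmetric = TRUE)
    v <- e$vectors[, c(n, n - 1L), drop = FALSE]
    lam <- pmax(e$values[c(n, n - 1L)], 0)
  } else {
    sp <- .lle_eigs_sparse(weights)
    v <- sp$vectors; lam <- sp$values
  }
  # exact orthogonality to the constant vector, unit norm, fixed signs
  v <- sweep(v, 2L, colMeans(v))
  v <- sweep(v, 2L, sqrt(colSums(v^2)), "/")
  for (j in 1:2) {
    nz <- which(abs(v[, j]) > 0)[1L]
    if (!is.na(nz) && v[nz, j] < 0) v[, j] <- -v[, j]
  }
  structure(list(points = unname(v), eigenvalues_used = lam),
            class = "planar_trajectory")
}

# Deterministic inverse subspace iteration for the two smallest non-constant
# eigenpairs of M = (I-W)'(I-W). The constant null mode (guaranteed by
# row-stochastic W) is deflated by projecting it out of every iterate, so
# the iteration converges to (v2, v3) directly; the tiny ridge on the
# Cholesky factor only regularises the deflated null direction, which the
# projection removes again after each solve.
.lle_eigs_sparse <- function(weights, tol = 1e-13, max_iter = 200L) {
  n <- nrow(weights)
  IW <- Matrix::Diagonal(n) - weights
  M <- Matrix::crossprod(IW)
  Msym <- Matrix::forceSymmetric(M)
  ch <- NULL
  for (eps in c(1e-12, 1e-8, 1e-4)) {
    ch <- tryCatch(Matrix::Cholesky(Msym + Matrix::Diagonal(n, eps),
                                    LDL = FALSE),
                   error = function(e) NULL)
    if (!is.null(ch)) break
  }
  if (is.null(ch)) .fail("eigen-solver failure: weight matrix is degenerate")
  deflate <- function(V) V - matrix(colMeans(V), n, ncol(V), byrow = TRUE)
  k <- 2L
  V <- qr.Q(qr(deflate(cbind(sin(seq_len(n)), cos(seq_len(n) * 0.7)))))
  lam <- c(Inf, Inf)
  for (it in seq_len(max_iter)) {
    Vold <- V
    V <- qr.Q(qr(deflate(as.matrix(Matrix::solve(ch, V)))))
    MV <- as.matrix(M %*% V)
    H <- crossprod(V, MV)
    e <- eigen((H + t(H)) / 2, symmetric = TRUE)
    V <- V %*% e$vectors[, k:1, drop = FALSE]
    lam_new <- e$values[k:1]
    # stop when the Ritz values and the subspace have stabilised; in a
    # near-degenerate bottom cluster the subspace keeps rotating without
    # changing the eigenvalues, so after enough sweeps value-stability
    # suffices - any orthonormal basis of the cluster is equally valid
    rot <- max(abs(abs(crossprod(V, Vold)) - diag(1, k)))
    lam_stable <- max(abs(lam_new - lam)) <= tol * max(1, abs(lam_new))
    lam <- lam_new
    if (lam_stable && (rot < 1e-12 || it >= 50L)) break
  }
  list(vectors = V, values = pmax(lam, 0))
}

#' @export
print.planar_trajectory <- function(x, ...) {
  cat(sprintf("<planar_trajectory> %d points (lambda2=%.3g, lambda3=%.3g)\n",
              nrow(x$points), x$eigenvalues_used[1], x$eigenvalues_used[2]))
  invisible(x)
}

#' @export
plot.planar_trajectory <- function(x, ...) {
  graphics::plot(x$points, type = "l", xlab = "u2", ylab = "u3",
                 asp = 1, ...)
  invisible(x)
}

#' Locally linear embedding of a trajectory to the plane
#'
#' Convenience wrapper: [find_neighbors()], [solve_weights()], [embed_2d()].
#'
#' @param points numeric matrix (e.g. `phase_trajectory$points`) or a
#'   `phase_trajectory`.
#' @param p neighbour count (default 4, the reconstruction-error minimiser
#'   on EEG trajectories).
#' @param reg weight regularisation, see [solve_weights()].
#' @param dense_cutoff see [embed_2d()].
#' @return A `planar_trajectory`.
#' @export
lle_embed <- function(points, p = 4L, reg = 1e-3, dense_cutoff = 512L) {
  if (inherits(points, "phase_trajectory")) points <- points$points
  g <- find_neighbors(points, p)
  W <- solve_weights(points, g, reg)
  embed_2d(W, dense_cutoff)
}

#' Scan the neighbour count by reconstruction error
#'
#' Computes the summed reconstruction error at the optimal weights for each
#' candidate `p` and returns the global argmin (ties toward the smaller
#' `p`).
#'
#' @param points numeric matrix of points.
#' @param p_range candidate neighbour counts (default `2:12`).
#' @param reg weight regularisation.
#' @return A list with `best_p` and `re_curve` (data frame `p`, `re`).
#' @export
select_neighbor_count <- function(points, p_range = 2:12, reg = 1e-3) {
  if (inherits(points, "phase_trajectory")) points <- points$points
  points <- as.matrix(points)
  if (nrow(points) <= max(p_range))
    .fail("need more points (%d) than the largest candidate p (%d)",
          nrow(points), max(p_range))
  re <- vapply(p_range, function(p) {
    g <- find_neighbors(points, p)
    reconstruction_error(points, solve_weights(points, g, reg))
  }, 0)
  list(best_p = p_range[which.min(re)],
       re_curve = data.frame(p = p_range, re = re))
}
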