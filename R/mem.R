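#' Distance-based Moran's eigenvector maps (dbMEM)
#'
#' Spatial eigenvector machinery used to absorb spatial autocorrelation in
#' the OLS submodels of the piecewise SEM.  The construction follows the
#' classical dbMEM recipe: a truncated spatial weighting matrix built from
#' the longest edge of the Euclidean minimum spanning tree over the cell
#' centroids, doubly centred and eigendecomposed; eigenvectors with positive
#' eigenvalues describe positive spatial autocorrelation at decreasing
#' spatial scales.
#'
#' @param coords numeric matrix (n x 2) of cell centroid coordinates.
#' @param truncation optional truncation distance; by default the longest
#'   edge of the minimum spanning tree over `coords`, the smallest distance
#'   keeping the connectivity graph connected.
#' @return an object of class `spatial_weights`: a list with the symmetric
#'   weight matrix `W` (zero diagonal, \eqn{w_{ij} = 1 - (d_{ij}/4t)^2} for
#'   \eqn{0 < d_{ij} \le t}, else 0), the truncation distance `truncation`,
#'   and the coordinates.
#' @examples
#' xy <- as.matrix(expand.grid(x = 1:5, y = 1:5))
#' sw <- build_spatial_weights(xy)
#' sw$truncation   # 1 on a unit lattice
#' @export
build_spatial_weights <- function(coords, truncation = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) stop("need at least 3 coordinates", call. = FALSE)
  if (anyDuplicated(as.data.frame(coords)) > 0) {
    stop("duplicate coordinates are not allowed", call. = FALSE)
  }
  d <- stats::dist(coords)
  if (is.null(truncation)) {
    mst <- vegan::spantree(d)
    truncation <- max(mst$dist)
  }
  dm <- as.matrix(d)
  W <- ifelse(dm > 0 & dm <= truncation, 1 - (dm / (4 * truncation))^2, 0)
  diag(W) <- 0
  structure(list(W = W, truncation = truncation, coords = coords),
            class = "spatial_weights")
}

as_weight_matrix <- function(weights) {
  if (inherits(weights, "spatial_weights")) weights$W else as.matrix(weights)
}

#' Compute the Moran's eigenvector basis
#'
#' Eigendecomposition of the doubly centred spatial weighting matrix
#' \eqn{\Omega = (I - 11'/n) W (I - 11'/n)}.  Eigenvectors with eigenvalues
#' above a numerical tolerance are retained (positive spatial
#' autocorrelation); each retained eigenvector sums to zero, the set is
#' orthonormal, and Moran's I is non-increasing with rank (it is
#' proportional to the eigenvalue).
#'
#' @param weights a `spatial_weights` object (or a bare symmetric matrix).
#' @param tol relative eigenvalue tolerance for retaining vectors.
#' @return an object of class `mem_basis`: list with `vectors` (n x k,
#'   columns `MEM1..MEMk`), `values`, and `moran` (Moran's I per vector).
#' @export
compute_mem_basis <- function(weights, tol = 1e-8) {
  W <- as_weight_matrix(weights)
  n <- nrow(W)
  if (n < 3) stop("need at least 3 cells for a MEM basis", call. = FALSE)
  H <- diag(n) - matrix(1 / n, n, n)
  Omega <- H %*% W %*% H
  Omega <- (Omega + t(Omega)) / 2
  eig <- eigen(Omega, symmetric = TRUE)
  keep <- eig$values > tol * max(abs(eig$values))
  V <- eig$vectors[, keep, drop = FALSE]
  if (ncol(V) > 0) colnames(V) <- paste0("MEM", seq_len(ncol(V)))
  moran <- if (ncol(V) > 0) apply(V, 2, morans_i, weights = W) else numeric(0)
  structure(list(vectors = V, values = eig$values[keep], moran = moran,
                 n = n), class = "mem_basis")
}

#' Moran's I spatial autocorrelation statistic
#'
#' \deqn{I = \frac{n}{S_0} \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}}
#' with \eqn{z = x - \bar x} and \eqn{S_0 = \sum_{ij} w_{ij}}.  The null
#' expectation under spatial randomness is \eqn{-1/(n-1)}.
#'
#' @param x numeric vector of per-cell values (non-constant).
#' @param weights `spatial_weights` object or weight matrix.
#' @export
morans_i <- function(x, weights) {
  W <- as_weight_matrix(weights)
  n <- length(x)
  if (n != nrow(W)) stop("length(x) must match the weight matrix", call. = FALSE)
  z <- x - mean(x)
  s2 <- sum(z^2)
  if (s2 == 0) stop("Moran's I is undefined for a constant vector", call. = FALSE)
  (n / sum(W)) * drop(crossprod(z, W %*% z)) / s2
}

#' Permutation test for Moran's I
#'
#' Two-sided permutation test on |I|: p = (1 + #\{|I_perm| >= |I_obs|\}) /
#' (n_perm + 1).  Permutations are vectorised into a single matrix product,
#' so calibration runs with thousands of replicates stay cheap.
#'
#' @inheritParams morans_i
#' @param n_perm number of permutations (>= 99).
#' @param seed optional integer seed for reproducibility.
#' @return list with `statistic`, `p_value`, `expectation`, `n_perm`.
#' @export
morans_i_test <- function(x, weights, n_perm = 999, seed = NULL) {
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  W <- as_weight_matrix(weights)
  n <- length(x)
  obs <- morans_i(x, W)
  if (!is.null(seed)) set.seed(seed)
  z <- x - mean(x)
  s2 <- sum(z^2)
  perm <- matrix(0, n, n_perm)
  for (b in seq_len(n_perm)) perm[, b] <- z[sample.int(n)]
  stat <- (n / sum(W)) * colSums(perm * (W %*% perm)) / s2
  p <- (1 + sum(abs(stat) >= abs(obs) - 1e-12)) / (n_perm + 1)
  list(statistic = obs, p_value = p, expectation = -1 / (n - 1),
       n_perm = n_perm)
}

#' Select MEMs by minimising residual spatial autocorrelation (MIR)
#'
#' Forward selection on model residuals: at each step the candidate
#' eigenvector whose inclusion most reduces |Moran's I| of the updated
#' residuals is added.  Selection stops when the residual autocorrelation is
#' no longer significant (permutation test at `alpha`), or — with
#' `criterion = "ceiling"` — when |Moran's I| falls below `i_ceiling`, or
#' when no candidate reduces |I|, or when the basis is exhausted.  Because
#' the basis is orthonormal, the updated residuals are obtained by
#' projecting out the selected eigenvectors directly.
#'
#' @param residuals residuals of the OLS fit without spatial covariates.
#' @param basis a `mem_basis` object.
#' @param weights `spatial_weights` (or matrix) matching the residuals.
#' @param alpha significance level for the residual Moran's I stop rule.
#' @param criterion `"alpha"` (default, permutation-test stop) or
#'   `"ceiling"` (stop once |I| < `i_ceiling`).
#' @param i_ceiling absolute Moran's I ceiling used by the `"ceiling"` rule.
#' @param n_perm permutations for the stop-rule test.
#' @param seed integer seed (the stop-rule tests are the only stochastic
#'   part; ties in |I| reduction break to the lowest eigenvector rank).
#' @param max_mems maximum number of eigenvectors to select.
#' @return list with `selected` (column names), `indices`, and a `path`
#'   data frame tracing |I| and p at each step.
#' @export
select_mems_mir <- function(residuals, basis, weights, alpha = 0.05,
                            criterion = c("alpha", "ceiling"),
                            i_ceiling = 0.8, n_perm = 999, seed = NULL,
                            max_mems = NULL) {
  criterion <- match.arg(criterion)
  W <- as_weight_matrix(weights)
  V <- basis$vectors
  k <- ncol(V)
  if (is.null(max_mems)) max_mems <- k
  empty <- list(selected = character(0), indices = integer(0),
                path = data.frame(step = integer(0), mem = character(0),
                                  moran = numeric(0), p = numeric(0)))
  if (k == 0) return(empty)
  if (!is.null(seed)) set.seed(seed)
  step_seeds <- sample.int(.Machine$integer.max - 1L, max_mems + 1L)

  r <- residuals
  chosen <- integer(0)
  path <- empty$path
  for (step in seq_len(max_mems + 1L)) {
    tst <- morans_i_test(r, W, n_perm = n_perm, seed = step_seeds[step])
    stop_now <- if (criterion == "alpha") tst$p_value > alpha
                else abs(tst$statistic) < i_ceiling
    path <- rbind(path, data.frame(
      step = step - 1L,
      mem = if (length(chosen)) colnames(V)[chosen[length(chosen)]] else "",
      moran = tst$statistic, p = tst$p_value))
    if (stop_now || length(chosen) >= max_mems) break
    cand <- setdiff(seq_len(k), chosen)
    if (length(cand) == 0) break
    cur_abs <- abs(tst$statistic)
    cand_abs <- vapply(cand, function(j) {
      Vs <- V[, c(chosen, j), drop = FALSE]
      r_try <- residuals - Vs %*% crossprod(Vs, residuals)
      if (sum((r_try - mean(r_try))^2) < 1e-12) return(0)
      abs(morans_i(drop(r_try), W))
    }, numeric(1))
    best <- cand[which.min(cand_abs)]   # which.min: lowest rank wins ties
    if (min(cand_abs) >= cur_abs) break
    chosen <- c(chosen, best)
    Vs <- V[, chosen, drop = FALSE]
    r <- drop(residuals - Vs %*% crossprod(Vs, residuals))
  }
  list(selected = colnames(V)[chosen], indices = chosen, path = path)
}
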