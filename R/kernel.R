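#' Depth kernel of the projection/backprojection operator
#'
#' Lateral shift invariance reduces the projection/backprojection operator
#' to a family of depth-by-depth kernels indexed by 2D spatial frequency,
#' and rotational symmetry to a function of the radial frequency only:
#' `K(rho, z, z')`. On the binned attribute grid,
#' `K[k, i, j] = sum_b Phat_b(rho_k, z_i) * Conj(Phat_b(rho_k, z_j))`,
#' where `Phat_b` is the 2D DFT of the lateral PRF slice of non-position
#' attribute bin b, evaluated at the frequency vector `(rho_k, 0)` (any
#' direction is equivalent by symmetry; `rho_vec` lets tests verify this).
#' The Gram construction makes every `K[k, , ]` Hermitian positive
#' semidefinite; for PRFs with point-reflection symmetry it is real, and the
#' imaginary residue is checked against `imag_tol` and discarded.
#'
#' @param prf a `prf_grid` whose depths match `grid`.
#' @param grid a [depth_grid()].
#' @param rho radial frequencies, cycles/um, each within the lateral Nyquist
#'   `1 / (2 * lateral_width)` of the PRF bins.
#' @param rho_vec optional 2-column matrix of explicit frequency vectors
#'   (one row per `rho`), overriding the `(rho, 0)` convention.
#' @param imag_tol relative tolerance on the discarded imaginary part.
#' @return an object of class `depth_kernel` with the array `K` of dimension
#'   `(length(rho), N, N)`.
#' @export
build_depth_kernel <- function(prf, grid, rho, rho_vec = NULL,
                               imag_tol = 1e-10) {
  stopifnot(inherits(prf, "prf_grid"), inherits(grid, "depth_grid"))
  if (length(prf$depths) != length(grid$z) ||
      max(abs(prf$depths - grid$z)) > 1e-9)
    stop_domain("PRF depths do not match the depth grid")
  nyq <- 1 / (2 * prf$bins$lateral_width)
  if (any(!is.finite(rho)) || any(rho < 0))
    stop_domain("`rho` must be nonnegative")
  if (any(rho > nyq + 1e-12))
    stop_domain(sprintf("requested frequency above the lateral Nyquist %g", nyq))
  if (is.null(rho_vec)) rho_vec <- cbind(rho, 0)
  if (!is.matrix(rho_vec) || nrow(rho_vec) != length(rho) || ncol(rho_vec) != 2)
    stop_domain("`rho_vec` must be a length(rho) x 2 matrix")

  N <- length(grid$z)
  cells <- prf$cells
  bcols <- intersect(c("ith", "iph", "iE"), names(cells))
  centers <- lateral_centers(prf$bins)
  xc <- centers[cells$ix + 1L]
  yc <- centers[cells$iy + 1L]
  # collapse to unique (b, x, y, depth) rows once; phases vary per frequency
  bkey <- if (length(bcols)) interaction_key(cells[bcols]) else rep("0", nrow(cells))
  bf <- match(bkey, unique(bkey))
  nb <- max(bf, 1L)
  agg_key <- paste(bf, cells$iz, xc, yc, sep = "\r")
  first <- !duplicated(agg_key)
  magg <- rowsum(cells$mass, agg_key, reorder = FALSE)
  mass <- magg[match(agg_key[first], rownames(magg)), 1L]
  bf <- bf[first]; iz <- cells$iz[first]; xc <- xc[first]; yc <- yc[first]

  K <- array(0, c(length(rho), N, N))
  max_imag <- 0
  for (k in seq_along(rho)) {
    a <- -2 * pi * (rho_vec[k, 1] * xc + rho_vec[k, 2] * yc)
    Mr <- Matrix::sparseMatrix(i = bf, j = iz, x = mass * cos(a),
                               dims = c(nb, N))
    Mi <- Matrix::sparseMatrix(i = bf, j = iz, x = mass * sin(a),
                               dims = c(nb, N))
    Kre <- as.matrix(Matrix::crossprod(Mr) + Matrix::crossprod(Mi))
    Kim <- as.matrix(Matrix::crossprod(Mr, Mi) - Matrix::crossprod(Mi, Mr))
    scale <- max(abs(Kre), 1e-300)
    max_imag <- max(max_imag, max(abs(Kim)) / scale)
    if (max(abs(Kim)) > imag_tol * scale)
      stop_domain(sprintf(
        "kernel imaginary residue %.2e exceeds tolerance at rho = %g (unsymmetrized PRF?)",
        max(abs(Kim)) / scale, rho[k]))
    K[k, , ] <- (Kre + t(Kre)) / 2
  }
  structure(list(rho = rho, K = K, depths = grid$z, dz = grid$dz,
                 attrs = prf$attrs, bins = prf$bins,
                 modality = prf$modality, source = prf$source,
                 imag_residual = max_imag),
            class = "depth_kernel")
}

#' @export
print.depth_kernel <- function(x, ...) {
  cat(sprintf(
    "Depth kernel K(rho, z, z'): %d x %d depths, %d radial frequencies in [%g, %g] /um (q = %d, %s)\n",
    length(x$depths), length(x$depths), length(x$rho), min(x$rho), max(x$rho),
    x$attrs$q, x$modality))
  invisible(x)
}

# linear interpolation of K in rho (convex combination preserves symmetry
# and positive semidefiniteness)
interpolate_kernel <- function(kernel, r) {
  rho <- kernel$rho
  if (r < rho[1] - 1e-12 || r > rho[length(rho)] + 1e-12)
    stop_domain(sprintf("frequency %g outside kernel coverage [%g, %g]",
                        r, rho[1], rho[length(rho)]))
  j <- findInterval(r, rho, all.inside = TRUE)
  w <- (r - rho[j]) / (rho[j + 1] - rho[j])
  w <- min(max(w, 0), 1)
  (1 - w) * kernel$K[j, , ] + w * kernel$K[j + 1, , ]
}

# eigendecomposition of one depth-kernel matrix under the dz-weighted inner
# product; returns eigenvalues (descending) and eigenvectors in object-space
# normalization (sum_i W_n(i) W_m(i) dz_i = delta_nm)
eigen_weighted <- function(Kmat, dz, neg_tol = 1e-10) {
  s <- sqrt(dz)
  A <- Kmat * outer(s, s)
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  mu <- e$values
  if (min(mu) < -neg_tol * max(mu[1], 1e-300))
    stop_domain(sprintf("eigenvalue %.3e below the negativity tolerance", min(mu)))
  mu[mu < 0] <- 0
  list(mu = mu, W = e$vectors / s)
}

#' Per-frequency eigendecomposition of a depth kernel
#'
#' Solves, at each radial frequency, the dz-weighted discretization of the
#' 1D eigenvalue problem `integral dz' K(rho, z, z') W(z') = mu W(z)` via the
#' similarity transform with the square-root weight matrix. Eigenvalues are
#' real and non-negative (negatives within `1e-10 * mu_max` are clipped);
#' eigenvectors are orthonormal under the dz-weighted inner product.
#'
#' @param kernel a [build_depth_kernel()] result.
#' @param grid a [depth_grid()] (defaults to the kernel's own depths/weights).
#' @return an object of class `cpet_eigen` with fields `rho`, `mu` (N x
#'   n_rho, descending per column), `W` (N x N x n_rho), `mu_max` (global
#'   maximum) and `lambda = mu / mu_max`.
#' @export
eigendecompose_kernel <- function(kernel, grid = NULL) {
  stopifnot(inherits(kernel, "depth_kernel"))
  dz <- if (is.null(grid)) kernel$dz else grid$dz
  N <- length(kernel$depths)
  n_rho <- length(kernel$rho)
  sym_err <- max(vapply(seq_len(n_rho), function(k) {
    Kk <- kernel$K[k, , ]
    max(abs(Kk - t(Kk))) / max(abs(Kk), 1e-300)
  }, 0))
  if (sym_err > 1e-10)
    stop_domain(sprintf("kernel asymmetry %.2e beyond tolerance", sym_err))
  mu <- matrix(0, N, n_rho)
  W <- array(0, c(N, N, n_rho))
  for (k in seq_len(n_rho)) {
    e <- eigen_weighted(kernel$K[k, , ], dz)
    mu[, k] <- e$mu
    W[, , k] <- e$W
  }
  mu_max <- max(mu)
  if (mu_max <= 0) stop_domain("degenerate system: all eigenvalues are zero")
  structure(list(rho = kernel$rho, mu = mu, W = W, mu_max = mu_max,
                 lambda = mu / mu_max, depths = kernel$depths, dz = dz,
                 attrs = kernel$attrs, modality = kernel$modality),
            class = "cpet_eigen")
}

#' @export
print.cpet_eigen <- function(x, ...) {
  cat(sprintf(
    "Eigen-system: %d eigenvalues at each of %d radial frequencies; mu_max = %.4g\n",
    nrow(x$mu), length(x$rho), x$mu_max))
  invisible(x)
}

#' Normalized eigenvalue spectrum lambda_n(rho)
#'
#' Eigenvalues scaled to the global maximum, `lambda_n(rho) = mu_n(rho) /
#' mu_max`, as plotted in eigenvalue-spectrum figures: values lie in
#' `[0, 1]`, are non-increasing in n at fixed rho, and exactly one `(n, rho)`
#' attains 1.
#'
#' @param es a [eigendecompose_kernel()] result.
#' @return a data frame with columns `rho`, `n`, `lambda`.
#' @export
normalized_spectrum <- function(es) {
  stopifnot(inherits(es, "cpet_eigen"))
  if (es$mu_max <= 0) stop_domain("degenerate system")
  N <- nrow(es$mu)
  data.frame(rho = rep(es$rho, each = N),
             n = rep(seq_len(N), length(es$rho)),
             lambda = as.vector(es$lambda))
}

#' @export
plot.cpet_eigen <- function(x, log = "y", floor = 1e-16, ...) {
  lam <- pmax(t(x$lambda), floor)
  graphics::matplot(x$rho, lam, type = "l", lty = 1, log = log,
                    xlab = "radial frequency (cycles/um)",
                    ylab = expression(lambda[n](rho)), ...)
  invisible(x)
}
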