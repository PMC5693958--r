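#' Assemble a CPET imaging system (PRF -> depth kernel -> eigen-systems)
#'
#' Builds the depth kernel at `n_rho` radial frequency samples spanning
#' `[0, rho_max]` and eigendecomposes it at each sample. The result carries
#' everything needed to decompose objects: kernels are interpolated linearly
#' in rho to the exact radii required by an object's DFT grid and
#' eigendecomposed there, so the per-frequency operator applied during
#' decomposition is always an exact symmetric projector. `rho_max` defaults
#' to the PRF's lateral Nyquist frequency; object frequencies beyond
#' `rho_max` have no eigen-system and are treated as fully null.
#'
#' @param prf a `prf_grid` ([alpha_prf_grid()] or [beta_prf_grid()]).
#' @param grid the [depth_grid()] the PRF was built on.
#' @param n_rho number of radial frequency samples.
#' @param rho_max maximum radial frequency (cycles/um); defaults to the PRF
#'   lateral Nyquist.
#' @return an object of class `cpet_system` bundling the kernel, the
#'   eigen-systems and the normalized spectrum.
#' @examples
#' m <- range_energy_model()
#' g <- depth_grid(seq(5, 35, by = 10), 40)
#' b <- bin_spec(2, 80, energy_max = 5160)
#' sys <- cpet_system(alpha_prf_grid(g, 3, b, m), g, n_rho = 16)
#' @export
cpet_system <- function(prf, grid, n_rho = 64, rho_max = NULL) {
  stopifnot(inherits(prf, "prf_grid"), inherits(grid, "depth_grid"))
  check_number(n_rho, "n_rho", lower = 2)
  rho_max <- rho_max %||% (1 / (2 * prf$bins$lateral_width))
  check_number(rho_max, "rho_max", lower = 0, strict_lower = TRUE)
  rho <- seq(0, rho_max, length.out = n_rho)
  kernel <- build_depth_kernel(prf, grid, rho)
  eig <- eigendecompose_kernel(kernel, grid)
  structure(list(kernel = kernel, eigen = eig, grid = grid,
                 attrs = prf$attrs, bins = prf$bins,
                 modality = prf$modality, source = prf$source,
                 sensitivity = prf$sensitivity),
            class = "cpet_system")
}

#' @export
print.cpet_system <- function(x, ...) {
  cat(sprintf(
    "CPET system (%s, q = %d): %d depths, kernel sampled at %d radii in [0, %.3g] /um\n",
    x$modality, x$attrs$q, length(x$grid$z), length(x$kernel$rho),
    max(x$kernel$rho)))
  cat(sprintf("  mu_max = %.4g; sensitivity %.3f .. %.3f\n",
              x$eigen$mu_max, min(x$sensitivity), max(x$sensitivity)))
  invisible(x)
}

#' @export
summary.cpet_system <- function(object, lambda_min = 1e-6, ...) {
  nret <- colSums(object$eigen$lambda >= lambda_min)
  out <- list(q = object$attrs$q, modality = object$modality,
              n_depths = length(object$grid$z), rho = object$eigen$rho,
              retained = nret, lambda_min = lambda_min,
              mu_max = object$eigen$mu_max)
  class(out) <- "summary.cpet_system"
  out
}

#' @export
print.summary.cpet_system <- function(x, ...) {
  cat(sprintf("CPET system summary (%s, q = %d)\n", x$modality, x$q))
  cat(sprintf("  modes with lambda >= %g per radial sample: %d .. %d (of %d)\n",
              x$lambda_min, min(x$retained), max(x$retained), x$n_depths))
  invisible(x)
}

#' @export
plot.cpet_system <- function(x, ...) plot(x$eigen, ...)

#' @export
simulate.cpet_system <- function(object, nsim = 1e4, seed = 1L,
                                 depth = NULL, ...) {
  if (object$modality != "alpha")
    stop_domain("simulate() is available for alpha systems; use simulate_point_source() for beta")
  src <- object$source
  depth <- depth %||% object$grid$z[ceiling(length(object$grid$z) / 2)]
  model <- range_energy_model(src$initial_energy, src$full_range,
                              src$exponent)
  sample_alpha_listmode(c(0, 0, depth), nsim, seed, model,
                        slab_geometry(object$grid$z_max,
                                      2 * object$bins$lateral_halfwidth),
                        alpha_source(src$energies, src$fractions))
}

# per-frequency projector onto eigenfunctions with lambda >= lambda_min,
# exact at radius r through kernel interpolation.
# P = W_keep (W_keep^T diag(dz)); symmetric wrt the dz inner product,
# idempotent by orthonormality.
retained_projector <- function(system, r, lambda_min) {
  Kr <- interpolate_kernel(system$kernel, r)
  e <- eigen_weighted(Kr, system$grid$dz)
  keep <- which(e$mu / system$eigen$mu_max >= lambda_min)
  if (!length(keep)) return(NULL)
  W <- e$W[, keep, drop = FALSE]
  W %*% (t(W) * system$grid$dz)
}

#' Measurement component of an object
#'
#' Projects a voxelized object onto the span of system eigenfunctions with
#' normalized eigenvalue `lambda >= lambda_min`. Algorithm: 2D DFT of each
#' depth slice; for every lateral frequency vector, the depth profile is
#' projected (under the dz-weighted inner product) onto the retained
#' eigenvectors of the kernel interpolated at that radial frequency; inverse
#' DFT reassembles the retained part. Frequencies outside the kernel's
#' radial coverage are fully null. The output is real up to conjugate-
#' symmetry roundoff, which is checked.
#'
#' @param object a `voxel_object` whose depth slices match the system grid.
#' @param system a [cpet_system()].
#' @param lambda_min eigenvalue cutoff in `(0, 1)`; default `1e-6`, chosen
#'   where numerically noisy eigenvalues start in typical spectra.
#' @return a `voxel_object` (the measurement component f_meas).
#' @export
measurement_component <- function(object, system, lambda_min = 1e-6) {
  stopifnot(inherits(object, "voxel_object"), inherits(system, "cpet_system"))
  if (!(lambda_min > 0 && lambda_min < 1))
    stop_domain("`lambda_min` must be in (0, 1)")
  if (length(object$depths) != length(system$grid$z) ||
      max(abs(object$depths - system$grid$z)) > 1e-9)
    stop_domain("object depth slices do not match the system depth grid")
  f <- object$values
  n <- dim(f)[1]
  N <- dim(f)[3]
  if (dim(f)[2] != n) stop_domain("lateral grid must be square")
  Fh <- array(0i, dim(f))
  for (iz in seq_len(N)) Fh[, , iz] <- stats::fft(f[, , iz])
  fr <- fft_freq(n, object$voxel_size)
  rmat <- sqrt(outer(fr, fr, function(a, b) a^2 + b^2))
  rho_max <- max(system$kernel$rho)
  rkey <- round(as.vector(rmat), 10)
  Fflat <- matrix(Fh, nrow = n * n)
  Mflat <- matrix(0i, n * n, N)
  for (r in unique(rkey)) {
    if (r > rho_max + 1e-12) next                 # beyond coverage: null
    P <- retained_projector(system, r, lambda_min)
    if (is.null(P)) next
    sel <- which(rkey == r)
    Mflat[sel, ] <- Fflat[sel, , drop = FALSE] %*% t(P)
  }
  fm <- array(0, dim(f))
  imag_resid <- 0
  for (iz in seq_len(N)) {
    slice <- stats::fft(matrix(Mflat[, iz], n, n), inverse = TRUE) / (n * n)
    imag_resid <- max(imag_resid, max(abs(Im(slice))))
    fm[, , iz] <- Re(slice)
  }
  scale <- max(abs(f), 1e-300)   # input sets the scale; f_meas may be ~ 0
  if (imag_resid > 1e-9 * scale)
    stop_domain("measurement component has non-negligible imaginary part")
  grid <- depth_grid(object$depths, max(object$depths), dz = object$dz)
  new_voxel_object(fm, object$voxel_size, grid)
}

#' Null component f_null = f - f_meas
#'
#' @param f the object.
#' @param f_meas its measurement component (matching grids).
#' @return a `voxel_object`.
#' @export
null_component <- function(f, f_meas) {
  stopifnot(inherits(f, "voxel_object"), inherits(f_meas, "voxel_object"))
  if (!identical(dim(f$values), dim(f_meas$values)) ||
      f$voxel_size != f_meas$voxel_size)
    stop_domain("object and measurement component are on different grids")
  grid <- depth_grid(f$depths, max(f$depths), dz = f$dz)
  new_voxel_object(f$values - f_meas$values, f$voxel_size, grid)
}

#' Scaled norm of a null function
#'
#' `||f_null||_2 / ||f||_2` under voxel-volume weighting: the fraction of
#' the object's L2 content invisible to the system, in `[0, 1]`.
#'
#' @param f_null the null component.
#' @param f the object (must have positive norm).
#' @return a scalar in `[0, 1]`.
#' @export
scaled_null_norm <- function(f_null, f) {
  stopifnot(inherits(f_null, "voxel_object"), inherits(f, "voxel_object"))
  nf <- l2_norm(f)
  if (nf <= 0) stop_domain("object has zero norm")
  l2_norm(f_null) / nf
}

#' Decompose an object into measurement and null components
#'
#' The central analysis: splits a voxelized object f into f_meas (the part
#' recoverable from noise-free data) and f_null = f - f_meas (the part
#' invisible to the imaging system), and reports the scaled null norm. The
#' two components are orthogonal and satisfy the Pythagorean identity
#' `||f||^2 = ||f_meas||^2 + ||f_null||^2`; both residuals are stored.
#'
#' `fitted()` returns the measurement component, `residuals()` the null
#' component.
#'
#' @inheritParams measurement_component
#' @return an object of class `cpet_decomposition` with fields `f`,
#'   `f_meas`, `f_null`, `scaled_null_norm`, `lambda_min`, `retained`
#'   (retained-mode count at each kernel radial sample), `orthogonality`
#'   (normalized inner product of the components) and `pythagoras`
#'   (relative norm-split residual).
#' @examples
#' m <- range_energy_model()
#' g <- depth_grid(seq(5, 35, by = 10), 40)
#' b <- bin_spec(2, 80, energy_max = 5160)
#' sys <- cpet_system(alpha_prf_grid(g, 3, b, m), g, n_rho = 16)
#' obj <- build_test_object(default_phantom(slab_geometry(40, 160)),
#'                          slab_geometry(40, 160), g, voxel_size = 4)
#' dec <- null_decompose(obj, sys)
#' dec$scaled_null_norm
#' @export
null_decompose <- function(object, system, lambda_min = 1e-6) {
  f_meas <- measurement_component(object, system, lambda_min)
  f_null <- null_component(object, f_meas)
  nf2 <- inner_product(object, object)
  if (nf2 <= 0) stop_domain("object has zero norm")
  ortho <- inner_product(f_meas, f_null) / nf2
  pyth <- abs(nf2 - inner_product(f_meas, f_meas) -
                inner_product(f_null, f_null)) / nf2
  structure(list(
    f = object, f_meas = f_meas, f_null = f_null,
    scaled_null_norm = scaled_null_norm(f_null, object),
    lambda_min = lambda_min,
    retained = colSums(system$eigen$lambda >= lambda_min),
    rho = system$eigen$rho,
    orthogonality = ortho, pythagoras = pyth,
    q = system$attrs$q, modality = system$modality),
    class = "cpet_decomposition")
}

#' @export
print.cpet_decomposition <- function(x, ...) {
  cat(sprintf("CPET null decomposition (%s, q = %d, lambda_min = %g)\n",
              x$modality, x$q, x$lambda_min))
  cat(sprintf("  scaled null norm ||f_null||/||f|| = %.4g\n",
              x$scaled_null_norm))
  cat(sprintf("  <f_meas, f_null>/||f||^2 = %.2e; norm-split residual %.2e\n",
              x$orthogonality, x$pythagoras))
  invisible(x)
}

#' @export
summary.cpet_decomposition <- function(object, ...) {
  cat(sprintf(
    "Decomposition (%s, q = %d): ||f|| = %.4g, ||f_meas|| = %.4g, ||f_null|| = %.4g\n",
    object$modality, object$q, l2_norm(object$f), l2_norm(object$f_meas),
    l2_norm(object$f_null)))
  cat(sprintf("  scaled null norm %.4g; retained modes per radial sample: %d .. %d\n",
              object$scaled_null_norm, min(object$retained),
              max(object$retained)))
  invisible(object)
}

#' @export
fitted.cpet_decomposition <- function(object, ...) object$f_meas

#' @export
residuals.cpet_decomposition <- function(object, ...) object$f_null

#' @export
plot.cpet_decomposition <- function(x, type = "projection", ...) {
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  plot(x$f, type = type, main = "object")
  plot(x$f_meas, type = type, main = "measurement component")
  plot(x$f_null, type = type, main = "null component")
  invisible(x)
}
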