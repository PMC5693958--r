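#' Tissue slab and detector geometry
#'
#' The detector plane sits at `z = 0`; depth z increases into the tissue. The
#' slab has thickness `z_max` (um) and the detector a finite square lateral
#' extent centered on the origin. Standard setups: a 40-um slab with a
#' 160 x 160 um^2 detector for alpha emission tomography, and a 100-um slab
#' with a 1024 x 1024 um^2 detector for beta emission tomography.
#'
#' @param thickness slab thickness z_max in um.
#' @param detector_size lateral detector edge lengths in um; scalar or
#'   length-2 vector.
#' @return an object of class `slab_geometry`.
#' @examples
#' slab_geometry(40, 160)    # alpha setup
#' slab_geometry(100, 1024)  # beta setup
#' @export
slab_geometry <- function(thickness, detector_size) {
  check_number(thickness, "thickness", lower = 0, strict_lower = TRUE)
  if (length(detector_size) == 1L) detector_size <- rep(detector_size, 2L)
  if (length(detector_size) != 2L || any(detector_size <= 0))
    stop_domain("`detector_size` must be one or two positive lengths")
  structure(list(thickness = thickness, detector_size = detector_size),
            class = "slab_geometry")
}

#' @export
print.slab_geometry <- function(x, ...) {
  cat(sprintf("Slab: %g um thick; detector %g x %g um^2 at z = 0\n",
              x$thickness, x$detector_size[1], x$detector_size[2]))
  invisible(x)
}

#' Discrete depth sampling of the slab
#'
#' The depth kernel K(rho, z, z') is evaluated on a finite set of source
#' depths, which also serve as the object's depth-slice centers. Default
#' grids: `{1, 3, ..., 39}` um for the 40-um alpha slab and `{5, 10, ...,
#' 100}` um for the 100-um beta slab (20 samples each). `dz` is the
#' quadrature weight attached to each sample; by default the (uniform) grid
#' spacing.
#'
#' @param z strictly increasing depth samples in um, all in `(0, z_max]`.
#' @param z_max slab thickness in um.
#' @param dz quadrature weight per sample; scalar or vector. Default: the
#'   grid spacing (must then be uniform).
#' @return an object of class `depth_grid`.
#' @examples
#' depth_grid(seq(1, 39, by = 2), 40)
#' depth_grid(seq(5, 100, by = 5), 100)
#' @export
depth_grid <- function(z, z_max, dz = NULL) {
  if (length(z) < 1L || any(!is.finite(z))) stop_domain("invalid depth samples")
  if (is.unsorted(z, strictly = TRUE)) stop_domain("`z` must be strictly increasing")
  check_number(z_max, "z_max", lower = 0, strict_lower = TRUE)
  if (z[1] <= 0 || z[length(z)] > z_max + 1e-9)
    stop_domain("depth samples must lie in (0, z_max]")
  if (is.null(dz)) {
    if (length(z) == 1L) stop_domain("`dz` is required for a single-depth grid")
    d <- diff(z)
    if (max(d) - min(d) > 1e-9)
      stop_domain("default `dz` needs uniform spacing; pass `dz` explicitly")
    dz <- rep(d[1], length(z))
  } else {
    if (length(dz) == 1L) dz <- rep(dz, length(z))
    if (length(dz) != length(z) || any(dz <= 0))
      stop_domain("`dz` must be positive, one weight per sample")
  }
  structure(list(z = z, z_max = z_max, dz = dz), class = "depth_grid")
}

#' @export
print.depth_grid <- function(x, ...) {
  cat(sprintf("Depth grid: %d samples in (0, %g] um: %s%s\n",
              length(x$z), x$z_max,
              paste(utils::head(x$z, 4), collapse = ", "),
              if (length(x$z) > 4) ", ..." else ""))
  invisible(x)
}
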