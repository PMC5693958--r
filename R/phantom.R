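#' Cylinder specification for test objects
#'
#' A z-axis-aligned cylinder of uniform activity density inside the slab.
#'
#' @param center lateral center `(x, y)`, um.
#' @param radius cylinder radius, um.
#' @param top depth of the top face, um.
#' @param height cylinder height, um.
#' @param density activity density (arbitrary units / um^3).
#' @return an object of class `cylinder_spec`.
#' @export
cylinder_spec <- function(center, radius, top, height, density = 1) {
  if (length(center) != 2L || any(!is.finite(center)))
    stop_domain("`center` must be (x, y)")
  check_number(radius, "radius", lower = 0, strict_lower = TRUE)
  check_number(top, "top", lower = 0)
  check_number(height, "height", lower = 0, strict_lower = TRUE)
  check_number(density, "density", lower = 0)
  structure(list(center = center, radius = radius, top = top,
                 height = height, density = density),
            class = "cylinder_spec")
}

#' Default 7-cylinder test phantom
#'
#' Seven z-aligned cylinders of unit density whose radii (10-30% of the slab
#' thickness), heights (25-60%) and depths span the slab at distinct lateral
#' positions. All dimensions scale with the slab thickness, so the same
#' relative object serves the 40-um alpha and 100-um beta setups. The
#' relative layout is shipped as a YAML config
#' (`system.file("extdata", "phantom7.yaml", package = "cpetnull")`).
#'
#' @param geom a [slab_geometry()] setting the scale.
#' @param config path to a YAML phantom config; default the shipped one.
#' @return a list of [cylinder_spec()].
#' @export
default_phantom <- function(geom, config = NULL) {
  stopifnot(inherits(geom, "slab_geometry"))
  config <- config %||% system.file("extdata", "phantom7.yaml",
                                    package = "cpetnull")
  spec <- yaml::read_yaml(config)
  zm <- geom$thickness
  lapply(spec$cylinders, function(cy) {
    cylinder_spec(center = c(cy$cx, cy$cy) * zm, radius = cy$radius * zm,
                  top = cy$top * zm, height = cy$height * zm,
                  density = cy$density %||% 1)
  })
}

#' Voxelize cylinders into an object function f(R)
#'
#' The object is sampled on a lateral grid of `voxel_size`-um square voxels
#' covering the detector extent, with depth slices centered on the depth-grid
#' samples (slice thickness = the grid's dz weights). A voxel belongs to a
#' cylinder if its center lies inside; overlapping cylinders sum their
#' densities. All cylinders must lie inside the slab.
#'
#' @param cylinders list of [cylinder_spec()] (may be empty for a zero
#'   object).
#' @param geom a [slab_geometry()].
#' @param grid a [depth_grid()].
#' @param voxel_size lateral voxel edge, um; must divide the detector extent.
#' @return an object of class `voxel_object`: fields `values` (nx x ny x N
#'   array), `voxel_size`, `depths`, `dz`, `extent`.
#' @export
build_test_object <- function(cylinders, geom, grid, voxel_size) {
  stopifnot(inherits(geom, "slab_geometry"), inherits(grid, "depth_grid"))
  check_number(voxel_size, "voxel_size", lower = 0, strict_lower = TRUE)
  L <- geom$detector_size[1]
  n <- L / voxel_size
  if (abs(n - round(n)) > 1e-9)
    stop_domain("`voxel_size` must divide the detector extent")
  n <- as.integer(round(n))
  xs <- (seq_len(n) - 0.5) * voxel_size - L / 2
  f <- array(0, c(n, n, length(grid$z)))
  for (cy in cylinders) {
    stopifnot(inherits(cy, "cylinder_spec"))
    if (cy$top + cy$height > geom$thickness + 1e-9 ||
        any(abs(cy$center) + cy$radius > L / 2 + 1e-9))
      stop_domain("cylinder extends outside the slab / lateral extent")
    inxy <- outer(xs - cy$center[1], xs - cy$center[2],
                  function(a, b) a^2 + b^2) <= cy$radius^2
    for (iz in which(grid$z >= cy$top & grid$z <= cy$top + cy$height))
      f[, , iz] <- f[, , iz] + cy$density * inxy
  }
  new_voxel_object(f, voxel_size, grid)
}

new_voxel_object <- function(values, voxel_size, grid) {
  structure(list(values = values, voxel_size = voxel_size,
                 depths = grid$z, dz = grid$dz,
                 extent = dim(values)[1] * voxel_size),
            class = "voxel_object")
}

#' @export
print.voxel_object <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "Voxel object: %d x %d x %d voxels (%g um lateral, %d depth slices), L2 norm %.4g\n",
    d[1], d[2], d[3], x$voxel_size, d[3], l2_norm(x)))
  invisible(x)
}

# voxel-volume-weighted L2 norm: [sum f^2 dV]^(1/2), dV = voxel_size^2 * dz_i
l2_norm <- function(obj) sqrt(inner_product(obj, obj))

inner_product <- function(a, b) {
  stopifnot(identical(dim(a$values), dim(b$values)))
  dz <- a$dz
  s <- vapply(seq_along(dz),
              function(i) sum(a$values[, , i] * b$values[, , i]) * dz[i], 0)
  sum(s) * a$voxel_size^2
}

#' Lateral cross-section views of a voxel object
#'
#' Returns the xz-plane view used in component figures: either the central
#' y slice or the mean over y.
#'
#' @param obj a `voxel_object`.
#' @param type `"slice"` (central y) or `"projection"` (mean over y).
#' @return a matrix (x along rows, depth along columns).
#' @export
cross_section_xz <- function(obj, type = c("projection", "slice")) {
  type <- match.arg(type)
  v <- obj$values
  if (type == "slice") v[, ceiling(dim(v)[2] / 2), ]
  else apply(v, c(1, 3), mean)
}

#' @export
plot.voxel_object <- function(x, type = "projection", ...) {
  m <- cross_section_xz(x, type)
  graphics::image(
    x = (seq_len(nrow(m)) - 0.5) * x$voxel_size - x$extent / 2,
    y = x$depths, z = m, xlab = "x (um)", ylab = "depth z (um)",
    ylim = rev(range(x$depths)), col = grDevices::hcl.colors(64, "viridis"),
    ...)
  invisible(x)
}

#' Refine or coarsen the lateral sampling of a voxel object
#'
#' Integer refinement replicates voxel values (piecewise-constant
#' interpolation); integer coarsening averages blocks. Used to move objects
#' onto a PRF's lateral grid for forward projection.
#'
#' @param obj a `voxel_object`.
#' @param voxel_size target lateral voxel edge, um; the ratio to the current
#'   size must be an integer (either way).
#' @return a `voxel_object` on the new lateral grid.
#' @export
regrid_lateral <- function(obj, voxel_size) {
  stopifnot(inherits(obj, "voxel_object"))
  r <- obj$voxel_size / voxel_size
  if (abs(r - round(r)) < 1e-9 && r >= 1) {          # refine
    r <- as.integer(round(r))
    if (r == 1L) return(obj)
    n <- dim(obj$values)[1]
    idx <- rep(seq_len(n), each = r)
    vals <- obj$values[idx, idx, , drop = FALSE]
  } else {
    r <- voxel_size / obj$voxel_size                  # coarsen
    if (abs(r - round(r)) > 1e-9)
      stop_domain("voxel-size ratio must be an integer")
    r <- as.integer(round(r))
    n <- dim(obj$values)[1] %/% r
    vals <- array(0, c(n, n, dim(obj$values)[3]))
    for (a in seq_len(r)) for (b in seq_len(r))
      vals <- vals + obj$values[seq(a, by = r, length.out = n),
                                seq(b, by = r, length.out = n), ,
                                drop = FALSE]
    vals <- vals / r^2
  }
  grid <- depth_grid(obj$depths, max(obj$depths), dz = obj$dz)
  new_voxel_object(vals, voxel_size, grid)
}
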