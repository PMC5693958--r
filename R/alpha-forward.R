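#' Detection sensitivity of a straight-line alpha emitter
#'
#' For isotropic emission at depth z above an unbounded detector plane, a
#' particle reaches the detector iff its straight path length to the plane,
#' `z / cos(theta)`, does not exceed the full range R0. The detected solid
#' angle is a cone of half-angle `acos(z / R0)`, giving
#' `S(z) = (1 - z / R0) / 2` for `z < R0` and 0 beyond.
#'
#' @param z source depth in um, `z > 0`; vectorized.
#' @param model a [range_energy_model()].
#' @return detection probability in `[0, 0.5)`.
#' @examples
#' m <- range_energy_model()
#' alpha_sensitivity(19.7, m)   # 0.25
#' @export
alpha_sensitivity <- function(z, model) {
  stopifnot(inherits(model, "range_energy_model"))
  if (any(!is.finite(z)) || any(z <= 0))
    stop_domain("`z` must be positive")
  pmax(1 - z / model$full_range, 0) / 2
}

#' Analytic binned PRF grids for alpha emission tomography
#'
#' Builds exact per-bin probability masses of the q = 5 point response
#' function at each source depth, then marginalizes to the requested
#' attribute combination. Tracks are straight lines: an emission at depth z
#' in direction `(theta, phi)` (theta measured from the detector normal)
#' reaches the detector at lateral offset `z * tan(theta)`, with direction
#' cosines `(sin(theta) cos(phi), sin(theta) sin(phi))` and residual energy
#' set by the path length `z / cos(theta)` through the range-energy relation.
#' The per-solid-angle emission density is `1 / (4 pi)`.
#'
#' All five attributes are deterministic functions of `(theta, phi)` at fixed
#' z, so every bin's mass is an integral of `sin(theta) / (4 pi)` over a
#' region bounded by radii at which theta-bin edges and energy-bin edges are
#' crossed (both maps are monotone in the lateral radius). The radial and
#' azimuthal integrals are evaluated in closed form on elementary polar cells
#' whose boundaries include every bin-edge preimage; the only approximation
#' is the assignment of each elementary cell to the Cartesian lateral bin
#' containing its midpoint, controlled by `radial_step` and `arc_step`.
#' Total mass per depth therefore equals `alpha_sensitivity(z)` up to
#' floating-point error, and marginal grids nest exactly.
#'
#' Depths at or beyond the full range yield all-zero slices. The lateral axes
#' must cover the geometric support radius `sqrt(R0^2 - z^2)` and the energy
#' axis the line energy, otherwise a coverage error is raised.
#'
#' @param z source depths in um (e.g. a [depth_grid()]'s samples).
#' @param attrs an [attribute_spec()] or q in 2:5.
#' @param bins a [bin_spec()]. For kernel building choose a lateral width no
#'   coarser than half the object voxel size so the kernel covers the object
#'   DFT's full radial frequency support (see the package vignette).
#' @param model a [range_energy_model()].
#' @param source an [alpha_source()]; multi-line sources are
#'   branching-weighted mixtures of single-line PRFs.
#' @param radial_step,arc_step maximum radial extent / arc length (um) of the
#'   elementary polar integration cells.
#' @return a `prf_grid` over the depths `z`.
#' @examples
#' m <- range_energy_model()
#' b <- bin_spec(4, 80, energy_max = 5160)
#' p <- alpha_prf_grid(c(10, 20), 3, b, m)
#' sum(p$cells$mass[p$cells$iz == 1])   # = alpha_sensitivity(10, m)
#' @export
alpha_prf_grid <- function(z, attrs, bins, model = range_energy_model(),
                           source = alpha_source(),
                           radial_step = 0.5, arc_step = 1) {
  stopifnot(inherits(bins, "bin_spec"), inherits(model, "range_energy_model"),
            inherits(source, "alpha_source"))
  attrs <- attribute_spec_of(attrs)
  if (inherits(z, "depth_grid")) z <- z$z
  if (any(!is.finite(z)) || any(z <= 0)) stop_domain("depths must be positive")
  check_number(radial_step, "radial_step", lower = 0, strict_lower = TRUE)
  check_number(arc_step, "arc_step", lower = 0, strict_lower = TRUE)
  if (max(source$energies) * 1000 > bins$energy_max + 1e-9)
    stop_domain("energy axis does not cover the emission line energy")
  slices <- lapply(z, function(zi) {
    parts <- lapply(seq_along(source$energies), function(k) {
      mod_k <- range_energy_model(
        source$energies[k],
        model$full_range * (source$energies[k] / model$initial_energy)^model$exponent,
        model$exponent)
      cells <- alpha_cells_one_depth(zi, bins, mod_k, radial_step, arc_step)
      cells$mass <- cells$mass * source$fractions[k]
      cells
    })
    do.call(rbind, parts)
  })
  cells <- do.call(rbind, lapply(seq_along(slices), function(i) {
    ci <- slices[[i]]
    if (nrow(ci)) ci$iz <- i else ci$iz <- integer(0)
    ci
  }))
  rownames(cells) <- NULL
  sens <- vapply(slices, function(s) sum(s$mass), 0)
  prf <- new_prf_grid(cells, attribute_spec(5), bins, depths = z,
                      sensitivity = sens, modality = "alpha",
                      source = list(energies = source$energies,
                                    fractions = source$fractions,
                                    initial_energy = model$initial_energy,
                                    full_range = model$full_range,
                                    exponent = model$exponent))
  marginalize_prf(prf, attrs)
}

# exact q = 5 cell masses for one depth and one emission line.
# Returns data.frame(ix, iy, ith, iph, iE, mass); empty for z >= full range.
alpha_cells_one_depth <- function(z, bins, model, radial_step, arc_step) {
  empty <- data.frame(ix = integer(0), iy = integer(0), ith = integer(0),
                      iph = integer(0), iE = integer(0), mass = numeric(0))
  R0 <- model$full_range
  if (z >= R0) return(empty)
  r_max <- sqrt(R0^2 - z^2)
  if (r_max > sqrt(2) * bins$lateral_halfwidth + 1e-9)
    stop_domain(sprintf(
      "lateral bins do not cover the PRF support radius %.1f um at z = %.1f um",
      r_max, z))
  # radial breakpoints: preimages of theta-bin edges and energy-bin edges,
  # plus a refinement grid for the lateral midpoint assignment
  th_edges <- seq(bins$theta_width, 90 - bins$theta_width, by = bins$theta_width)
  r_theta <- z * tan(th_edges * pi / 180)
  E_edges <- seq(bins$energy_width, by = bins$energy_width,
                 length.out = bins$n_energy - 1L) / 1000   # MeV
  E_edges <- E_edges[E_edges < model$initial_energy]
  path_E <- R0 - range_from_energy(E_edges, model)         # path at which E is reached
  r_E <- sqrt(pmax(path_E^2 - z^2, 0))[path_E > z]
  br <- sort(unique(round(c(0, r_max, r_theta[r_theta < r_max], r_E,
                            seq(0, r_max, by = radial_step)), 9)))
  br <- br[br <= r_max + 1e-9]
  r1 <- br[-length(br)]; r2 <- br[-1]
  keep <- (r2 - r1) > 1e-9
  r1 <- r1[keep]; r2 <- r2[keep]
  if (!length(r1)) return(empty)
  r_mid <- (r1 + r2) / 2
  # exact full-circle mass of each radial interval: (cos th1 - cos th2)/2
  mass_r <- 0.5 * (z / sqrt(z^2 + r1^2) - z / sqrt(z^2 + r2^2))
  ith <- pmin(bin_index(atan2(r_mid, z) * 180 / pi, 0, bins$theta_width),
              bins$n_theta - 1L)
  E_mid <- energy_from_residual_range(pmax(R0 - sqrt(z^2 + r_mid^2), 0), model)
  iE <- pmin(bin_index(E_mid * 1000, 0, bins$energy_width), bins$n_energy - 1L)
  # azimuthal subdivision: split each phi bin so arcs stay below arc_step
  n_sub <- pmax(1L, ceiling(r2 * (bins$phi_width * pi / 180) / arc_step))
  out <- vector("list", length(unique(n_sub)))
  u <- 0L
  for (ns in sort(unique(n_sub))) {
    sel <- which(n_sub == ns)
    dphi <- bins$phi_width / ns
    phi_c <- seq(-180 + dphi / 2, 180 - dphi / 2, by = dphi)
    n_phi_cells <- length(phi_c)
    idx <- rep(sel, each = n_phi_cells)
    phis <- rep(phi_c, length(sel))
    xc <- r_mid[idx] * cos(phis * pi / 180)
    yc <- r_mid[idx] * sin(phis * pi / 180)
    u <- u + 1L
    out[[u]] <- data.frame(
      ix = lateral_index(xc, bins),
      iy = lateral_index(yc, bins),
      ith = ith[idx],
      iph = bin_index(phis, -180, bins$phi_width),
      iE = iE[idx],
      mass = mass_r[idx] * (dphi / 360))
  }
  cells <- do.call(rbind, out)
  # clamp the rare midpoint that lands exactly on the outer lateral edge
  cells$ix <- pmin(pmax(cells$ix, 0L), bins$n_lateral - 1L)
  cells$iy <- pmin(pmax(cells$iy, 0L), bins$n_lateral - 1L)
  key <- interaction_key(cells[c("ix", "iy", "ith", "iph", "iE")])
  agg <- rowsum(cells$mass, key, reorder = FALSE)
  first <- !duplicated(key)
  res <- cells[first, c("ix", "iy", "ith", "iph", "iE"), drop = FALSE]
  res$mass <- agg[match(key[first], rownames(agg)), 1L]
  rownames(res) <- NULL
  res
}

#' Sample alpha list-mode events exactly
#'
#' Draws `n` isotropic emissions from a point source and records the exact
#' attributes of those whose straight track reaches the detector plane within
#' the particle range and inside the finite detector extent. Serves as the
#' Monte Carlo cross-check of the analytic [alpha_prf_grid()].
#'
#' @param position source position `(x, y, z)` in um; z is depth.
#' @param n number of emissions.
#' @param seed integer seed (the function calls `set.seed()`).
#' @param model a [range_energy_model()].
#' @param geom a [slab_geometry()].
#' @param source an [alpha_source()].
#' @return a [listmode_table()]; empty if `z >= full_range`.
#' @export
sample_alpha_listmode <- function(position, n, seed,
                                  model = range_energy_model(),
                                  geom = slab_geometry(40, 160),
                                  source = alpha_source()) {
  stopifnot(inherits(model, "range_energy_model"),
            inherits(geom, "slab_geometry"))
  if (length(position) != 3L || any(!is.finite(position)))
    stop_domain("`position` must be (x, y, z)")
  z <- position[3]
  if (z <= 0 || z > geom$thickness)
    stop_domain("source depth must lie inside the slab (0, z_max]")
  check_number(n, "n", lower = 1)
  set.seed(as.integer(seed))
  meta <- list(source = "alpha", depth = z, n_emitted = n, seed = seed,
               modality = "alpha")
  line <- sample.int(length(source$energies), n, replace = TRUE,
                     prob = source$fractions)
  R0 <- model$full_range * (source$energies[line] / model$initial_energy)^model$exponent
  u <- runif(n, -1, 1)                 # cos(angle to +z); detector is at -z
  phi <- runif(n, 0, 2 * pi)
  up <- -u                             # cosine of angle towards the detector
  det <- up > z / R0                   # path z/up must be < R0
  if (!any(det))
    return(listmode_table(meta = meta))
  up <- up[det]; phi <- phi[det]; line_d <- line[det]; R0 <- R0[det]
  st <- sqrt(pmax(1 - up^2, 0))
  r <- z * st / up
  xd <- position[1] + r * cos(phi)
  yd <- position[2] + r * sin(phi)
  path <- z / up
  E <- source$energies[line_d] * ((R0 - path) / R0)^(1 / model$exponent)
  inside <- abs(xd) <= geom$detector_size[1] / 2 &
    abs(yd) <= geom$detector_size[2] / 2
  listmode_table(xd[inside], yd[inside],
                 (st * cos(phi))[inside], (st * sin(phi))[inside],
                 1000 * E[inside], meta = meta)
}
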