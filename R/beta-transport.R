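#' Condensed-history transport parameters
#'
#' Physics constants and stepping controls for the electron Monte Carlo.
#' This transport model is a documented simplified stand-in for a full
#' simulation toolkit: per step it applies deterministic collision energy
#' loss (midpoint rule on the stopping power) and a Gaussian multiple-
#' scattering deflection of Highland width
#' `theta_0 = (13.6 MeV / (beta c p)) sqrt(ds / X0)` in two orthogonal
#' planes. Radiative losses, energy-loss straggling, annihilation and
#' secondary production are omitted. All constants are implementer-chosen
#' defaults from standard electron-transport references, not fitted values:
#' Berger-Seltzer collision stopping power for water with mean excitation
#' energy 75 eV, radiation length 36.08 cm.
#'
#' @param step_max maximum step length, um.
#' @param step_frac step length as a fraction of the (first-order) residual
#'   CSDA range; the step is `min(step_max, step_frac * range)`.
#' @param cutoff low-energy cutoff, keV; particles below it are absorbed.
#' @param X0 radiation length of the medium, cm.
#' @param scatter logical; disable to get straight-line (ballistic) tracks.
#' @param lateral_bound half-width (um) of the lateral bookkeeping region;
#'   tracks leaving it are scored as escaped.
#' @param max_path_factor track-length guard, in units of the initial CSDA
#'   range.
#' @param stopping one of `"water"` (Berger-Seltzer electron stopping power)
#'   or `"powerlaw"` (range-energy power law, mirroring the straight-line
#'   alpha model; used for ballistic cross-checks).
#' @param powerlaw for `stopping = "powerlaw"`: list with `E0` (keV), `R0`
#'   (um) and `p` (exponent).
#' @return an object of class `transport_params`.
#' @export
transport_params <- function(step_max = 1, step_frac = 0.02, cutoff = 10,
                             X0 = 36.08, scatter = TRUE,
                             lateral_bound = 4096, max_path_factor = 1.5,
                             stopping = c("water", "powerlaw"),
                             powerlaw = NULL) {
  stopping <- match.arg(stopping)
  check_number(step_max, "step_max", lower = 0, strict_lower = TRUE)
  check_number(step_frac, "step_frac", lower = 0, strict_lower = TRUE)
  check_number(cutoff, "cutoff", lower = 0, strict_lower = TRUE)
  check_number(X0, "X0", lower = 0, strict_lower = TRUE)
  check_number(lateral_bound, "lateral_bound", lower = 0, strict_lower = TRUE)
  check_number(max_path_factor, "max_path_factor", lower = 0, strict_lower = TRUE)
  if (stopping == "powerlaw") {
    if (is.null(powerlaw) || !all(c("E0", "R0", "p") %in% names(powerlaw)))
      stop_domain("`powerlaw` must supply E0 (keV), R0 (um) and p")
  }
  structure(list(step_max = step_max, step_frac = step_frac, cutoff = cutoff,
                 X0 = X0, scatter = scatter, lateral_bound = lateral_bound,
                 max_path_factor = max_path_factor, stopping = stopping,
                 powerlaw = powerlaw),
            class = "transport_params")
}

#' Electron state
#'
#' @param position `(x, y, z)` in um, z = depth into the tissue.
#' @param direction unit propagation vector `(d_x, d_y, d_z)`; `d_z < 0`
#'   points towards the detector.
#' @param energy kinetic energy, keV.
#' @return an object of class `electron_state`.
#' @export
electron_state <- function(position, direction, energy) {
  if (length(position) != 3L || any(!is.finite(position)))
    stop_domain("`position` must be a finite (x, y, z)")
  if (length(direction) != 3L || any(!is.finite(direction)) ||
      abs(sum(direction^2) - 1) > 1e-12)
    stop_domain("`direction` must be a unit 3-vector")
  check_number(energy, "energy", lower = 0)
  structure(list(position = position, direction = direction, energy = energy),
            class = "electron_state")
}

transport_batch <- function(pos, dir, energy, params, geom) {
  res <- cpp_transport(
    pos[, 1], pos[, 2], pos[, 3], dir[, 1], dir[, 2], dir[, 3], energy,
    geom$thickness, params$lateral_bound, params$step_max, params$step_frac,
    params$cutoff, params$X0 * 1e4, params$scatter, params$max_path_factor,
    if (params$stopping == "powerlaw") 1L else 0L,
    params$powerlaw$E0 %||% 1, params$powerlaw$R0 %||% 1,
    params$powerlaw$p %||% 1)
  res
}

#' Transport a single electron through the slab
#'
#' Steps one [electron_state()] until it crosses the detector plane, is
#' absorbed below the energy cutoff, or escapes the slab / bookkeeping
#' region. See [transport_params()] for the physics.
#'
#' @param state an [electron_state()] inside the slab with energy above the
#'   cutoff.
#' @param params a [transport_params()].
#' @param geom a [slab_geometry()].
#' @param seed optional integer seed.
#' @return a list with `status` (`"detected"`, `"absorbed"` or `"escaped"`),
#'   and for detected tracks `x_d`, `y_d`, `s_x`, `s_y` (direction cosines at
#'   the crossing), `E` (residual energy, keV) and `path` (um).
#' @export
transport_electron <- function(state, params, geom, seed = NULL) {
  stopifnot(inherits(state, "electron_state"),
            inherits(params, "transport_params"),
            inherits(geom, "slab_geometry"))
  if (state$position[3] <= 0 || state$position[3] > geom$thickness)
    stop_domain("electron must start inside the slab")
  if (state$energy <= params$cutoff)
    stop_domain("starting energy must exceed the transport cutoff")
  if (!is.null(seed)) set.seed(as.integer(seed))
  r <- transport_batch(matrix(state$position, 1), matrix(state$direction, 1),
                       state$energy, params, geom)
  status <- c("detected", "absorbed", "escaped")[r$status[1] + 1L]
  out <- list(status = status)
  if (status == "detected")
    out <- c(out, list(x_d = r$x_d[1], y_d = r$y_d[1], s_x = r$s_x[1],
                       s_y = r$s_y[1], E = r$E[1], path = r$path[1]))
  out
}

#' Simulate a beta point source at depth z
#'
#' Emits `n` particles isotropically with energies drawn from the source
#' spectrum, transports each through the slab, and returns one list-mode row
#' per track that crosses the detector plane inside the finite detector
#' extent. Fully deterministic given `seed`.
#'
#' @param z source depth, um, in `(0, z_max]`.
#' @param n number of emitted particles.
#' @param src a [beta_source()].
#' @param params a [transport_params()].
#' @param geom a [slab_geometry()].
#' @param seed integer seed.
#' @return a [listmode_table()] with metadata (`depth`, `n_emitted`, `seed`,
#'   source and physics parameters).
#' @export
simulate_point_source <- function(z, n, src = beta_source(),
                                  params = transport_params(),
                                  geom = slab_geometry(100, 1024),
                                  seed = 1L) {
  stopifnot(inherits(src, "beta_source"), inherits(params, "transport_params"),
            inherits(geom, "slab_geometry"))
  check_number(z, "z", lower = 0, strict_lower = TRUE, upper = geom$thickness)
  check_number(n, "n", lower = 1)
  set.seed(as.integer(seed))
  E <- sample_emission_energy(src, n)
  u <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  st <- sqrt(pmax(1 - u^2, 0))
  dir <- cbind(st * cos(phi), st * sin(phi), u)
  pos <- cbind(0, 0, rep(z, n))
  alive <- E > params$cutoff
  res <- transport_batch(pos[alive, , drop = FALSE], dir[alive, , drop = FALSE],
                         E[alive], params, geom)
  det <- res$status == 0L &
    abs(res$x_d) <= geom$detector_size[1] / 2 &
    abs(res$y_d) <= geom$detector_size[2] / 2
  meta <- list(source = src$isotope, mode = src$mode, energy = src$energy,
               depth = z, n_emitted = n, seed = seed, modality = "beta",
               physics = params[c("step_max", "step_frac", "cutoff", "X0",
                                  "scatter", "stopping")])
  listmode_table(res$x_d[det], res$y_d[det], res$s_x[det], res$s_y[det],
                 res$E[det], meta = meta)
}

#' Monte Carlo PRF grid for beta emission tomography
#'
#' Runs [simulate_point_source()] at each depth of a [depth_grid()] and
#' histograms the detected events into a multi-depth `prf_grid` with
#' [histogram_listmode()]. Per-depth seeds are derived from `seed` so the
#' grid is reproducible. Events are point-reflection symmetrized by default
#' (see [histogram_listmode()]).
#'
#' @param grid a [depth_grid()] (or numeric depths).
#' @param n_per_depth emitted particles per depth.
#' @param bins a [bin_spec()].
#' @param attrs an [attribute_spec()] or q.
#' @param src,params,geom source, transport and geometry settings.
#' @param seed integer base seed.
#' @param symmetrize passed to [histogram_listmode()].
#' @return a `prf_grid`.
#' @export
beta_prf_grid <- function(grid, n_per_depth, bins, attrs = 5,
                          src = beta_source(), params = transport_params(),
                          geom = slab_geometry(100, 1024), seed = 1L,
                          symmetrize = TRUE) {
  z <- if (inherits(grid, "depth_grid")) grid$z else grid
  attrs <- attribute_spec_of(attrs)
  slices <- lapply(seq_along(z), function(i) {
    tab <- simulate_point_source(z[i], n_per_depth, src, params, geom,
                                 seed = as.integer(seed) + 7919L * i)
    histogram_listmode(tab, bins, attrs, n_emitted = n_per_depth,
                       symmetrize = symmetrize)
  })
  prf <- stack_prf(slices, z)
  prf$modality <- "beta"
  prf$source <- list(isotope = src$isotope, mode = src$mode,
                     energy = src$energy, n_per_depth = n_per_depth,
                     seed = seed)
  prf
}
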