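#' Measured-attribute combinations of a particle-processing detector
#'
#' A detector estimates q of the five per-particle attributes
#' (x_d, y_d, s_x, s_y, E). Four combinations are supported, all containing
#' the interaction position: position only (q = 2), position + energy
#' (q = 3), position + direction (q = 4), and all five (q = 5).
#'
#' @param q number of measured attributes (2, 3, 4 or 5), or a character
#'   vector naming them from `c("x_d", "y_d", "s_x", "s_y", "E")`.
#' @return an object of class `attribute_spec` with fields `attrs` and `q`.
#' @examples
#' attribute_spec(3)                            # position + energy
#' attribute_spec(c("x_d", "y_d", "s_x", "s_y"))
#' @export
attribute_spec <- function(q) {
  combos <- list(
    `2` = c("x_d", "y_d"),
    `3` = c("x_d", "y_d", "E"),
    `4` = c("x_d", "y_d", "s_x", "s_y"),
    `5` = c("x_d", "y_d", "s_x", "s_y", "E"))
  if (is.character(q)) {
    attrs <- q
    match_ok <- vapply(combos, function(cb) setequal(cb, attrs), logical(1))
    if (!any(match_ok))
      stop_domain("attribute set must be one of: (x_d,y_d), (x_d,y_d,E), ",
                  "(x_d,y_d,s_x,s_y), (x_d,y_d,s_x,s_y,E)")
    attrs <- combos[[which(match_ok)[1]]]
  } else {
    check_number(q, "q", lower = 2, upper = 5)
    attrs <- combos[[as.character(as.integer(q))]]
    if (is.null(attrs)) stop_domain("`q` must be 2, 3, 4 or 5")
  }
  structure(list(attrs = attrs, q = length(attrs)), class = "attribute_spec")
}

has_energy <- function(attrs) "E" %in% attrs$attrs
has_direction <- function(attrs) "s_x" %in% attrs$attrs

#' @export
print.attribute_spec <- function(x, ...) {
  cat(sprintf("Attribute spec: q = %d (%s)\n", x$q,
              paste(x$attrs, collapse = ", ")))
  invisible(x)
}

#' Attribute-space binning
#'
#' Bin widths and ranges for histogramming list-mode data and for tabulating
#' PRFs. Lateral bins are half-open `[lo, hi)` and centered on the origin;
#' direction is binned in polar/azimuthal angles (theta, phi) of the track at
#' the detector plane even though list-mode rows store direction cosines;
#' energy in keV. Defaults follow the standard analysis binning
#' (dtheta = dphi = 2 degrees, dE = 20 keV); the lateral width is
#' setup-dependent: 4 um is the Monte Carlo histogram bin used for beta
#' list-mode data, while analytic alpha PRFs are typically tabulated finer
#' (see [alpha_prf_grid()]).
#'
#' @param lateral_width lateral bin width in um.
#' @param lateral_halfwidth lateral axis half-range in um; must be a
#'   multiple of `lateral_width`. Lateral bins are centered on integer
#'   multiples of the width (an odd count of `2 * K + 1` bins with
#'   `K = lateral_halfwidth / lateral_width`), so the zero-offset bin is
#'   centered on the origin, the axis is exactly reflection-symmetric, and
#'   PRF slices align with voxel grids of the same spacing under discrete
#'   convolution.
#' @param energy_max upper edge of the energy axis in keV (rounded up to a
#'   whole number of bins).
#' @param theta_width,phi_width angular bin widths in degrees; theta spans
#'   `[0, 90)`, phi spans `[-180, 180)`, and both spans must divide evenly.
#' @param energy_width energy bin width in keV.
#' @return an object of class `bin_spec`.
#' @examples
#' bin_spec(4, 512, energy_max = 640)    # beta analysis bins
#' bin_spec(1, 80, energy_max = 5160)    # fine alpha tabulation
#' @export
bin_spec <- function(lateral_width, lateral_halfwidth, energy_max,
                     theta_width = 2, phi_width = 2, energy_width = 20) {
  for (nm in c("lateral_width", "lateral_halfwidth", "energy_max",
               "theta_width", "phi_width", "energy_width"))
    check_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  K_lat <- lateral_halfwidth / lateral_width
  if (abs(K_lat - round(K_lat)) > 1e-9)
    stop_domain("lateral half-range must be a multiple of the bin width")
  n_lat <- 2 * round(K_lat) + 1
  if (abs(90 / theta_width - round(90 / theta_width)) > 1e-9 ||
      abs(360 / phi_width - round(360 / phi_width)) > 1e-9)
    stop_domain("angular bin widths must divide 90 (theta) and 360 (phi)")
  n_E <- ceiling(energy_max / energy_width - 1e-9)
  structure(list(
    lateral_width = lateral_width,
    lateral_halfwidth = lateral_halfwidth,
    n_lateral = as.integer(round(n_lat)),
    theta_width = theta_width, n_theta = as.integer(round(90 / theta_width)),
    phi_width = phi_width, n_phi = as.integer(round(360 / phi_width)),
    energy_width = energy_width, n_energy = as.integer(n_E),
    energy_max = n_E * energy_width), class = "bin_spec")
}

#' @export
print.bin_spec <- function(x, ...) {
  cat(sprintf(
    "Bins: lateral %g um over [-%g, %g); theta %g deg; phi %g deg; E %g keV up to %g keV\n",
    x$lateral_width, x$lateral_halfwidth, x$lateral_halfwidth,
    x$theta_width, x$phi_width, x$energy_width, x$energy_max))
  invisible(x)
}

# lateral bin centers (um), length n_lateral (odd), centered on 0
lateral_centers <- function(bins) {
  K <- (bins$n_lateral - 1L) %/% 2L
  (seq_len(bins$n_lateral) - 1L - K) * bins$lateral_width
}

# 0-based lateral bin index for offsets; bins are [c - w/2, c + w/2) around
# centers c = k * w
lateral_index <- function(x, bins) {
  K <- (bins$n_lateral - 1L) %/% 2L
  as.integer(floor(x / bins$lateral_width + 0.5)) + K
}
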