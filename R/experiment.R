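#' Experiment configuration
#'
#' Validated settings for an end-to-end null-function experiment on one
#' modality, possibly sweeping several detector attribute combinations.
#' Defaults reproduce the standard setups: alpha — 5.15-MeV source with
#' 39.4-um range in a 40-um slab, 160-um detector, depths `{1, 3, ..., 39}`
#' um, analytic PRF on a 1-um lateral grid, 2-um object voxels; beta —
#' F-18-like source in a 100-um slab, 1024-um detector, depths
#' `{5, 10, ..., 100}` um, Monte Carlo PRF histogrammed on a 2-um lateral
#' grid, 4-um object voxels.
#'
#' @param modality `"alpha"` or `"beta"`.
#' @param q detector attribute counts to analyze (subset of 2:5).
#' @param lambda_min eigenvalue cutoff.
#' @param n_rho radial frequency samples for the kernel.
#' @param n_particles (beta) emitted particles per depth.
#' @param seed integer seed for all randomness.
#' @param voxel_size lateral object voxel, um.
#' @param prf_lateral_width lateral PRF bin width for kernel building, um.
#' @param phantom optional list of [cylinder_spec()] (default: the shipped
#'   7-cylinder phantom scaled to the slab).
#' @param ... overrides for `model` ([range_energy_model()]), `source`,
#'   `params` ([transport_params()]), `geom`, `grid`, `bins`.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(modality = c("alpha", "beta"), q = 2:5,
                              lambda_min = 1e-6, n_rho = 64,
                              n_particles = 1e5, seed = 1L,
                              voxel_size = NULL, prf_lateral_width = NULL,
                              phantom = NULL, ...) {
  modality <- match.arg(modality)
  if (!all(q %in% 2:5)) stop_domain("`q` must be a subset of 2:5")
  dots <- list(...)
  if (modality == "alpha") {
    model <- dots$model %||% range_energy_model()
    geom <- dots$geom %||% slab_geometry(40, 160)
    grid <- dots$grid %||% depth_grid(seq(1, 39, by = 2), geom$thickness)
    prf_lateral_width <- prf_lateral_width %||% 1
    voxel_size <- voxel_size %||% 2
    bins <- dots$bins %||% bin_spec(prf_lateral_width,
                                    geom$detector_size[1] / 2,
                                    energy_max = 5160)
    source <- dots$source %||% alpha_source()
    params <- NULL
  } else {
    model <- NULL
    geom <- dots$geom %||% slab_geometry(100, 1024)
    grid <- dots$grid %||% depth_grid(seq(5, 100, by = 5), geom$thickness)
    prf_lateral_width <- prf_lateral_width %||% 2
    voxel_size <- voxel_size %||% 4
    bins <- dots$bins %||% bin_spec(prf_lateral_width,
                                    geom$detector_size[1] / 2,
                                    energy_max = 640)
    source <- dots$source %||% beta_source()
    params <- dots$params %||% transport_params()
  }
  cfg <- list(modality = modality, q = sort(unique(q)),
              lambda_min = lambda_min, n_rho = n_rho,
              n_particles = n_particles, seed = as.integer(seed),
              voxel_size = voxel_size, prf_lateral_width = prf_lateral_width,
              model = model, source = source, params = params,
              geom = geom, grid = grid, bins = bins, phantom = phantom)
  check_number(lambda_min, "lambda_min", lower = 0, upper = 1,
               strict_lower = TRUE)
  structure(cfg, class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("Experiment config: %s, q in {%s}, lambda_min = %g, seed %d\n",
              x$modality, paste(x$q, collapse = ", "), x$lambda_min, x$seed))
  invisible(x)
}

#' Run an end-to-end null-function experiment
#'
#' Pipeline: forward model -> PRF grids (the full q = 5 grid is built once
#' and marginalized per detector) -> depth kernels -> eigen-systems ->
#' decomposition of the test object -> scaled null norms. Deterministic
#' given the config seed. The result bundle carries the spectra, per-q
#' decompositions, the norm-vs-q table and a manifest (config digest, seeds,
#' tolerances, package version).
#'
#' @param config an [experiment_config()].
#' @param object optional `voxel_object` to decompose (default: the config
#'   phantom voxelized at the config voxel size).
#' @param keep_prf keep the q = 5 PRF grid in the bundle.
#' @return an object of class `cpet_experiment` with elements `systems`
#'   (per q), `decompositions` (per q), `norms` (data frame q, scaled null
#'   norm), `spectra` (per q), `object`, `manifest`.
#' @export
run_experiment <- function(config, object = NULL, keep_prf = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed [config %s]: %s", name,
                   substr(manifest$config_digest, 1, 8),
                   conditionMessage(e)), call. = FALSE)
    })
  }
  manifest <- list(
    package = as.character(utils::packageVersion("cpetnull")),
    modality = config$modality, q = config$q, seed = config$seed,
    lambda_min = config$lambda_min, n_rho = config$n_rho,
    n_particles = if (config$modality == "beta") config$n_particles,
    config_digest = object_digest(unclass(config)))

  prf5 <- stage("prf", {
    if (config$modality == "alpha")
      alpha_prf_grid(config$grid, 5, config$bins, config$model, config$source)
    else
      beta_prf_grid(config$grid, config$n_particles, config$bins, 5,
                    config$source, config$params, config$geom,
                    seed = config$seed)
  })
  if (is.null(object)) {
    phantom <- config$phantom %||% default_phantom(config$geom)
    object <- stage("phantom",
                    build_test_object(phantom, config$geom, config$grid,
                                      config$voxel_size))
  }
  systems <- list(); decs <- list(); spectra <- list()
  for (qq in config$q) {
    key <- as.character(qq)
    prf_q <- stage("marginalize", marginalize_prf(prf5, attribute_spec(qq)))
    sys_q <- stage("kernel/eigen",
                   cpet_system(prf_q, config$grid, n_rho = config$n_rho))
    systems[[key]] <- sys_q
    spectra[[key]] <- normalized_spectrum(sys_q$eigen)
    decs[[key]] <- stage("decompose",
                         null_decompose(object, sys_q, config$lambda_min))
  }
  norms <- data.frame(
    q = config$q,
    scaled_null_norm = vapply(decs, function(d) d$scaled_null_norm, 0))
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  structure(list(systems = systems, decompositions = decs, norms = norms,
                 spectra = spectra, object = object,
                 prf = if (keep_prf) prf5, config = config,
                 manifest = manifest),
            class = "cpet_experiment")
}

#' @export
print.cpet_experiment <- function(x, ...) {
  cat(sprintf("CPET experiment (%s), seed %d:\n", x$config$modality,
              x$config$seed))
  print(x$norms, row.names = FALSE)
  invisible(x)
}

#' Export figure-data tables from experiment bundles
#'
#' Emits, per bundle: (a) the normalized eigenvalue spectra lambda_n(rho)
#' for each q, (b) xz cross-section views of the object and its measurement
#' and null components, and (c) the scaled-null-norm-vs-q table. With
#' `out_dir` the tables are also written as CSV files.
#'
#' @param bundles a `cpet_experiment` or list of them.
#' @param out_dir optional output directory for CSV export.
#' @param allow_mixed allow bundles from different modalities.
#' @return a list with elements `spectra`, `cross_sections`, `norms`.
#' @export
make_report <- function(bundles, out_dir = NULL, allow_mixed = FALSE) {
  if (inherits(bundles, "cpet_experiment")) bundles <- list(bundles)
  if (!length(bundles)) stop_domain("need at least one experiment bundle")
  mods <- unique(vapply(bundles, function(b) b$config$modality, ""))
  if (length(mods) > 1 && !allow_mixed)
    stop_domain("bundles mix modalities; pass allow_mixed = TRUE if intended")
  spectra <- do.call(rbind, lapply(bundles, function(b) {
    do.call(rbind, lapply(names(b$spectra), function(k) {
      cbind(modality = b$config$modality, q = as.integer(k), b$spectra[[k]])
    }))
  }))
  norms <- do.call(rbind, lapply(bundles, function(b)
    cbind(modality = b$config$modality, b$norms)))
  cross_sections <- lapply(bundles, function(b) {
    lapply(b$decompositions, function(d) {
      list(object = cross_section_xz(d$f),
           measurement = cross_section_xz(d$f_meas),
           null = cross_section_xz(d$f_null))
    })
  })
  names(cross_sections) <- vapply(bundles, function(b)
    sprintf("%s_seed%d", b$config$modality, b$config$seed), "")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(spectra, file.path(out_dir, "spectra.csv"),
                     row.names = FALSE)
    utils::write.csv(norms, file.path(out_dir, "null_norm_vs_q.csv"),
                     row.names = FALSE)
    for (nm in names(cross_sections))
      for (k in names(cross_sections[[nm]]))
        for (comp in names(cross_sections[[nm]][[k]]))
          utils::write.csv(
            cross_sections[[nm]][[k]][[comp]],
            file.path(out_dir, sprintf("xz_%s_q%s_%s.csv", nm, k, comp)),
            row.names = FALSE)
  }
  list(spectra = spectra, cross_sections = cross_sections, norms = norms)
}
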