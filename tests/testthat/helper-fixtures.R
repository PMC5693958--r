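# Shared fixtures. Everything is generated in code; the heavier objects are
# memoized so several test files can reuse them within one session.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache))
    assign(key, expr, envir = fixture_cache)
  get(key, envir = fixture_cache)
}

alpha_model <- function() range_energy_model()   # 5.15 MeV / 39.4 um / p = 1.8

alpha_geom <- function() slab_geometry(40, 160)

# 4-depth grid keeps kernels small while spanning the slab
small_alpha_grid <- function() depth_grid(c(6, 14, 22, 30), 40, dz = 8)

small_alpha_bins <- function(width = 2) bin_spec(width, 80, energy_max = 5160)

small_alpha_prf5 <- function() cached(
  "alpha_prf5",
  alpha_prf_grid(small_alpha_grid(), 5, small_alpha_bins(), alpha_model()))

small_alpha_prf <- function(q) {
  if (q == 5) return(small_alpha_prf5())
  cached(paste0("alpha_prf", q),
         marginalize_prf(small_alpha_prf5(), attribute_spec(q)))
}

small_alpha_system <- function(q, n_rho = 24) cached(
  sprintf("alpha_sys_%d_%d", q, n_rho),
  cpet_system(small_alpha_prf(q), small_alpha_grid(), n_rho = n_rho))

small_phantom_object <- function(voxel = 4) cached(
  sprintf("phantom_%g", voxel),
  build_test_object(default_phantom(alpha_geom()), alpha_geom(),
                    small_alpha_grid(), voxel))

beta_geom <- function() slab_geometry(100, 1024)

# Pearson chi-square p-value for observed counts vs expected counts from a
# known model (bins with small expectation are pooled by the caller)
chisq_pvalue <- function(observed, expected) {
  stopifnot(length(observed) == length(expected), all(expected > 0))
  x2 <- sum((observed - expected)^2 / expected)
  stats::pchisq(x2, df = length(observed), lower.tail = FALSE)
}

# chi-square comparison of a list-mode sample against an analytic PRF grid,
# pooling bins below `min_expected` expected counts into one class
prf_sampler_chisq <- function(prf, table, n_emitted, min_expected = 5) {
  counts <- histogram_listmode(table, prf$bins, prf$attrs,
                               n_emitted = n_emitted)
  key_cols <- setdiff(names(prf$cells), c("iz", "mass"))
  ek <- interaction_key(prf$cells[key_cols])
  ok <- interaction_key(counts$cells[key_cols])
  expected <- prf$cells$mass * n_emitted
  observed <- counts$cells$mass[match(ek, ok)] * n_emitted
  observed[is.na(observed)] <- 0
  # events in bins the analytic grid calls empty join the pooled class
  stray <- sum(counts$cells$mass[!ok %in% ek]) * n_emitted
  big <- expected >= min_expected
  obs <- c(observed[big], sum(observed[!big]) + stray)
  exp <- c(expected[big], sum(expected[!big]))
  keep <- exp > 0
  chisq_pvalue(obs[keep], exp[keep])
}

interaction_key <- cpetnull:::interaction_key
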