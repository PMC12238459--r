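## Dose engine: R-side wrappers around the compiled voxel transport, batch
## execution, merging and batch-statistics uncertainty grids.
##
## Conventions: a DoseBatch stores the per-primary normalized dose grid
## (Gy per decay) plus the raw sum of squared per-primary voxel doses
## (the DoseActor-style squared-dose accumulator).  Merged grids are
## primary-weighted averages of the per-primary batch grids, so the merged
## dose is itself Gy per decay; multiplying by the total primaries gives
## the total dose the printed formulas operate on.

ELECTRON_CUT_KEV <- 10

## pack a phantom for the compiled engine
grid_pack <- function(phantom) {
  registry <- material_registry()
  tab <- phantom$label_table
  mat_names <- c("air", tab$material)
  midx <- match(mat_names, registry$name) - 1L     # 0-based
  key <- match(phantom$label, c(0L, tab$label))
  rt <- load_range_table()
  list(dims = dim(phantom$label),
       voxel_mm = phantom$voxel_mm,
       mat = array(midx[key], dim(phantom$label)),
       density = registry$density,
       sps = registry$stopping_power_scale,
       mu_egrid = attr(registry, "egrid_kev"),
       mu_pe = attr(registry, "mu_pe"),
       mu_co = attr(registry, "mu_compton"),
       range_egrid = rt$energy_kev,
       range_gcm2 = rt$csda_range_g_cm2)
}

emission_pack <- function(model = build_spectrum()) {
  lines <- model$lines
  list(beta_invcdf = beta_inverse_cdf(model$spectrum),
       beta_yield = model$beta_yield,
       line_energy = lines$energy_kev,
       line_yield = lines$yield,
       line_is_photon = as.integer(lines$kind %in% c("gamma", "xray")))
}

#' Run one simulation batch
#'
#' Simulates `n_primaries` decays drawn from a normalized activity image
#' (uniform position within the chosen voxel), transports all emissions,
#' and accumulates per-voxel dose and squared dose.  Deterministic for a
#' fixed (seed, n) on one platform.
#'
#' @param phantom a `voxel_phantom`.
#' @param activity an `activity_image` from [make_source_image()].
#' @param n_primaries number of decays (>= 1).
#' @param seed integer RNG seed for this batch.
#' @param model emission model (defaults to bundled Lu-177).
#' @param electrons_only if TRUE, photon lines are skipped (used by the
#'   energy-conservation checks).
#' @param step_mm electron step length override, mm (default: half a
#'   voxel); smaller steps are used by the discretization-convergence
#'   oracle.
#' @return object of class `dose_batch`: `dose` (3D array, Gy per decay),
#'   `dose_sq` (3D array, raw sum of squared per-decay voxel doses, Gy^2),
#'   `n_primaries`, `seed`, `emitted_kev`, `deposited_kev`.
#' @export
run_batch <- function(phantom, activity, n_primaries, seed,
                      model = build_spectrum(), electrons_only = FALSE,
                      step_mm = NULL) {
  stopifnot(n_primaries >= 1)
  s <- sum(activity$grid)
  if (abs(s - 1) > 1e-6) stop("activity image is not normalized (sum = ", s, ")")
  src <- which(activity$grid > 0)
  cdf <- cumsum(activity$grid[src])
  cdf <- cdf / cdf[length(cdf)]
  out <- cpp_run_batch(grid_pack(phantom), emission_pack(model),
                       as.integer(src - 1L), cdf,
                       n_primaries, as.integer(seed), ELECTRON_CUT_KEV,
                       electrons_only, if (is.null(step_mm)) 0 else step_mm)
  structure(list(dose = array(out$dose, dim(phantom$label)),
                 dose_sq = array(out$dose_sq, dim(phantom$label)),
                 n_primaries = n_primaries, seed = seed,
                 emitted_kev = out$emitted_kev,
                 deposited_kev = out$deposited_kev),
            class = "dose_batch")
}

#' Merge simulation batches
#'
#' Primary-weighted average of the per-primary batch dose grids,
#' D_k = sum_i n_i D_k,i / sum_i n_i; the total primary count is
#' N = sum_i n_i.  Order-independent.
#'
#' @param batches list of `dose_batch` objects on congruent grids.
#' @return object of class `merged_dose`: `dose` (Gy per decay),
#'   `n_primaries` (total N), `n_batches`.
#' @export
merge_batches <- function(batches) {
  if (inherits(batches, "dose_batch")) batches <- list(batches)
  stopifnot(length(batches) >= 1)
  d0 <- dim(batches[[1]]$dose)
  for (b in batches)
    if (!identical(dim(b$dose), d0)) stop("batch grids have mismatched shapes")
  ## canonical accumulation order (by seed, then size) so that merging is
  ## bit-identical regardless of the order batches are supplied in
  seeds <- vapply(batches, function(b) as.numeric(b$seed %||% 0), 0.0)
  sizes <- vapply(batches, function(b) b$n_primaries, 0.0)
  batches <- batches[order(seeds, sizes)]
  n <- vapply(batches, function(b) b$n_primaries, 0.0)
  acc <- array(0, d0)
  for (i in seq_along(batches)) acc <- acc + n[i] * batches[[i]]$dose
  structure(list(dose = acc / sum(n), n_primaries = sum(n),
                 n_batches = length(batches)),
            class = "merged_dose")
}

#' Batch-statistics dose uncertainty
#'
#' History-by-history style estimator applied over the per-primary
#' normalized batch realizations D_k,i (N = number of batches):
#' delta D_k = sqrt( (1/(N-1)) ( sum D^2 / N - (sum D / N)^2 ) ),
#' eps_k = delta D_k / D_k where D_k > 0 (NA elsewhere).
#'
#' @param batches list of >= 2 `dose_batch` objects.
#' @return object of class `uncertainty_grid`: `delta` (Gy per decay),
#'   `rel` (unitless, NA where the merged dose is zero), `n_batches`.
#' @export
batch_uncertainty <- function(batches) {
  if (length(batches) < 2) stop("need at least 2 batches for uncertainty")
  d0 <- dim(batches[[1]]$dose)
  N <- length(batches)
  s1 <- array(0, d0); s2 <- array(0, d0)
  for (b in batches) {
    if (!identical(dim(b$dose), d0)) stop("batch grids have mismatched shapes")
    s1 <- s1 + b$dose
    s2 <- s2 + b$dose^2
  }
  varg <- pmax(s2 / N - (s1 / N)^2, 0) / (N - 1)
  delta <- sqrt(varg)
  mean_d <- s1 / N
  rel <- ifelse(mean_d > 0, delta / mean_d, NA_real_)
  structure(list(delta = delta, rel = array(rel, d0), n_batches = N),
            class = "uncertainty_grid")
}

#' Single-particle transport (testing interface)
#'
#' Transport one electron or photon through a phantom and return the
#' total deposited energy and the per-voxel deposit grid in keV.
#'
#' @param phantom a `voxel_phantom`.
#' @param energy_kev initial kinetic energy, keV.
#' @param position_mm world position (inside the grid), mm.
#' @param direction direction vector (normalized internally).
#' @param seed RNG seed (photons only).
#' @param step_mm electron step length override, mm (default half a voxel).
#' @return list with `deposited_kev` and `grid_kev` (3D array).
#' @export
transport_electron <- function(phantom, energy_kev, position_mm, direction,
                               step_mm = NULL) {
  stopifnot(energy_kev > 0)
  out <- cpp_transport_electron(grid_pack(phantom), energy_kev, position_mm,
                                direction, ELECTRON_CUT_KEV,
                                if (is.null(step_mm)) 0 else step_mm)
  out$grid_kev <- array(out$grid_kev, dim(phantom$label))
  out
}

#' @rdname transport_electron
#' @export
transport_photon <- function(phantom, energy_kev, position_mm, direction,
                             seed = 1L) {
  stopifnot(energy_kev > 0)
  out <- cpp_transport_photon(grid_pack(phantom), energy_kev, position_mm,
                              direction, as.integer(seed))
  out$grid_kev <- array(out$grid_kev, dim(phantom$label))
  out
}

#' Batch seeds derived from a master seed
#'
#' Child seed sequence: `master * 1000 + source_index * 100 + batch index`,
#' kept below 2^31.  Documented so any grid can be re-derived from the run
#' manifest.
#'
#' @param master_seed master integer seed.
#' @param n_batches number of batches.
#' @param source_index 1-based index of the source in the run.
#' @return integer vector of per-batch seeds.
#' @export
batch_seeds <- function(master_seed, n_batches, source_index = 1L) {
  base <- (as.numeric(master_seed) * 1000 + source_index * 100) %% 2^31
  as.integer((base + seq_len(n_batches) - 1) %% 2^31)
}
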