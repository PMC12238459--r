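## Sphere validation surface: self-dose S-values of unit-density spheres
## uniformly filled with Lu-177, the geometry-simple, physics-determined
## quantity the engine is validated against.

#' Phantom of a single sphere inside a soft-tissue block
#'
#' Voxelizes a sphere of the given mass and density (diameter from
#' V = m/rho) centred in a soft-tissue block with a configurable margin on
#' all sides, at the requested voxel size.
#'
#' @param mass_g sphere mass, g.
#' @param voxel_mm isotropic voxel size, mm (0.29 for the high-resolution
#'   configuration, 0.625 for the low-resolution one).
#' @param density_g_cm3 sphere density, g/cm^3.
#' @param margin_mm soft-tissue margin around the sphere, mm; the default
#'   exceeds twice the maximum beta range in tissue.
#' @return a `voxel_phantom` with regions "body" and "sphere".
#' @export
sphere_phantom <- function(mass_g, voxel_mm, density_g_cm3 = 1.0,
                           margin_mm = 4) {
  d_mm <- (6 * mass_g / (pi * density_g_cm3))^(1 / 3) * 10
  n <- ceiling((d_mm + 2 * margin_mm) / voxel_mm)
  ctr <- rep(n * voxel_mm / 2, 3)
  build_phantom(list(
    resolution = list(dim = rep(n, 3), voxel_mm = voxel_mm),
    body = solid_box("body", ctr, rep(n * voxel_mm / 2, 3), class = "body"),
    organs = list(solid_sphere("sphere", ctr, d_mm / 2, material = "tumour"))))
}

#' Self-dose S-value of a uniformly filled sphere
#'
#' Simulates decays uniformly distributed over the voxelized sphere in
#' `n_batches` batches, merges them, and returns the sphere self-dose
#' S-value with its propagated uncertainty.
#'
#' @inheritParams sphere_phantom
#' @param n_primaries total number of decays across batches.
#' @param n_batches number of independent batches (>= 2 for uncertainty).
#' @param seed master seed; per-batch seeds follow [batch_seeds()].
#' @param model emission model (bundled Lu-177 by default).
#' @return list: `s_per_decay` (Gy/(Bq s)), `s_per_mbq_s` (Gy/(MBq s)),
#'   `delta_s_per_decay`, `rel_unc_pct`, `mass_voxelized_g`, `n_primaries`.
#' @export
sphere_self_svalue <- function(mass_g, voxel_mm, n_primaries = 2e6,
                               n_batches = 10, seed = 1,
                               density_g_cm3 = 1.0, model = build_spectrum()) {
  ph <- sphere_phantom(mass_g, voxel_mm, density_g_cm3)
  act <- make_source_image(ph, "sphere")
  per_batch <- ceiling(n_primaries / n_batches)
  seeds <- batch_seeds(seed, n_batches)
  batches <- lapply(seeds, function(s) run_batch(ph, act, per_batch, s, model))
  merged <- merge_batches(batches)
  unc <- batch_uncertainty(batches)
  mask <- organ_mask(ph, "sphere")
  N <- merged$n_primaries
  s <- compute_svalue(mean_organ_dose(merged$dose * N, mask), N)
  ds <- svalue_uncertainty(unc$delta * N, mask, N)
  list(s_per_decay = s, s_per_mbq_s = s_per_decay_to_per_mbq_s(s),
       delta_s_per_decay = ds,
       rel_unc_pct = if (s > 0) 100 * ds / s else NA_real_,
       mass_voxelized_g = organ_mass(ph, "sphere"), n_primaries = N)
}
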