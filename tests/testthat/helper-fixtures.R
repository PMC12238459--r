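## Shared fixtures: small phantoms built in code.

## cube of water with an embedded sphere organ (voxel_mm in mm)
fixture_sphere <- function(radius_vox = 5, voxel_mm = 0.5, n = NULL,
                           material = "soft_tissue") {
  if (is.null(n)) n <- 2L * radius_vox + 7L
  ctr <- rep(n * voxel_mm / 2, 3)
  build_phantom(list(
    resolution = list(dim = rep(as.integer(n), 3), voxel_mm = voxel_mm),
    body = solid_box("body", ctr, rep(n * voxel_mm / 2, 3), class = "body"),
    organs = list(solid_sphere("sphere", ctr, radius_vox * voxel_mm,
                               material = material))))
}

## homogeneous soft-tissue block, no organs
fixture_block <- function(n = 20L, voxel_mm = 1) {
  ctr <- rep(n * voxel_mm / 2, 3)
  build_phantom(list(
    resolution = list(dim = rep(as.integer(n), 3), voxel_mm = voxel_mm),
    body = solid_box("body", ctr, rep(n * voxel_mm / 2, 3), class = "body"),
    organs = list()))
}

## tiny two-organ phantom for pipeline smoke tests
fixture_two_organs <- function(n = 24L, voxel_mm = 1) {
  c1 <- c(7, 12, 12); c2 <- c(17, 12, 12)
  build_phantom(list(
    resolution = list(dim = rep(as.integer(n), 3), voxel_mm = voxel_mm),
    body = solid_box("body", rep(12, 3), rep(12, 3), class = "body"),
    organs = list(solid_sphere("organ a", c1, 3.5),
                  solid_sphere("organ b", c2, 3.5))))
}

## single-line emission model: one electron line, always emitted
fixture_local_model <- function(energy_kev = 5) {
  spectrum <- structure(list(energy_grid = c(1, 2), pdf = c(1, 0),
                             endpoint = 2), class = "beta_spectrum")
  structure(list(spectrum = spectrum,
                 lines = data.frame(kind = "auger", energy_kev = energy_kev,
                                    yield = 1.0, shape = ""),
                 beta_yield = 0, mean_beta_kev = 0,
                 mean_electron_kev = energy_kev, mean_photon_kev = 0),
            class = "emission_model")
}

## cached Lu-177 model (spectrum build is cheap but used everywhere)
lu177_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_spectrum()
    m
  }
})
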