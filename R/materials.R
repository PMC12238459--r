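## Material registry and photon attenuation model.
##
## Electron transport uses the water CSDA range scaled by density and the
## mass-stopping-power ratio to water; photon transport uses per-material
## linear attenuation split into incoherent (Klein-Nishina x electron
## density) and photoelectric (parametric Z_eff/E^3 scaling anchored on
## water) components.  Rayleigh and bound-electron effects are neglected.

# energy grid on which mu tables are tabulated (keV)
MU_EGRID_KEV <- exp(seq(log(10), log(500), length.out = 80))

#' Material specification
#'
#' A material as used by the phantom and the dose engine: density, a linear
#' attenuation table over 10-500 keV, and the mass stopping power ratio to
#' water.
#'
#' @param name material name.
#' @param density mass density in g/cm^3.
#' @param mu_by_energy data.frame with columns `energy_kev` and `mu_cm`
#'   (linear attenuation, 1/cm), monotone-interpolable over 10-500 keV.
#' @param stopping_power_scale mass collision stopping power relative to
#'   water (unitless).
#' @return object of class `material_spec`.
#' @export
material_spec <- function(name, density, mu_by_energy, stopping_power_scale = 1) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(density) || density <= 0) stop("density must be > 0")
  if (!all(c("energy_kev", "mu_cm") %in% names(mu_by_energy)))
    stop("mu_by_energy needs columns energy_kev, mu_cm")
  if (any(mu_by_energy$mu_cm < 0)) stop("mu values must be >= 0")
  if (is.unsorted(mu_by_energy$energy_kev, strictly = TRUE))
    stop("mu_by_energy must be strictly increasing in energy")
  structure(list(name = name, density = density,
                 mu_by_energy = mu_by_energy,
                 stopping_power_scale = stopping_power_scale),
            class = "material_spec")
}

## Klein-Nishina total cross-section per electron, cm^2 (E in keV)
kn_sigma <- function(E) {
  k <- E / 511.0
  re2 <- 7.940787e-26  # r_e^2 in cm^2
  2 * pi * re2 * ((1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k) +
                    log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2)
}

## water mass attenuation components, cm^2/g
water_mu_en_components <- function(E) {
  ne_water <- 3.343e23  # electrons per gram
  compton <- kn_sigma(E) * ne_water
  # photoelectric: parametric fit anchored at tau/rho(30 keV) = 0.0927 cm^2/g
  pe <- 0.0927 * (30 / E)^3.05
  list(compton = compton, pe = pe)
}

#' Bundled material registry
#'
#' Returns the registry of bundled materials (air, water, soft tissue,
#' tumour, bone, marrow, lung) with densities, stopping-power scales and
#' attenuation component tables evaluated on the working energy grid.
#'
#' @return data.frame with one row per material plus attribute tables
#'   `mu_pe` and `mu_compton` (matrices, material x energy, 1/cm) and
#'   `egrid_kev`.
#' @export
material_registry <- function() {
  mats <- vd_read_table("materials.csv")
  E <- MU_EGRID_KEV
  w <- water_mu_en_components(E)
  mu_co <- outer(mats$density * mats$compton_scale, w$compton)    # 1/cm
  zr <- (mats$zeff / 7.42)^3.1
  mu_pe <- outer(mats$density * mats$compton_scale * zr, w$pe)    # 1/cm
  rownames(mu_co) <- rownames(mu_pe) <- mats$name
  attr(mats, "mu_compton") <- mu_co
  attr(mats, "mu_pe") <- mu_pe
  attr(mats, "egrid_kev") <- E
  mats
}

## lookup a material row; error on unknown name
material_row <- function(registry, name) {
  i <- match(name, registry$name)
  if (is.na(i)) stop("unknown material: ", name)
  i
}

#' Material as a `material_spec`
#'
#' @param name one of the bundled material names.
#' @param registry a registry from [material_registry()].
#' @return a [material_spec()] object.
#' @export
get_material <- function(name, registry = material_registry()) {
  i <- material_row(registry, name)
  mu <- attr(registry, "mu_pe")[i, ] + attr(registry, "mu_compton")[i, ]
  material_spec(name, registry$density[i],
                data.frame(energy_kev = attr(registry, "egrid_kev"), mu_cm = mu),
                registry$stopping_power_scale[i])
}
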