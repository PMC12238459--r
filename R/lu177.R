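## Lu-177 emission model: beta spectrum from branch data via the
## relativistic Fermi function, discrete electron/photon lines, samplers,
## and electron range utilities built on the bundled water CSDA table.

MEC2_KEV <- 510.99895
ALPHA_FS <- 1 / 137.035999
J_PER_KEV <- 1.602176634e-16

## relativistic Fermi function F(Z, T) for beta-minus, point-ish nucleus with
## finite-size factor (2 p R)^(2 gamma - 2); T in keV, vectorized
fermi_function <- function(T, Z = 72, A = 177) {
  W <- 1 + T / MEC2_KEV
  p <- sqrt(pmax(W^2 - 1, 1e-12))
  g <- sqrt(1 - (ALPHA_FS * Z)^2)
  nu <- ALPHA_FS * Z * W / p
  Rn <- 0.426 * ALPHA_FS * A^(1 / 3)
  # |Gamma(g + i nu)|^2 via the complex log-gamma Lanczos expansion
  lg <- Re(vd_lgamma_complex(g, nu))
  2 * (1 + g) * (2 * p * Rn)^(2 * g - 2) *
    exp(pi * nu + 2 * (lg - lgamma(2 * g + 1)))
}

## Re(log Gamma(x + i y)) by Lanczos approximation (g=7, n=9), vectorized in y
vd_lgamma_complex <- function(x, y) {
  cf <- c(0.99999999999980993, 676.5203681218851, -1259.1392167224028,
          771.32342877765313, -176.61502916214059, 12.507343278686905,
          -0.13857109526572012, 9.9843695780195716e-6, 1.5056327351493116e-7)
  z <- complex(real = x - 1, imaginary = y)
  s <- cf[1]
  for (k in 1:8) s <- s + cf[k + 1] / (z + k)
  t <- z + 7.5
  Re(0.5 * log(2 * pi) + (z + 0.5) * log(t) - t + log(s))
}

load_decay_data <- function() vd_read_table("lu177_decay.csv")

load_range_table <- function() vd_read_table("water_csda_range.csv")

#' Build the Lu-177 emission model
#'
#' Constructs the combined beta spectrum from the bundled branch data
#' (relativistic Fermi function, allowed shape - the forbidden transitions
#' of Lu-177 are non-unique and take the allowed shape) and collects the
#' discrete electron and photon lines.
#'
#' @param decay_dataset data.frame in the bundled decay-table schema
#'   (columns kind, energy_kev, yield, shape); defaults to the bundled
#'   Lu-177 table.
#' @param egrid_kev energy grid (keV) for the spectrum probability density.
#' @return list of class `emission_model` with elements `spectrum` (class
#'   `beta_spectrum`: energy_grid, pdf per keV conditional on a beta being
#'   emitted, endpoint), `lines` (data.frame of discrete lines),
#'   `beta_yield`, and the per-decay mean energies `mean_electron_kev`,
#'   `mean_photon_kev`.
#' @export
build_spectrum <- function(decay_dataset = load_decay_data(),
                           egrid_kev = seq(0.25, 500, by = 0.25)) {
  d <- decay_dataset
  if (any(d$yield < 0) || any(d$energy_kev <= 0))
    stop("decay data: yields must be >= 0 and energies > 0")
  betas <- d[d$kind == "beta_branch", ]
  lines <- d[d$kind != "beta_branch", ]
  elec_yield <- sum(betas$yield) +
    sum(lines$yield[lines$kind %in% c("conversion_electron", "auger")])
  if (elec_yield < 0.9 || elec_yield > 1.5)
    stop(sprintf("implausible total electron yield per decay: %.3f", elec_yield))

  E <- egrid_kev
  pdf <- numeric(length(E))
  for (i in seq_len(nrow(betas))) {
    Q <- betas$energy_kev[i]
    W <- 1 + E / MEC2_KEV; W0 <- 1 + Q / MEC2_KEV
    p <- sqrt(pmax(W^2 - 1, 1e-12)); q <- pmax(W0 - W, 0)
    f <- p * W * q^2 * fermi_function(E)
    f[E >= Q] <- 0
    f <- f / trapz(E, f)
    pdf <- pdf + betas$yield[i] * f
  }
  beta_yield <- sum(betas$yield)
  pdf <- pdf / trapz(E, pdf)  # conditional on a beta being emitted
  endpoint <- max(betas$energy_kev)

  mean_beta <- trapz(E, pdf * E)
  is_e <- lines$kind %in% c("conversion_electron", "auger")
  mean_elec <- mean_beta * beta_yield + sum(lines$energy_kev[is_e] * lines$yield[is_e])
  mean_phot <- sum(lines$energy_kev[!is_e] * lines$yield[!is_e])

  spectrum <- structure(list(energy_grid = E, pdf = pdf, endpoint = endpoint),
                        class = "beta_spectrum")
  structure(list(spectrum = spectrum, lines = lines, beta_yield = beta_yield,
                 mean_beta_kev = mean_beta, mean_electron_kev = mean_elec,
                 mean_photon_kev = mean_phot),
            class = "emission_model")
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

## inverse-CDF lookup table for beta energy sampling (n equiprobable nodes)
beta_inverse_cdf <- function(spectrum, n = 4096) {
  E <- spectrum$energy_grid
  cdf <- c(0, cumsum(diff(E) * (spectrum$pdf[-1] + spectrum$pdf[-length(E)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  keep <- !duplicated(cdf)
  approx(cdf[keep], E[keep], xout = seq(0, 1, length.out = n), rule = 2)$y
}

#' Sample Lu-177 emissions for a number of decays
#'
#' Per decay, a beta electron is emitted with probability equal to the total
#' branch yield (energy drawn by inverse-CDF from the combined spectrum) and
#' each discrete line independently with probability equal to its yield.
#'
#' @param rng_seed integer seed (results are reproducible for a fixed seed).
#' @param n number of decays (>= 0).
#' @param model emission model from [build_spectrum()].
#' @return data.frame with columns `decay` (index), `kind`, `energy_kev`.
#' @export
sample_emissions <- function(rng_seed, n, model = build_spectrum()) {
  stopifnot(n >= 0)
  if (n == 0)
    return(data.frame(decay = integer(), kind = character(), energy_kev = numeric()))
  set.seed(rng_seed)
  inv <- beta_inverse_cdf(model$spectrum)
  out <- list()
  nb <- which(runif(n) < model$beta_yield)
  if (length(nb))
    out[[1]] <- data.frame(decay = nb, kind = "beta",
                           energy_kev = inv[pmax(1L, ceiling(runif(length(nb)) * length(inv)))])
  for (i in seq_len(nrow(model$lines))) {
    hit <- which(runif(n) < model$lines$yield[i])
    if (length(hit))
      out[[length(out) + 1]] <- data.frame(decay = hit, kind = model$lines$kind[i],
                                           energy_kev = model$lines$energy_kev[i])
  }
  res <- do.call(rbind, out)
  res[order(res$decay), , drop = FALSE]
}

#' CSDA range of an electron in a material
#'
#' Log-log interpolation of the bundled water CSDA range table, scaled by
#' the material's density and mass-stopping-power ratio to water.
#'
#' @param energy_kev electron kinetic energy in keV (within the table span).
#' @param material a [material_spec()].
#' @return range in mm.
#' @export
csda_range <- function(energy_kev, material) {
  rt <- load_range_table()
  lo <- min(rt$energy_kev[rt$csda_range_g_cm2 > 0]); hi <- max(rt$energy_kev)
  if (any(energy_kev < lo | energy_kev > hi))
    stop(sprintf("energy outside range table span [%.3g, %.3g] keV", lo, hi))
  ok <- rt$csda_range_g_cm2 > 0
  r_gcm2 <- exp(approx(log(rt$energy_kev[ok]), log(rt$csda_range_g_cm2[ok]),
                       xout = log(energy_kev))$y)
  r_gcm2 / (material$density * material$stopping_power_scale) * 10  # cm -> mm
}

#' Mean and maximum beta range in a material
#'
#' The maximum range is the CSDA range at the spectrum endpoint.  The "mean
#' range" is reported under two documented definitions which differ for a
#' continuous spectrum: the range evaluated at the mean spectrum energy, and
#' the expectation of the range over the spectrum.
#'
#' @param spectrum a `beta_spectrum` (or an `emission_model`).
#' @param material a [material_spec()].
#' @return list with `mean_range_at_mean_energy_mm`,
#'   `mean_range_expectation_mm`, `max_range_mm` (all mm).
#' @export
beta_range_summary <- function(spectrum, material) {
  if (inherits(spectrum, "emission_model")) spectrum <- spectrum$spectrum
  E <- spectrum$energy_grid; pdf <- spectrum$pdf
  mean_E <- trapz(E, pdf * E)
  ok <- E >= 1.1  # below the table floor the range is negligible
  r <- csda_range(pmin(E[ok], spectrum$endpoint), material)
  list(mean_range_at_mean_energy_mm = csda_range(mean_E, material),
       mean_range_expectation_mm = trapz(E[ok], pdf[ok] * r) / trapz(E[ok], pdf[ok]),
       max_range_mm = csda_range(spectrum$endpoint, material))
}
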