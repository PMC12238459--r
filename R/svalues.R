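## S-value pipeline: the dose-to-S-value arithmetic, propagated
## uncertainties, mass correction against reference phantoms, and the
## tumour-size sensitivity metric.
##
## Internal unit is Gy per decay (= Gy/(Bq s)); unit helpers convert to the
## Gy/(MBq s) convention used for sphere/tumour tables (factor 1e6).

#' Mean dose in a target organ
#'
#' Unweighted voxel mean over the mask, exactly as the printed estimator:
#' Dbar = sum_k D_k / v.  A mass-weighted variant is available via
#' `weights`.
#'
#' @param merged a `merged_dose` (or any object with a `dose` array), or a
#'   bare 3D array of total dose in Gy.
#' @param mask an [organ_mask()] (integer voxel indices).
#' @param weights optional per-voxel weights (e.g. voxel masses) for the
#'   non-default mass-weighted mean.
#' @return mean dose in the grid's dose unit.
#' @export
mean_organ_dose <- function(merged, mask, weights = NULL) {
  g <- if (is.list(merged)) merged$dose else merged
  if (!length(mask)) stop("empty organ mask")
  if (any(mask < 1 | mask > length(g))) stop("mask outside grid")
  if (is.null(weights)) mean(g[mask])
  else sum(g[mask] * weights) / sum(weights)
}

#' S-value from mean dose and primaries
#'
#' S(target <- source) = Dbar / N where Dbar is the mean target dose in Gy
#' accumulated over N simulated decays.
#'
#' @param mean_dose mean target dose, Gy.
#' @param n_primaries number of simulated decays (>= 1).
#' @return S-value in Gy per decay (Gy/(Bq s)).
#' @export
compute_svalue <- function(mean_dose, n_primaries) {
  stopifnot(n_primaries >= 1)
  mean_dose / n_primaries
}

#' Unit conversions for S-values
#'
#' Gy per decay (Gy/(Bq s)) to Gy/(MBq s) and back: a factor 1e6.
#'
#' @param s S-value(s).
#' @return converted value(s).
#' @export
s_per_decay_to_per_mbq_s <- function(s) s * 1e6

#' @rdname s_per_decay_to_per_mbq_s
#' @export
s_per_mbq_s_to_per_decay <- function(s) s / 1e6

#' Propagated S-value uncertainty
#'
#' delta S = sqrt( sum_k delta D_k^2 ) / (N v) over the target mask, with
#' delta D_k the per-voxel statistical dose uncertainty on the same (total
#' dose) scale used for Dbar.
#'
#' @param unc an `uncertainty_grid` (or a bare 3D array of delta D_k, Gy).
#' @param mask an [organ_mask()].
#' @param n_primaries number of simulated decays.
#' @return delta S in Gy per decay.
#' @export
svalue_uncertainty <- function(unc, mask, n_primaries) {
  d <- if (is.list(unc)) unc$delta else unc
  if (!length(mask)) stop("empty organ mask")
  sqrt(sum(d[mask]^2)) / (n_primaries * length(mask))
}

#' Build an S-value table from per-source merged doses
#'
#' One record per (source, target) over all masks, plus aggregate targets:
#' the bone-marrow union (all marrow labels) and the whole-skeleton union
#' (bone + marrow labels).  Relative uncertainties are populated as
#' 100 * delta S / S.
#'
#' The per-primary merged grids and batch-statistics delta grids are
#' internally rescaled to the total-dose scale so the printed formulas
#' S = Dbar/N and delta S = sqrt(sum delta^2)/(N v) apply as written.
#'
#' @param merged_by_source named list (source organ -> `merged_dose`).
#' @param unc_by_source named list (source organ -> `uncertainty_grid`),
#'   may be NULL for tables without uncertainties.
#' @param masks named list (target organ -> [organ_mask()]).
#' @param n_by_source named numeric (source organ -> total primaries); if
#'   NULL, taken from each `merged_dose`.
#' @return data.frame of class `svalue_table` with columns source, target,
#'   s (Gy/(Bq s)), delta_s, rel_unc_pct.
#' @export
build_svalue_table <- function(merged_by_source, unc_by_source = NULL,
                               masks, n_by_source = NULL) {
  sources <- names(merged_by_source)
  if (is.null(sources)) stop("merged_by_source must be a named list")
  if (!is.null(unc_by_source) && !all(sources %in% names(unc_by_source)))
    stop("missing uncertainty grids for some sources")
  rows <- list()
  for (src in sources) {
    merged <- merged_by_source[[src]]
    N <- if (!is.null(n_by_source)) n_by_source[[src]] else merged$n_primaries
    if (is.null(N)) stop("missing primaries count for source ", src)
    total <- merged$dose * N           # total-dose scale
    unc <- unc_by_source[[src]]
    delta_total <- if (!is.null(unc)) unc$delta * N else NULL
    targets <- c(masks, aggregate_masks(masks))
    for (tgt in names(targets)) {
      mask <- targets[[tgt]]
      s <- compute_svalue(mean_organ_dose(total, mask), N)
      ds <- if (!is.null(delta_total))
        svalue_uncertainty(delta_total, mask, N) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        source = src, target = tgt, s = s, delta_s = ds,
        rel_unc_pct = if (!is.na(ds) && s > 0) 100 * ds / s else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("svalue_table", class(out))
  out
}

## aggregate targets: BM = union of marrow masks, Skeleton = bone + marrow
aggregate_masks <- function(masks) {
  agg <- list()
  marrow <- grep("marrow", names(masks), ignore.case = TRUE, value = TRUE)
  bone <- attr(masks, "bone_targets")
  if (length(marrow) > 1 || (!is.null(bone) && length(bone)))
    agg[["BM"]] <- sort(unique(unlist(masks[marrow], use.names = FALSE)))
  skel <- unique(c(marrow, bone))
  if (length(skel) > 1)
    agg[["Skeleton"]] <- sort(unique(unlist(masks[skel], use.names = FALSE)))
  agg[vapply(agg, length, 0L) > 0]
}

#' Organ masks for all labels of a phantom
#'
#' @param phantom a `voxel_phantom`.
#' @param organs optional character vector restricting the organs.
#' @return named list of [organ_mask()]s with attribute `bone_targets`
#'   naming the skeleton-class organs (used for aggregate targets).
#' @export
phantom_masks <- function(phantom, organs = NULL) {
  tab <- phantom$label_table
  if (is.null(organs)) organs <- tab$organ
  masks <- lapply(organs, function(o) organ_mask(phantom, o))
  names(masks) <- organs
  attr(masks, "bone_targets") <-
    tab$organ[tab$class == "skeleton" & tab$organ %in% organs]
  masks
}

#' Mass-corrected S-value
#'
#' Scales a computed S-value to a reference phantom's organ mass:
#' S_corrected = S_computed * (m_phantom / m_reference).
#'
#' @param s_computed computed S-value.
#' @param m_phantom organ mass in this phantom, g (> 0).
#' @param m_reference organ mass in the reference phantom, g (> 0).
#' @return corrected S-value.
#' @export
mass_correct <- function(s_computed, m_phantom, m_reference) {
  if (any(m_phantom <= 0) || any(m_reference <= 0))
    stop("organ masses must be > 0")
  s_computed * (m_phantom / m_reference)
}

#' Percent difference against a reference
#'
#' 100 * (a - b) / b.
#'
#' @param a computed value(s).
#' @param b_reference reference value(s), nonzero.
#' @return percent difference(s).
#' @export
percent_difference <- function(a, b_reference) {
  if (any(b_reference == 0)) stop("zero reference value")
  100 * (a - b_reference) / b_reference
}

#' Tumour-size sensitivity of S-values
#'
#' Change in S-value relative to the smallest tumour mass present:
#' 100 * (S(m) - S(m0)) / S(m0); exactly 0 at m0.
#'
#' @param table_by_mass named list or numeric: tumour mass (as name or a
#'   `mass` column) -> S-value for the chosen target.
#' @return data.frame with columns mass_g, s, change_pct (sorted by mass).
#' @export
tumour_relative_change <- function(table_by_mass) {
  if (is.list(table_by_mass) && !is.data.frame(table_by_mass))
    table_by_mass <- unlist(table_by_mass)
  m <- as.numeric(names(table_by_mass))
  if (any(is.na(m))) stop("masses must be supplied as names")
  if (length(m) < 2) stop("need at least two tumour masses")
  o <- order(m)
  m <- m[o]; s <- as.numeric(table_by_mass)[o]
  s0 <- s[1]
  if (s0 == 0) stop("S at the smallest mass is zero")
  data.frame(mass_g = m, s = s, change_pct = 100 * (s - s0) / s0)
}

#' Format an S-value for reports
#'
#' Three significant figures in scientific notation, matching the table
#' style of published S-value compendia.
#'
#' @param s numeric S-value(s).
#' @return character vector.
#' @export
format_svalue <- function(s) formatC(s, format = "e", digits = 2)
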