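## Default rodent-like anatomy and run configuration handling.
##
## The default anatomy is a documented analytic approximation of a ~25 g
## mouse: a soft-tissue body ellipsoid, a skull shell with a brain, a spine
## and four long bones (each with an inner marrow core), heart and stomach
## as hollow shells, lungs at 0.3 g/cm^3, liver, kidneys, spleen, bladder
## and testes.  Coordinates are world mm with the grid corner at 0; the
## subcutaneous left-shoulder tumour site sits on the body surface, clear
## of all bone for tumours up to the largest sweep mass.

#' Default mouse-like phantom configuration
#'
#' @param resolution "lr" (0.625 mm voxels) or "hr" (0.29 mm), or a custom
#'   list(dim, voxel_mm).
#' @param target_mass_g whole-body mass target, g (isotropic scaling).
#' @return a configuration list for [build_phantom()].
#' @export
mouse_config <- function(resolution = "hr", target_mass_g = 25) {
  c0 <- c(18.5, 18.5, 55)
  organs <- list(
    solid_shell("skull", c(18.5, 18.5, 92), c(5.4, 5.4, 5.4), 1.5,
                material = "bone", class = "skeleton"),
    solid_sphere("brain", c(18.5, 18.5, 92), 3.6),
    solid_capsule("spine", c(18.5, 23.0, 12), c(18.5, 21.5, 84), 2.0),
    solid_capsule("humerus left", c(24.0, 18.5, 72), c(27.5, 18.5, 62), 1.6),
    solid_capsule("humerus right", c(13.0, 18.5, 72), c(9.5, 18.5, 62), 1.6),
    solid_capsule("femur left", c(26.0, 18.5, 22), c(30.0, 18.5, 13), 1.6),
    solid_capsule("femur right", c(11.0, 18.5, 22), c(7.0, 18.5, 13), 1.6),
    solid_shell("heart", c(16.0, 14.0, 70), c(4.0, 4.0, 4.5), 1.5),
    solid_ellipsoid("lung left", c(24.5, 15.0, 73), c(3.8, 4.5, 6.5),
                    material = "lung"),
    solid_ellipsoid("lung right", c(8.5, 15.0, 73), c(3.8, 4.5, 6.5),
                    material = "lung"),
    solid_ellipsoid("liver", c(18.5, 15.0, 58), c(7.5, 5.5, 6.0)),
    solid_shell("stomach wall", c(12.5, 19.0, 50), c(3.5, 3.0, 3.5), 1.0),
    solid_ellipsoid("kidney left", c(24.0, 20.0, 42), c(2.5, 2.0, 3.5)),
    solid_ellipsoid("kidney right", c(13.0, 20.0, 42), c(2.5, 2.0, 3.5)),
    solid_ellipsoid("spleen", c(25.5, 16.0, 50), c(2.5, 1.8, 3.0)),
    solid_sphere("bladder", c(18.5, 14.0, 16), 2.0),
    solid_sphere("testis left", c(21.5, 17.0, 12), 1.8),
    solid_sphere("testis right", c(15.5, 17.0, 12), 1.8)
  )
  list(resolution = resolution,
       body = solid_ellipsoid("body", c0, c(10.6, 10.6, 43.5), class = "body"),
       organs = organs,
       target_mass_g = target_mass_g,
       shoulder_site = c(28.0, 15.5, 80))
}

#' Convert a plain list (e.g. parsed from YAML) to a solid
#'
#' Dispatches on the `shape` field to the solid constructors, so organ
#' geometry can be declared in configuration files.
#'
#' @param x list with a `shape` field plus the constructor's arguments
#'   (numeric vectors for centres/axes), or an existing solid (returned
#'   unchanged).
#' @return a `solid`.
#' @export
as_solid <- function(x) {
  if (inherits(x, "solid")) return(x)
  if (is.null(x$shape)) stop("solid spec needs a 'shape' field")
  fields <- x[setdiff(names(x), "shape")]
  fields <- lapply(fields, function(v) if (is.list(v)) unlist(v) else v)
  ctor <- switch(x$shape,
    sphere = solid_sphere, ellipsoid = solid_ellipsoid,
    capsule = solid_capsule, box = solid_box, shell = solid_shell,
    stop("unknown shape: ", x$shape))
  do.call(ctor, fields)
}

#' Read a run configuration from YAML
#'
#' Schema: `phantom` (resolution, target_mass_g, or `preset: mouse`),
#' `sources` (organ names), `tumour_masses_g`, `n_primaries`, `n_batches`,
#' `seed`, `out_dir`, `units`, `write_grids`.
#'
#' @param path YAML file path.
#' @return a run-config list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(n_primaries = 1e6, n_batches = 10, seed = 1,
                   units = "per-decay", write_grids = FALSE,
                   out_dir = "voxeldose-out")
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (cfg$n_batches < 2) stop("n_batches must be >= 2 when uncertainty is requested")
  if (!is.null(cfg$tumour_masses_g)) {
    if (any(cfg$tumour_masses_g <= 0)) stop("tumour masses must be positive")
    if (is.unsorted(cfg$tumour_masses_g)) stop("tumour masses must be sorted")
  }
  cfg
}
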