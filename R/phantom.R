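## Synthetic voxelized rodent-like phantoms.
##
## Anatomy is described as analytic solids (ellipsoids, spheres, capsules
## for long bones, shells for hollow organs) voxelized on an isotropic grid
## with a centre-inside rule: a voxel belongs to a solid iff its centre lies
## inside.  Overlaps resolve by class priority skeleton > marrow > organ >
## body; equal-priority overlaps without a declared priority are an error.
## Long bones carry an inner marrow core generated as the same solid shrunk
## by a uniform shell thickness, so marrow voxels lie strictly inside bone.

RESOLUTIONS <- list(
  lr = list(dim = c(74L, 74L, 184L), voxel_mm = 0.625,
            expanded_dim = c(80L, 80L, 175L), marrow_thickness_mm = 0.625),
  hr = list(dim = c(128L, 128L, 400L), voxel_mm = 0.29,
            expanded_dim = c(140L, 140L, 355L), marrow_thickness_mm = 0.58)
)

CLASS_PRIORITY <- c(body = 1, organ = 2, marrow = 3, skeleton = 4)

#' Analytic solids for phantom configuration
#'
#' Constructors for the solid primitives understood by [build_phantom()]:
#' spheres, ellipsoids, capsules (cylinders with hemispherical caps, used
#' for long bones), boxes and ellipsoidal shells (hollow organs; the cavity
#' is left unlabelled and reverts to body).
#'
#' @param name organ name (unique within a config).
#' @param center world coordinates of the centre, mm.
#' @param radius,semiaxes,halfwidths,thickness_mm dimensions in mm.
#' @param p1,p2 capsule axis endpoints, mm.
#' @param material bundled material name.
#' @param class one of "skeleton", "organ", "body" (drives overlap priority).
#' @param marrow_thickness_mm for skeleton solids: thickness of the bone
#'   shell left around the marrow core; NULL uses the resolution default.
#' @param priority optional explicit numeric priority overriding the class
#'   default, used to break declared overlaps.
#' @return a `solid` list understood by [build_phantom()].
#' @export
solid_sphere <- function(name, center, radius, material = "soft_tissue",
                         class = "organ", marrow_thickness_mm = NULL,
                         priority = NULL) {
  vd_solid(name, "sphere", class, material, priority,
           center = center, radius = radius,
           marrow_thickness_mm = marrow_thickness_mm)
}

#' @rdname solid_sphere
#' @export
solid_ellipsoid <- function(name, center, semiaxes, material = "soft_tissue",
                            class = "organ", marrow_thickness_mm = NULL,
                            priority = NULL) {
  vd_solid(name, "ellipsoid", class, material, priority,
           center = center, semiaxes = semiaxes,
           marrow_thickness_mm = marrow_thickness_mm)
}

#' @rdname solid_sphere
#' @export
solid_capsule <- function(name, p1, p2, radius, material = "bone",
                          class = "skeleton", marrow_thickness_mm = NULL,
                          priority = NULL) {
  vd_solid(name, "capsule", class, material, priority,
           p1 = p1, p2 = p2, radius = radius,
           marrow_thickness_mm = marrow_thickness_mm)
}

#' @rdname solid_sphere
#' @export
solid_box <- function(name, center, halfwidths, material = "soft_tissue",
                      class = "organ", priority = NULL) {
  vd_solid(name, "box", class, material, priority,
           center = center, halfwidths = halfwidths)
}

#' @rdname solid_sphere
#' @export
solid_shell <- function(name, center, semiaxes, thickness_mm,
                        material = "soft_tissue", class = "organ",
                        priority = NULL) {
  vd_solid(name, "shell", class, material, priority,
           center = center, semiaxes = semiaxes, thickness_mm = thickness_mm)
}

vd_solid <- function(name, shape, class, material, priority, ...) {
  stopifnot(class %in% names(CLASS_PRIORITY))
  structure(c(list(name = name, shape = shape, class = class,
                   material = material, priority = priority), list(...)),
            class = "solid")
}

## mm bounding box of a solid: list(lo, hi)
solid_bbox <- function(s) {
  switch(s$shape,
    sphere = list(lo = s$center - s$radius, hi = s$center + s$radius),
    ellipsoid = ,
    shell = list(lo = s$center - s$semiaxes, hi = s$center + s$semiaxes),
    box = list(lo = s$center - s$halfwidths, hi = s$center + s$halfwidths),
    capsule = list(lo = pmin(s$p1, s$p2) - s$radius,
                   hi = pmax(s$p1, s$p2) + s$radius),
    stop("unknown shape: ", s$shape))
}

## logical inside-test at points (3-column matrix, mm)
solid_inside <- function(s, pts) {
  switch(s$shape,
    sphere = colSums((t(pts) - s$center)^2) <= s$radius^2,
    ellipsoid = colSums(((t(pts) - s$center) / s$semiaxes)^2) <= 1,
    box = apply(abs(t(pts) - s$center) <= s$halfwidths, 2, all),
    shell = {
      u <- colSums(((t(pts) - s$center) / s$semiaxes)^2) <= 1
      inner <- pmax(s$semiaxes - s$thickness_mm, 0)
      v <- if (all(inner > 0))
        colSums(((t(pts) - s$center) / inner)^2) <= 1 else FALSE
      u & !v
    },
    capsule = {
      ax <- s$p2 - s$p1; L2 <- sum(ax^2)
      d <- t(pts) - s$p1
      t0 <- if (L2 > 0) pmin(pmax(colSums(d * ax) / L2, 0), 1) else 0
      proj <- s$p1 + outer(ax, t0)
      colSums((t(pts) - proj)^2) <= s$radius^2
    })
}

## shrink a solid by t mm (marrow core construction)
solid_shrink <- function(s, t) {
  s2 <- s
  if (s$shape == "sphere") s2$radius <- s$radius - t
  else if (s$shape == "ellipsoid") s2$semiaxes <- s$semiaxes - t
  else if (s$shape == "capsule") {
    ax <- s$p2 - s$p1; L <- sqrt(sum(ax^2))
    if (L > 2 * t) { u <- ax / L; s2$p1 <- s$p1 + t * u; s2$p2 <- s$p2 - t * u }
    s2$radius <- s$radius - t
  } else if (s$shape == "box") s2$halfwidths <- s$halfwidths - t
  else stop("cannot shrink shape ", s$shape)
  s2
}

solid_degenerate <- function(s) {
  switch(s$shape,
    sphere = s$radius <= 0,
    ellipsoid = any(s$semiaxes <= 0),
    capsule = s$radius <= 0,
    box = any(s$halfwidths <= 0),
    shell = s$thickness_mm <= 0)
}

## geometric scaling of a solid about a fixed point
solid_scale <- function(s, f, about) {
  sc <- function(p) about + f * (p - about)
  s2 <- s
  if (!is.null(s$center)) s2$center <- sc(s$center)
  if (!is.null(s$p1)) { s2$p1 <- sc(s$p1); s2$p2 <- sc(s$p2) }
  for (fld in c("radius", "semiaxes", "halfwidths", "thickness_mm"))
    if (!is.null(s[[fld]])) s2[[fld]] <- s[[fld]] * f
  s2
}

#' Build a voxelized phantom from an analytic configuration
#'
#' Voxelizes a body solid plus organ/bone solids on an isotropic grid.
#' Skeleton solids with a positive marrow thickness automatically gain an
#' inner marrow core.  If `target_mass_g` is set, all solids are scaled
#' isotropically (one common factor, no per-organ scaling) so the voxelized
#' whole-body mass matches the target.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{resolution}{"lr", "hr", or a list(dim, voxel_mm).}
#'     \item{body}{a solid of class "body" (NULL for an all-air grid).}
#'     \item{organs}{list of solids (may be empty for a body-only phantom).}
#'     \item{target_mass_g}{optional whole-body mass target, g.}
#'     \item{shoulder_site}{optional world mm of the subcutaneous left
#'       shoulder tumour site (stored for [insert_tumour()]).}
#'   }
#' @return object of class `voxel_phantom`: `label` (3D integer array, 0 =
#'   outside-body air), `voxel_mm`, `origin` (world mm of the centre of
#'   voxel (0,0,0)), `label_table` (label, organ, material, density, class).
#' @export
build_phantom <- function(config) {
  res <- config$resolution
  if (is.character(res)) {
    res_name <- match.arg(res, c("lr", "hr"))
    res <- RESOLUTIONS[[res_name]]
  } else {
    res_name <- "custom"
    if (is.null(res$marrow_thickness_mm)) res$marrow_thickness_mm <- 2 * res$voxel_mm
    if (is.null(res$expanded_dim)) res$expanded_dim <- res$dim
  }
  dims <- as.integer(res$dim); h <- res$voxel_mm

  solids <- config$organs
  body <- config$body
  if (!is.null(body)) solids <- c(list(body), solids)

  ## isotropic whole-body scaling toward the mass target
  if (!is.null(config$target_mass_g) && length(solids)) {
    m0 <- phantom_total_mass(solids, dims, h, res$marrow_thickness_mm)
    if (m0 > 0) {
      f <- (config$target_mass_g / m0)^(1 / 3)
      about <- dims * h / 2
      solids <- lapply(solids, solid_scale, f = f, about = about)
    }
  }

  ph <- voxelize_solids(solids, dims, h, res$marrow_thickness_mm)
  ph$resolution <- res_name
  ph$expanded_dim <- as.integer(res$expanded_dim)
  ph$shoulder_site <- config$shoulder_site
  ph
}

phantom_total_mass <- function(solids, dims, h, marrow_t) {
  ph <- voxelize_solids(solids, dims, h, marrow_t, quiet = TRUE)
  sum(vapply(ph$label_table$label, function(l) organ_mass(ph, l), 0.0))
}

voxelize_solids <- function(solids, dims, h, marrow_t, quiet = FALSE) {
  registry <- material_registry()
  ## expand skeleton solids with marrow cores
  expanded <- list()
  for (s in solids) {
    expanded[[length(expanded) + 1]] <- s
    if (identical(s$class, "skeleton")) {
      t <- if (is.null(s$marrow_thickness_mm)) marrow_t else s$marrow_thickness_mm
      if (t > 0 && !s$shape %in% c("shell")) {
        core <- solid_shrink(s, t)
        if (!solid_degenerate(core)) {
          core$name <- paste(s$name, "marrow")
          core$class <- "marrow"; core$material <- "marrow"; core$priority <- NULL
          core$parent_name <- s$name
          expanded[[length(expanded) + 1]] <- core
        }
      }
    }
  }

  label <- array(0L, dims)
  prio  <- array(0L, dims)
  tab <- data.frame(label = integer(), organ = character(),
                    material = character(), density = numeric(),
                    class = character(), stringsAsFactors = FALSE)
  centers <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * h)
  next_label <- 1L

  for (s in expanded) {
    bb <- solid_bbox(s)
    ir <- lapply(1:3, function(a) {
      lo <- max(1L, floor(bb$lo[a] / h - 0.5) + 1L)
      hi <- min(dims[a], ceiling(bb$hi[a] / h + 0.5))
      if (lo > hi) integer() else lo:hi
    })
    if (any(lengths(ir) == 0)) {
      if (!quiet) warning("organ '", s$name, "' lies outside the grid; dropped")
      next
    }
    pts <- as.matrix(expand.grid(x = centers[[1]][ir[[1]]],
                                 y = centers[[2]][ir[[2]]],
                                 z = centers[[3]][ir[[3]]]))
    inside <- solid_inside(s, pts)
    if (!any(inside)) {
      if (!quiet) warning("organ '", s$name,
                          "' is thinner than one voxel at this resolution; dropped")
      next
    }
    idx <- as.matrix(expand.grid(ir[[1]], ir[[2]], ir[[3]]))[inside, , drop = FALSE]
    lin <- idx[, 1] + dims[1] * (idx[, 2] - 1L) + dims[1] * dims[2] * (idx[, 3] - 1L)
    p <- if (!is.null(s$priority)) s$priority else CLASS_PRIORITY[[s$class]]
    if (!is.null(s$parent_name)) {
      ## marrow core: carve only into its own bone's voxels
      parent_lab <- tab$label[tab$organ == s$parent_name]
      win <- label[lin] %in% parent_lab
    } else {
      clash <- label[lin] != 0L & prio[lin] == p
      if (any(clash))
        stop("overlapping organ solids without a declared priority: '", s$name,
             "' vs label ", label[lin][which(clash)[1]])
      win <- prio[lin] < p | label[lin] == 0L
    }
    lab <- next_label; next_label <- next_label + 1L
    label[lin[win]] <- lab
    prio[lin[win]] <- p
    i <- material_row(registry, s$material)
    tab <- rbind(tab, data.frame(label = lab, organ = s$name,
                                 material = s$material,
                                 density = registry$density[i],
                                 class = s$class, stringsAsFactors = FALSE))
  }

  ## drop labels fully shadowed by higher-priority solids
  present <- sort(unique(as.vector(label)))
  gone <- setdiff(tab$label, present)
  if (length(gone)) {
    if (!quiet) warning("organ(s) fully overlapped and dropped: ",
                        paste(tab$organ[tab$label %in% gone], collapse = ", "))
    tab <- tab[!(tab$label %in% gone), , drop = FALSE]
  }

  structure(list(label = label, voxel_mm = h, origin = rep(h / 2, 3),
                 label_table = tab), class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$label)
  cat(sprintf("voxel_phantom: %d x %d x %d @ %.3g mm, %d labelled regions\n",
              d[1], d[2], d[3], x$voxel_mm, nrow(x$label_table)))
  invisible(x)
}

resolve_label <- function(phantom, label) {
  tab <- phantom$label_table
  if (is.character(label)) {
    i <- match(label, tab$organ)
    if (is.na(i)) stop("unknown organ label: ", label)
    tab$label[i]
  } else {
    if (!label %in% tab$label) stop("unknown organ label: ", label)
    label
  }
}

#' Mask (voxel index set) of one organ
#'
#' @param phantom a `voxel_phantom`.
#' @param label integer label or organ name.
#' @return integer vector of linear voxel indices (class `organ_mask`, with
#'   attribute `v` = voxel count).
#' @export
organ_mask <- function(phantom, label) {
  lab <- resolve_label(phantom, label)
  idx <- which(phantom$label == lab)
  if (!length(idx)) stop("organ has no voxels: ", label)
  structure(idx, v = length(idx), class = "organ_mask")
}

#' Voxelized organ mass
#'
#' Mass of a labelled region: voxel count x voxel volume x material density.
#'
#' @inheritParams organ_mask
#' @return mass in g.
#' @export
organ_mass <- function(phantom, label) {
  lab <- resolve_label(phantom, label)
  v <- sum(phantom$label == lab)
  if (v == 0) stop("organ has no voxels: ", label)
  rho <- phantom$label_table$density[phantom$label_table$label == lab]
  v * (phantom$voxel_mm / 10)^3 * rho
}

#' Uniform normalized source image for one organ
#'
#' Each voxel of the source organ holds 1/v (v = voxel count); all other
#' voxels are zero, so the grid sums to one: a single unit of activity
#' spread uniformly over the source tissue.
#'
#' @inheritParams organ_mask
#' @return object of class `activity_image`: `grid` (3D array summing to
#'   1), `source_label`.
#' @export
make_source_image <- function(phantom, label) {
  lab <- resolve_label(phantom, label)
  idx <- which(phantom$label == lab)
  if (!length(idx)) stop("organ has no voxels: ", label)
  g <- array(0, dim(phantom$label))
  g[idx] <- 1 / length(idx)
  structure(list(grid = g, source_label = lab), class = "activity_image")
}

#' Tumour specification
#'
#' A spherical unit-density (by default) subcutaneous tumour, characterized
#' by its mass; the diameter follows from d = (6 m / (pi rho))^(1/3).
#'
#' @param mass_g tumour mass in g (> 0).
#' @param density_g_cm3 tumour density, g/cm^3.
#' @param center world mm of the tumour centre; NULL uses the phantom's
#'   configured left-shoulder site.
#' @param label reserved integer label; NULL assigns the next free label.
#' @return object of class `tumour_spec` (with derived `diameter_mm`).
#' @export
tumour_spec <- function(mass_g, density_g_cm3 = 1.0, center = NULL, label = NULL) {
  if (!is.numeric(mass_g) || mass_g <= 0) stop("tumour mass must be > 0")
  d_cm <- (6 * mass_g / (pi * density_g_cm3))^(1 / 3)
  structure(list(mass_g = mass_g, density_g_cm3 = density_g_cm3,
                 center = center, label = label, diameter_mm = d_cm * 10),
            class = "tumour_spec")
}

#' Insert a spherical tumour into a phantom
#'
#' The matrix is expanded by zero-padding in x/y to the configured enlarged
#' shape (and cropped symmetrically in z when the configured shape is
#' shorter, mirroring the published matrix definitions).  Tumour voxels
#' override overlapped soft tissue but never skeleton or marrow: a tumour
#' overlapping bone is an error, since the xenografts are subcutaneous.
#'
#' @param phantom a `voxel_phantom`.
#' @param spec a [tumour_spec()].
#' @return a new `voxel_phantom` with the tumour labelled and the grid at
#'   the expanded shape.
#' @export
insert_tumour <- function(phantom, spec) {
  h <- phantom$voxel_mm
  if (spec$diameter_mm <= 2 * h)
    stop(sprintf("tumour diameter %.2f mm must exceed 2 voxel lengths (%.2f mm)",
                 spec$diameter_mm, 2 * h))
  dims <- dim(phantom$label)
  newd <- phantom$expanded_dim
  if (is.null(newd)) newd <- dims

  pad_lo <- pmax(0L, (newd - dims) %/% 2L)
  crop_lo <- pmax(0L, (dims - newd) %/% 2L)
  lab <- array(0L, newd)
  src <- lapply(1:3, function(a) seq.int(crop_lo[a] + 1L,
                                         crop_lo[a] + min(dims[a], newd[a])))
  dst <- lapply(1:3, function(a) seq.int(pad_lo[a] + 1L,
                                         pad_lo[a] + min(dims[a], newd[a])))
  cropped <- phantom$label[src[[1]], src[[2]], src[[3]]]
  n_lost <- sum(phantom$label != 0L) - sum(cropped != 0L)
  if (n_lost > 0)
    warning(n_lost, " labelled voxel(s) outside the expanded matrix were cropped")
  lab[dst[[1]], dst[[2]], dst[[3]]] <- cropped

  ## world frame shift: new origin moves by (crop - pad) voxels
  shift_vox <- crop_lo - pad_lo
  origin <- phantom$origin + shift_vox * h

  center <- spec$center
  if (is.null(center)) center <- phantom$shoulder_site
  if (is.null(center)) stop("no tumour centre given and no shoulder site configured")
  center_new <- center - shift_vox * h   # same world point in the new frame

  r <- spec$diameter_mm / 2
  ctr_idx <- lapply(1:3, function(a) {
    rng <- floor((center_new[a] - r) / h):ceiling((center_new[a] + r) / h + 1)
    rng[rng >= 1 & rng <= newd[a]]
  })
  pts <- as.matrix(expand.grid((ctr_idx[[1]] - 0.5) * h,
                               (ctr_idx[[2]] - 0.5) * h,
                               (ctr_idx[[3]] - 0.5) * h))
  inside <- colSums((t(pts) - center_new)^2) <= r^2
  idx <- as.matrix(expand.grid(ctr_idx[[1]], ctr_idx[[2]], ctr_idx[[3]]))[inside, , drop = FALSE]
  lin <- idx[, 1] + newd[1] * (idx[, 2] - 1L) + newd[1] * newd[2] * (idx[, 3] - 1L)
  if (!length(lin)) stop("tumour does not intersect the expanded matrix")

  tab <- phantom$label_table
  bone_labels <- tab$label[tab$class %in% c("skeleton", "marrow")]
  if (any(lab[lin] %in% bone_labels))
    stop("tumour overlaps skeleton voxels; xenografts are subcutaneous")

  new_lab <- if (!is.null(spec$label)) spec$label else max(tab$label, 0L) + 1L
  if (new_lab %in% tab$label) stop("tumour label already in use: ", new_lab)
  lab[lin] <- as.integer(new_lab)

  vox_mass <- length(lin) * (h / 10)^3 * spec$density_g_cm3
  if (abs(vox_mass / spec$mass_g - 1) > 0.05)
    warning(sprintf("voxelized tumour mass %.3g g deviates >5%% from %.3g g",
                    vox_mass, spec$mass_g))

  tab <- rbind(tab, data.frame(label = as.integer(new_lab), organ = "tumour",
                               material = "tumour", density = spec$density_g_cm3,
                               class = "organ", stringsAsFactors = FALSE))
  out <- phantom
  out$label <- lab; out$label_table <- tab; out$origin <- origin
  out$tumour_label <- as.integer(new_lab)
  out
}

#' Attenuation image of a phantom
#'
#' Per-pixel linear attenuation (in 1/pixel, i.e. mu * voxel length) at a
#' working energy, from the material registry.
#'
#' @param phantom a `voxel_phantom`.
#' @param energy_kev working photon energy, keV.
#' @return 3D array, units 1/pixel.
#' @export
attenuation_image <- function(phantom, energy_kev = 140) {
  registry <- material_registry()
  E <- attr(registry, "egrid_kev")
  mu <- attr(registry, "mu_pe") + attr(registry, "mu_compton")
  mu_e <- apply(mu, 1, function(row) exp(approx(log(E), log(pmax(row, 1e-12)),
                                                xout = log(energy_kev))$y))
  lut <- c(mu_e[material_row(registry, "air")],
           mu_e[match(phantom$label_table$material, registry$name)])
  key <- match(phantom$label, c(0L, phantom$label_table$label))
  array(lut[key] * (phantom$voxel_mm / 10), dim(phantom$label))
}

#' Convert a per-pixel attenuation map to Hounsfield units
#'
#' Divides per-pixel values by the voxel size (cm) to obtain 1/cm, then
#' inverse-interpolates the piecewise-linear HU-to-mu calibration curve.
#' Values outside the curve range are clamped to its endpoints with a
#' warning.
#'
#' @param mu_map array of per-pixel attenuation values (1/pixel).
#' @param voxel_size_mm voxel edge length, mm.
#' @param curve data.frame with columns `hu` and `mu_cm`, strictly monotone
#'   in mu; defaults to the bundled calibration nodes (140 keV).
#' @return array of HU values, same shape as `mu_map`.
#' @export
mu_to_hu <- function(mu_map, voxel_size_mm, curve = vd_read_table("hu_curve.csv")) {
  if (is.unsorted(curve$mu_cm, strictly = TRUE))
    stop("calibration curve must be strictly monotone in mu")
  mu_cm <- mu_map / (voxel_size_mm / 10)
  out_of_range <- mu_cm < min(curve$mu_cm) | mu_cm > max(curve$mu_cm)
  if (any(out_of_range))
    warning(sum(out_of_range), " value(s) outside the calibration curve; clamped")
  hu <- approx(curve$mu_cm, curve$hu, xout = as.vector(mu_cm), rule = 2)$y
  array(hu, dim(mu_map))
}
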