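test_that("LR preset yields the documented grid geometry", {
  ph <- build_phantom(list(resolution = "lr", body = NULL, organs = list()))
  expect_identical(dim(ph$label), c(74L, 74L, 184L))
  expect_equal(ph$voxel_mm, 0.625)
})

test_that("zero-organ config gives a body-only phantom with two labels", {
  ph <- build_phantom(list(
    resolution = list(dim = c(16L, 16L, 16L), voxel_mm = 1),
    body = solid_ellipsoid("body", rep(8, 3), rep(6, 3), class = "body"),
    organs = list()))
  expect_identical(sort(unique(as.vector(ph$label))), c(0L, 1L))
  expect_identical(ph$label_table$organ, "body")
})

test_that("voxelized sphere mass matches the analytic volume oracle", {
  for (r_vox in c(5, 8)) {
    ph <- fixture_sphere(radius_vox = r_vox, voxel_mm = 0.5)
    analytic <- 4 / 3 * pi * (r_vox * 0.05)^3 * 1.0   # cm^3 * g/cm^3
    expect_lt(abs(organ_mass(ph, "sphere") / analytic - 1), 0.05)
  }
})

test_that("labels partition the grid and masses are additive", {
  ph <- fixture_two_organs()
  tab <- ph$label_table
  counts <- vapply(tab$label, function(l) sum(ph$label == l), 0L)
  expect_identical(sum(counts) + sum(ph$label == 0L), length(ph$label))
  total <- sum(vapply(tab$label, function(l) organ_mass(ph, l), 0))
  by_hand <- sum(vapply(seq_len(nrow(tab)), function(i)
    sum(ph$label == tab$label[i]) * (ph$voxel_mm / 10)^3 * tab$density[i], 0))
  expect_equal(total, by_hand)
})

test_that("same analytic config voxelized at LR and HR agrees within 10%", {
  cfg <- function(res) list(
    resolution = res,
    body = solid_ellipsoid("body", c(18.5, 18.5, 55), c(10, 10, 40),
                           class = "body"),
    organs = list(solid_sphere("brain", c(18.5, 18.5, 85), 3.5),
                  solid_ellipsoid("liver", c(18.5, 15, 58), c(7, 5, 6)),
                  solid_capsule("spine", c(18.5, 23, 20), c(18.5, 23, 80), 2.5,
                                marrow_thickness_mm = 1.0)))
  lr <- build_phantom(cfg("lr")); hr <- build_phantom(cfg("hr"))
  for (organ in c("body", "brain", "liver", "spine", "spine marrow"))
    expect_lt(abs(organ_mass(lr, organ) / organ_mass(hr, organ) - 1), 0.10,
              label = paste("mass ratio deviation for", organ))
})

test_that("overlapping same-priority solids error; thin organs are dropped", {
  base <- list(resolution = list(dim = c(20L, 20L, 20L), voxel_mm = 1),
               body = solid_box("body", rep(10, 3), rep(10, 3), class = "body"))
  bad <- c(base, list(organs = list(solid_sphere("a", c(8, 10, 10), 3),
                                    solid_sphere("b", c(11, 10, 10), 3))))
  expect_error(build_phantom(bad), "declared priority")
  ok <- c(base, list(organs = list(
    solid_sphere("a", c(8, 10, 10), 3),
    solid_sphere("b", c(11, 10, 10), 3, priority = 2.5))))
  expect_silent(ph <- build_phantom(ok))
  expect_true(all(c("a", "b") %in% ph$label_table$organ))
  thin <- c(base, list(organs = list(solid_ellipsoid("film", c(10, 10, 10),
                                                     c(4, 4, 0.2)))))
  expect_warning(ph2 <- build_phantom(thin), "dropped")
  expect_false("film" %in% ph2$label_table$organ)
})

test_that("marrow cores lie strictly inside their bone", {
  ph <- build_phantom(list(
    resolution = list(dim = c(30L, 30L, 60L), voxel_mm = 0.5),
    body = solid_box("body", c(7.5, 7.5, 15), c(7.5, 7.5, 15), class = "body"),
    organs = list(solid_capsule("femur", c(7.5, 7.5, 5), c(7.5, 7.5, 25), 2.0,
                                marrow_thickness_mm = 0.8))))
  expect_true("femur marrow" %in% ph$label_table$organ)
  marrow_lab <- ph$label_table$label[ph$label_table$organ == "femur marrow"]
  bone_lab <- ph$label_table$label[ph$label_table$organ == "femur"]
  marrow <- which(ph$label == marrow_lab)
  ## every marrow voxel's 6-neighbourhood is bone or marrow (never body/air)
  d <- dim(ph$label)
  ijk <- arrayInd(marrow, d)
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
    nb <- sweep(ijk, 2, off, "+")
    keep <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    vals <- ph$label[nb[keep, , drop = FALSE]]
    expect_true(all(vals %in% c(bone_lab, marrow_lab)))
  }
})

test_that("hollow organs keep unlabelled cavities", {
  ph <- build_phantom(list(
    resolution = list(dim = c(24L, 24L, 24L), voxel_mm = 1),
    body = solid_box("body", rep(12, 3), rep(12, 3), class = "body"),
    organs = list(solid_shell("heart", rep(12, 3), c(6, 6, 6), 2))))
  body_lab <- ph$label_table$label[ph$label_table$organ == "body"]
  ## the cavity centre voxel reverts to body
  expect_identical(ph$label[12, 12, 12], body_lab)
})

test_that("tumour insertion expands the matrix and respects bone", {
  ph_hr <- build_phantom(mouse_config("hr"))
  pht <- insert_tumour(ph_hr, tumour_spec(0.54))
  expect_identical(dim(pht$label), c(140L, 140L, 355L))
  expect_lt(abs(organ_mass(pht, "tumour") / 0.54 - 1), 0.05)
  ## too-small tumour violates the two-voxel precondition
  tiny_mass <- 0.9 * 4 / 3 * pi * (0.29 / 10)^3  # below the 2-voxel diameter
  expect_error(insert_tumour(ph_hr, tumour_spec(tiny_mass)), "2 voxel")
  ## a tumour centred on the spine overlaps bone
  expect_error(insert_tumour(ph_hr, tumour_spec(0.5, center = c(18.5, 21.5, 60))),
               "subcutaneous")
})

test_that("tumour sweep voxelized masses are strictly increasing", {
  ph <- build_phantom(mouse_config("lr"))
  masses <- c(0.13, 0.26, 0.37, 0.48, 0.60, 0.71, 0.81, 0.93, 1.04, 1.15)
  vox <- vapply(masses, function(m)
    organ_mass(insert_tumour(ph, tumour_spec(m)), "tumour"), 0)
  expect_true(all(diff(vox) > 0))
})

test_that("organ_mass follows v * voxel volume * density", {
  ## one LR soft-tissue voxel
  ph <- build_phantom(list(
    resolution = list(dim = c(5L, 5L, 5L), voxel_mm = 0.625),
    body = NULL,
    organs = list(solid_box("dot", c(1.6, 1.6, 1.6), rep(0.3, 3)))))
  expect_identical(sum(ph$label != 0L), 1L)
  expect_equal(organ_mass(ph, "dot"), 2.4414e-4, tolerance = 1e-4)
  ## 1 cm^3 of marrow at 1.03 g/cm^3
  ph2 <- build_phantom(list(
    resolution = list(dim = c(20L, 20L, 20L), voxel_mm = 0.625),
    body = NULL,
    organs = list(solid_box("bm", rep(6.25, 3), rep(5, 3), material = "marrow"))))
  expect_equal(organ_mass(ph2, "bm"), 1.03, tolerance = 1e-6)
  expect_error(organ_mass(ph2, "unknown"), "unknown")
  expect_error(organ_mass(ph2, 99L), "unknown")
})

test_that("source images are uniform, normalized and supported on the organ", {
  ph <- build_phantom(list(
    resolution = list(dim = c(10L, 10L, 10L), voxel_mm = 1),
    body = NULL,
    organs = list(solid_box("cube", rep(5, 3), rep(1, 3)))))  # 2x2x2 voxels
  act <- make_source_image(ph, "cube")
  expect_identical(sum(act$grid > 0), 8L)
  expect_true(all(act$grid[act$grid > 0] == 0.125))
  expect_equal(sum(act$grid), 1, tolerance = 1e-12)
  expect_true(all(act$grid[ph$label == 0L] == 0))
  expect_error(make_source_image(ph, "nope"), "unknown")
})

test_that("mu_to_hu implements the HU definition with clamping", {
  curve <- voxeldose:::vd_read_table("hu_curve.csv")
  mu_water_pix <- 0.1537 * 0.0625          # 1/pixel at 0.625 mm
  expect_equal(mu_to_hu(array(mu_water_pix, c(1, 1, 1)), 0.625)[1], 0,
               tolerance = 1e-6)
  expect_warning(hu0 <- mu_to_hu(array(0, c(1, 1, 1)), 0.625), "clamped")
  expect_equal(hu0[1], -1000)
  ## per-pixel 0.01 at 0.625 mm voxel -> 0.16 1/cm before interpolation
  manual <- approx(curve$mu_cm, curve$hu, xout = 0.01 / 0.0625)$y
  expect_equal(mu_to_hu(array(0.01, c(1, 1, 1)), 0.625)[1], manual)
  bad <- curve[order(-curve$mu_cm), ]
  expect_error(mu_to_hu(array(0.01, c(1, 1, 1)), 0.625, bad), "monotone")
})

test_that("attenuation image round-trips through the HU conversion", {
  ph <- fixture_block(n = 8L)
  att <- attenuation_image(ph, 140)
  hu <- suppressWarnings(mu_to_hu(att, ph$voxel_mm))
  expect_identical(dim(hu), dim(att))
  inside <- ph$label == 1L
  expect_true(all(abs(hu[inside]) < 80))    # soft tissue near water
  expect_true(all(hu[!inside] <= -990))     # air
})
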