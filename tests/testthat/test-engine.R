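test_that("electron energy is conserved deep inside a homogeneous grid", {
  ph <- fixture_block(n = 24L, voxel_mm = 1)   # 24 mm cube, range(300) ~ 0.8 mm
  ctr <- rep(12, 3)
  out <- transport_electron(ph, 300, ctr, c(1, 0, 0))
  expect_equal(out$deposited_kev, 300, tolerance = 1e-9)
  expect_equal(sum(out$grid_kev), 300, tolerance = 1e-9)
  ## outward-pointing electron one voxel from the edge escapes with energy
  out2 <- transport_electron(ph, 300, c(23.5, 12, 12), c(1, 0, 0))
  expect_lt(out2$deposited_kev, 300)
})

test_that("electron stepping converges: half-voxel vs 10x finer step", {
  ph <- fixture_sphere(radius_vox = 9, voxel_mm = 0.56)  # ~0.54 cm^3 sphere
  act <- make_source_image(ph, "sphere")
  mask <- organ_mask(ph, "sphere")
  m <- lu177_model()
  coarse <- run_batch(ph, act, 3e4, seed = 5, model = m, electrons_only = TRUE)
  fine <- run_batch(ph, act, 3e4, seed = 5, model = m, electrons_only = TRUE,
                    step_mm = 0.028)
  ## identical RNG stream (no photons): only the discretization differs
  af_c <- sum(coarse$dose[mask]) ; af_f <- sum(fine$dose[mask])
  expect_lt(abs(af_c / af_f - 1), 0.02)
})

test_that("photons do not interact in an all-air grid", {
  ph <- build_phantom(list(
    resolution = list(dim = c(30L, 30L, 30L), voxel_mm = 1),
    body = NULL, organs = list(solid_box("dot", rep(15, 3), rep(0.6, 3)))))
  out <- transport_photon(ph, 208, rep(15, 3), c(0, 0, 1), seed = 2)
  expect_equal(out$deposited_kev, 0, tolerance = 0.5)
})

test_that("photon attenuation follows exp(-mu d) within 3 sigma", {
  ## water slab 20 mm thick along z, vacuum elsewhere handled by grid exit
  ph <- fixture_block(n = 20L, voxel_mm = 1)
  n <- 3000
  uninteracted <- 0
  for (i in seq_len(n)) {
    out <- transport_photon(ph, 208, c(10, 10, 0.001), c(0, 0, 1), seed = i)
    if (out$deposited_kev == 0) uninteracted <- uninteracted + 1
  }
  reg <- material_registry()
  mu <- attr(reg, "mu_pe") + attr(reg, "mu_compton")
  Eg <- attr(reg, "egrid_kev")
  mu208 <- exp(approx(log(Eg), log(mu["soft_tissue", ]), xout = log(208))$y)
  p_expected <- exp(-mu208 * 2.0)   # 2 cm
  se <- sqrt(p_expected * (1 - p_expected) / n)
  expect_lt(abs(uninteracted / n - p_expected), 3 * se + 1e-9)
})

test_that("a single local-deposit decay produces dose E/m in one voxel", {
  ph <- fixture_block(n = 10L, voxel_mm = 1)
  act0 <- make_source_image(ph, "body")
  ## single-voxel source
  g <- array(0, dim(ph$label)); g[5, 5, 5] <- 1
  act <- structure(list(grid = g, source_label = 1L), class = "activity_image")
  model <- fixture_local_model(energy_kev = 5)   # below the transport cut
  b <- run_batch(ph, act, 1, seed = 9, model = model)
  m_kg <- (0.1)^3 * 1.0 * 1e-3                   # 1 mm voxel of unit density
  expect_equal(b$dose[5, 5, 5], 5 * 1.602176634e-16 / m_kg, tolerance = 1e-12)
  expect_identical(sum(b$dose > 0), 1L)
  expect_equal(b$n_primaries, 1)
  ## unnormalized activity is rejected
  gg <- g * 2
  act_bad <- structure(list(grid = gg, source_label = 1L),
                       class = "activity_image")
  expect_error(run_batch(ph, act_bad, 10, 1, model = model), "not normalized")
})

test_that("merging is weight-correct, order-independent and shape-checked", {
  d <- c(4L, 4L, 4L)
  mk <- function(val, n) structure(list(dose = array(val, d), dose_sq = array(0, d),
                                        n_primaries = n, seed = 0),
                                   class = "dose_batch")
  one <- merge_batches(list(mk(2, 100)))
  expect_equal(one$dose, array(2, d))
  two <- merge_batches(list(mk(2, 100), mk(2, 100)))
  expect_equal(two$dose, array(2, d))          # identical batches: unchanged
  expect_equal(two$n_primaries, 200)
  forty <- merge_batches(lapply(1:40, function(i) mk(1, 1.25e8)))
  expect_equal(forty$n_primaries, 5e9)
  ## weighted average with unequal primaries, any order
  a <- mk(1, 100); b <- mk(4, 300)
  m1 <- merge_batches(list(a, b)); m2 <- merge_batches(list(b, a))
  expect_equal(m1$dose[1], (100 * 1 + 300 * 4) / 400)
  expect_identical(m1$dose, m2$dose)
  bad <- structure(list(dose = array(0, c(2L, 2L, 2L)), n_primaries = 1),
                   class = "dose_batch")
  expect_error(merge_batches(list(a, bad)), "mismatch")
})

test_that("batch uncertainty reproduces the printed estimator exactly", {
  d <- c(3L, 3L, 3L)
  mk <- function(arr) structure(list(dose = arr, n_primaries = 10),
                                class = "dose_batch")
  same <- lapply(1:4, function(i) mk(array(2, d)))
  u0 <- batch_uncertainty(same)
  expect_true(all(u0$delta == 0))
  ## voxel values {1, 3} across N = 2 batches -> delta = 1
  u1 <- batch_uncertainty(list(mk(array(1, d)), mk(array(3, d))))
  expect_equal(u1$delta[1], 1)
  expect_equal(u1$rel[1], 0.5)                 # delta / mean = 1 / 2
  expect_error(batch_uncertainty(list(mk(array(1, d)))), "at least 2")
  ## random grids vs a brute-force oracle
  set.seed(31)
  grids <- lapply(1:6, function(i) array(runif(27), d))
  u <- batch_uncertainty(lapply(grids, mk))
  N <- 6
  x <- simplify2array(grids)                   # 3 x 3 x 3 x 6
  oracle <- apply(x, 1:3, function(v)
    sqrt(max(0, (sum(v^2) / N - (sum(v) / N)^2) / (N - 1))))
  expect_equal(u$delta, oracle, tolerance = 1e-12)
})

test_that("energy is conserved within 0.1% for contained electron sources", {
  ph <- fixture_sphere(radius_vox = 3, voxel_mm = 0.5, n = 26L)
  ## margin (26 - 6)/2 * 0.5 = 5 mm on each side > 1.8 mm max range
  act <- make_source_image(ph, "sphere")
  b <- run_batch(ph, act, 2e4, seed = 3, model = lu177_model(),
                 electrons_only = TRUE)
  expect_lte(b$deposited_kev, b$emitted_kev)
  expect_lt(abs(b$deposited_kev / b$emitted_kev - 1), 0.001)
  ## dose-to-energy bookkeeping closes: sum(dose * voxel mass) = deposited
  vox_kg <- (ph$voxel_mm / 10)^3 * 1e-3
  rho <- c(voxeldose:::material_registry()$density)
  names(rho) <- voxeldose:::material_registry()$name
  key <- match(ph$label, c(0L, ph$label_table$label))
  dens <- array(c(rho["air"], ph$label_table$density)[key], dim(ph$label))
  joules <- sum(b$dose * b$n_primaries * dens * vox_kg)
  expect_equal(joules / 1.602176634e-16, b$deposited_kev, tolerance = 1e-9)
})

test_that("median relative uncertainty halves when primaries quadruple", {
  ph <- fixture_sphere(radius_vox = 4, voxel_mm = 0.5)
  act <- make_source_image(ph, "sphere")
  mask <- organ_mask(ph, "sphere")
  m <- lu177_model()
  eps_for <- function(n_per_batch, seed0) {
    batches <- lapply(1:8, function(i)
      run_batch(ph, act, n_per_batch, seed = seed0 + i, model = m))
    u <- batch_uncertainty(batches)
    merged <- merge_batches(batches)
    median(u$delta[mask] / merged$dose[mask])
  }
  r <- eps_for(500, 100) / eps_for(2000, 900)
  expect_gt(r, 1.8); expect_lt(r, 2.2)
})

test_that("runs are bit-identical under a fixed seed", {
  ph <- fixture_sphere(radius_vox = 3, voxel_mm = 0.5)
  act <- make_source_image(ph, "sphere")
  m <- lu177_model()
  b1 <- run_batch(ph, act, 5000, seed = 77, model = m)
  b2 <- run_batch(ph, act, 5000, seed = 77, model = m)
  expect_identical(b1$dose, b2$dose)
  expect_identical(b1$dose_sq, b2$dose_sq)
  b3 <- run_batch(ph, act, 5000, seed = 78, model = m)
  expect_false(identical(b1$dose, b3$dose))
})
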