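test_that("rasterized sphere activity matches the closed-form volume", {
  # single 34 mm sphere at 0.52 MBq/ml: analytic activity 0.52*(pi/6)*3.4^3
  spec <- jaszczak_phantom_spec(dim = c(32, 32, 24), cylinder_radius = 50,
                                cylinder_height = 90,
                                sphere_diameters = 34, ring_radius = 0,
                                background_concentration = 0)
  ras <- rasterize_phantom(spec)
  analytic <- 0.52 * pi / 6 * 3.4^3
  expect_equal(ras$sphere_activity_MBq[["d34"]], analytic,
               tolerance = 0.01)
  expect_equal(sum(ras$activity$data), analytic, tolerance = 0.01)
})

test_that("default phantom concentrations give a 13:1 hot ratio", {
  spec <- jaszczak_phantom_spec()
  expect_equal(spec$spheres[[1]]$concentration /
                 spec$background_concentration, 13)
})

test_that("zero concentrations give an all-zero activity grid", {
  spec <- tiny_phantom()
  spec$background_concentration <- 0
  for (i in seq_along(spec$spheres)) spec$spheres[[i]]$concentration <- 0
  ras <- rasterize_phantom(spec)
  expect_true(all(ras$activity$data == 0))
})

test_that("total phantom activity matches concentration x region volume", {
  ras <- rasterize_phantom(tiny_phantom(supersampling = 4))
  cyl_ml <- pi * 60^2 * 100 / 1000
  sph_ml <- sum(pi / 6 * c(3.4, 1.6, 0.8)^3)
  expected <- 0.04 * (cyl_ml - sph_ml) + 0.52 * sph_ml
  expect_equal(ras$total_activity_MBq, expected, tolerance = 0.01)
})

test_that("a sphere outside the cylinder is rejected", {
  expect_error(rasterize_phantom(
    jaszczak_phantom_spec(cylinder_radius = 40, ring_radius = 38,
                          sphere_diameters = 34)),
    "outside")
})

test_that("degenerate acquisition model reproduces activity times CF", {
  ras <- rasterize_phantom(tiny_phantom())
  m <- acquisition_model(cf = 9049, psf_fwhm = 0, noise = "none")
  obs <- simulate_acquisition(ras$activity, m)
  expect_equal(obs$data, ras$activity$data * 9049, tolerance = 1e-12)
  expect_identical(obs$units, "cps")
})

test_that("the PSF blur conserves total counts", {
  ras <- rasterize_phantom(tiny_phantom())
  m <- acquisition_model(cf = 9049, psf_fwhm = 12, noise = "none")
  obs <- simulate_acquisition(ras$activity, m)
  expect_equal(sum(obs$data), sum(ras$activity$data) * 9049,
               tolerance = 5e-3)
})

test_that("Poisson simulation is reproducible under a fixed seed", {
  ras <- rasterize_phantom(tiny_phantom())
  m <- acquisition_model(seed = 99)
  o1 <- simulate_acquisition(ras$activity, m)
  o2 <- simulate_acquisition(ras$activity, m)
  expect_identical(o1$data, o2$data)
  m2 <- acquisition_model(seed = 100)
  expect_false(identical(o1$data,
                         simulate_acquisition(ras$activity, m2)$data))
})

test_that("seeded Poisson counts are unbiased for a hot region", {
  # 20-voxel hot region, 200 seeded repetitions: empirical mean within 3 SE
  act <- array(0, c(8, 8, 4)); act[3:7, 4, 2] <- 0.002; act[3:7, 5, 2:4] <- 0.002
  g <- voxel_grid(act, units = "MBq")
  t_s <- 35
  lam <- act[act > 0][1] * 9049 * t_s
  nhot <- sum(act > 0)
  means <- vapply(1:200, function(s) {
    m <- acquisition_model(cf = 9049, psf_fwhm = 0, noise = "poisson",
                           acquisition_seconds = t_s, seed = s)
    mean(simulate_acquisition(g, m)$data[act > 0]) * t_s
  }, numeric(1))
  se <- sqrt(lam / (nhot * 200))
  expect_lt(abs(mean(means) - lam), 3 * se)
})

test_that("paired studies share anatomy and record exact truth", {
  spec <- tiny_liver_spec()
  ma <- acquisition_model(noise = "none")
  pair <- make_paired_study(spec, ma, ma)
  expect_equal(pair$study_a$spect$data, pair$study_b$spect$data)
  expect_identical(pair$study_a$agent, "MAA")
  expect_identical(pair$study_b$agent, "Y90")
  expect_equal(pair$truth$true_tlr, 5, tolerance = 1e-6)
  expect_equal(pair$truth$inverse_transform_mm, c(0, 0, 0))
})

test_that("misaligned pair records the inverse transform", {
  spec <- tiny_liver_spec(misalignment = c(9.328, 0, -4.664))
  pair <- make_paired_study(spec, acquisition_model(noise = "none"),
                            acquisition_model(noise = "none"))
  expect_equal(pair$truth$inverse_transform_mm, c(-9.328, 0, 4.664))
  expect_false(isTRUE(all.equal(pair$study_a$spect$data,
                                pair$study_b$spect$data)))
})

test_that("necrotic cores carry zero activity", {
  spec <- tiny_liver_spec(necrotic_core_fraction = 0.5)
  ras <- rasterize_liver(spec)
  tm <- spec$tumors[[1]]
  core_semi <- tm$semi * 0.5^(1 / 3) * 0.8   # safely interior points
  dimv <- spec$dim; sp <- rep(spec$voxel_size, 3)
  idx <- which(array(TRUE, dimv), arr.ind = TRUE)
  w <- sweep(sweep(idx - 1, 2, sp, `*`), 2, spec$origin, `+`)
  inside_core <- rowSums(sweep(w, 2, tm$center, `-`)^2 /
                           matrix(core_semi^2, nrow(w), 3, byrow = TRUE)) <= 1
  expect_true(all(ras$activity$data[inside_core] == 0))
})

test_that("tumors outside the liver are rejected", {
  expect_error(liver_study_spec(
    tumors = list(list(center = c(75, 0, 0), semi = c(30, 25, 20),
                       uptake = 5))),
    "outside")
})
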