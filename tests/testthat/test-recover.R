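test_that("PSF kernel is normalized, centred, and has the right sigma", {
  expect_equal(psf_model(11)$sigma, 11 / sqrt(8 * log(2)), tolerance = 1e-12)
  expect_equal(psf_model(11)$sigma, 4.672, tolerance = 1e-3)
  sp <- c(4.664, 4.664, 4.664)
  for (fwhm in c(5, 10, 20)) {
    k <- gaussian_psf_kernel(psf_model(fwhm), sp)
    expect_equal(sum(k), 1, tolerance = 1e-12)
    expect_true(all(dim(k) %% 2 == 1))
    ctr <- (dim(k) + 1) / 2
    expect_equal(which.max(k), ((ctr[3] - 1) * dim(k)[2] + ctr[2] - 1) *
                   dim(k)[1] + ctr[1])
  }
  expect_identical(gaussian_psf_kernel(psf_model(0), sp),
                   array(1, c(1, 1, 1)))
  expect_error(psf_model(-1), ">= 0")
})

test_that("a delta PSF is a fixpoint of the Richardson-Lucy update", {
  g <- grid_of(runif(4^3), c(4, 4, 4))
  r <- rl_deconvolve(g, psf_model(0), 5)
  for (e in r$estimates) expect_equal(e$data, g$data, tolerance = 1e-12)
})

test_that("Richardson-Lucy conserves counts for interior sources", {
  a <- array(0, c(24, 24, 24)); a[10:14, 10:14, 10:14] <- 5
  obs <- simulate_acquisition(voxel_grid(a, units = "MBq"),
                              acquisition_model(cf = 1, psf_fwhm = 10,
                                                noise = "none"))
  r <- rl_deconvolve(obs, psf_model(10), 6, keep = "last")
  expect_equal(sum(r$estimates[[1]]$data), sum(obs$data), tolerance = 0.01)
})

test_that("every iterate is non-negative on random non-negative input", {
  set.seed(42)
  for (rep in 1:3) {
    g <- grid_of(rpois(16^3, 4), c(16, 16, 16))
    r <- rl_deconvolve(g, psf_model(10), 8)
    for (e in r$estimates) expect_true(all(e$data >= 0))
  }
})

test_that("deconvolving a blurred point sharpens monotonically in place", {
  a <- array(0, c(21, 21, 21)); a[11, 11, 11] <- 100
  obs <- simulate_acquisition(voxel_grid(a, units = "MBq"),
                              acquisition_model(cf = 1, psf_fwhm = 10,
                                                noise = "none"))
  r <- rl_deconvolve(obs, psf_model(10), 20)
  peaks <- vapply(r$estimates, function(e) max(e$data), numeric(1))
  locs <- vapply(r$estimates, function(e) which.max(e$data), numeric(1))
  expect_true(all(diff(c(max(obs$data), peaks)) > 0))
  expect_true(all(locs == which.max(obs$data)))
})

test_that("the 3-D solver agrees with an independent 1-D update loop", {
  n <- 40
  true1 <- rep(0, n); true1[15:20] <- 10; true1[30] <- 25
  psf <- psf_model(10); sp <- c(4.664, 4.664, 4.664)
  k1 <- apply(gaussian_psf_kernel(psf, sp), 1, sum)
  obs1 <- conv1_reflect(true1, k1)
  r <- rl_deconvolve(voxel_grid(array(obs1, c(n, 1, 1)), spacing = sp,
                                units = "cps"), psf, 5)
  est <- obs1
  for (i in 1:5) {
    den <- conv1_reflect(est, k1)
    est <- est * conv1_reflect(obs1 / pmax(den, 1e-12), k1)
  }
  expect_lt(max(abs(r$estimates[[5]]$data[, 1, 1] - est)), 1e-10)
})

test_that("all-zero input is returned unchanged with a warning", {
  g <- grid_of(0, c(4, 4, 4))
  expect_warning(r <- rl_deconvolve(g, psf_model(10), 3), "all-zero")
  expect_equal(r$estimates[[3]]$data, g$data)
  expect_error(rl_deconvolve(grid_of(-1, c(3, 3, 3)), psf_model(5), 1),
               "non-negative")
})

test_that("consecutive RMSE follows its definition", {
  expect_equal(rmse_consecutive(grid_of(3, c(2, 2, 2)),
                                grid_of(3, c(2, 2, 2))), 0)
  expect_equal(rmse_consecutive(grid_of(5, c(2, 2, 2)),
                                grid_of(3, c(2, 2, 2))), 2)
  a <- grid_of(c(0, 0), c(2, 1, 1)); b <- grid_of(c(3, 4), c(2, 1, 1))
  expect_equal(rmse_consecutive(a, b), sqrt(25 / 2), tolerance = 1e-10)
  expect_error(rmse_consecutive(grid_of(1, c(2, 2, 2)),
                                grid_of(1, c(3, 3, 3))), "shape")
})

test_that("CNR follows its definition including cold regions", {
  img <- grid_of(1, c(4, 4, 4))
  img$data[1:2, , ] <- 2
  tm <- mask_of(array(slice.index(img$data, 1) <= 2, c(4, 4, 4)), "tumor")
  bg <- mask_of(array(slice.index(img$data, 1) > 2, c(4, 4, 4)),
                "healthy_liver")
  expect_equal(cnr(img, tm, bg), 1)
  img$data[1:2, , ] <- 1
  expect_equal(cnr(img, tm, bg), 0)
  img$data[1:2, , ] <- 0.5
  expect_equal(cnr(img, tm, bg), -0.5)
})

test_that("Q_H measures fractional contrast recovery", {
  img <- grid_of(1, c(6, 6, 6))
  sph <- array(FALSE, c(6, 6, 6)); sph[3:4, 3:4, 3:4] <- TRUE
  bg <- !sph
  sphere <- mask_of(sph, "sphere"); background <- mask_of(bg, "background")
  img$data[sph] <- 13
  expect_equal(q_h(img, sphere, background, 13), 100)
  img$data[sph] <- 1
  expect_equal(q_h(img, sphere, background, 13), 0)
  img$data[sph] <- 2
  expect_equal(q_h(img, sphere, background, 13), 100 / 12, tolerance = 1e-10)
  expect_error(q_h(img, sphere, background, 1), "> 1")
})

test_that("central-slice Q_H samples only the centroid slice", {
  img <- grid_of(1, c(6, 6, 6))
  sph <- array(FALSE, c(6, 6, 6)); sph[3:4, 3:4, 2:4] <- TRUE
  sphere <- mask_of(sph, "sphere"); background <- mask_of(!sph, "background")
  img$data[, , 3] <- ifelse(sph[, , 3], 25, 1)   # hot only on the mid slice
  full <- q_h(img, sphere, background, 13, mode = "matched_voi")
  slice <- q_h(img, sphere, background, 13, mode = "central_slice")
  expect_gt(slice, full)
  expect_equal(slice, 100 * (25 / mean(img$data[!sph]) - 1) / 12,
               tolerance = 1e-6)
})

test_that("iteration selection follows the Q_H max / RMSE decline rule", {
  # global max among RMSE-declining iterations
  expect_identical(select_iteration(c(10, 20, 25, 24), c(4, 3, 2, 1)), 3L)
  # constant Q_H with flat RMSE: no decline anywhere -> plain argmax, first
  expect_identical(select_iteration(rep(5, 4), rep(2, 4)), 1L)
  # RMSE rises at 2, declines only at 3 -> forced to 3 despite max at 2
  expect_identical(select_iteration(c(5, 30, 10), c(9, 10, 8)), 3L)
  expect_error(select_iteration(numeric(0), numeric(0)), "length")
})
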