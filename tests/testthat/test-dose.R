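make_test_kernel <- function(voxel = 3, extent = 1, scale = 1) {
  off <- as.matrix(expand.grid(i = -extent:extent, j = -extent:extent,
                               k = -extent:extent))
  vals <- scale * exp(-sqrt(rowSums(off^2)))
  list(kernel = svalue_kernel(off, vals, voxel_size = voxel),
       offsets = off, values = vals)
}

test_that("kernel construction enforces the self-dose maximum", {
  expect_error(svalue_kernel(matrix(c(0, 0, 0, 1, 0, 0), 2, byrow = TRUE),
                             c(1, 2), 3), "maximum")
  expect_error(svalue_kernel(matrix(c(0, 0, 0), 1), -1, 3), ">= 0")
  k <- make_test_kernel()$kernel
  expect_equal(y90quant:::kernel_value(k, 0, 0, 0), 1)
  expect_equal(y90quant:::kernel_value(k, 5, 5, 5), 0)  # outside support
})

test_that("kernel CSV round-trip preserves every entry and the metadata", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  k <- synthetic_y90_kernel(voxel_size = 4.664, extent = 2)
  write_kernel_csv(k, tmp)
  back <- read_kernel_csv(tmp)
  expect_equal(back$S, k$S, tolerance = 1e-12)
  expect_equal(back$voxel_size, 4.664)
  expect_identical(back$units, k$units)
})

test_that("size interpolation is exact at endpoints and for worked values", {
  k3 <- svalue_kernel(matrix(c(0, 0, 0), 1), 1.0, 3)
  k6 <- svalue_kernel(matrix(c(0, 0, 0), 1), 4.0, 6)
  expect_equal(interpolate_kernel(k3, k6, 4.664)$S[1, 1, 1], 2.664,
               tolerance = 1e-12)
  expect_equal(interpolate_kernel(k3, k6, 3)$S, k3$S)
  expect_equal(interpolate_kernel(k3, k6, 6)$S, k6$S)
  # degenerate: identical parents -> identical child
  expect_equal(interpolate_kernel(k3, svalue_kernel(matrix(c(0, 0, 0), 1),
                                                    1.0, 6), 4.5)$S[1, 1, 1],
               1.0)
  expect_error(interpolate_kernel(k3, k6, 7), "extrapolate")
  expect_equal(interpolate_kernel(k3, k6, 7, extrapolate = TRUE)$S[1, 1, 1],
               5.0)
})

test_that("an interpolated kernel lies entry-wise between its parents", {
  t3 <- make_test_kernel(3, 2, scale = 1)
  t6 <- make_test_kernel(6, 2, scale = 3)
  ki <- interpolate_kernel(t3$kernel, t6$kernel, 4.664)
  lo <- pmin(t3$kernel$S, t6$kernel$S)
  hi <- pmax(t3$kernel$S, t6$kernel$S)
  expect_true(all(ki$S >= lo - 1e-12 & ki$S <= hi + 1e-12))
})

test_that("bundled synthetic kernel files load and bracket 4.664 mm", {
  k3 <- read_kernel_csv(extdata("svalue_y90_3mm_synthetic.csv"))
  k6 <- read_kernel_csv(extdata("svalue_y90_6mm_synthetic.csv"))
  ki <- interpolate_kernel(k3, k6, 4.664)
  expect_equal(ki$voxel_size, 4.664)
  expect_true(ki$S[4, 4, 4] >= min(k3$S[4, 4, 4], k6$S[4, 4, 4]))
})

test_that("cumulated activity follows physical decay only", {
  z <- voxel_grid(array(0, c(2, 2, 2)), units = "MBq")
  expect_true(all(cumulated_activity(z)$data == 0))
  one <- voxel_grid(array(1, c(2, 2, 2)), units = "MBq")
  expect_equal(cumulated_activity(one, 64.05)$data[1],
               64.05 * 3600 / log(2), tolerance = 1e-9)
  expect_equal(cumulated_activity(one, 128.1)$data[1],
               2 * cumulated_activity(one, 64.05)$data[1])
  expect_identical(cumulated_activity(one)$units, "MBq.s")
})

test_that("a delta kernel returns the scaled source distribution", {
  a <- voxel_grid(array(0, c(4, 4, 4)), spacing = c(3, 3, 3),
                  units = "MBq.s")
  a$data[2, 3, 1] <- 1
  k <- svalue_kernel(matrix(c(0, 0, 0), 1), 2.0, 3)
  for (engine in c("direct", "transform")) {
    d <- dose_convolve(a, k, engine)
    expect_equal(d$grid$data[2, 3, 1], 2, tolerance = 1e-9)
    expect_equal(sum(d$grid$data), 2, tolerance = 1e-9)
    expect_identical(d$grid$units, "mGy")
  }
})

test_that("both engines match an independent triple-loop oracle", {
  set.seed(30)
  tk <- make_test_kernel(3, 1)
  a <- voxel_grid(array(runif(125), c(5, 5, 5)), spacing = c(3, 3, 3),
                  units = "MBq.s")
  oracle <- brute_force_dose(a$data, tk$offsets, tk$values)
  d1 <- dose_convolve(a, tk$kernel, "direct")
  d2 <- dose_convolve(a, tk$kernel, "transform")
  expect_lt(max(abs(d1$grid$data - oracle)), 1e-10)
  expect_lt(max(abs(d2$grid$data - d1$grid$data)) / max(d1$grid$data), 1e-6)
})

test_that("dose is linear and superposes over sources", {
  tk <- make_test_kernel(3, 1)
  base <- array(0, c(6, 6, 6))
  a1 <- base; a1[2, 2, 2] <- 1
  a2 <- base; a2[5, 4, 3] <- 1
  g <- function(arr) voxel_grid(arr, spacing = c(3, 3, 3), units = "MBq.s")
  d1 <- dose_convolve(g(a1), tk$kernel)$grid$data
  d2 <- dose_convolve(g(a2), tk$kernel)$grid$data
  d12 <- dose_convolve(g(a1 + a2), tk$kernel)$grid$data
  expect_equal(d12, d1 + d2, tolerance = 1e-9)
  expect_equal(dose_convolve(g(2 * a1), tk$kernel)$grid$data, 2 * d1,
               tolerance = 1e-9)
})

test_that("kernel-weighted totals are conserved for interior sources", {
  set.seed(31)
  tk <- make_test_kernel(3, 1)
  a <- array(0, c(9, 9, 9))
  a[3:7, 3:7, 3:7] <- runif(125)
  g <- voxel_grid(a, spacing = c(3, 3, 3), units = "MBq.s")
  d <- dose_convolve(g, tk$kernel, "direct")
  expect_equal(sum(d$grid$data), sum(a) * sum(tk$values),
               tolerance = 1e-9)
})

test_that("spacing/kernel mismatch and unit errors are caught", {
  a <- voxel_grid(array(1, c(3, 3, 3)), spacing = c(4.664, 4.664, 4.664),
                  units = "MBq.s")
  k <- svalue_kernel(matrix(c(0, 0, 0), 1), 1, 3)
  expect_error(dose_convolve(a, k), "match")
  b <- voxel_grid(array(1, c(3, 3, 3)), spacing = c(3, 3, 3), units = "MBq")
  expect_error(dose_convolve(b, k), "MBq.s")
})

test_that("cDVH is a step for uniform dose and enumerates small cases", {
  dm <- structure(list(grid = grid_of(2000, c(4, 4, 4), units = "mGy")),
                  class = "dose_map")
  voi <- mask_of(array(TRUE, c(4, 4, 4)))
  dv <- cdvh(dm, voi, n_bins = 10)
  expect_equal(dv$fraction[dv$dose_Gy <= 2], rep(1, sum(dv$dose_Gy <= 2)))
  # two voxels {1, 3} Gy: fraction at 2 Gy is 0.5
  dm2 <- structure(list(grid = grid_of(c(1000, 3000, 0, 0), c(2, 2, 1),
                                       units = "mGy")),
                   class = "dose_map")
  voi2 <- mask_of(array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1)))
  dv2 <- cdvh(dm2, voi2, n_bins = 6)
  expect_equal(dv2$fraction[which.min(abs(dv2$dose_Gy - 2))], 0.5)
  expect_true(all(diff(dv2$fraction) <= 0))
  expect_equal(dv2$fraction[1], 1)
})

test_that("cDVH area equals the mean VOI dose within binning error", {
  set.seed(33)
  dm <- structure(list(grid = grid_of(rgamma(12^3, 2) * 1000, c(12, 12, 12),
                                      units = "mGy")),
                  class = "dose_map")
  voi <- mask_of(array(runif(12^3) > 0.3, c(12, 12, 12)))
  dv <- cdvh(dm, voi, n_bins = 512)
  area <- sum(diff(dv$dose_Gy) *
                (head(dv$fraction, -1) + tail(dv$fraction, -1)) / 2)
  expect_equal(area, dv$mean_Gy, tolerance = 0.01)
})

test_that("isodose masks are nested and hit the extremes", {
  set.seed(34)
  dm <- structure(list(grid = grid_of(runif(6^3), c(6, 6, 6),
                                      units = "mGy")),
                  class = "dose_map")
  iso <- isodose_levels(dm, c(80, 50, 20))
  expect_true(all(iso$p80$mask$data <= iso$p50$mask$data))
  expect_true(all(iso$p50$mask$data <= iso$p20$mask$data))
  top <- isodose_levels(dm, 100)$p100$mask
  expect_equal(which(top$data), which.max(dm$grid$data))
  everything <- isodose_levels(dm, 0)$p0$mask
  expect_true(all(everything$data))
})

test_that("dose VOI summary converts to Gy and requires disjoint masks", {
  dm <- structure(list(grid = grid_of(10000, c(4, 4, 4), units = "mGy")),
                  class = "dose_map")
  tm <- array(FALSE, c(4, 4, 4)); tm[1:2, , ] <- TRUE
  tumor <- mask_of(tm, "tumor"); healthy <- mask_of(!tm, "healthy_liver")
  s <- dose_voi_summary(dm, tumor, healthy)
  expect_equal(s$mean_tumor_Gy, 10)
  expect_equal(s$mean_healthy_Gy, 10)
  expect_error(dose_voi_summary(dm, tumor, tumor), "overlap")
})

test_that("self-dose-only kernels give the closed-form tumor dose", {
  s_self <- 1.5
  k <- svalue_kernel(matrix(c(0, 0, 0), 1), s_self, 4.664)
  act <- voxel_grid(array(0.002, c(5, 5, 5)), units = "MBq")
  acum <- cumulated_activity(act, 64.05)
  dm <- dose_convolve(acum, k)
  tm <- array(FALSE, c(5, 5, 5)); tm[2:3, 2:3, 2:3] <- TRUE
  s <- dose_voi_summary(dm, mask_of(tm, "tumor"),
                        mask_of(!tm, "healthy_liver"))
  expect_equal(s$mean_tumor_Gy,
               0.002 * 64.05 * 3600 / log(2) * s_self / 1000,
               tolerance = 1e-9)
})
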