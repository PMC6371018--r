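#' Voxel S-value kernel
#'
#' A voxel S-value table maps integer source-to-target voxel offsets to the
#' absorbed dose in the target per unit cumulated activity in the source, at
#' a declared cubic voxel size.  Canonical units here are mGy/(MBq.s) with
#' cumulated activity in MBq.s.  The self-dose entry S(0,0,0) must be the
#' maximum; entries must be non-negative.
#'
#' @param offsets integer matrix (n x 3) of (i, j, k) voxel offsets.
#' @param values S values, same length, >= 0.
#' @param voxel_size cubic voxel edge, mm.
#' @param units declared units string.
#' @param radionuclide label, e.g. \code{"Y90"}.
#' @return an object of class \code{svalue_kernel} storing a dense odd-sized
#'   3-D array \code{S} and its per-axis \code{extent}.
#' @export
svalue_kernel <- function(offsets, values, voxel_size,
                          units = "mGy/(MBq.s)", radionuclide = "Y90") {
  offsets <- as.matrix(offsets)
  if (ncol(offsets) != 3L || nrow(offsets) != length(values))
    stop("offsets must be n x 3 with matching values")
  if (any(values < 0)) stop("S values must be >= 0")
  if (voxel_size <= 0) stop("voxel_size must be positive")
  ext <- unname(apply(abs(offsets), 2, max))
  S <- array(0, dim = 2 * ext + 1)
  S[cbind(offsets[, 1] + ext[1] + 1, offsets[, 2] + ext[2] + 1,
          offsets[, 3] + ext[3] + 1)] <- values
  centre <- S[ext[1] + 1, ext[2] + 1, ext[3] + 1]
  if (centre <= 0 || centre < max(S))
    stop("S(0,0,0) must be positive and the maximum entry")
  structure(list(S = S, extent = ext, voxel_size = voxel_size,
                 units = units, radionuclide = radionuclide),
            class = "svalue_kernel")
}

#' @export
print.svalue_kernel <- function(x, ...) {
  cat(sprintf(
    "<svalue_kernel> %s @ %.3f mm, extent %d/%d/%d, S0 = %.4g %s\n",
    x$radionuclide, x$voxel_size, x$extent[1], x$extent[2], x$extent[3],
    x$S[x$extent[1] + 1, x$extent[2] + 1, x$extent[3] + 1], x$units))
  invisible(x)
}

# S value at a given integer offset (0 outside the tabulated support)
kernel_value <- function(kernel, i, j, k) {
  e <- kernel$extent
  if (abs(i) > e[1] || abs(j) > e[2] || abs(k) > e[3]) return(0)
  kernel$S[i + e[1] + 1, j + e[2] + 1, k + e[3] + 1]
}

#' Read / write a voxel S-value kernel as CSV
#'
#' Schema: comment header lines \code{# radionuclide:}, \code{#
#' voxel_size_mm:}, \code{# units:}, then columns \code{i,j,k,S_value}.
#'
#' @param path CSV path.
#' @return an \code{svalue_kernel}.
#' @export
read_kernel_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- function(key, default = NA_character_) {
    m <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (!length(m)) return(default)
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", m[1]))
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (!all(c("i", "j", "k", "S_value") %in% names(df)))
    stop("kernel CSV must have columns i,j,k,S_value")
  svalue_kernel(as.matrix(df[, c("i", "j", "k")]), df$S_value,
                voxel_size = as.numeric(meta("voxel_size_mm")),
                units = meta("units", "mGy/(MBq.s)"),
                radionuclide = meta("radionuclide", "Y90"))
}

#' @rdname read_kernel_csv
#' @param kernel an \code{svalue_kernel} to write.
#' @export
write_kernel_csv <- function(kernel, path) {
  e <- kernel$extent
  grid <- expand.grid(i = -e[1]:e[1], j = -e[2]:e[2], k = -e[3]:e[3])
  vals <- kernel$S[cbind(grid$i + e[1] + 1, grid$j + e[2] + 1,
                         grid$k + e[3] + 1)]
  keep <- vals > 0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# radionuclide: %s", kernel$radionuclide),
               sprintf("# voxel_size_mm: %g", kernel$voxel_size),
               sprintf("# units: %s", kernel$units)), con)
  utils::write.csv(data.frame(grid[keep, ], S_value = vals[keep]), con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Interpolate a kernel to an intermediate voxel size
#'
#' Published S-value tables exist at discrete voxel sizes (here 3 mm and
#' 6 mm); for the clinical 4.664 mm grid each offset entry is linearly
#' interpolated in voxel size:
#' \code{S(target) = S3 + (target - 3) / (6 - 3) * (S6 - S3)}.
#' Offsets missing from one parent are treated as 0.  Index-wise
#' correspondence between the two lattices is used; this is a documented
#' numerical convenience, not transport physics.
#'
#' @param k3,k6 \code{svalue_kernel}s at the smaller / larger voxel size,
#'   same radionuclide and units.
#' @param target_size target voxel edge, mm, inside
#'   \code{[k3$voxel_size, k6$voxel_size]} unless \code{extrapolate}.
#' @param extrapolate allow targets outside the bracketing sizes.
#' @return an \code{svalue_kernel} at \code{target_size}.
#' @export
interpolate_kernel <- function(k3, k6, target_size, extrapolate = FALSE) {
  stopifnot(inherits(k3, "svalue_kernel"), inherits(k6, "svalue_kernel"))
  if (!identical(k3$units, k6$units)) stop("kernel unit mismatch")
  if (!identical(k3$radionuclide, k6$radionuclide))
    stop("kernel radionuclide mismatch")
  if (!extrapolate &&
      (target_size < k3$voxel_size || target_size > k6$voxel_size))
    stop("target_size outside bracketing voxel sizes; set extrapolate=TRUE")
  ext <- pmax(k3$extent, k6$extent)
  t <- (target_size - k3$voxel_size) / (k6$voxel_size - k3$voxel_size)
  grid <- expand.grid(i = -ext[1]:ext[1], j = -ext[2]:ext[2],
                      k = -ext[3]:ext[3])
  s3 <- mapply(kernel_value, grid$i, grid$j, grid$k,
               MoreArgs = list(kernel = k3))
  s6 <- mapply(kernel_value, grid$i, grid$j, grid$k,
               MoreArgs = list(kernel = k6))
  svalue_kernel(as.matrix(grid), s3 + t * (s6 - s3),
                voxel_size = target_size, units = k3$units,
                radionuclide = k3$radionuclide)
}

#' Synthetic energy-conserving S-value kernel
#'
#' A synthetic stand-in for published Y-90 voxel S-value tables, built so
#' that the kernel-weighted total equals the mean beta energy emitted per
#' decay deposited in water-equivalent voxels: entries fall off
#' exponentially with source-target distance (scale \code{rho} mm,
#' comparable to the Y-90 mean beta range) and are normalized so that
#' \code{sum(S) * voxel_mass = E_mean per MBq.s}.  Suitable for exercising
#' the dose engine and its conservation properties; it is NOT a published
#' dosimetry table.
#'
#' @param voxel_size cubic voxel edge, mm.
#' @param extent kernel half-extent in voxels.
#' @param rho exponential fall-off scale, mm.
#' @param mean_energy_MeV mean emitted energy per decay (Y-90 beta: 0.9336).
#' @return an \code{svalue_kernel} in mGy/(MBq.s).
#' @export
synthetic_y90_kernel <- function(voxel_size = 4.664, extent = 4, rho = 2.5,
                                 mean_energy_MeV = 0.9336) {
  grid <- expand.grid(i = -extent:extent, j = -extent:extent,
                      k = -extent:extent)
  dist <- sqrt(grid$i^2 + grid$j^2 + grid$k^2) * voxel_size
  w <- exp(-dist / rho)
  mass_kg <- (voxel_size / 10)^3 / 1000          # water, cm^3 -> kg
  joule_per_MBq_s <- mean_energy_MeV * 1.602e-13 * 1e6
  s_total_mGy <- joule_per_MBq_s / mass_kg * 1000
  svalue_kernel(as.matrix(grid), w / sum(w) * s_total_mGy,
                voxel_size = voxel_size, units = "mGy/(MBq.s)",
                radionuclide = "Y90-synthetic")
}

#' Time-integrated (cumulated) activity for a permanent implant
#'
#' Microspheres are a permanent implant: no biological elimination,
#' redistribution or washout, so the time integral of activity is governed
#' by physical decay alone: \code{A_cum = A0 * T_half / ln 2} (in seconds).
#'
#' @param a0 \code{voxel_grid} in MBq (activity at implant time).
#' @param half_life_h physical half-life in hours (Y-90: 64.05).
#' @return \code{voxel_grid} in MBq.s.
#' @export
cumulated_activity <- function(a0, half_life_h = 64.05) {
  check_units(a0, "MBq")
  if (half_life_h <= 0) stop("half_life_h must be positive")
  voxel_grid(a0$data * half_life_h * 3600 / log(2), spacing = a0$spacing,
             origin = a0$origin, units = "MBq.s")
}

#' Convolve cumulated activity with a voxel S-value kernel
#'
#' \code{D(t) = sum_s A_cum(s) * S(t - s)} over the kernel support; dose
#' beyond the grid boundary is discarded (zero padding).  The
#' \code{"direct"} engine sums shifted copies offset by offset; the
#' \code{"transform"} engine evaluates the same linear convolution by
#' zero-padded FFT.  Both agree to high relative accuracy and the result is
#' linear in the activity.
#'
#' @param a_cum \code{voxel_grid} in MBq.s.
#' @param kernel an \code{svalue_kernel} whose voxel size matches the grid
#'   spacing within 1\%.
#' @param engine \code{"transform"} (default) or \code{"direct"}.
#' @return an object of class \code{dose_map}: a \code{voxel_grid} in mGy
#'   plus kernel provenance.
#' @export
dose_convolve <- function(a_cum, kernel, engine = c("transform", "direct")) {
  engine <- match.arg(engine)
  check_units(a_cum, "MBq.s")
  stopifnot(inherits(kernel, "svalue_kernel"))
  if (any(abs(a_cum$spacing - kernel$voxel_size) / kernel$voxel_size > 0.01))
    stop(sprintf("grid spacing %.3f mm does not match kernel voxel size %.3f mm",
                 a_cum$spacing[1], kernel$voxel_size))
  a <- a_cum$data
  e <- kernel$extent
  if (engine == "direct") {
    out <- array(0, dim = dim(a))
    for (i in -e[1]:e[1]) for (j in -e[2]:e[2]) for (k in -e[3]:e[3]) {
      s <- kernel$S[i + e[1] + 1, j + e[2] + 1, k + e[3] + 1]
      if (s != 0) out <- out + s * shift3(a, c(i, j, k))
    }
  } else {
    d <- dim(a)
    dp <- d + 2 * e
    ap <- array(0, dim = dp)
    ap[e[1] + seq_len(d[1]), e[2] + seq_len(d[2]), e[3] + seq_len(d[3])] <- a
    kp <- array(0, dim = dp)
    kd <- dim(kernel$S)
    ix <- ((seq_len(kd[1]) - 1L - e[1]) %% dp[1]) + 1L
    iy <- ((seq_len(kd[2]) - 1L - e[2]) %% dp[2]) + 1L
    iz <- ((seq_len(kd[3]) - 1L - e[3]) %% dp[3]) + 1L
    kp[ix, iy, iz] <- kernel$S
    full <- Re(fft(fft(ap) * fft(kp), inverse = TRUE)) / prod(dp)
    out <- full[e[1] + seq_len(d[1]), e[2] + seq_len(d[2]),
                e[3] + seq_len(d[3]), drop = FALSE]
    out <- pmax(out, 0)        # clip FFT round-off below zero
    dim(out) <- d
  }
  structure(list(grid = voxel_grid(out, spacing = a_cum$spacing,
                                   origin = a_cum$origin, units = "mGy"),
                 kernel_id = kernel$radionuclide,
                 kernel_voxel_size = kernel$voxel_size, engine = engine),
            class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("<dose_map> kernel %s (%s engine), max %.3g mGy\n",
              x$kernel_id, x$engine, max(x$grid$data)))
  invisible(x)
}

#' Cumulative dose-volume histogram
#'
#' Fraction of the VOI volume receiving at least each dose level, evaluated
#' at \code{n_bins + 1} edges from 0 to the maximum VOI dose.
#'
#' @param dose a \code{dose_map}.
#' @param voi non-empty \code{voi_mask}.
#' @param n_bins number of bins (>= 1).
#' @param voi_label label stored with the curve.
#' @return an object of class \code{dvh}: \code{dose_Gy} (edges),
#'   \code{fraction} (non-increasing, starts at 1).
#' @export
cdvh <- function(dose, voi, n_bins = 512, voi_label = "") {
  stopifnot(inherits(dose, "dose_map"))
  vals_gy <- voi_stats_values(dose$grid, voi) / 1000
  edges <- seq(0, max(vals_gy), length.out = n_bins + 1)
  frac <- vapply(edges, function(e) mean(vals_gy >= e), numeric(1))
  structure(list(dose_Gy = edges, fraction = frac, voi_label = voi_label,
                 mean_Gy = mean(vals_gy)),
            class = "dvh")
}

# masked values helper (errors on empty masks like voi_stats)
voi_stats_values <- function(img, mask) {
  check_aligned(img, mask)
  if (sum(mask$data) < 1L) stop("empty mask")
  img$data[mask$data]
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh>%s %d edges to %.2f Gy, mean %.2f Gy\n",
              if (nzchar(x$voi_label)) paste0(" [", x$voi_label, "]") else "",
              length(x$dose_Gy), max(x$dose_Gy), x$mean_Gy))
  invisible(x)
}

#' Write a DVH curve as CSV (dose_Gy, fraction)
#' @param dvh a \code{dvh}.
#' @param path output CSV path.
#' @export
write_dvh_csv <- function(dvh, path) {
  utils::write.csv(data.frame(dose_Gy = dvh$dose_Gy,
                              fraction = dvh$fraction),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Isodose thresholds and masks
#'
#' Thresholds are percentages of the maximum absorbed dose; the returned
#' masks are nested (a higher percentage is contained in a lower one).
#'
#' @param dose a \code{dose_map} with positive maximum.
#' @param percents percentages of the maximum dose.
#' @return named list per level with \code{threshold_mGy} and \code{mask}.
#' @export
isodose_levels <- function(dose, percents = c(20, 50, 80)) {
  stopifnot(inherits(dose, "dose_map"))
  mx <- max(dose$grid$data)
  if (mx <= 0) stop("all-zero dose map")
  out <- lapply(percents, function(p) {
    thr <- p / 100 * mx
    list(percent = p, threshold_mGy = thr,
         mask = voi_mask(dose$grid$data >= thr, role = "body",
                         label = sprintf("isodose %g%%", p)))
  })
  names(out) <- paste0("p", percents)
  out
}

#' Mean/extreme absorbed dose in tumor and healthy liver
#'
#' @param dose a \code{dose_map}.
#' @param tumor,healthy non-empty disjoint \code{voi_mask}s.
#' @return list of per-VOI summaries in Gy.
#' @export
dose_voi_summary <- function(dose, tumor, healthy) {
  stopifnot(inherits(dose, "dose_map"))
  if (any(tumor$data & healthy$data))
    stop("tumor and healthy masks overlap")
  tv <- voi_stats_values(dose$grid, tumor) / 1000
  hv <- voi_stats_values(dose$grid, healthy) / 1000
  list(mean_tumor_Gy = mean(tv), mean_healthy_Gy = mean(hv),
       min_tumor_Gy = min(tv), max_tumor_Gy = max(tv),
       min_healthy_Gy = min(hv), max_healthy_Gy = max(hv))
}
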