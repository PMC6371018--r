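#' Sphere insert specification
#'
#' @param center world-mm centre (length 3).
#' @param diameter inner diameter, mm (> 0).
#' @param concentration activity concentration, MBq/ml (>= 0).
#' @export
sphere_spec <- function(center, diameter, concentration) {
  if (diameter <= 0) stop("diameter must be > 0")
  if (concentration < 0) stop("concentration must be >= 0")
  structure(list(center = as.numeric(center), diameter = diameter,
                 concentration = concentration), class = "sphere_spec")
}

#' Digital Jaszczak-phantom specification
#'
#' A water-filled cylinder (about 6 L) holding eight fillable spherical
#' inserts of inner diameter 2, 8, 10, 12, 16, 25, 31 and 34 mm arranged on
#' a ring.  Default concentrations are 0.52 MBq/ml in the spheres and
#' 0.04 MBq/ml in the background, a 13:1 sphere-to-background concentration
#' ratio.  Concentrations are the primary ground truth; per-sphere activity
#' follows as concentration times volume.
#'
#' @param voxel_size isotropic voxel edge, mm.
#' @param dim grid extents in voxels.
#' @param supersampling integer subdivisions per axis used for
#'   partial-volume rasterization of region boundaries.
#' @param sphere_concentration MBq/ml in the hot spheres.
#' @param background_concentration MBq/ml in the cylinder background.
#' @param cylinder_radius,cylinder_height phantom body, mm (defaults give
#'   about 5.8 L).
#' @param sphere_diameters inner diameters, mm.
#' @param ring_radius radius of the circle the sphere centres sit on, mm.
#' @return an object of class \code{phantom_spec}.
#' @export
jaszczak_phantom_spec <- function(voxel_size = 4.664, dim = c(96, 96, 64),
                                  supersampling = 4,
                                  sphere_concentration = 0.52,
                                  background_concentration = 0.04,
                                  cylinder_radius = 100,
                                  cylinder_height = 186,
                                  sphere_diameters = c(34, 31, 25, 16, 12,
                                                       10, 8, 2),
                                  ring_radius = 55) {
  if (voxel_size <= 0) stop("voxel_size must be positive")
  ang <- (seq_along(sphere_diameters) - 1) * 2 * pi / length(sphere_diameters)
  spheres <- lapply(seq_along(sphere_diameters), function(i)
    sphere_spec(center = c(ring_radius * cos(ang[i]),
                           ring_radius * sin(ang[i]), 0),
                diameter = sphere_diameters[i],
                concentration = sphere_concentration))
  names(spheres) <- paste0("d", sphere_diameters)
  structure(list(cylinder = list(center = c(0, 0, 0),
                                 radius = cylinder_radius,
                                 height = cylinder_height),
                 background_concentration = background_concentration,
                 spheres = spheres, voxel_size = voxel_size,
                 dim = as.integer(dim), supersampling = as.integer(supersampling),
                 origin = -(dim - 1) / 2 * voxel_size),
            class = "phantom_spec")
}

# fractional occupancy of a sphere on the voxel lattice (supersampled
# boundary voxels inside the sphere bounding box only)
sphere_occupancy <- function(dimv, spacing, origin, center, radius, s) {
  occ <- array(0, dim = dimv)
  lo <- pmax(floor((center - radius - origin) / spacing) + 1, 1)
  hi <- pmin(ceiling((center + radius - origin) / spacing) + 1, dimv)
  if (any(lo > hi)) return(occ)
  ax <- lapply(1:3, function(a) lo[a]:hi[a])
  ctr <- lapply(1:3, function(a) origin[a] + (ax[[a]] - 1) * spacing[a])
  off <- ((seq_len(s) - 0.5) / s - 0.5)
  sub <- expand.grid(ox = off, oy = off, oz = off)
  nb <- prod(hi - lo + 1)
  cx <- array(rep(ctr[[1]], times = prod(hi[2:3] - lo[2:3] + 1)),
              dim = hi - lo + 1)
  cy <- array(rep(rep(ctr[[2]], each = hi[1] - lo[1] + 1),
                  times = hi[3] - lo[3] + 1), dim = hi - lo + 1)
  cz <- array(rep(ctr[[3]], each = prod(hi[1:2] - lo[1:2] + 1)),
              dim = hi - lo + 1)
  acc <- array(0, dim = hi - lo + 1)
  for (r in seq_len(nrow(sub))) {
    dx <- cx + sub$ox[r] * spacing[1] - center[1]
    dy <- cy + sub$oy[r] * spacing[2] - center[2]
    dz <- cz + sub$oz[r] * spacing[3] - center[3]
    acc <- acc + (dx^2 + dy^2 + dz^2 <= radius^2)
  }
  occ[ax[[1]], ax[[2]], ax[[3]]] <- acc / nrow(sub)
  occ
}

# fractional occupancy of an axis-aligned ellipsoid
ellipsoid_occupancy <- function(dimv, spacing, origin, center, semi, s) {
  occ <- array(0, dim = dimv)
  lo <- pmax(floor((center - semi - origin) / spacing) + 1, 1)
  hi <- pmin(ceiling((center + semi - origin) / spacing) + 1, dimv)
  if (any(lo > hi)) return(occ)
  ax <- lapply(1:3, function(a) lo[a]:hi[a])
  ctr <- lapply(1:3, function(a) origin[a] + (ax[[a]] - 1) * spacing[a])
  off <- ((seq_len(s) - 0.5) / s - 0.5)
  sub <- expand.grid(ox = off, oy = off, oz = off)
  bd <- hi - lo + 1
  cx <- array(rep(ctr[[1]], times = prod(bd[2:3])), dim = bd)
  cy <- array(rep(rep(ctr[[2]], each = bd[1]), times = bd[3]), dim = bd)
  cz <- array(rep(ctr[[3]], each = prod(bd[1:2])), dim = bd)
  acc <- array(0, dim = bd)
  for (r in seq_len(nrow(sub))) {
    dx <- (cx + sub$ox[r] * spacing[1] - center[1]) / semi[1]
    dy <- (cy + sub$oy[r] * spacing[2] - center[2]) / semi[2]
    dz <- (cz + sub$oz[r] * spacing[3] - center[3]) / semi[3]
    acc <- acc + (dx^2 + dy^2 + dz^2 <= 1)
  }
  occ[ax[[1]], ax[[2]], ax[[3]]] <- acc / nrow(sub)
  occ
}

# cylinder occupancy, separable: supersampled disc in-plane times exact
# axial overlap
cylinder_occupancy <- function(dimv, spacing, origin, center, radius,
                               height, s) {
  xs <- origin[1] + (seq_len(dimv[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dimv[2]) - 1) * spacing[2]
  off <- ((seq_len(s) - 0.5) / s - 0.5)
  disc <- matrix(0, dimv[1], dimv[2])
  dx <- outer(xs - center[1], rep(1, dimv[2]))
  dy <- outer(rep(1, dimv[1]), ys - center[2])
  rr <- sqrt(dx^2 + dy^2)
  half_diag <- sqrt(spacing[1]^2 + spacing[2]^2) / 2
  disc[rr <= radius - half_diag] <- 1
  edge <- which(abs(rr - radius) <= half_diag, arr.ind = TRUE)
  if (nrow(edge)) {
    sub <- expand.grid(ox = off, oy = off)
    acc <- numeric(nrow(edge))
    ex <- xs[edge[, 1]]; ey <- ys[edge[, 2]]
    for (r in seq_len(nrow(sub))) {
      acc <- acc + ((ex + sub$ox[r] * spacing[1] - center[1])^2 +
                    (ey + sub$oy[r] * spacing[2] - center[2])^2 <= radius^2)
    }
    disc[edge] <- acc / nrow(sub)
  }
  zs <- origin[3] + (seq_len(dimv[3]) - 1) * spacing[3]
  zlo <- center[3] - height / 2; zhi <- center[3] + height / 2
  zfrac <- pmax(0, pmin(zs + spacing[3] / 2, zhi) -
                   pmax(zs - spacing[3] / 2, zlo)) / spacing[3]
  occ <- array(0, dim = dimv)
  for (k in seq_len(dimv[3])) if (zfrac[k] > 0) occ[, , k] <- disc * zfrac[k]
  occ
}

#' Rasterize a digital phantom to an activity grid with truth masks
#'
#' Per-voxel activity is concentration times voxel volume, with boundary
#' voxels fractionally weighted by supersampled occupancy.  Truth masks
#' (occupancy >= 0.5; for spheres smaller than a voxel, the single voxel of
#' maximum occupancy) are returned for each sphere and for the background
#' (cylinder voxels free of any sphere occupancy).
#'
#' @param spec a \code{phantom_spec}.
#' @return list with \code{activity} (\code{voxel_grid}, MBq per voxel),
#'   \code{truth_masks} (named \code{voi_mask} list: one per sphere plus
#'   \code{background} and \code{body}), \code{sphere_activity_MBq}
#'   (rasterized totals) and \code{total_activity_MBq}.
#' @export
rasterize_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dimv <- spec$dim; sp <- rep(spec$voxel_size, 3); org <- spec$origin
  vvol <- prod(sp) / 1000
  cyl <- spec$cylinder
  for (s in spec$spheres) {
    r <- s$diameter / 2
    inplane <- sqrt(sum((s$center[1:2] - cyl$center[1:2])^2))
    if (inplane + r > cyl$radius ||
        abs(s$center[3] - cyl$center[3]) + r > cyl$height / 2)
      stop("sphere extends outside the cylinder")
  }
  cyl_occ <- cylinder_occupancy(dimv, sp, org, cyl$center, cyl$radius,
                                cyl$height, spec$supersampling)
  sph_occ <- lapply(spec$spheres, function(s)
    sphere_occupancy(dimv, sp, org, s$center, s$diameter / 2,
                     spec$supersampling))
  tot_sph <- Reduce(`+`, sph_occ)
  bg_occ <- pmax(cyl_occ - tot_sph, 0)
  act <- spec$background_concentration * bg_occ * vvol
  for (i in seq_along(sph_occ))
    act <- act + spec$spheres[[i]]$concentration * sph_occ[[i]] * vvol
  masks <- lapply(seq_along(sph_occ), function(i) {
    m <- sph_occ[[i]] >= 0.5
    if (!any(m)) m[which.max(sph_occ[[i]])] <- TRUE
    voi_mask(array(m, dim = dimv), role = "sphere",
             label = names(spec$spheres)[i])
  })
  names(masks) <- names(spec$spheres)
  masks$background <- voi_mask(cyl_occ >= 0.5 & tot_sph == 0,
                               role = "background", label = "background")
  masks$body <- voi_mask(cyl_occ >= 0.5, role = "body", label = "phantom")
  sph_act <- vapply(seq_along(sph_occ), function(i)
    spec$spheres[[i]]$concentration * sum(sph_occ[[i]]) * vvol, numeric(1))
  names(sph_act) <- names(spec$spheres)
  list(activity = voxel_grid(act, spacing = sp, origin = org, units = "MBq"),
       truth_masks = masks, sphere_activity_MBq = sph_act,
       total_activity_MBq = sum(act))
}

#' Acquisition model for forward simulation
#'
#' Converts a ground-truth activity grid to a reconstructed count-rate image
#' by scaling with a calibration factor, blurring with the Gaussian
#' collimator-detector PSF, and (optionally) drawing Poisson counts at the
#' per-view acquisition time before dividing back to cps.
#'
#' @param cf calibration factor, cps/MBq (> 0); default the phantom-regime
#'   value 9049.
#' @param psf_fwhm Gaussian PSF FWHM, mm (>= 0).
#' @param noise \code{"poisson"} or \code{"none"}.
#' @param acquisition_seconds dwell time used to scale cps to counts for the
#'   Poisson draw (> 0).
#' @param seed RNG seed for the Poisson draw; identical seeds give identical
#'   output.
#' @return an object of class \code{acquisition_model}.
#' @export
acquisition_model <- function(cf = 9049, psf_fwhm = 12,
                              noise = c("poisson", "none"),
                              acquisition_seconds = 35, seed = 1L) {
  noise <- match.arg(noise)
  if (cf <= 0) stop("cf must be positive")
  if (psf_fwhm < 0) stop("psf_fwhm must be >= 0")
  if (acquisition_seconds <= 0) stop("acquisition_seconds must be positive")
  structure(list(cf = cf, psf_fwhm = psf_fwhm, noise = noise,
                 acquisition_seconds = acquisition_seconds,
                 seed = as.integer(seed)),
            class = "acquisition_model")
}

#' Simulate a SPECT acquisition from a ground-truth activity grid
#'
#' @param activity \code{voxel_grid} in MBq (per voxel).
#' @param model an \code{acquisition_model}.
#' @return \code{voxel_grid} in cps.
#' @export
simulate_acquisition <- function(activity, model) {
  check_units(activity, "MBq")
  stopifnot(inherits(model, "acquisition_model"))
  expected <- activity$data * model$cf
  if (model$psf_fwhm > 0) {
    kernel <- gaussian_psf_kernel(psf_model(model$psf_fwhm),
                                  activity$spacing)
    expected <- conv3_reflect(expected, kernel)
  }
  expected <- pmax(expected, 0)
  out <- if (model$noise == "poisson") {
    t <- model$acquisition_seconds
    with_seed(model$seed,
              array(stats::rpois(length(expected), expected * t) / t,
                    dim = dim(expected)))
  } else expected
  voxel_grid(out, spacing = activity$spacing, origin = activity$origin,
             units = "cps")
}

#' Synthetic liver-study specification
#'
#' An ellipsoidal liver with one or more ellipsoidal tumor blobs whose
#' uptake multiplier is the true tumor-to-liver ratio, an optional
#' zero-uptake necrotic core, and a rigid translation applied to the second
#' study of a pair (emulating pre/post-treatment misregistration).
#'
#' @param liver list with \code{center} and \code{semi} (semi-axes), mm.
#' @param tumors list of lists with \code{center}, \code{semi}, and
#'   \code{uptake} (> 0, the true TLR).
#' @param necrotic_core_fraction inner fraction (by linear scale cube root
#'   of volume fraction) of each tumor with zero uptake, or 0.
#' @param misalignment rigid translation (mm, length 3) applied to study B.
#' @param total_activity_MBq total activity in the grid; the concentration
#'   field is scaled to this value.
#' @param voxel_size,dim,supersampling lattice parameters.
#' @return an object of class \code{liver_study_spec}.
#' @export
liver_study_spec <- function(liver = list(center = c(0, 0, 0),
                                          semi = c(80, 55, 45)),
                             tumors = list(list(center = c(30, 12, 8),
                                                semi = c(30, 25, 20),
                                                uptake = 5)),
                             necrotic_core_fraction = 0,
                             misalignment = c(0, 0, 0),
                             total_activity_MBq = 1000,
                             voxel_size = 4.664, dim = c(48, 48, 36),
                             supersampling = 4) {
  for (tm in tumors) {
    if (tm$uptake <= 0) stop("uptake multiplier must be > 0")
    rho <- sqrt(sum(((tm$center - liver$center) / liver$semi)^2))
    if (rho + max(tm$semi / liver$semi) > 1.05)
      stop("tumor extends outside the liver")
  }
  if (necrotic_core_fraction < 0 || necrotic_core_fraction >= 1)
    stop("necrotic_core_fraction must be in [0, 1)")
  structure(list(liver = liver, tumors = tumors,
                 necrotic_core_fraction = necrotic_core_fraction,
                 misalignment = as.numeric(misalignment),
                 total_activity_MBq = total_activity_MBq,
                 voxel_size = voxel_size, dim = as.integer(dim),
                 supersampling = as.integer(supersampling),
                 origin = -(dim - 1) / 2 * voxel_size),
            class = "liver_study_spec")
}

#' Rasterize a liver-study specification
#'
#' @param spec a \code{liver_study_spec}.
#' @return list with \code{activity} (\code{voxel_grid}, MBq per voxel,
#'   summing to \code{total_activity_MBq}) and truth masks (\code{liver},
#'   \code{tumor}, \code{healthy}).
#' @export
rasterize_liver <- function(spec) {
  stopifnot(inherits(spec, "liver_study_spec"))
  dimv <- spec$dim; sp <- rep(spec$voxel_size, 3); org <- spec$origin
  liver_occ <- ellipsoid_occupancy(dimv, sp, org, spec$liver$center,
                                   spec$liver$semi, spec$supersampling)
  tum_occ <- array(0, dim = dimv)
  conc <- liver_occ                     # base concentration 1 in liver
  for (tm in spec$tumors) {
    occ <- ellipsoid_occupancy(dimv, sp, org, tm$center, tm$semi,
                               spec$supersampling)
    core <- if (spec$necrotic_core_fraction > 0)
      ellipsoid_occupancy(dimv, sp, org, tm$center,
                          tm$semi * spec$necrotic_core_fraction^(1 / 3),
                          spec$supersampling)
    else array(0, dim = dimv)
    conc <- conc + occ * (tm$uptake - 1) - core * tm$uptake
    tum_occ <- pmax(tum_occ, occ - core)
  }
  conc <- pmax(conc, 0)
  act <- conc / sum(conc) * spec$total_activity_MBq
  tumor <- tum_occ >= 0.5
  liver <- liver_occ >= 0.5
  # "core" masks keep clear of rasterization boundaries so ground-truth
  # concentration ratios can be read off exactly
  tumor_core <- tum_occ >= 0.999
  healthy_core <- liver_occ >= 0.999 & tum_occ == 0
  list(activity = voxel_grid(act, spacing = sp, origin = org,
                             units = "MBq"),
       truth_masks = list(
         liver = voi_mask(liver, role = "whole_liver", label = "liver"),
         tumor = voi_mask(tumor & liver, role = "tumor", label = "tumor"),
         healthy = voi_mask(liver & !tumor, role = "healthy_liver",
                            label = "healthy"),
         tumor_core = voi_mask(tumor_core, role = "tumor",
                               label = "tumor core"),
         healthy_core = voi_mask(healthy_core, role = "healthy_liver",
                                 label = "healthy core")))
}

#' Generate a paired pre/post study with known ground truth
#'
#' Two acquisitions of the same anatomy: study A (MAA-like surrogate) on the
#' reference grid and study B (Y-90-like) rigidly displaced by
#' \code{spec$misalignment}.  The truth record carries the masks, the true
#' TLR measured on the truth activity grid, and the exact inverse transform.
#'
#' @param spec a \code{liver_study_spec}.
#' @param model_a,model_b \code{acquisition_model}s for the two studies.
#' @return list with \code{study_a}, \code{study_b} (\code{study_set}s) and
#'   \code{truth} (activity grids, masks, \code{true_tlr},
#'   \code{inverse_transform_mm}).
#' @export
make_paired_study <- function(spec, model_a = acquisition_model(seed = 1),
                              model_b = acquisition_model(seed = 2)) {
  ras <- rasterize_liver(spec)
  act_a <- ras$activity
  true_tlr <- tlr(act_a, ras$truth_masks$tumor_core,
                  ras$truth_masks$healthy_core)
  act_b <- if (all(spec$misalignment == 0)) act_a else {
    shifted_src <- voxel_grid(act_a$data, spacing = act_a$spacing,
                              origin = act_a$origin + spec$misalignment,
                              units = "MBq")
    resample_to(shifted_src, act_a, mode = "trilinear")
  }
  mk <- function(act, model, agent) {
    study_set(simulate_acquisition(act, model),
              ct_masks = ras$truth_masks,
              administered_activity = spec$total_activity_MBq,
              agent = agent, patient_id = "synthetic")
  }
  list(study_a = mk(act_a, model_a, "MAA"),
       study_b = mk(act_b, model_b, "Y90"),
       truth = list(activity_a = act_a, activity_b = act_b,
                    masks = ras$truth_masks, true_tlr = true_tlr,
                    inverse_transform_mm = -spec$misalignment))
}

#' Generate a seeded synthetic patient cohort
#'
#' \code{n} paired studies with administered activities spread over the
#' clinical range and true TLRs drawn uniformly from \code{tlr_range},
#' mirroring a retrospective radioembolization cohort.
#'
#' @param n number of patients.
#' @param seed cohort seed; patient-level seeds are derived from it.
#' @param activity_range administered activity range, MBq.
#' @param tlr_range true tumor-to-liver uptake ratio range.
#' @param model_template \code{acquisition_model} whose cf/PSF/noise
#'   settings are shared by all studies (seeds are replaced per study).
#' @param dim,voxel_size lattice parameters for every study.
#' @return list of per-patient lists: \code{pair} (see
#'   \code{\link{make_paired_study}}), \code{administered_MBq},
#'   \code{true_tlr}.
#' @export
make_liver_cohort <- function(n = 12, seed = 1,
                              activity_range = c(500, 2100),
                              tlr_range = c(2, 15),
                              model_template = acquisition_model(),
                              dim = c(48, 48, 36), voxel_size = 4.664) {
  draws <- with_seed(seed, list(
    act = seq(activity_range[1], activity_range[2], length.out = n),
    tlr = stats::runif(n, tlr_range[1], tlr_range[2]),
    size = stats::runif(n, 24, 34)))
  lapply(seq_len(n), function(i) {
    spec <- liver_study_spec(
      tumors = list(list(center = c(30, 12, 8),
                         semi = draws$size[i] * c(1, 0.85, 0.75),
                         uptake = draws$tlr[i])),
      total_activity_MBq = draws$act[i],
      dim = dim, voxel_size = voxel_size)
    ma <- model_template; mb <- model_template
    ma$seed <- seed * 10000L + 2L * i
    mb$seed <- seed * 10000L + 2L * i + 1L
    list(pair = make_paired_study(spec, ma, mb),
         administered_MBq = draws$act[i], true_tlr = draws$tlr[i])
  })
}
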