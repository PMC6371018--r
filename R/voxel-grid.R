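#' Construct a voxel grid
#'
#' A \code{voxel_grid} is the package's canonical 3-D image container: a
#' real-valued lattice together with its voxel spacing (mm), the world
#' coordinate of the centre of voxel (0,0,0) (mm), and a units tag.  All
#' quantification stages operate on this container; units are checked at
#' every operation boundary so that, for example, a count-rate image is never
#' silently convolved with a dose kernel.
#'
#' Voxel indices are 0-based in the world-coordinate convention:
#' \code{world = origin + index * spacing} (voxel-centred).  Internally R's
#' 1-based array indexing is used.
#'
#' @param data 3-D numeric array of voxel values.
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin numeric length-3, world position (mm) of the first voxel
#'   centre.
#' @param units one of \code{"cps"}, \code{"MBq"}, \code{"MBq.s"},
#'   \code{"mGy"}, \code{"unitless"}.
#' @return An object of class \code{voxel_grid}.
#' @export
voxel_grid <- function(data, spacing = c(4.664, 4.664, 4.664),
                       origin = c(0, 0, 0),
                       units = c("unitless", "cps", "MBq", "MBq.s", "mGy")) {
  units <- match.arg(units)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  if (any(dim(data) < 1L)) stop("all grid extents must be positive")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values (mm)")
  if (any(!is.finite(data))) stop("grid values must be finite")
  structure(list(data = data, spacing = spacing, origin = origin,
                 units = units),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s  %d x %d x %d voxels @ %.3f x %.3f x %.3f mm\n",
              x$units, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (mm): %.2f %.2f %.2f   range: [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Volume of one voxel in millilitres
#' @param grid a \code{voxel_grid}.
#' @return voxel volume in ml (1 ml = 1000 mm^3).
#' @export
voxel_volume_ml <- function(grid) prod(grid$spacing) / 1000

#' Construct a binary volume-of-interest mask
#'
#' Masks are binary lattices aligned voxel-for-voxel with a companion
#' \code{voxel_grid}; no implicit resampling is ever performed inside
#' statistics.  The \code{role} tag records what the mask delineates.
#'
#' @param data 3-D logical (or 0/1 numeric) array.
#' @param role one of \code{"tumor"}, \code{"healthy_liver"},
#'   \code{"whole_liver"}, \code{"sphere"}, \code{"background"},
#'   \code{"body"}.
#' @param label free-text label.
#' @return An object of class \code{voi_mask}.
#' @export
voi_mask <- function(data, role = c("tumor", "healthy_liver", "whole_liver",
                                    "sphere", "background", "body"),
                     label = "") {
  role <- match.arg(role)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  if (is.numeric(data)) {
    if (any(!data %in% c(0, 1))) stop("mask values must be 0/1")
    data <- array(data > 0, dim = dim(data))
  }
  if (!is.logical(data)) stop("mask must be logical or 0/1 numeric")
  structure(list(data = data, role = role, label = label),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> role=%s%s  %d x %d x %d, %d voxels set\n",
              x$role, if (nzchar(x$label)) paste0(" (", x$label, ")") else "",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], sum(x$data)))
  invisible(x)
}

#' Bundle one SPECT study with its CT-derived masks
#'
#' @param spect \code{voxel_grid} in cps (reconstructed count rate).
#' @param ct_masks named list of \code{voi_mask} aligned to \code{spect}.
#' @param administered_activity administered activity, MBq (>= 0).
#' @param agent \code{"MAA"} (pre-treatment Tc-99m-MAA surrogate) or
#'   \code{"Y90"} (post-treatment microspheres).
#' @param patient_id free text identifier.
#' @return An object of class \code{study_set}.
#' @export
study_set <- function(spect, ct_masks = list(), administered_activity = 0,
                      agent = c("Y90", "MAA"), patient_id = "") {
  agent <- match.arg(agent)
  stopifnot(inherits(spect, "voxel_grid"))
  if (administered_activity < 0) stop("administered_activity must be >= 0")
  for (m in ct_masks) check_aligned(spect, m)
  structure(list(spect = spect, ct_masks = ct_masks,
                 administered_activity = administered_activity,
                 agent = agent, patient_id = patient_id),
            class = "study_set")
}

# mask/grid alignment guard shared by every VOI statistic
check_aligned <- function(img, mask) {
  stopifnot(inherits(img, "voxel_grid"), inherits(mask, "voi_mask"))
  if (!identical(dim(img$data), dim(mask$data)))
    stop("mask and image shapes differ: no implicit resampling is performed")
  invisible(TRUE)
}

check_units <- function(grid, expected) {
  if (!identical(grid$units, expected))
    stop(sprintf("expected a grid in '%s' but got '%s'", expected,
                 grid$units))
  invisible(TRUE)
}

#' Read a 3-D NIfTI volume as a voxel grid
#'
#' @param path path to a \code{.nii} / \code{.nii.gz} file.
#' @param expected_units units tag to attach (NIfTI carries no activity
#'   units).
#' @return a \code{voxel_grid} with spacing and origin taken from the header.
#' @export
read_grid <- function(path, expected_units = "unitless") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(as.numeric(img), dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L) stop("expected a 3-D volume, got ", length(d), "-D")
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  if (any(spacing <= 0)) stop("non-positive voxel spacing in header")
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (!inherits(xf, "try-error") && is.matrix(xf)) xf[1:3, 4]
            else c(0, 0, 0)
  voxel_grid(array(as.numeric(img), dim = d), spacing = spacing,
             origin = origin, units = expected_units)
}

#' Write a voxel grid to NIfTI
#'
#' @param grid a \code{voxel_grid}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @param datatype on-disk storage type; masks use \code{"uint8"}.
#' @return \code{path}, invisibly.
#' @export
write_grid <- function(grid, path, datatype = "double") {
  stopifnot(inherits(grid, "voxel_grid"))
  img <- RNifti::asNifti(grid$data)
  RNifti::pixdim(img) <- grid$spacing
  xf <- diag(c(grid$spacing, 1))
  xf[1:3, 4] <- grid$origin
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a VOI mask to NIfTI (0/1 unsigned 8-bit)
#' @param mask a \code{voi_mask}.
#' @param ref companion \code{voxel_grid} supplying the geometry.
#' @param path output path.
#' @export
write_mask <- function(mask, ref, path) {
  check_aligned(ref, mask)
  g <- voxel_grid(array(as.numeric(mask$data), dim = dim(mask$data)),
                  spacing = ref$spacing, origin = ref$origin,
                  units = "unitless")
  write_grid(g, path, datatype = "uint8")
}

#' Read a NIfTI volume as a VOI mask
#' @param path path to the mask file (values 0/1).
#' @param role role tag for the mask.
#' @param label free-text label.
#' @export
read_mask <- function(path, role = "body", label = "") {
  g <- read_grid(path, "unitless")
  voi_mask(g$data > 0.5, role = role, label = label)
}

#' Resample a grid onto the lattice of a reference grid
#'
#' Used to place pre- and post-treatment studies on a common grid before
#' mutual-information comparison.  Trilinear interpolation preserves constant
#' fields exactly; nearest-neighbour preserves the value set (and is the
#' default for mapping CT-space masks onto the SPECT grid).
#'
#' @param src grid to resample.
#' @param ref grid whose lattice defines the output geometry.
#' @param mode \code{"trilinear"} or \code{"nearest"}.
#' @return a \code{voxel_grid} on \code{ref}'s lattice with \code{src}'s
#'   units.
#' @export
resample_to <- function(src, ref, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(inherits(src, "voxel_grid"), inherits(ref, "voxel_grid"))
  dref <- dim(ref$data)
  dsrc <- dim(src$data)
  # continuous source index of every output voxel centre, axis by axis
  idx <- lapply(1:3, function(ax) {
    w <- ref$origin[ax] + (seq_len(dref[ax]) - 1) * ref$spacing[ax]
    f <- (w - src$origin[ax]) / src$spacing[ax]   # 0-based
    pmin(pmax(f, 0), dsrc[ax] - 1)
  })
  fx <- array(rep(idx[[1]], times = dref[2] * dref[3]), dim = dref)
  fy <- array(rep(rep(idx[[2]], each = dref[1]), times = dref[3]), dim = dref)
  fz <- array(rep(idx[[3]], each = dref[1] * dref[2]), dim = dref)
  if (mode == "nearest") {
    out <- src$data[cbind(c(round(fx)) + 1, c(round(fy)) + 1,
                          c(round(fz)) + 1)]
  } else {
    x0 <- floor(fx); y0 <- floor(fy); z0 <- floor(fz)
    x1 <- pmin(x0 + 1, dsrc[1] - 1)
    y1 <- pmin(y0 + 1, dsrc[2] - 1)
    z1 <- pmin(z0 + 1, dsrc[3] - 1)
    tx <- fx - x0; ty <- fy - y0; tz <- fz - z0
    gv <- function(i, j, k) src$data[cbind(c(i) + 1, c(j) + 1, c(k) + 1)]
    out <- (1 - tx) * (1 - ty) * (1 - tz) * gv(x0, y0, z0) +
           tx * (1 - ty) * (1 - tz) * gv(x1, y0, z0) +
           (1 - tx) * ty * (1 - tz) * gv(x0, y1, z0) +
           tx * ty * (1 - tz) * gv(x1, y1, z0) +
           (1 - tx) * (1 - ty) * tz * gv(x0, y0, z1) +
           tx * (1 - ty) * tz * gv(x1, y0, z1) +
           (1 - tx) * ty * tz * gv(x0, y1, z1) +
           tx * ty * tz * gv(x1, y1, z1)
  }
  voxel_grid(array(out, dim = dref), spacing = ref$spacing,
             origin = ref$origin, units = src$units)
}

#' Summary statistics of an image over a VOI
#'
#' @param img a \code{voxel_grid}.
#' @param mask a \code{voi_mask} aligned to \code{img} with at least one
#'   voxel set.
#' @return list with \code{mean}, \code{total} (plain sum over masked
#'   voxels), \code{voxel_count} and \code{volume_ml}.
#' @export
voi_stats <- function(img, mask) {
  check_aligned(img, mask)
  n <- sum(mask$data)
  if (n < 1L) stop("empty mask")
  vals <- img$data[mask$data]
  tot <- sum(vals)
  list(mean = tot / n, total = tot, voxel_count = n,
       volume_ml = n * voxel_volume_ml(img))
}

#' Set difference of two aligned masks
#'
#' Used to derive the healthy-liver mask by subtracting the segmented tumor
#' from the whole-liver volume.
#'
#' @param whole,part aligned \code{voi_mask} objects.
#' @param role role tag of the result.
#' @export
mask_difference <- function(whole, part, role = "healthy_liver") {
  stopifnot(inherits(whole, "voi_mask"), inherits(part, "voi_mask"))
  if (!identical(dim(whole$data), dim(part$data)))
    stop("mask shapes differ")
  voi_mask(whole$data & !part$data, role = role,
           label = paste0(whole$label, " minus ", part$label))
}
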