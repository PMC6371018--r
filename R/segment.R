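#' Chan-Vese segmentation parameters
#'
#' The two-phase piecewise-constant Chan-Vese energy
#' \deqn{E = \mu Per(\Sigma) + \lambda_1 \sum_{in} (I - c_1)^2 +
#'       \lambda_2 \sum_{out} (I - c_2)^2}
#' is minimized over binary partitions of the liver support.  Intensities are
#' min-max normalized inside the liver before segmentation so the same
#' defaults transfer between Tc-99m-MAA and Y-90 count scales, whose
#' administered activities differ by an order of magnitude.
#'
#' @param mu contour-length weight (on normalized intensities).
#' @param lambda1,lambda2 region-fit weights (> 0).
#' @param max_iterations maximum sweeps (>= 1).
#' @param tolerance convergence threshold on the relative change of the two
#'   region means.
#' @param init \code{"threshold"} seeds the high phase above the in-liver
#'   mean; \code{"checkerboard"} starts from an alternating pattern.
#' @return an object of class \code{chan_vese_params}.
#' @export
chan_vese_params <- function(mu = 0.25, lambda1 = 1, lambda2 = 1,
                             max_iterations = 200, tolerance = 1e-4,
                             init = c("threshold", "checkerboard")) {
  init <- match.arg(init)
  if (mu < 0 || lambda1 <= 0 || lambda2 <= 0) stop("invalid weights")
  if (max_iterations < 1L) stop("max_iterations must be >= 1")
  structure(list(mu = mu, lambda1 = lambda1, lambda2 = lambda2,
                 max_iterations = max_iterations, tolerance = tolerance,
                 init = init),
            class = "chan_vese_params")
}

# neighbour tallies used by the discrete perimeter term: for every voxel,
# how many 6-neighbours inside `inmask` carry a different / equal label
cv_neighbour_counts <- function(lab, inmask) {
  d <- dim(lab)
  diffc <- array(0, dim = d); samec <- array(0, dim = d)
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    nl <- shift3(lab, s)
    nm <- shift3(inmask, s)
    diffc <- diffc + nm * (nl != lab)
    samec <- samec + nm * (nl == lab)
  }
  list(diff = diffc, same = samec)
}

cv_energy <- function(v, lab, inmask, p) {
  per <- 0
  for (s in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    nl <- shift3(lab, s); nm <- shift3(inmask, s)
    per <- per + sum(inmask * nm * (nl != lab))
  }
  in1 <- inmask == 1 & lab == 1
  in0 <- inmask == 1 & lab == 0
  c1 <- if (any(in1)) mean(v[in1]) else mean(v[inmask == 1])
  c2 <- if (any(in0)) mean(v[in0]) else mean(v[inmask == 1])
  p$mu * per + p$lambda1 * sum((v[in1] - c1)^2) +
    p$lambda2 * sum((v[in0] - c2)^2)
}

#' Chan-Vese delineation of high-uptake regions inside the liver
#'
#' Two-phase piecewise-constant active-contour segmentation restricted to the
#' liver VOI, minimized by direct energy-descent label flips on a
#' checkerboard sweep schedule (each accepted flip strictly decreases the
#' discrete Chan-Vese energy, so the energy trace is non-increasing).  The
#' phase with the higher mean intensity is labelled tumor; the healthy-liver
#' mask is the set difference.  All connected components of the high phase
#' are kept (multi-focal disease is not collapsed to one lesion).
#'
#' @param img a \code{voxel_grid}.
#' @param liver non-empty \code{voi_mask} aligned to \code{img}.
#' @param params a \code{chan_vese_params}.
#' @return an object of class \code{segmentation_result}: \code{tumor} and
#'   \code{healthy} masks, volumes in ml, \code{converged},
#'   \code{iterations_used}, \code{energy_trace}, region means
#'   \code{c_tumor}, \code{c_healthy} (normalized intensities).
#' @export
chan_vese <- function(img, liver, params = chan_vese_params()) {
  check_aligned(img, liver)
  if (!inherits(params, "chan_vese_params")) stop("invalid params")
  if (sum(liver$data) == 0L) stop("empty liver mask")
  full_dim <- dim(img$data)
  empty_result <- function() {
    structure(list(
      tumor = voi_mask(array(FALSE, full_dim), role = "tumor"),
      healthy = voi_mask(liver$data, role = "healthy_liver"),
      tumor_volume_ml = 0,
      healthy_volume_ml = sum(liver$data) * voxel_volume_ml(img),
      converged = FALSE, iterations_used = 0L, energy_trace = numeric(0),
      c_tumor = NA_real_, c_healthy = NA_real_),
      class = "segmentation_result")
  }
  rngv <- range(img$data[liver$data])
  if (rngv[1] == rngv[2]) return(empty_result())   # no contrast to segment

  # crop to the liver bounding box for speed
  idx <- which(liver$data, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, full_dim)
  sub <- lapply(1:3, function(ax) lo[ax]:hi[ax])
  inmask <- array(0, dim = hi - lo + 1L)
  inmask[] <- as.numeric(liver$data[sub[[1]], sub[[2]], sub[[3]]])
  v <- (img$data[sub[[1]], sub[[2]], sub[[3]]] - rngv[1]) /
       (rngv[2] - rngv[1])
  d <- dim(inmask)

  lab <- array(0, dim = d)
  if (params$init == "threshold") {
    lab[inmask == 1 & v > mean(v[inmask == 1])] <- 1
  } else {
    ii <- slice.index(lab, 1) + slice.index(lab, 2) + slice.index(lab, 3)
    lab[inmask == 1 & (ii %% 2L == 0L)] <- 1
  }
  if (sum(lab) == 0) lab[inmask == 1 & v == max(v[inmask == 1])] <- 1

  parity <- (slice.index(lab, 1) %% 2L) + 2L * (slice.index(lab, 2) %% 2L) +
            4L * (slice.index(lab, 3) %% 2L)
  in_idx <- inmask == 1

  sweep_once <- function(lab, p) {
    flips <- 0L
    for (p8 in 0:7) {
      n1 <- sum(lab[in_idx]); n0 <- sum(in_idx) - n1
      if (n1 == 0L || n0 == 0L) break
      c1 <- mean(v[in_idx & lab == 1])
      c2 <- mean(v[in_idx & lab == 0])
      nc <- cv_neighbour_counts(lab, inmask)
      d_data <- ifelse(lab == 1,
                       p$lambda2 * (v - c2)^2 - p$lambda1 * (v - c1)^2,
                       p$lambda1 * (v - c1)^2 - p$lambda2 * (v - c2)^2)
      d_e <- d_data + p$mu * (nc$same - nc$diff)
      do_flip <- in_idx & parity == p8 & d_e < 0
      # never empty a phase entirely (keeps the two-phase model defined)
      if (sum(do_flip & lab == 1) >= n1) next
      if (sum(do_flip & lab == 0) >= n0) next
      if (any(do_flip)) {
        lab[do_flip] <- 1 - lab[do_flip]
        flips <- flips + sum(do_flip)
      }
    }
    list(lab = lab, flips = flips)
  }

  # a checkerboard start has nearly equal region means, so the length term
  # would dominate the first sweeps; let the data term separate the means
  # first (two-means relaxation), then minimize the full energy
  if (params$init == "checkerboard") {
    warm <- params; warm$mu <- 0
    for (it in seq_len(10)) {
      sw <- sweep_once(lab, warm)
      lab <- sw$lab
      if (sw$flips == 0L) break
    }
  }
  energy_trace <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  c1_prev <- c2_prev <- NA_real_
  for (it in seq_len(params$max_iterations)) {
    iterations <- it
    sw <- sweep_once(lab, params)
    lab <- sw$lab
    flips <- sw$flips
    c1 <- mean(v[in_idx & lab == 1]); c2 <- mean(v[in_idx & lab == 0])
    energy_trace <- c(energy_trace, cv_energy(v, lab, inmask, params))
    if (flips == 0L) { converged <- TRUE; break }
    if (!is.na(c1_prev) &&
        max(abs(c1 - c1_prev), abs(c2 - c2_prev)) < params$tolerance) {
      converged <- TRUE; break
    }
    c1_prev <- c1; c2_prev <- c2
  }

  # high-mean phase is tumor
  c1 <- mean(v[in_idx & lab == 1]); c2 <- mean(v[in_idx & lab == 0])
  high <- if (c1 >= c2) lab == 1 else lab == 0
  tumor_full <- array(FALSE, full_dim)
  tumor_full[sub[[1]], sub[[2]], sub[[3]]] <- high & in_idx
  tumor <- voi_mask(tumor_full, role = "tumor")
  healthy <- mask_difference(voi_mask(liver$data, role = "whole_liver"),
                             tumor, role = "healthy_liver")
  structure(list(tumor = tumor, healthy = healthy,
                 tumor_volume_ml = sum(tumor$data) * voxel_volume_ml(img),
                 healthy_volume_ml = sum(healthy$data) * voxel_volume_ml(img),
                 converged = converged, iterations_used = iterations,
                 energy_trace = energy_trace,
                 c_tumor = max(c1, c2), c_healthy = min(c1, c2)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> tumor %.1f ml, healthy %.1f ml, %s after %d sweeps\n",
    x$tumor_volume_ml, x$healthy_volume_ml,
    if (x$converged) "converged" else "NOT converged", x$iterations_used))
  invisible(x)
}

#' Tumor-to-liver ratio
#'
#' Mean counts per voxel in the tumor divided by the mean in the healthy
#' liver.  Counts are proportional to activity concentration, so the ratio
#' is unit-free and invariant under any global rescaling of the image.
#'
#' @param img a \code{voxel_grid}.
#' @param tumor,healthy non-empty aligned \code{voi_mask}s.
#' @export
tlr <- function(img, tumor, healthy) {
  mt <- voi_stats(img, tumor)$mean
  mh <- voi_stats(img, healthy)$mean
  if (mh == 0) stop("healthy-liver mean is zero")
  mt / mh
}

#' Segment and compare a pre/post treatment pair
#'
#' Runs Chan-Vese delineation separately on the pre-treatment (MAA) and
#' post-treatment (Y-90) studies over the same liver support, computes the
#' per-study TLR and tumor volumes, and returns a row consumable by the
#' cohort statistics (\code{\link{paired_t}}, \code{\link{pearson_r}}).
#'
#' @param pre,post \code{study_set}s.
#' @param liver_pre,liver_post liver masks for each study
#'   (\code{liver_post} defaults to \code{liver_pre}).
#' @param params a \code{chan_vese_params}.
#' @return list with \code{tlr_pre}, \code{tlr_post}, \code{volume_pre_ml},
#'   \code{volume_post_ml}, and the two \code{segmentation_result}s.
#' @export
compare_pre_post <- function(pre, post, liver_pre, liver_post = NULL,
                             params = chan_vese_params()) {
  stopifnot(inherits(pre, "study_set"), inherits(post, "study_set"))
  if (is.null(liver_post)) liver_post <- liver_pre
  seg_pre <- chan_vese(pre$spect, liver_pre, params)
  seg_post <- chan_vese(post$spect, liver_post, params)
  if (sum(seg_pre$tumor$data) == 0L || sum(seg_post$tumor$data) == 0L)
    stop("segmentation produced an empty tumor mask")
  list(tlr_pre = tlr(pre$spect, seg_pre$tumor, seg_pre$healthy),
       tlr_post = tlr(post$spect, seg_post$tumor, seg_post$healthy),
       volume_pre_ml = seg_pre$tumor_volume_ml,
       volume_post_ml = seg_post$tumor_volume_ml,
       segmentation_pre = seg_pre, segmentation_post = seg_post)
}
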