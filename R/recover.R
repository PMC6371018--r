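#' Gaussian collimator-detector response model
#'
#' Bremsstrahlung SPECT images are degraded by the point spread function of
#' the collimator-detector pair.  The response is modelled as an isotropic
#' 3-D Gaussian parameterized by its full width at half maximum;
#' \code{sigma = fwhm / sqrt(8 * log(2))}.
#'
#' @param fwhm full width at half maximum, mm (>= 0; 0 gives a delta PSF).
#' @param truncation_radius kernel half-extent in multiples of sigma.
#' @return an object of class \code{psf_model}.
#' @export
psf_model <- function(fwhm = 12, truncation_radius = 4) {
  if (fwhm < 0) stop("fwhm must be >= 0")
  structure(list(fwhm = fwhm, sigma = fwhm / sqrt(8 * log(2)),
                 truncation_radius = truncation_radius),
            class = "psf_model")
}

#' Discrete Gaussian PSF kernel
#'
#' Separable Gaussian sampled at voxel centres and normalized to sum exactly
#' to 1, with odd extents and centred on the middle voxel.  \code{fwhm = 0}
#' degenerates to a single-voxel delta kernel.
#'
#' @param model a \code{psf_model}.
#' @param spacing voxel spacing, mm (length 3, all > 0).
#' @return a 3-D array summing to 1.
#' @export
gaussian_psf_kernel <- function(model, spacing) {
  stopifnot(inherits(model, "psf_model"))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive values")
  if (model$sigma == 0) return(array(1, dim = c(1, 1, 1)))
  w1 <- lapply(1:3, function(ax) {
    m <- max(1L, ceiling(model$truncation_radius * model$sigma / spacing[ax]))
    x <- (-m:m) * spacing[ax]
    w <- exp(-x^2 / (2 * model$sigma^2))
    w / sum(w)
  })
  k <- outer(outer(w1[[1]], w1[[2]]), w1[[3]])
  k / sum(k)
}

#' Richardson-Lucy deconvolution
#'
#' Iterative expectation-maximization deconvolution for images degraded by a
#' known PSF.  With \code{A} the observed reconstruction and \code{A'_0 = A},
#' each update is
#' \deqn{A'_i = [ (A / (A'_{i-1} \otimes PSF)) \otimes PSF ] \cdot A'_{i-1}}
#' where \eqn{\otimes} is 3-D convolution.  The PSF is held fixed; only the
#' image is estimated.  Estimates stay non-negative on non-negative input and
#' total counts are conserved up to boundary effects (reflective padding is
#' used, which conserves counts for interior sources).
#'
#' @param observed non-negative \code{voxel_grid}.
#' @param psf a \code{psf_model}.
#' @param iterations number of updates (>= 1).
#' @param keep \code{"all"} returns every iterate, \code{"last"} only the
#'   final one (memory-friendly for large grids).
#' @return list with \code{estimates} (list of \code{voxel_grid}, indexed by
#'   iteration; under \code{keep = "last"} a single element) and
#'   \code{rmse_trace}, the root-mean-square difference between consecutive
#'   estimates (whole image).
#' @export
rl_deconvolve <- function(observed, psf, iterations,
                          keep = c("all", "last")) {
  keep <- match.arg(keep)
  stopifnot(inherits(observed, "voxel_grid"), inherits(psf, "psf_model"))
  if (iterations < 1L) stop("iterations must be >= 1")
  a <- observed$data
  if (any(a < 0)) stop("observed image must be non-negative")
  if (all(a == 0)) {
    warning("all-zero input: returned unchanged")
    est <- if (keep == "all") rep(list(observed), iterations)
           else list(observed)
    return(list(estimates = est, rmse_trace = rep(0, iterations)))
  }
  kernel <- gaussian_psf_kernel(psf, observed$spacing)
  wrap <- function(arr) voxel_grid(arr, spacing = observed$spacing,
                                   origin = observed$origin,
                                   units = observed$units)
  est <- a
  out <- vector("list", if (keep == "all") iterations else 1L)
  rmse <- numeric(iterations)
  for (i in seq_len(iterations)) {
    denom <- conv3_reflect(est, kernel)
    ratio <- a / pmax(denom, 1e-12)       # guard against 0/0
    nxt <- pmax(est * conv3_reflect(ratio, kernel), 0)
    rmse[i] <- sqrt(mean((nxt - est)^2))
    est <- nxt
    if (keep == "all") out[[i]] <- wrap(est)
  }
  if (keep == "last") out[[1]] <- wrap(est)
  list(estimates = out, rmse_trace = rmse)
}

#' Root-mean-square difference between two grids
#'
#' Used between consecutive deconvolution estimates as the convergence trace.
#'
#' @param a,b \code{voxel_grid}s of identical shape.
#' @export
rmse_consecutive <- function(a, b) {
  stopifnot(inherits(a, "voxel_grid"), inherits(b, "voxel_grid"))
  if (!identical(dim(a$data), dim(b$data))) stop("shape mismatch")
  sqrt(mean((a$data - b$data)^2))
}

#' Contrast-to-noise ratio
#'
#' \code{CNR = (M_T - M_B) / M_B} with \code{M_T} and \code{M_B} the mean
#' counts in the tumor and healthy-liver (background) VOIs.
#'
#' @param img a \code{voxel_grid}.
#' @param tumor,background non-empty aligned \code{voi_mask}s.
#' @export
cnr <- function(img, tumor, background) {
  mt <- voi_stats(img, tumor)$mean
  mb <- voi_stats(img, background)$mean
  if (mb == 0) stop("background mean is zero")
  (mt - mb) / mb
}

#' Hot-sphere contrast recovery coefficient
#'
#' \code{Q_H = 100 * (C_S / C_B - 1) / (R - 1)} where \code{C_S} and
#' \code{C_B} are the mean counts in the sphere and background VOIs and
#' \code{R} is the true sphere-to-background activity concentration ratio.
#' 100 means the full contrast survived imaging; 0 means none did.
#'
#' @param img a \code{voxel_grid}.
#' @param sphere,background non-empty aligned \code{voi_mask}s.
#' @param true_ratio true concentration ratio R (> 1).
#' @param mode \code{"matched_voi"} uses the full 3-D sphere mask (required
#'   for dosimetry-matched VOIs); \code{"central_slice"} restricts the sphere
#'   sample to the axial slice through the sphere centroid, the convention
#'   used by several phantom studies and giving systematically higher values.
#' @return Q_H in percent.
#' @export
q_h <- function(img, sphere, background, true_ratio,
                mode = c("matched_voi", "central_slice")) {
  mode <- match.arg(mode)
  if (true_ratio <= 1) stop("true_ratio must be > 1")
  check_aligned(img, sphere)
  if (mode == "central_slice") {
    idx <- which(sphere$data, arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("empty mask")
    zc <- round(mean(idx[, 3]))
    keep <- array(FALSE, dim = dim(sphere$data))
    keep[, , zc] <- TRUE
    sphere <- voi_mask(sphere$data & keep, role = sphere$role,
                       label = sphere$label)
  }
  cs <- voi_stats(img, sphere)$mean
  cb <- voi_stats(img, background)$mean
  if (cb == 0) stop("background mean is zero")
  100 * (cs / cb - 1) / (true_ratio - 1)
}

#' Phantom-driven stopping rule for the deconvolution
#'
#' Returns the 1-based iteration index at which the contrast recovery
#' coefficient of the reference sphere attains its global maximum among
#' iterations where the RMSE between consecutive estimates declined relative
#' to the previous iteration.  Ties break toward the smaller index; if no
#' iteration satisfies the RMSE-decline condition the plain Q_H argmax is
#' returned.
#'
#' @param qh_trace per-iteration Q_H values.
#' @param rmse_trace per-iteration consecutive-estimate RMSE values (same
#'   length).
#' @return integer iteration index.
#' @export
select_iteration <- function(qh_trace, rmse_trace) {
  n <- length(qh_trace)
  if (n < 1L || length(rmse_trace) != n) stop("traces must be same length >= 1")
  declining <- which(c(FALSE, diff(rmse_trace) < 0))
  cand <- if (length(declining)) declining else seq_len(n)
  cand[which.max(qh_trace[cand])]
}

#' Run contrast recovery with quality traces and iteration selection
#'
#' Convenience driver: runs Richardson-Lucy deconvolution for
#' \code{max_iterations} updates, records the per-iteration Q_H of a
#' reference sphere (when reference VOIs are given) and the consecutive RMSE,
#' applies \code{\link{select_iteration}}, and returns the estimate at the
#' selected iteration.  When no reference VOIs are available (patient
#' studies) the stopping iteration must be supplied, typically the value
#' calibrated on a phantom.
#'
#' @param observed non-negative \code{voxel_grid} (cps).
#' @param psf a \code{psf_model}.
#' @param max_iterations maximum updates (default 15).
#' @param sphere,background reference VOIs for the Q_H trace, or NULL.
#' @param true_ratio true sphere:background concentration ratio.
#' @param fixed_iteration stopping iteration to use when no reference VOIs
#'   are given.
#' @return an object of class \code{recovery_result}: \code{final}
#'   (\code{voxel_grid}), \code{chosen_iteration}, \code{qh_trace},
#'   \code{rmse_trace}, \code{max_iterations}.
#' @export
recover_contrast <- function(observed, psf, max_iterations = 15,
                             sphere = NULL, background = NULL,
                             true_ratio = 13, fixed_iteration = 6) {
  have_ref <- !is.null(sphere) && !is.null(background)
  rl <- rl_deconvolve(observed, psf, max_iterations, keep = "all")
  qh_trace <- if (have_ref)
    vapply(rl$estimates, q_h, numeric(1), sphere = sphere,
           background = background, true_ratio = true_ratio)
  else NULL
  chosen <- if (have_ref) select_iteration(qh_trace, rl$rmse_trace)
            else min(fixed_iteration, max_iterations)
  structure(list(final = rl$estimates[[chosen]],
                 chosen_iteration = chosen,
                 qh_trace = qh_trace, rmse_trace = rl$rmse_trace,
                 max_iterations = max_iterations),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("<recovery_result> %d iterations run, iteration %d selected\n",
              x$max_iterations, x$chosen_iteration))
  if (!is.null(x$qh_trace))
    cat("  Q_H trace (%):", paste(sprintf("%.1f", x$qh_trace),
                                  collapse = " "), "\n")
  invisible(x)
}
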