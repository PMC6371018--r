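#' Joint intensity histogram of two aligned grids
#'
#' Linear binning over each image's own (min, max) range; voxels outside the
#' support are excluded.  A constant image (zero range) falls back to a
#' single bin on that axis.  The \code{"body"} support keeps voxels where
#' either image exceeds zero — near-empty air around the patient otherwise
#' dominates the histogram.
#'
#' @param a,b \code{voxel_grid}s of identical shape.
#' @param bins number of bins per image (>= 2).
#' @param support \code{"body"} (either image > 0) or \code{"all"}.
#' @return an object of class \code{joint_histogram}: \code{counts} (matrix,
#'   rows index a's bins), \code{bins}, \code{ranges}, \code{n} included
#'   voxels.
#' @export
joint_histogram <- function(a, b, bins = 64, support = c("body", "all")) {
  support <- match.arg(support)
  stopifnot(inherits(a, "voxel_grid"), inherits(b, "voxel_grid"))
  if (!identical(dim(a$data), dim(b$data))) stop("shape mismatch")
  if (bins < 2L) stop("bins must be >= 2")
  keep <- if (support == "body") (a$data > 0) | (b$data > 0)
          else array(TRUE, dim = dim(a$data))
  va <- a$data[keep]; vb <- b$data[keep]
  n <- length(va)
  if (n == 0L) stop("empty support")
  bin_of <- function(v) {
    rng <- range(v)
    if (rng[1] == rng[2]) return(list(idx = rep(1L, length(v)), nb = 1L,
                                      rng = rng))
    i <- pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * bins) + 1L, bins)
    list(idx = as.integer(i), nb = as.integer(bins), rng = rng)
  }
  ba <- bin_of(va); bb <- bin_of(vb)
  counts <- matrix(tabulate(ba$idx + ba$nb * (bb$idx - 1L),
                            nbins = ba$nb * bb$nb),
                   nrow = ba$nb, ncol = bb$nb)
  structure(list(counts = counts, bins = c(ba$nb, bb$nb),
                 ranges = list(a = ba$rng, b = bb$rng), n = n),
            class = "joint_histogram")
}

#' Shannon entropy of a histogram, in bits
#'
#' \code{H = -sum p log2 p} over nonzero cells; accepts a count vector,
#' matrix, or \code{joint_histogram}.
#'
#' @param counts nonnegative counts with positive total.
#' @export
shannon_entropy <- function(counts) {
  if (inherits(counts, "joint_histogram")) counts <- counts$counts
  counts <- as.numeric(counts)
  tot <- sum(counts)
  if (tot <= 0) stop("empty histogram")
  p <- counts[counts > 0] / tot
  -sum(p * log2(p))
}

#' Mutual information between two aligned grids
#'
#' \code{I(A, B) = H(A) + H(B) - H(A, B)} in bits, with all three entropies
#' computed from the same joint histogram so that \code{MI(a, a) = H(a)}
#' holds exactly.
#'
#' @inheritParams joint_histogram
#' @param candidate_label label carried through to selection reports.
#' @return an object of class \code{mi_result}: \code{mi_bits}, \code{h_a},
#'   \code{h_b}, \code{h_ab}, \code{candidate_label}.
#' @export
mutual_information <- function(a, b, bins = 64, support = c("body", "all"),
                               candidate_label = "") {
  jh <- joint_histogram(a, b, bins = bins, support = support)
  h_a <- shannon_entropy(rowSums(jh$counts))
  h_b <- shannon_entropy(colSums(jh$counts))
  h_ab <- shannon_entropy(jh$counts)
  structure(list(mi_bits = h_a + h_b - h_ab, h_a = h_a, h_b = h_b,
                 h_ab = h_ab, candidate_label = candidate_label),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("<mi_result>%s MI = %.4f bits (H_A %.3f, H_B %.3f, H_AB %.3f)\n",
              if (nzchar(x$candidate_label))
                paste0(" [", x$candidate_label, "]") else "",
              x$mi_bits, x$h_a, x$h_b, x$h_ab))
  invisible(x)
}

#' Select the best registration approach by mutual information
#'
#' Candidate co-registered image pairs (produced by external registration
#' tools) are compared by the mutual information between their members; the
#' candidate with the highest MI wins.  Ties break toward the earlier
#' candidate.
#'
#' @param candidates named list; each element a list with grids \code{a} and
#'   \code{b} already resampled to a common lattice.  At least 2 candidates.
#' @param bins,support passed to \code{\link{mutual_information}}.
#' @return list with \code{best} (winning label), \code{results} (named list
#'   of \code{mi_result}), \code{mi_bits} (named numeric).
#' @export
select_registration <- function(candidates, bins = 64,
                                support = c("body", "all")) {
  support <- match.arg(support)
  if (length(candidates) < 2L) stop("need >= 2 candidates")
  labels <- names(candidates)
  if (is.null(labels)) labels <- paste0("candidate_", seq_along(candidates))
  results <- lapply(seq_along(candidates), function(i)
    mutual_information(candidates[[i]]$a, candidates[[i]]$b, bins = bins,
                       support = support, candidate_label = labels[i]))
  names(results) <- labels
  mi <- vapply(results, function(r) r$mi_bits, numeric(1))
  list(best = labels[which.max(mi)], results = results, mi_bits = mi)
}

#' Translation-only registration by exhaustive MI search
#'
#' Searches integer voxel shifts in a cube of the given radius and returns
#' the shift maximizing the mutual information between \code{fixed} and the
#' shifted \code{moving} image, evaluated over the overlap region.  This is
#' deliberately minimal plumbing for closed-loop synthetic tests; full
#' spatial normalization is expected from external tools.
#'
#' @param moving,fixed \code{voxel_grid}s on the same lattice.
#' @param search_radius maximum |shift| per axis, voxels (>= 1).
#' @param bins histogram bins.
#' @param support \code{"body"} or \code{"all"}.
#' @return list with \code{shift} (integer length-3: the displacement
#'   applied to \code{moving}'s sampling, i.e. \code{moving[x + shift]} is
#'   compared with \code{fixed[x]}), \code{mi_bits} at the optimum.
#' @export
translate_register <- function(moving, fixed, search_radius = 3, bins = 64,
                               support = c("body", "all")) {
  support <- match.arg(support)
  stopifnot(inherits(moving, "voxel_grid"), inherits(fixed, "voxel_grid"))
  d <- dim(fixed$data)
  if (!identical(dim(moving$data), d)) stop("shape mismatch")
  r <- as.integer(search_radius)
  if (r < 1L) stop("search_radius must be >= 1")
  if (any(r >= d)) stop("search radius exceeds grid extent")
  grid_shifts <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  # visit small displacements first so ties resolve toward the identity
  grid_shifts <- grid_shifts[order(rowSums(abs(grid_shifts))), , drop = FALSE]
  best <- NULL
  for (row in seq_len(nrow(grid_shifts))) {
    s <- grid_shifts[row, ]
    sub <- lapply(1:3, function(ax) {
      lo <- max(1L, 1L - s[ax]); hi <- min(d[ax], d[ax] - s[ax])
      lo:hi
    })
    fsub <- fixed$data[sub[[1]], sub[[2]], sub[[3]], drop = FALSE]
    msub <- moving$data[sub[[1]] + s[1], sub[[2]] + s[2], sub[[3]] + s[3],
                        drop = FALSE]
    mi <- mutual_information(
      voxel_grid(fsub, spacing = fixed$spacing, units = fixed$units),
      voxel_grid(msub, spacing = moving$spacing, units = moving$units),
      bins = bins, support = support)$mi_bits
    if (is.null(best) || mi > best$mi_bits)
      best <- list(shift = unname(s), mi_bits = mi)
  }
  best
}
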