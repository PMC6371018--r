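# Internal numerical helpers shared across modules.

# Symmetric (reflective) padding of a 3-D array by integer radii r (length 3).
pad_reflect <- function(a, r) {
  d <- dim(a)
  idx <- lapply(1:3, function(ax) {
    n <- d[ax]; ri <- r[ax]
    if (ri == 0L) return(seq_len(n))
    if (ri > n) stop("padding radius exceeds array extent")
    c(ri:1, 1:n, n:(n - ri + 1))
  })
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# Linear convolution of a 3-D array with a small odd-sized kernel, reflective
# boundaries, computed as circular FFT convolution on the padded array.
# Kernels here are symmetric so convolution equals correlation.
conv3_reflect <- function(a, kernel) {
  # along singleton axes symmetric extension repeats the single value, so
  # convolving there reduces to collapsing the kernel by summation
  for (ax in which(dim(a) == 1L)) {
    if (dim(kernel)[ax] > 1L) {
      kernel <- array(apply(kernel, setdiff(1:3, ax), sum),
                      dim = replace(dim(kernel), ax, 1L))
    }
  }
  kd <- dim(kernel)
  if (any(kd %% 2L == 0L)) stop("kernel extents must be odd")
  r <- (kd - 1L) %/% 2L
  if (all(r == 0L)) return(a * kernel[1, 1, 1])
  ap <- pad_reflect(a, r)
  dp <- dim(ap)
  kp <- array(0, dim = dp)
  ix <- ((seq_len(kd[1]) - 1L - r[1]) %% dp[1]) + 1L
  iy <- ((seq_len(kd[2]) - 1L - r[2]) %% dp[2]) + 1L
  iz <- ((seq_len(kd[3]) - 1L - r[3]) %% dp[3]) + 1L
  kp[ix, iy, iz] <- kernel
  out <- Re(fft(fft(ap) * fft(kp), inverse = TRUE)) / prod(dp)
  out[r[1] + seq_len(dim(a)[1]), r[2] + seq_len(dim(a)[2]),
      r[3] + seq_len(dim(a)[3]), drop = FALSE]
}

# Shift a 3-D array by integer offsets, zero-filling vacated voxels:
# out[t] = a[t - s] where defined.
shift3 <- function(a, s) {
  d <- dim(a)
  out <- array(0, dim = d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    si <- s[ax]
    if (abs(si) >= d[ax]) return(out)
    if (si >= 0) { dst[[ax]] <- (1 + si):d[ax]; src[[ax]] <- 1:(d[ax] - si) }
    else { dst[[ax]] <- 1:(d[ax] + si); src[[ax]] <- (1 - si):d[ax] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Round half away from zero (report-table convention).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
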