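# Shared builders and independent oracles used across test files.

grid_of <- function(values, dim, spacing = c(4.664, 4.664, 4.664),
                    units = "cps") {
  voxel_grid(array(values, dim = dim), spacing = spacing, units = units)
}

mask_of <- function(logical_array, role = "body") {
  voi_mask(array(logical_array, dim = dim(logical_array)), role = role)
}

# a small, fast phantom: fewer voxels, three spheres, same concentrations
tiny_phantom <- function(supersampling = 4)
  jaszczak_phantom_spec(dim = c(40, 40, 28), supersampling = supersampling,
                        cylinder_radius = 60, cylinder_height = 100,
                        sphere_diameters = c(34, 16, 8), ring_radius = 32)

# a small paired liver study
tiny_liver_spec <- function(...)
  liver_study_spec(dim = c(40, 40, 30), ...)

# brute-force dose convolution (independent of the package engines)
brute_force_dose <- function(a, offsets, values) {
  d <- dim(a)
  out <- array(0, dim = d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    acc <- 0
    for (r in seq_len(nrow(offsets))) {
      sx <- x - offsets[r, 1]; sy <- y - offsets[r, 2]; sz <- z - offsets[r, 3]
      if (sx >= 1 && sx <= d[1] && sy >= 1 && sy <= d[2] &&
          sz >= 1 && sz <= d[3])
        acc <- acc + a[sx, sy, sz] * values[r]
    }
    out[x, y, z] <- acc
  }
  out
}

# independent 1-D convolution with symmetric (reflect) boundary
conv1_reflect <- function(v, k) {
  n <- length(v); m <- (length(k) - 1) / 2
  vp <- v[c(m:1, 1:n, n:(n - m + 1))]
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- sum(vp[i:(i + 2 * m)] * k)
  out
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

extdata <- function(f) system.file("extdata", f, package = "y90quant")

with_seed_helper <- function(seed, expr) {
  set.seed(seed)
  force(expr)
}
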