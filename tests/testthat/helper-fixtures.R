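# Shared fixture builders. Everything is generated in code at test time.

# Dose-like smooth 2-D field: a low base plus a few Gaussian blobs whose
# widths (>= 4 mm) mimic penumbra-scale dose modulation on a 1 mm grid.
dose_blob_field <- function(n, seed, spacing = 1, base = 2) {
  set.seed(seed)
  ax <- (0:(n - 1)) * spacing
  f <- matrix(base, n, n)
  for (b in 1:4) {
    cx <- runif(1, 0.2, 0.8) * max(ax)
    cy <- runif(1, 0.2, 0.8) * max(ax)
    s <- runif(1, 4, 8)
    amp <- runif(1, 5, 10)
    f <- f + amp * outer(exp(-(ax - cx)^2 / (2 * s^2)),
                         exp(-(ax - cy)^2 / (2 * s^2)))
  }
  f
}

# perturbed companion field: mostly a rescaled reference plus a little
# independent structure, the typical plan-vs-plan situation
dose_blob_pair <- function(n, seed, spacing = 1) {
  ref <- dose_blob_field(n, seed, spacing)
  ev <- dose_blob_field(n, seed + 5000, spacing) * 0.04 + ref * 0.97
  list(ref = ref, ev = ev)
}

# Scalar, deliberately plain point-in-polygon crossing counter (half-open
# edges, even-odd) used as the rasterization oracle.
brute_point_in_polygon <- function(x, y, vx, vy) {
  n <- length(vx)
  cnt <- 0L
  for (e in seq_len(n)) {
    x1 <- vx[e]; y1 <- vy[e]
    x2 <- vx[e %% n + 1L]; y2 <- vy[e %% n + 1L]
    if ((y1 > y) != (y2 > y)) {
      xi <- x1 + (y - y1) * (x2 - x1) / (y2 - y1)
      if (x < xi) cnt <- cnt + 1L
    }
  }
  cnt %% 2L == 1L
}

unit_grid <- function(shape = c(12, 12, 1), spacing = c(1, 1, 1),
                      origin = c(0, 0, 0)) {
  voxel_grid(origin = origin, spacing = spacing, shape = shape)
}

random_mask <- function(grid, p = 0.3, seed = 1) {
  set.seed(seed)
  binary_mask(array(runif(prod(grid$shape)) < p, dim = grid$shape), grid)
}

# the exhaustive gamma reference (dense search grid, sorted radii with the
# provably-safe early exit)
gamma_oracle <- function(ref, ev, spacing, dose_tol = 1, dta = 1,
                         threshold = 10, step = 0.01, radius = 5) {
  refmax <- max(ref)
  gasdose:::gamma_brute_cpp(ref, ev, spacing[1], spacing[2],
                            dose_tol / 100 * refmax,
                            threshold / 100 * refmax,
                            dta, step * dta, radius * dta)
}

oracle_gpr <- function(gmap) 100 * mean(gmap[!is.na(gmap)] <= 1 + 1e-9)
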