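# Independent oracles used across the suite. These deliberately avoid the
# package's own rasterization / counting code paths: areas come from exact
# polygon clipping, counts from explicit per-pixel loops.

# -- exact area of a rotated rectangle clipped to one pixel ------------------

# Sutherland-Hodgman clip of polygon (n x 2 matrix) against half-plane
# a*x + b*y <= c
clip_halfplane <- function(poly, a, b, c) {
  if (nrow(poly) == 0) return(poly)
  out <- matrix(numeric(0), ncol = 2)
  n <- nrow(poly)
  for (i in seq_len(n)) {
    p <- poly[i, ]; q <- poly[if (i == n) 1 else i + 1, ]
    dp <- a * p[1] + b * p[2] - c
    dq <- a * q[1] + b * q[2] - c
    if (dp <= 0) out <- rbind(out, p)
    if ((dp < 0) != (dq < 0)) {
      t <- dp / (dp - dq)
      out <- rbind(out, p + t * (q - p))
    }
  }
  out
}

shoelace_area <- function(poly) {
  if (is.null(nrow(poly)) || nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# exact fraction of pixel [x0,x0+s] x [y0,y0+s] covered by a rotated
# rectangle (centre cx,cy, half-sizes hx,hy, rotation theta deg)
exact_pixel_fraction <- function(x0, y0, s, cx, cy, hx, hy, theta_deg) {
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  corners <- t(R %*% t(matrix(c(-hx, -hy, hx, -hy, hx, hy, -hx, hy),
                              ncol = 2, byrow = TRUE))) +
    matrix(c(cx, cy), 4, 2, byrow = TRUE)
  poly <- corners
  poly <- clip_halfplane(poly, -1, 0, -x0)       # x >= x0
  poly <- clip_halfplane(poly, 1, 0, x0 + s)     # x <= x0+s
  poly <- clip_halfplane(poly, 0, -1, -y0)       # y >= y0
  poly <- clip_halfplane(poly, 0, 1, y0 + s)     # y <= y0+s
  shoelace_area(poly) / s^2
}

# -- brute-force overlap counting -------------------------------------------

# per-pixel loop implementation of the thresholded-average metrics
brute_force_overlap <- function(value_arrays, denom_array, t) {
  stopifnot(length(value_arrays) >= 1)
  dims <- dim(denom_array)
  n_over <- 0L; n_denom <- 0L
  for (k in seq_len(prod(dims))) {
    avg <- 0
    for (arr in value_arrays) avg <- avg + arr[k]
    avg <- avg / length(value_arrays)
    if (avg > t) n_over <- n_over + 1L
    if (denom_array[k] > t) n_denom <- n_denom + 1L
  }
  100 * n_over / n_denom
}

# -- toy masks ---------------------------------------------------------------

# wrap a bare value array as a voxel_mask on a unit grid (for metric tests)
toy_mask <- function(values, spacing = 0.5,
                     dims = NULL) {
  shape <- dim(values)
  spec_dims <- if (is.null(dims)) shape * spacing else dims
  spec <- voxplace::voxel_spec("toy", "toy", spec_dims,
                               shape * spacing / 2, c(0, 0, 0))
  structure(list(values = values,
                 grid = voxplace::vox_grid(shape, spacing, c(0, 0, 0)),
                 spec = spec),
            class = "voxel_mask")
}

# -- rigid ground-truth transforms ------------------------------------------

rigid_about <- function(angles_deg, translation, center) {
  R <- voxplace::rotation_from_angulation(angles_deg)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- center + translation - R %*% center
  voxplace::rigid_transform(matrix = m)
}

affine9_about <- function(angles_deg, scales, translation, center) {
  R <- voxplace::rotation_from_angulation(angles_deg)
  A <- R %*% diag(scales)
  m <- diag(4)
  m[1:3, 1:3] <- A
  m[1:3, 4] <- center + translation - A %*% center
  voxplace::affine_transform9(matrix = m)
}

# -- quick phantom profile ---------------------------------------------------

# small, fast phantom used throughout the suite: 48^3 at 4 mm (192 mm FOV)
quick_phantom <- function(seed = 1, shape = 48, spacing = 4,
                          noise_sigma = 0.02, head_scale = 1) {
  voxplace::make_phantom(shape = shape, spacing = spacing,
                         noise_sigma = noise_sigma, seed = seed,
                         head_scale = head_scale)
}

quick_control <- function() voxplace::reg_control()

table1_template_spec <- function(center = c(32, 25, 22.5)) {
  voxplace::voxel_spec("dlpfc_study", "l_dlpfc", c(15, 20, 15), center,
                       c(7.0, 20.0, 15.0))
}
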