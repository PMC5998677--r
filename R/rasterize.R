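# Partial-volume rasterization of a voxel prescription onto a regular grid.
#
# Grids use the half-open extent [origin, origin + shape * spacing); pixel
# (i, j, k) (0-based) covers [origin + i*spacing, origin + (i+1)*spacing)
# and has its centre at origin + (i + 0.5) * spacing.

#' Regular rasterization grid
#'
#' @param shape integer triple of grid dimensions.
#' @param spacing mm triple (or scalar) of pixel sizes; default 0.5 mm
#'   isotropic, the resolution at which overlap metrics are computed.
#' @param origin mm triple: the low corner of the grid extent.
#' @param orientation axis-order label carried through to outputs.
#' @return object of class `vox_grid`.
#' @export
vox_grid <- function(shape, spacing = 0.5, origin = c(0, 0, 0),
                     orientation = "LAS") {
  shape <- as.integer(shape)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(length(shape) == 3, length(spacing) == 3, length(origin) == 3,
            all(shape >= 1), all(spacing > 0), all(is.finite(origin)))
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), orientation = orientation),
            class = "vox_grid")
}

#' @export
print.vox_grid <- function(x, ...) {
  cat(sprintf("<vox_grid> %d x %d x %d @ (%g, %g, %g) mm, origin (%g, %g, %g)\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

grid_pixel_volume <- function(grid) prod(grid$spacing)

# world coordinates of pixel centres along one axis
grid_axis_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 0.5) * grid$spacing[axis]
}

#' Index -> world affine of a grid (pixel centres)
#'
#' NIfTI-style 4x4 affine mapping 0-based pixel indices to the world
#' coordinates of pixel centres.
#'
#' @param grid a [vox_grid()].
#' @export
grid_affine <- function(grid) {
  m <- diag(4)
  m[1:3, 1:3] <- diag(grid$spacing)
  m[1:3, 4] <- grid$origin + grid$spacing / 2
  m
}

#' Grid enclosing a voxel prescription
#'
#' Builds a 0.5 mm (by default) grid whose extent covers the rotated voxel
#' plus a margin. The origin is snapped down to an integer multiple of the
#' spacing so that grids built for different specs share one world lattice.
#'
#' @param spec a [voxel_spec()], or a list of specs to enclose jointly.
#' @param spacing pixel size in mm (scalar or triple).
#' @param margin mm of padding around the voxel corners.
#' @export
grid_for_spec <- function(spec, spacing = 0.5, margin = 2) {
  specs <- if (inherits(spec, "voxel_spec")) list(spec) else spec
  corners <- do.call(rbind, lapply(specs, voxel_corners))
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  lo <- apply(corners, 2, min) - margin
  hi <- apply(corners, 2, max) + margin
  origin <- floor(lo / spacing) * spacing
  shape <- ceiling((hi - origin) / spacing)
  vox_grid(shape, spacing, origin, orientation = specs[[1]]$orientation)
}

#' Rasterize a voxel prescription into a partial-volume mask
#'
#' Each pixel's value is the fraction of the pixel's volume inside the
#' rotated cuboid, estimated by regular subdivision supersampling
#' (`subdiv^3` subsamples per pixel). Pixels wholly inside get 1, wholly
#' outside 0; only the boundary shell is supersampled. A rotated voxel
#' therefore carries edge pixels with values strictly between 0 and 1 —
#' the partial-volume effect the overlap thresholding is designed around.
#'
#' @param spec a [voxel_spec()].
#' @param grid a [vox_grid()]; defaults to [grid_for_spec()] of `spec`.
#' @param subdiv subsamples per pixel edge (default 5).
#' @return object of class `voxel_mask`: list with `values` (3D array in
#'   [0,1]), `grid`, and `spec`.
#' @export
rasterize_voxel <- function(spec, grid = grid_for_spec(spec), subdiv = 5) {
  stopifnot(inherits(spec, "voxel_spec"), inherits(grid, "vox_grid"),
            subdiv >= 1)
  corners <- voxel_corners(spec)
  g_lo <- grid$origin
  g_hi <- grid$origin + grid$shape * grid$spacing
  tol <- 1e-9  # a voxel flush with the boundary is still fully captured
  bad <- which(apply(corners, 1, function(p)
    any(p < g_lo - tol) || any(p > g_hi + tol)))
  if (length(bad) > 0) {
    p <- corners[bad[1], ]
    stop(sprintf(paste0("voxel extends beyond grid extent: corner ",
                        "(%.2f, %.2f, %.2f) outside [%g, %g) x [%g, %g) x ",
                        "[%g, %g)"),
                 p[1], p[2], p[3], g_lo[1], g_hi[1], g_lo[2], g_hi[2],
                 g_lo[3], g_hi[3]), call. = FALSE)
  }

  R <- rotation_from_angulation(spec$angulation)
  h <- spec$dims / 2
  vals <- array(0, dim = grid$shape)

  # candidate pixels: bounding box of the corners, padded by one pixel
  lo_idx <- pmax(1L, floor((apply(corners, 2, min) - g_lo) / grid$spacing))
  hi_idx <- pmin(grid$shape, ceiling((apply(corners, 2, max) - g_lo) /
                                       grid$spacing) + 1L)
  ix <- lo_idx[1]:hi_idx[1]; iy <- lo_idx[2]:hi_idx[2]
  iz <- lo_idx[3]:hi_idx[3]
  cx <- g_lo[1] + (ix - 0.5) * grid$spacing[1]
  cy <- g_lo[2] + (iy - 0.5) * grid$spacing[2]
  cz <- g_lo[3] + (iz - 0.5) * grid$spacing[3]
  pts <- cbind(rep(cx, times = length(cy) * length(cz)),
               rep(rep(cy, each = length(cx)), times = length(cz)),
               rep(cz, each = length(cx) * length(cy)))
  # voxel-frame coordinates of pixel centres
  local <- (pts - matrix(spec$center, nrow(pts), 3, byrow = TRUE)) %*% R
  # any point of a pixel lies within r of its centre (rotation-invariant)
  r <- sqrt(sum((grid$spacing / 2)^2))
  excess <- sweep(abs(local), 2, h, "-")
  mx <- pmax(excess[, 1], pmax(excess[, 2], excess[, 3]))
  inside <- mx <= -r
  outside <- mx >= r
  border <- !inside & !outside

  frac <- numeric(nrow(pts))
  frac[inside] <- 1
  if (any(border)) {
    bpts <- pts[border, , drop = FALSE]
    off <- (seq_len(subdiv) - 0.5) / subdiv - 0.5
    grid_off <- as.matrix(expand.grid(x = off * grid$spacing[1],
                                      y = off * grid$spacing[2],
                                      z = off * grid$spacing[3]))
    cnt <- numeric(nrow(bpts))
    ctr <- matrix(spec$center, nrow(bpts), 3, byrow = TRUE)
    for (s in seq_len(nrow(grid_off))) {
      sl <- (bpts + matrix(grid_off[s, ], nrow(bpts), 3, byrow = TRUE) -
               ctr) %*% R
      cnt <- cnt + (abs(sl[, 1]) <= h[1] & abs(sl[, 2]) <= h[2] &
                      abs(sl[, 3]) <= h[3])
    }
    frac[border] <- cnt / nrow(grid_off)
  }
  vals[ix, iy, iz] <- array(frac, dim = c(length(ix), length(iy),
                                          length(iz)))
  structure(list(values = vals, grid = grid, spec = spec),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> %s/%s on %d x %d x %d grid, PV volume %.1f mm^3\n",
              x$spec$study, x$spec$description,
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              mask_volume(x)))
  invisible(x)
}

#' Partial-volume-weighted mask volume in mm^3
#' @param mask a `voxel_mask`.
#' @export
mask_volume <- function(mask) sum(mask$values) * grid_pixel_volume(mask$grid)

#' Default candidate threshold lattice
#'
#' Thresholds 0.05 to 0.95 in steps of 0.05, spanning the useful range for
#' superlevel binarization of a partial-volume mask.
#' @export
default_thresholds <- function() seq(0.05, 0.95, by = 0.05)

#' Threshold table for a partial-volume mask
#'
#' For each candidate threshold `t`, counts pixels with value strictly
#' greater than `t`, the corresponding volume, and that volume as a
#' percentage of the nominal (unrotated) voxel volume — the "Percent Total
#' Voxel" figure used to pick the working threshold.
#'
#' @param mask a `voxel_mask`.
#' @param thresholds fractions in (0, 1).
#' @return data.frame of class `threshold_table` with columns `threshold`,
#'   `pixel_count`, `volume_mm3`, `percent_total`.
#' @export
threshold_table <- function(mask, thresholds = default_thresholds()) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (length(thresholds) == 0)
    stop("'thresholds' must be a non-empty list of fractions", call. = FALSE)
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly inside (0, 1)", call. = FALSE)
  thresholds <- sort(thresholds)
  pv <- grid_pixel_volume(mask$grid)
  nom <- nominal_volume(mask$spec)
  cnt <- vapply(thresholds, function(t) sum(mask$values > t), numeric(1))
  out <- data.frame(threshold = thresholds, pixel_count = as.integer(cnt),
                    volume_mm3 = cnt * pv,
                    percent_total = 100 * cnt * pv / nom)
  class(out) <- c("threshold_table", "data.frame")
  attr(out, "nominal_volume") <- nom
  attr(out, "rotated") <- is_rotated(mask$spec)
  out
}

#' Select the working pixel-intensity threshold
#'
#' For a rotated voxel, picks the threshold whose Percent Total Voxel is
#' closest to, without exceeding, 100% of the unrotated voxel volume. For an
#' unrotated voxel every threshold gives exactly 100%, so the highest
#' candidate threshold (0.95) is used. If every row exceeds 100% the row
#' with the smallest percent is returned with a warning.
#'
#' @param table a [threshold_table()].
#' @param rotated logical; defaults to the rotation flag recorded on the
#'   table (all-zero angulation within 1e-6 deg counts as unrotated).
#' @return the selected threshold (scalar fraction).
#' @export
select_threshold <- function(table, rotated = attr(table, "rotated")) {
  stopifnot(inherits(table, "threshold_table"), nrow(table) > 0)
  if (is.null(rotated)) rotated <- TRUE
  if (!rotated) return(0.95)
  ok <- table$percent_total <= 100
  if (!any(ok)) {
    warning("no threshold yields Percent Total Voxel <= 100%; ",
            "returning the closest row", call. = FALSE)
    return(table$threshold[which.min(table$percent_total)])
  }
  cand <- table[ok, ]
  cand$threshold[which.max(cand$percent_total)]
}

#' Convert a voxel mask to a NIfTI-compatible image volume
#'
#' The mask is wrapped as an [image_volume()] whose affine places it in the
#' same world frame as the template image, so any NIfTI viewer can overlay
#' it on the anatomy.
#'
#' @param mask a `voxel_mask`.
#' @export
mask_as_image <- function(mask) {
  image_volume(mask$values, grid_affine(mask$grid),
               orientation = mask$grid$orientation)
}
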