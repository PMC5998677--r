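# Intensity-based volume registration: correlation-ratio cost, trilinear
# interpolation, multi-resolution schedule with a coarse rotation search
# followed by derivative-free refinement. Entirely deterministic.

#' 3D image volume
#'
#' A scalar intensity field together with its NIfTI-style index -> world
#' affine (0-based indices map to pixel-centre mm coordinates).
#'
#' @param data 3D numeric array.
#' @param affine 4x4 invertible index->world matrix.
#' @param orientation optional axis-order label; derived from the affine
#'   when omitted.
#' @return object of class `image_volume`.
#' @export
image_volume <- function(data, affine = diag(4), orientation = NULL) {
  if (length(dim(data)) != 3)
    stop("image data must be a 3D array", call. = FALSE)
  stopifnot(all(dim(affine) == c(4, 4)))
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("header affine is not invertible", call. = FALSE)
  if (!all(is.finite(data)))
    stop("image intensities must be finite", call. = FALSE)
  if (is.null(orientation)) orientation <- orientation_label(affine)
  structure(list(data = data, affine = unname(affine),
                 orientation = orientation),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  sp <- image_spacing(x)
  cat(sprintf("<image_volume> %d x %d x %d [%s], spacing %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], x$orientation, sp[1], sp[2], sp[3]))
  invisible(x)
}

image_spacing <- function(img) sqrt(colSums(img$affine[1:3, 1:3]^2))

#' World coordinate of the image-volume centre
#' @param img an [image_volume()].
#' @export
image_center <- function(img) {
  as.numeric(img$affine %*% c((dim(img$data) - 1) / 2, 1))[1:3]
}

# axis-order label ("LAS" etc.) from an index->world affine
orientation_label <- function(affine) {
  codes <- rbind(c("R", "L"), c("A", "P"), c("S", "I"))
  lab <- character(3)
  used <- integer(0)
  A <- affine[1:3, 1:3]
  for (j in 1:3) {
    v <- A[, j]
    ax <- setdiff(order(abs(v), decreasing = TRUE), used)[1]
    used <- c(used, ax)
    lab[j] <- if (v[ax] >= 0) codes[ax, 1] else codes[ax, 2]
  }
  paste(lab, collapse = "")
}

# ---- correlation ratio -----------------------------------------------------

#' Correlation ratio between two intensity samples
#'
#' Measures how well `b` is predicted by binned values of `a`:
#' `1 - sum_k n_k Var_k(b) / (N Var(b))` over equal-width bins of `a`.
#' Equals 1 when `b` is a deterministic function of `a`'s bin and is near 0
#' for independent samples.
#'
#' @param a,b numeric vectors of equal length (>= 2 * bins).
#' @param bins number of equal-width bins over the range of `a`.
#' @return similarity in [0, 1].
#' @export
correlation_ratio <- function(a, b, bins = 32) {
  stopifnot(length(a) == length(b), bins >= 2)
  if (length(a) < 2 * bins)
    stop("need at least 2 * bins samples", call. = FALSE)
  vb <- mean(b^2) - mean(b)^2
  if (vb <= 0) {
    warning("'b' has zero variance; correlation ratio defined as 0",
            call. = FALSE)
    return(0)
  }
  ra <- range(a)
  if (ra[1] == ra[2]) return(0)
  idx <- pmin(bins, pmax(1L, 1L + floor((a - ra[1]) / (ra[2] - ra[1]) * bins)))
  n_k <- tabulate(idx, nbins = bins)
  s_k <- rowsum_vec(b, idx, bins)
  s2_k <- rowsum_vec(b^2, idx, bins)
  nz <- n_k > 0
  within <- sum(s2_k[nz] - s_k[nz]^2 / n_k[nz])
  max(0, min(1, 1 - within / (length(b) * vb)))
}

rowsum_vec <- function(x, idx, nbins) {
  out <- numeric(nbins)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

# ---- trilinear interpolation ----------------------------------------------

# sample a 3D array at continuous 0-based indices (n x 3); outside -> 0
interp_trilinear <- function(data, idx) {
  d <- dim(data)
  x <- idx[, 1]; y <- idx[, 2]; z <- idx[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  inb <- x0 >= -1 & x0 <= d[1] - 1 & y0 >= -1 & y0 <= d[2] - 1 &
    z0 >= -1 & z0 <= d[3] - 1
  out <- numeric(nrow(idx))
  if (!any(inb)) return(out)
  x0 <- x0[inb]; y0 <- y0[inb]; z0 <- z0[inb]
  fx <- fx[inb]; fy <- fy[inb]; fz <- fz[inb]
  # zero-padded gather: out-of-range corners contribute 0
  gather <- function(i, j, k) {
    ok <- i >= 0 & i < d[1] & j >= 0 & j < d[2] & k >= 0 & k < d[3]
    v <- numeric(length(i))
    lin <- 1 + i[ok] + d[1] * (j[ok] + d[2] * k[ok])
    v[ok] <- data[lin]
    v
  }
  acc <- gather(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    gather(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    gather(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
    gather(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
    gather(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
    gather(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
    gather(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
    gather(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
  out[inb] <- acc
  out
}

# world coordinates of all pixel centres of an image/grid (n x 3)
volume_world_coords <- function(affine, shape, stride = 1L) {
  ix <- seq(0L, shape[1] - 1L, by = stride)
  iy <- seq(0L, shape[2] - 1L, by = stride)
  iz <- seq(0L, shape[3] - 1L, by = stride)
  idx <- cbind(rep(ix, times = length(iy) * length(iz)),
               rep(rep(iy, each = length(ix)), times = length(iz)),
               rep(iz, each = length(ix) * length(iy)))
  list(idx = idx,
       world = idx %*% t(affine[1:3, 1:3]) +
         matrix(affine[1:3, 4], nrow(idx), 3, byrow = TRUE),
       shape = c(length(ix), length(iy), length(iz)))
}

#' Resample an image through a spatial transform
#'
#' Pulls `img` back through transform `t` (moving-world to fixed-world)
#' onto `target`, with trilinear interpolation; locations outside the
#' source field of view are set to 0.
#'
#' @param img source [image_volume()].
#' @param t spatial transform or 4x4 matrix mapping `img`'s world frame
#'   into the target world frame; identity by default.
#' @param target a [vox_grid()] or [image_volume()] defining the output
#'   geometry.
#' @return an [image_volume()] on the target geometry.
#' @export
resample_trilinear <- function(img, t = diag(4), target) {
  stopifnot(inherits(img, "image_volume"))
  if (inherits(target, "vox_grid")) {
    t_aff <- grid_affine(target)
    shape <- target$shape
  } else if (inherits(target, "image_volume")) {
    t_aff <- target$affine
    shape <- dim(target$data)
  } else stop("'target' must be a vox_grid or image_volume", call. = FALSE)
  m <- as_transform_matrix(t)
  vc <- volume_world_coords(t_aff, shape)
  back <- solve(m)
  src_world <- vc$world %*% t(back[1:3, 1:3]) +
    matrix(back[1:3, 4], nrow(vc$world), 3, byrow = TRUE)
  inv_aff <- solve(img$affine)
  src_idx <- src_world %*% t(inv_aff[1:3, 1:3]) +
    matrix(inv_aff[1:3, 4], nrow(src_world), 3, byrow = TRUE)
  vals <- interp_trilinear(img$data, src_idx)
  image_volume(array(vals, dim = shape), t_aff,
               orientation = orientation_label(t_aff))
}

# ---- parameterized transforms ---------------------------------------------

# transform anchored at world point C:  x_fixed = C + R S (x_moving - C) + t
param_transform <- function(par, center, dof) {
  R <- rotation_from_angulation(par[1:3])
  s <- if (dof == 9) exp(par[7:9]) else c(1, 1, 1)
  A <- R %*% diag(s)
  m <- diag(4)
  m[1:3, 1:3] <- A
  m[1:3, 4] <- center + par[4:6] - A %*% center
  m
}

transform_from_params <- function(par, center, dof) {
  m <- param_transform(par, center, dof)
  if (dof == 6) rigid_transform(matrix = m) else affine_transform9(matrix = m)
}

#' Registration settings
#'
#' @param bins histogram bins for the correlation ratio.
#' @param levels pyramid downsampling factors, coarse to fine.
#' @param rot_search coarse per-axis rotation candidates (degrees) scanned
#'   at the coarsest level.
#' @param maxit Nelder-Mead iteration cap per level.
#' @param final_stride sampling stride at the finest level (cost is
#'   evaluated on every `final_stride`-th pixel).
#' @export
reg_control <- function(bins = 32, levels = c(4, 2), rot_search = seq(-30, 30, by = 15),
                        maxit = 150, final_stride = 2L) {
  list(bins = bins, levels = levels, rot_search = rot_search,
       maxit = maxit, final_stride = as.integer(final_stride))
}

# separable 1-2-1 smoothing (replicated edges); applied to both volumes
# before optimization so that the extra smoothing the moving image picks up
# from trilinear interpolation no longer biases the cost away from identity
smooth_121 <- function(arr) {
  d <- dim(arr)
  for (ax in 1:3) {
    lo <- c(1, seq_len(d[ax] - 1))
    hi <- c(seq_len(d[ax] - 1) + 1, d[ax])
    arr <- switch(ax,
                  (2 * arr + arr[lo, , , drop = FALSE] +
                     arr[hi, , , drop = FALSE]) / 4,
                  (2 * arr + arr[, lo, , drop = FALSE] +
                     arr[, hi, , drop = FALSE]) / 4,
                  (2 * arr + arr[, , lo, drop = FALSE] +
                     arr[, , hi, drop = FALSE]) / 4)
  }
  arr
}

# block-average downsample by integer factor, adjusting the affine
downsample_volume <- function(img, f) {
  if (f == 1) return(img)
  d <- dim(img$data)
  nd <- pmax(1L, d %/% f)
  a <- img$data[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f),
                drop = FALSE]
  a <- array(a, dim = c(f, nd[1], f, nd[2], f, nd[3]))
  sm <- apply(a, c(2, 4, 6), mean)
  aff <- img$affine
  naff <- aff
  naff[1:3, 1:3] <- aff[1:3, 1:3] * f
  naff[1:3, 4] <- aff[1:3, 4] + aff[1:3, 1:3] %*% rep((f - 1) / 2, 3)
  image_volume(sm, naff, orientation = img$orientation)
}

# cost = 1 - correlation ratio, computed on the fixed image's lattice
make_cost <- function(moving, fixed, center, dof, bins, stride = 1L) {
  vc <- volume_world_coords(fixed$affine, dim(fixed$data), stride)
  fvals <- if (stride == 1L) as.numeric(fixed$data) else
    as.numeric(fixed$data[seq(1L, dim(fixed$data)[1], by = stride),
                          seq(1L, dim(fixed$data)[2], by = stride),
                          seq(1L, dim(fixed$data)[3], by = stride)])
  inv_aff <- solve(moving$affine)
  fw <- vc$world
  # restrict the cost to the head plus a dilated background band: pure
  # background carries only noise (whose interpolation smoothing would bias
  # the optimum), but the band just outside the head must stay in the cost
  # or inflating the moving image's scale would go unpenalized
  keep <- array(fvals > 0.05 * max(fvals), dim = vc$shape)
  keep <- dilate_mask(keep, iters = 2L)
  keep <- as.vector(keep)
  if (sum(keep) >= 4 * bins) {
    fw <- fw[keep, , drop = FALSE]
    fvals <- fvals[keep]
  }
  function(par) {
    m <- param_transform(par, center, dof)
    back <- solve(m)
    src <- fw %*% t(back[1:3, 1:3]) +
      matrix(back[1:3, 4], nrow(fw), 3, byrow = TRUE)
    idx <- src %*% t(inv_aff[1:3, 1:3]) +
      matrix(inv_aff[1:3, 4], nrow(src), 3, byrow = TRUE)
    mv <- interp_trilinear(moving$data, idx)
    1 - correlation_ratio(fvals, mv, bins = bins)
  }
}

# binary dilation with an L-infinity ball of radius `iters`
dilate_mask <- function(m, iters = 1L) {
  d <- dim(m)
  for (i in seq_len(iters)) {
    lo1 <- c(1, seq_len(d[1] - 1)); hi1 <- c(seq_len(d[1] - 1) + 1, d[1])
    lo2 <- c(1, seq_len(d[2] - 1)); hi2 <- c(seq_len(d[2] - 1) + 1, d[2])
    lo3 <- c(1, seq_len(d[3] - 1)); hi3 <- c(seq_len(d[3] - 1) + 1, d[3])
    m <- m | m[lo1, , ] | m[hi1, , ] | m[, lo2, ] | m[, hi2, ] |
      m[, , lo3] | m[, , hi3]
  }
  m
}

# intensity centroid in world coordinates
intensity_centroid <- function(img) {
  vc <- volume_world_coords(img$affine, dim(img$data))
  w <- as.numeric(img$data)
  w <- pmax(w, 0)
  as.numeric(colSums(vc$world * w) / sum(w))
}

# intensity-weighted coordinate variances per axis (size estimate); with a
# rotation the coordinates are mapped into the rotated frame first, so the
# estimate is comparable across images in different orientations
intensity_axis_var <- function(img, rotation = NULL) {
  vc <- volume_world_coords(img$affine, dim(img$data))
  w <- pmax(as.numeric(img$data), 0)
  ctr <- colSums(vc$world * w) / sum(w)
  x <- sweep(vc$world, 2, ctr)
  if (!is.null(rotation)) x <- x %*% t(rotation)
  colSums(x^2 * w) / sum(w)
}

#' Register two image volumes
#'
#' Estimates the world-to-world transform mapping `moving` onto `fixed` by
#' maximizing the correlation ratio under trilinear interpolation. The
#' schedule is a multi-resolution pyramid: at the coarsest level the
#' translation is initialized from intensity centroids and a coarse
#' per-axis rotation grid is scanned; each level then refines all
#' parameters with Nelder-Mead. `dof = 6` estimates a rigid transform;
#' `dof = 9` adds anisotropic scales (positive, applied about the fixed
#' image's centre). The procedure has no stochastic steps: identical inputs
#' give identical transforms.
#'
#' @param moving,fixed [image_volume()] objects.
#' @param dof 6 (rigid) or 9 (rigid + scale).
#' @param control a [reg_control()] list.
#' @param init optional initial transform (e.g. a previous rigid fit used
#'   to warm-start a 9-dof fit).
#' @return a [rigid_transform()] or [affine_transform9()] mapping
#'   moving-world to fixed-world, with attributes `similarity` (final
#'   correlation ratio) and `converged`.
#' @export
register <- function(moving, fixed, dof = 6, control = reg_control(),
                     init = NULL) {
  stopifnot(inherits(moving, "image_volume"), inherits(fixed, "image_volume"),
            dof %in% c(6, 9))
  if (var(as.numeric(moving$data)) == 0 || var(as.numeric(fixed$data)) == 0)
    stop("degenerate input: constant-intensity image cannot be registered",
         call. = FALSE)
  center <- image_center(fixed)
  moving <- image_volume(smooth_121(moving$data), moving$affine,
                         moving$orientation)
  fixed <- image_volume(smooth_121(fixed$data), fixed$affine,
                        fixed$orientation)
  npar <- if (dof == 9) 9L else 6L
  par <- numeric(npar)

  if (is.null(init)) {
    par[4:6] <- intensity_centroid(fixed) - intensity_centroid(moving)
  } else {
    par <- params_from_transform(init, center, npar)
  }
  if (dof == 9 && all(abs(par[7:9]) < 1e-8)) {
    # moment-based anisotropic size estimate seeds the scale search; the
    # moving image's variances are taken in the frame already rotated by
    # the current rotation estimate so orientation does not leak into size
    R0 <- rotation_from_angulation(par[1:3])
    par[7:9] <- 0.5 * log(intensity_axis_var(fixed) /
                            intensity_axis_var(moving, rotation = R0))
  }

  levels <- sort(unique(c(control$levels, 1)), decreasing = TRUE)
  for (li in seq_along(levels)) {
    f <- levels[li]
    mv <- downsample_volume(moving, f)
    fx <- downsample_volume(fixed, f)
    stride <- if (f == 1) control$final_stride else 1L
    cost <- make_cost(mv, fx, center, dof, control$bins, stride)
    if (li == 1 && is.null(init)) {
      # coarse global orientation scan (per-axis and joint lattice)
      best <- cost(par); best_par <- par
      cand <- as.matrix(expand.grid(control$rot_search, control$rot_search,
                                    control$rot_search))
      for (i in seq_len(nrow(cand))) {
        p <- par; p[1:3] <- cand[i, ]
        v <- cost(p)
        if (v < best) { best <- v; best_par <- p }
      }
      par <- best_par
    }
    scale_par <- c(rep(5, 3), rep(5, 3), rep(0.05, npar - 6))
    fit <- optim(par, cost, method = "Nelder-Mead",
                 control = list(maxit = control$maxit, reltol = 1e-9,
                                parscale = scale_par))
    par <- fit$par
  }

  sim <- 1 - cost(par)
  sim0 <- 1 - cost(numeric(npar))
  out <- transform_from_params(par, center, dof)
  attr(out, "similarity") <- sim
  attr(out, "converged") <- TRUE
  if (sim < sim0 + 1e-6 && max(abs(par[1:6])) > 0.5) {
    warning("registration failed to improve over identity", call. = FALSE)
    attr(out, "converged") <- FALSE
  }
  attr(out, "params") <- par
  out
}

# recover the parameter vector of a transform anchored at `center`
params_from_transform <- function(t, center, npar) {
  m <- as_transform_matrix(t)
  A <- m[1:3, 1:3]
  s <- sqrt(colSums(A^2))
  R <- sweep(A, 2, s, "/")
  ang <- as.numeric(angulation_from_rotation(R))
  tr <- m[1:3, 4] - center + A %*% center
  par <- c(ang, as.numeric(tr))
  if (npar == 9) par <- c(par, log(s))
  par[seq_len(npar)]
}
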