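# Synthetic head phantom: nested ellipsoidal compartments (CSF shell, GM
# ribbon, WM core) with T1-like contrast, two asymmetric internal
# structures (a CSF "ventricle" and a deep-GM nodule) that anchor rotational
# alignment, soft compartment boundaries, and additive Gaussian noise.
# Partial-volume maps are built from the same geometry, so ground-truth
# tissue fractions are known by construction.

PHANTOM_INTENSITY <- c(wm = 1.0, gm = 0.7, csf = 0.3)

# clamped linear step: 0 below -w/2, 1 above +w/2
softstep <- function(x, w) pmin(pmax(x / w + 0.5, 0), 1)

#' Generate a synthetic head phantom
#'
#' Builds a T1-like head volume of nested ellipsoids — an outer CSF shell,
#' a GM ribbon and a WM core — plus two asymmetric internal structures (an
#' off-centre CSF ventricle and a deep grey-matter nodule) that break the
#' ellipsoids' rotational symmetry so that orientation is identifiable by
#' registration. Compartment boundaries are softened over roughly one pixel
#' and per-tissue partial-volume (PVE) maps are produced from the same
#' geometry, so the tissue composition of any region is known analytically.
#' WM, GM and CSF mean intensities are 1.0, 0.7 and 0.3 (T1-like contrast);
#' noise is additive Gaussian.
#'
#' @param shape grid dimensions (triple or scalar); default 128^3.
#' @param spacing pixel size in mm; default 1.5 mm isotropic.
#' @param noise_sigma Gaussian noise SD in units of the WM intensity;
#'   default 0.02 (2% of WM).
#' @param seed integer seed; identical seeds give bit-identical phantoms.
#' @param head_scale multiplier on the head semi-axes relative to the field
#'   of view; values below 1 leave headroom for large repositioning
#'   transforms.
#' @return list with `image` (an [image_volume()]) and `pve` (named list of
#'   `gm`, `wm`, `csf` [image_volume()] maps).
#' @export
make_phantom <- function(shape = c(128, 128, 128), spacing = 1.5,
                         noise_sigma = 0.02, seed = 1, head_scale = 1) {
  if (length(shape) == 1) shape <- rep(shape, 3)
  shape <- as.integer(shape)
  if (any(shape < 8)) stop("degenerate phantom shape", call. = FALSE)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(all(spacing > 0), noise_sigma >= 0)

  fov <- shape * spacing
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- -fov / 2 + spacing / 2  # centred world frame, LAS-like axes
  ctr <- c(0, 0, 0)

  # head semi-axes: an adult-head-like triaxial ellipsoid inside the FOV
  semi <- c(0.36, 0.44, 0.40) * fov * head_scale
  x <- (seq_len(shape[1]) - 1) * spacing[1] + aff[1, 4]
  y <- (seq_len(shape[2]) - 1) * spacing[2] + aff[2, 4]
  z <- (seq_len(shape[3]) - 1) * spacing[3] + aff[3, 4]
  X <- array(rep(x, times = shape[2] * shape[3]), dim = shape)
  Y <- array(rep(rep(y, each = shape[1]), times = shape[3]), dim = shape)
  Z <- array(rep(z, each = shape[1] * shape[2]), dim = shape)

  rho <- sqrt(((X - ctr[1]) / semi[1])^2 + ((Y - ctr[2]) / semi[2])^2 +
                ((Z - ctr[3]) / semi[3])^2)
  # normalized boundary radii: WM core, GM ribbon, CSF shell
  r_wm <- 0.78; r_gm <- 0.92; r_head <- 1.0
  w <- 1.2 * mean(spacing) / mean(semi)  # ~one-pixel soft edge

  in_head <- softstep(r_head - rho, w)
  in_gm_out <- softstep(r_gm - rho, w)
  in_wm <- softstep(r_wm - rho, w)
  pve_wm <- in_wm
  pve_gm <- in_gm_out - in_wm
  pve_csf <- in_head - in_gm_out

  # asymmetric internal structures (positions in head-normalized units)
  blob <- function(center_n, semi_mm) {
    cb <- center_n * semi
    sqrt(((X - cb[1]) / semi_mm[1])^2 + ((Y - cb[2]) / semi_mm[2])^2 +
           ((Z - cb[3]) / semi_mm[3])^2)
  }
  wb <- 1.2 * mean(spacing) / 12
  vent <- softstep(1 - blob(c(0.18, 0.22, 0.05), c(10, 22, 12)), wb)
  nodule <- softstep(1 - blob(c(-0.28, -0.18, -0.15), c(12, 10, 14)), wb)
  # reassign WM mass to CSF (ventricle) then to GM (nodule)
  pve_csf <- pve_csf + vent * pve_wm
  pve_wm <- pve_wm * (1 - vent)
  pve_gm <- pve_gm + nodule * pve_wm
  pve_wm <- pve_wm * (1 - nodule)

  img <- PHANTOM_INTENSITY["wm"] * pve_wm + PHANTOM_INTENSITY["gm"] * pve_gm +
    PHANTOM_INTENSITY["csf"] * pve_csf
  if (noise_sigma > 0) {
    set.seed(as.integer(seed))
    img <- img + array(rnorm(prod(shape), sd = noise_sigma), dim = shape)
  }
  list(image = image_volume(unname(img), aff, orientation = "LAS"),
       pve = list(gm = image_volume(unname(pve_gm), aff),
                  wm = image_volume(unname(pve_wm), aff),
                  csf = image_volume(unname(pve_csf), aff)))
}

#' Simulate a repositioned "subject" scan from a phantom
#'
#' Resamples the template phantom through a known rigid (or rotation+scale)
#' transform with trilinear interpolation and adds a fresh noise
#' realization, emulating a subject whose head sits in a different position
#' in the scanner. The supplied transform maps template-world anatomy to
#' subject-world locations and is returned as the ground truth.
#'
#' @param template an [image_volume()] (typically `make_phantom()$image`).
#' @param transform a [rigid_transform()] or [affine_transform9()].
#' @param noise_sigma Gaussian noise SD (WM-intensity units).
#' @param seed integer seed for the noise realization.
#' @return list with `image` (the subject [image_volume()], on the template
#'   grid) and `ground_truth` (the input transform).
#' @export
perturb_subject <- function(template, transform, noise_sigma = 0.02,
                            seed = 1) {
  stopifnot(inherits(template, "image_volume"))
  out <- resample_trilinear(template, transform, target = template)
  # estimate how much head mass the move pushed out of the field of view
  # (thresholded so rectified background noise does not count as mass)
  mass_in <- sum(out$data[out$data > 0.1])
  mass_tot <- sum(template$data[template$data > 0.1])
  clipped <- 1 - mass_in / mass_tot
  if (clipped > 0.02)
    warning(sprintf("head clipped by field of view: ~%.1f%% of intensity mass lost",
                    100 * clipped), call. = FALSE)
  if (noise_sigma > 0) {
    set.seed(as.integer(seed))
    out$data <- out$data + array(rnorm(length(out$data), sd = noise_sigma),
                                 dim = dim(out$data))
  }
  list(image = out, ground_truth = transform)
}

#' Generate a multi-subject phantom study
#'
#' Draws per-subject rigid ground-truth transforms uniformly within the
#' stated ranges (about the template-volume centre) and produces one
#' perturbed subject image per subject and timepoint, each with an
#' independent noise realization. With `max_scale > 0`, per-axis scales are
#' drawn too and the transforms are 9-dof.
#'
#' @param n_subjects number of subjects.
#' @param timepoints timepoint labels (each subject is re-perturbed
#'   slightly per timepoint to emulate repositioning between visits).
#' @param shape,spacing,noise_sigma passed to [make_phantom()].
#' @param max_translation,max_rotation per-axis ranges (+-mm, +-deg) for
#'   subject poses.
#' @param reposition_sd SD (mm / deg) of the small between-visit
#'   repositioning jitter.
#' @param max_scale per-axis log-scale half-range (0 for rigid subjects).
#' @param seed integer seed; the whole study is reproducible from it.
#' @param head_scale passed to [make_phantom()].
#' @return list with `template`, `pve`, and `subjects` — a list of records
#'   `(subject_id, timepoint, image, ground_truth)`.
#' @export
make_phantom_study <- function(n_subjects = 4, timepoints = "baseline",
                               shape = c(128, 128, 128), spacing = 1.5,
                               noise_sigma = 0.02, max_translation = 15,
                               max_rotation = 15, reposition_sd = 1,
                               max_scale = 0, seed = 1, head_scale = 1) {
  ph <- make_phantom(shape, spacing, noise_sigma, seed = seed,
                     head_scale = head_scale)
  ctr <- image_center(ph$image)
  set.seed(as.integer(seed) + 1L)
  subjects <- list()
  for (s in seq_len(n_subjects)) {
    base_t <- runif(3, -max_translation, max_translation)
    base_r <- runif(3, -max_rotation, max_rotation)
    base_s <- if (max_scale > 0) exp(runif(3, -max_scale, max_scale)) else
      c(1, 1, 1)
    for (tp in timepoints) {
      jt <- if (tp == timepoints[1]) c(0, 0, 0) else rnorm(3, sd = reposition_sd)
      jr <- if (tp == timepoints[1]) c(0, 0, 0) else rnorm(3, sd = reposition_sd)
      R <- rotation_from_angulation(base_r + jr)
      A <- R %*% diag(base_s)
      m <- diag(4)
      m[1:3, 1:3] <- A
      m[1:3, 4] <- ctr + base_t + jt - A %*% ctr
      gt <- if (max_scale > 0) affine_transform9(matrix = m) else
        rigid_transform(matrix = m)
      sub <- perturb_subject(ph$image, gt, noise_sigma = noise_sigma,
                             seed = as.integer(seed) + 100L * s +
                               match(tp, timepoints))
      subjects[[length(subjects) + 1]] <-
        list(subject_id = sprintf("sub%02d", s), timepoint = tp,
             image = sub$image, ground_truth = gt)
    }
  }
  list(template = ph$image, pve = ph$pve, subjects = subjects, seed = seed)
}
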