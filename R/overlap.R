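# Post-hoc voxel placement quantification: acquired voxels are
# reconstructed in template space (mirroring the prescription procedure,
# run in reverse) and compared by thresholded-average overlap.

#' Acquired MRS voxel
#'
#' The voxel geometry actually used at acquisition, read from the
#' spectroscopy DICOM header or a JSON sidecar — deliberately distinct from
#' a `prescription`, so that overlap is always computed from the region the
#' spectra came from, never from the prescription pipeline's own matrices.
#'
#' @param subject_id subject identifier.
#' @param timepoint timepoint label (e.g. `"baseline"`).
#' @param spec the acquired [voxel_spec()], in the subject frame.
#' @param subject_image optional subject [image_volume()] (needed for
#'   reconstruction in template space).
#' @param source `"dicom"` or `"manual"`.
#' @return object of class `acquired_voxel`.
#' @export
acquired_voxel <- function(subject_id, timepoint, spec,
                           subject_image = NULL, source = "manual") {
  stopifnot(inherits(spec, "voxel_spec"))
  structure(list(subject_id = as.character(subject_id),
                 timepoint = as.character(timepoint), spec = spec,
                 subject_image = subject_image, source = source),
            class = "acquired_voxel")
}

#' Reconstruct an acquired voxel in template space
#'
#' Mirrors the prescription procedure in reverse: a rigid 6-dof
#' subject-to-template registration supplies the rotation composed with the
#' acquired angulation, a 9-dof registration maps the centre coordinate
#' (calibrating for anatomical size differences), and the voxel is
#' re-rasterized in template space with its original dimensions — never
#' scaled.
#'
#' @param av an [acquired_voxel()] with `subject_image` set.
#' @param template the template [image_volume()].
#' @param grid optional template-space [vox_grid()] for rasterization.
#' @param control a [reg_control()].
#' @param transforms optional precomputed `list(rigid =, affine9 =)`
#'   subject-to-template transforms (skips registration; used when several
#'   acquisitions share one subject image).
#' @param backend registration backend (see [prescribe_voxel()]).
#' @return a `voxel_mask` in template space; the mapped spec is available
#'   as `$spec`, and the transforms as attribute `transforms`.
#' @export
reconstruct_in_template <- function(av, template, grid = NULL,
                                    control = reg_control(),
                                    transforms = NULL, backend = register) {
  stopifnot(inherits(av, "acquired_voxel"))
  if (is.null(transforms)) {
    if (is.null(av$subject_image))
      stop("subject ", av$subject_id, "/", av$timepoint,
           ": no subject image available for reconstruction", call. = FALSE)
    transforms <- tryCatch({
      reg6 <- backend(av$subject_image, template, dof = 6,
                      control = control)
      reg9 <- backend(av$subject_image, template, dof = 9,
                      control = control, init = reg6)
      list(rigid = reg6, affine9 = reg9)
    }, error = function(e)
      stop("registration failed for ", av$subject_id, "/", av$timepoint,
           ": ", conditionMessage(e), call. = FALSE))
  }
  mapped <- map_spec_through(av$spec, transforms$rigid, transforms$affine9)
  spec_t <- mapped$spec
  if (is.null(grid)) grid <- grid_for_spec(spec_t)
  mask <- rasterize_voxel(spec_t, grid)
  attr(mask, "transforms") <- transforms
  mask
}

count_above <- function(mask, t) sum(mask$values > t)

check_same_grid <- function(...) {
  grids <- lapply(list(...), function(m) m$grid)
  g0 <- grids[[1]]
  for (g in grids[-1])
    if (!isTRUE(all.equal(g0$shape, g$shape)) ||
        !isTRUE(all.equal(g0$origin, g$origin)) ||
        !isTRUE(all.equal(g0$spacing, g$spacing)))
      stop("masks are not on the same grid", call. = FALSE)
  invisible(TRUE)
}

#' Voxel placement accuracy
#'
#' Percentage 3D geometric overlap of one subject voxel with the template
#' voxel: the two binarized (partial-volume) masks are summed, the per-pixel
#' average taken, and the count of averaged pixels above the threshold is
#' divided by the count of template-voxel pixels above the same threshold.
#'
#' @param subject_mask,template_mask `voxel_mask` objects on one grid.
#' @param t the selected pixel-intensity threshold.
#' @return overlap percentage.
#' @export
accuracy <- function(subject_mask, template_mask, t) {
  check_same_grid(subject_mask, template_mask)
  denom <- count_above(template_mask, t)
  if (denom == 0)
    stop("template mask has no pixels above threshold ", t, call. = FALSE)
  avg <- (subject_mask$values + template_mask$values) / 2
  100 * sum(avg > t) / denom
}

#' Between-subject voxel overlap
#'
#' All subject voxels at one timepoint are summed in template space, the
#' per-pixel average taken, and the averaged pixels above the threshold are
#' counted against the template-voxel pixel count (template voxel in
#' isolation). The template voxel itself does not enter the average.
#'
#' @param masks list of subject `voxel_mask` objects (one timepoint).
#' @param template_mask the template `voxel_mask` (denominator only).
#' @param t the selected threshold.
#' @return overlap percentage.
#' @export
between_subject_overlap <- function(masks, template_mask, t) {
  if (length(masks) < 1) stop("need at least one subject mask", call. = FALSE)
  do.call(check_same_grid, c(masks, list(template_mask)))
  denom <- count_above(template_mask, t)
  if (denom == 0)
    stop("template mask has no pixels above threshold ", t, call. = FALSE)
  avg <- Reduce(`+`, lapply(masks, function(m) m$values)) / length(masks)
  100 * sum(avg > t) / denom
}

#' Within-subject voxel overlap
#'
#' One subject's voxels across timepoints are summed, averaged and
#' thresholded; the count is divided by the denominator mask's count above
#' the same threshold (the template voxel by default, for the same
#' denominator semantics as the other metrics).
#'
#' @param masks_by_timepoint list of the subject's `voxel_mask`s, one per
#'   timepoint (>= 2).
#' @param denominator_mask mask supplying the denominator pixel count.
#' @param t the selected threshold.
#' @return overlap percentage.
#' @export
within_subject_overlap <- function(masks_by_timepoint, denominator_mask, t) {
  if (length(masks_by_timepoint) < 2)
    stop("within-subject overlap needs at least 2 timepoints", call. = FALSE)
  do.call(check_same_grid, c(masks_by_timepoint, list(denominator_mask)))
  denom <- count_above(denominator_mask, t)
  if (denom == 0)
    stop("denominator mask has no pixels above threshold ", t, call. = FALSE)
  avg <- Reduce(`+`, lapply(masks_by_timepoint, function(m) m$values)) /
    length(masks_by_timepoint)
  100 * sum(avg > t) / denom
}

#' Coefficient of variation (percent)
#'
#' `100 * sd(values) / mean(values)` with the sample (n - 1) standard
#' deviation.
#'
#' @param values numeric vector of length >= 2 with nonzero mean.
#' @export
cv_percent <- function(values) {
  if (length(values) < 2)
    stop("CV% needs at least two values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("CV% undefined: mean is zero", call. = FALSE)
  100 * sd(values) / m
}

#' Tissue composition of a thresholded voxel
#'
#' Sums each tissue's partial-volume map over the pixels of the thresholded
#' voxel mask and expresses each tissue as a percentage of the total tissue
#' mass inside the voxel. PVE maps are resampled onto the mask grid by
#' trilinear interpolation first.
#'
#' @param pve named list of `gm`, `wm`, `csf` [image_volume()] maps.
#' @param mask a `voxel_mask`.
#' @param t the selected threshold.
#' @return named numeric `(gm, wm, csf)` percentages summing to 100.
#' @export
tissue_fractions <- function(pve, mask, t) {
  stopifnot(all(c("gm", "wm", "csf") %in% names(pve)))
  sel <- mask$values > t
  if (!any(sel))
    stop("thresholded mask is empty at threshold ", t, call. = FALSE)
  sums <- vapply(c("gm", "wm", "csf"), function(tc) {
    res <- resample_trilinear(pve[[tc]], diag(4), target = mask$grid)
    sum(res$data[sel])
  }, numeric(1))
  100 * sums / sum(sums)
}

# ---- pipeline --------------------------------------------------------------

#' Full overlap evaluation of a set of acquired voxels
#'
#' The complete post-hoc pipeline: each acquired voxel is reconstructed in
#' template space (two registrations per acquisition), all masks are
#' rasterized on one shared 0.5 mm template-space grid, the threshold table
#' of the template voxel is computed and the working threshold selected,
#' and accuracy (per subject), between-subject overlap (per timepoint),
#' within-subject overlap (per subject across timepoints, with group mean
#' and CV%) and tissue composition are calculated.
#'
#' @param template the template [image_volume()].
#' @param template_spec the template [voxel_spec()].
#' @param acquisitions list of [acquired_voxel()] objects with subject
#'   images attached.
#' @param pve optional tissue maps: either one named `gm`/`wm`/`csf` list
#'   applied to all subjects (template-space maps) or a list keyed by
#'   subject id.
#' @param thresholds candidate threshold lattice.
#' @param spacing grid spacing in mm (default 0.5).
#' @param control a [reg_control()].
#' @param threshold optional fixed threshold overriding selection.
#' @param within_denominator `"template"` (default) to count within-subject
#'   overlap against the template voxel, or `"first_timepoint"` to use the
#'   subject's first-timepoint voxel.
#' @param backend registration backend (see [prescribe_voxel()]).
#' @return object of class `overlap_report`.
#' @export
avp_overlap <- function(template, template_spec, acquisitions, pve = NULL,
                        thresholds = default_thresholds(), spacing = 0.5,
                        control = reg_control(), threshold = NULL,
                        within_denominator = c("template",
                                               "first_timepoint"),
                        backend = register) {
  within_denominator <- match.arg(within_denominator)
  stopifnot(inherits(template_spec, "voxel_spec"), length(acquisitions) >= 1)

  dims0 <- acquisitions[[1]]$spec$dims
  for (av in acquisitions)
    if (!isTRUE(all.equal(av$spec$dims, dims0)))
      warning("acquired voxel dims differ across acquisitions (",
              av$subject_id, "/", av$timepoint, ")", call. = FALSE)

  # registrations are per subject image; map the specs first
  mapped <- list()
  reg_cache <- list()
  for (av in acquisitions) {
    key <- av$subject_id
    tr <- reg_cache[[key]]
    if (is.null(tr) || !identical(attr(tr, "timepoint"), av$timepoint)) {
      reg6 <- backend(av$subject_image, template, dof = 6, control = control)
      reg9 <- backend(av$subject_image, template, dof = 9, control = control,
                      init = reg6)
      tr <- list(rigid = reg6, affine9 = reg9)
      attr(tr, "timepoint") <- av$timepoint
      reg_cache[[key]] <- tr
    }
    mapped[[length(mapped) + 1]] <-
      list(av = av, spec = map_spec_through(av$spec, tr$rigid,
                                            tr$affine9)$spec,
           transforms = tr)
  }

  all_specs <- c(list(template_spec), lapply(mapped, `[[`, "spec"))
  grid <- grid_for_spec(all_specs, spacing = spacing)
  template_mask <- rasterize_voxel(template_spec, grid)
  tab <- threshold_table(template_mask, thresholds)
  sel <- if (is.null(threshold)) select_threshold(tab) else threshold

  masks <- lapply(mapped, function(m) {
    msk <- rasterize_voxel(m$spec, grid)
    attr(msk, "transforms") <- m$transforms
    msk
  })
  ids <- vapply(mapped, function(m) m$av$subject_id, character(1))
  tps <- vapply(mapped, function(m) m$av$timepoint, character(1))

  acc <- data.frame(subject = ids, timepoint = tps,
                    accuracy = vapply(masks, accuracy, numeric(1),
                                      template_mask = template_mask, t = sel),
                    stringsAsFactors = FALSE)
  acc_summary <- do.call(rbind, lapply(split(acc, acc$timepoint), function(d)
    data.frame(timepoint = d$timepoint[1], mean = mean(d$accuracy),
               sd = if (nrow(d) > 1) sd(d$accuracy) else NA_real_,
               n = nrow(d))))

  between <- vapply(split(seq_along(masks), tps), function(ii)
    between_subject_overlap(masks[ii], template_mask, sel), numeric(1))
  mean_masks <- lapply(split(seq_along(masks), tps), function(ii) {
    m <- masks[[ii[1]]]
    m$values <- Reduce(`+`, lapply(masks[ii], function(x) x$values)) /
      length(ii)
    m
  })

  within <- NULL
  for (sid in unique(ids)) {
    ii <- which(ids == sid)
    if (length(unique(tps[ii])) < 2) next
    denom <- if (within_denominator == "template") template_mask else
      masks[[ii[order(tps[ii])][1]]]
    within <- rbind(within, data.frame(
      subject = sid,
      overlap = within_subject_overlap(masks[ii], denom, sel),
      stringsAsFactors = FALSE))
  }
  within_summary <- if (!is.null(within) && nrow(within) >= 2)
    c(mean = mean(within$overlap), cv = cv_percent(within$overlap))
  else if (!is.null(within))
    c(mean = mean(within$overlap), cv = NA_real_)
  else NULL

  tissue <- NULL
  if (!is.null(pve)) {
    per_subject <- !all(c("gm", "wm", "csf") %in% names(pve))
    for (k in seq_along(masks)) {
      maps <- if (per_subject) pve[[ids[k]]] else pve
      if (is.null(maps)) next
      fr <- tissue_fractions(maps, masks[[k]], sel)
      tissue <- rbind(tissue, data.frame(
        subject = ids[k], timepoint = tps[k],
        gm = fr[["gm"]], wm = fr[["wm"]], csf = fr[["csf"]],
        stringsAsFactors = FALSE))
    }
  }

  structure(list(threshold_table = tab, selected_threshold = sel,
                 accuracy = acc, accuracy_summary = acc_summary,
                 between_subject = between, within_subject = within,
                 within_subject_summary = within_summary,
                 tissue_fractions = tissue, template_mask = template_mask,
                 subject_masks = masks, mean_masks = mean_masks,
                 grid = grid),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> threshold %.2f (Percent Total Voxel %.1f%%)\n",
              x$selected_threshold,
              x$threshold_table$percent_total[
                x$threshold_table$threshold == x$selected_threshold]))
  for (i in seq_len(nrow(x$accuracy_summary))) {
    r <- x$accuracy_summary[i, ]
    cat(sprintf("  accuracy [%s]: %.1f%% +/- %s (n = %d)\n", r$timepoint,
                r$mean, ifelse(is.na(r$sd), "NA", sprintf("%.1f%%", r$sd)),
                r$n))
  }
  for (tp in names(x$between_subject))
    cat(sprintf("  between-subject [%s]: %.1f%%\n", tp,
                x$between_subject[[tp]]))
  if (!is.null(x$within_subject_summary))
    cat(sprintf("  within-subject: %.1f%% (CV%% = %.2f%%)\n",
                x$within_subject_summary[["mean"]],
                x$within_subject_summary[["cv"]]))
  invisible(x)
}

#' Write the overlap summary file
#'
#' Tab-separated `Overlap_Summary.txt` with `#` section headers: the
#' threshold table (Percent Total Voxel), per-subject accuracy,
#' between-subject overlap per timepoint, within-subject overlap with group
#' mean and CV%, and tissue fractions.
#'
#' @param report an `overlap_report`.
#' @param path output path.
#' @export
write_overlap_summary <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# Overlap_Summary")
  wl(sprintf("# selected_threshold\t%.2f", report$selected_threshold))
  wl("# [1] threshold table")
  wl("Threshold\tPixelCount\tVolume_mm3\tPercent Total Voxel")
  tt <- report$threshold_table
  for (i in seq_len(nrow(tt)))
    wl(sprintf("%.2f\t%d\t%.3f\t%.3f", tt$threshold[i], tt$pixel_count[i],
               tt$volume_mm3[i], tt$percent_total[i]))
  wl("# [2] accuracy (subject voxel vs template voxel)")
  wl("Subject\tTimepoint\tAccuracy_pct")
  a <- report$accuracy
  for (i in seq_len(nrow(a)))
    wl(sprintf("%s\t%s\t%.3f", a$subject[i], a$timepoint[i], a$accuracy[i]))
  wl("# [3] between-subject overlap per timepoint")
  wl("Timepoint\tOverlap_pct")
  for (tp in names(report$between_subject))
    wl(sprintf("%s\t%.3f", tp, report$between_subject[[tp]]))
  wl("# [4] within-subject overlap")
  wl("Subject\tOverlap_pct")
  if (!is.null(report$within_subject)) {
    w <- report$within_subject
    for (i in seq_len(nrow(w)))
      wl(sprintf("%s\t%.3f", w$subject[i], w$overlap[i]))
    if (!is.null(report$within_subject_summary)) {
      wl(sprintf("GroupMean\t%.3f", report$within_subject_summary[["mean"]]))
      wl(sprintf("CV_pct\t%.3f", report$within_subject_summary[["cv"]]))
    }
  }
  wl("# [5] tissue fractions (% of voxel)")
  wl("Subject\tTimepoint\tGM_pct\tWM_pct\tCSF_pct")
  if (!is.null(report$tissue_fractions)) {
    tf <- report$tissue_fractions
    for (i in seq_len(nrow(tf)))
      wl(sprintf("%s\t%s\t%.3f\t%.3f\t%.3f", tf$subject[i], tf$timepoint[i],
                 tf$gm[i], tf$wm[i], tf$csf[i]))
  }
  invisible(path)
}
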