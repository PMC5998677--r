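# Template-voxel authoring and template->subject voxel prescription.
#
# Prescription maps a template voxel onto a subject anatomical image using
# two registrations: a rigid 6-dof fit supplies the rotation that carries
# the template angulation into the subject frame, and a 9-dof
# (rotation + scale) fit maps the centre coordinate, calibrating for head
# size differences while the voxel dimensions are preserved exactly.

#' Author a template voxel on the template image
#'
#' Rasterizes the prescription in template space (conceptually: the cuboid
#' is rotated about the field-of-view centre and then translated to its
#' final centre — equivalent to rotating about its own centre in place),
#' returns the partial-volume mask for visual appraisal, and records the
#' voxel in the plain-text library for future coregistration. Re-running
#' with `overwrite = TRUE` replaces the record with the same
#' study + description key.
#'
#' @param spec a [voxel_spec()].
#' @param template the template [image_volume()] (used to check the voxel
#'   lies inside the field of view).
#' @param library_path optional `voxel_locations.txt` path to record the
#'   voxel in.
#' @param overlay_path optional NIfTI path; the mask is written there in
#'   template world coordinates so any viewer can overlay it.
#' @param template_image_path path string stored in the library record.
#' @param overwrite replace an existing library record.
#' @param spacing rasterization pixel size in mm.
#' @return the `voxel_mask`, invisibly carrying the library record as
#'   attribute `record`.
#' @export
create_template_voxel <- function(spec, template, library_path = NULL,
                                  overlay_path = NULL,
                                  template_image_path = "",
                                  overwrite = FALSE, spacing = 0.5) {
  stopifnot(inherits(spec, "voxel_spec"), inherits(template, "image_volume"))
  # voxel must sit inside the template field of view
  d <- dim(template$data)
  fov_corners <- as.matrix(expand.grid(x = c(-0.5, d[1] - 0.5),
                                       y = c(-0.5, d[2] - 0.5),
                                       z = c(-0.5, d[3] - 0.5)))
  fov_world <- fov_corners %*% t(template$affine[1:3, 1:3]) +
    matrix(template$affine[1:3, 4], 8, 3, byrow = TRUE)
  lo <- apply(fov_world, 2, min); hi <- apply(fov_world, 2, max)
  vc <- voxel_corners(spec)
  if (any(t(vc) < lo) || any(t(vc) > hi))
    stop("voxel extends beyond the template field of view", call. = FALSE)
  mask <- rasterize_voxel(spec, grid_for_spec(spec, spacing = spacing))
  if (!is.null(library_path))
    write_voxel_record(spec, library_path, template_image_path,
                       overwrite = overwrite)
  if (!is.null(overlay_path))
    write_volume(mask, overlay_path)
  attr(mask, "record") <- spec
  mask
}

#' Map a template voxel onto a subject image
#'
#' Runs the two-registration prescription procedure: (a) a rigid 6-dof
#' template-to-subject registration whose rotation part is composed with
#' the template voxel's rotation and decomposed back to subject-frame
#' angulation angles; (b) a 9-dof registration that maps the template
#' voxel's centre coordinate into subject space; (c) voxel dimensions are
#' copied unchanged. The result carries both the full-precision parameters
#' and a copy quantized to scanner entry precision (0.1 mm / 0.1 degrees).
#'
#' @param template the template [image_volume()].
#' @param template_spec the template [voxel_spec()].
#' @param subject the subject [image_volume()].
#' @param control a [reg_control()].
#' @param backend registration backend: any function with the signature
#'   `function(moving, fixed, dof, control, init = NULL)` returning a
#'   world-to-world spatial transform may be plugged in; defaults to the
#'   built-in [register()].
#' @return object of class `prescription`: list with `spec` (subject-frame
#'   [voxel_spec()]), `rounded`, `rigid`, `affine9`, and `provenance`.
#' @export
prescribe_voxel <- function(template, template_spec, subject,
                            control = reg_control(), backend = register) {
  stopifnot(inherits(template_spec, "voxel_spec"))
  reg6 <- backend(template, subject, dof = 6, control = control)
  reg9 <- backend(template, subject, dof = 9, control = control,
                  init = reg6)
  map_spec_through(template_spec, reg6, reg9,
                   provenance = list(template_voxel = template_spec$description,
                                     study = template_spec$study,
                                     similarity6 = attr(reg6, "similarity"),
                                     similarity9 = attr(reg9, "similarity"),
                                     timestamp = format(Sys.time(),
                                                        "%Y-%m-%dT%H:%M:%S")))
}

# shared by prescription (template->subject) and overlap reconstruction
# (subject->template): rigid rotation re-angulates, 9-dof maps the centre,
# dims are preserved exactly.
map_spec_through <- function(spec, rigid, affine9, provenance = list()) {
  R_reg <- as_transform_matrix(rigid)[1:3, 1:3]
  R_vox <- rotation_from_angulation(spec$angulation)
  ang <- angulation_from_rotation(R_reg %*% R_vox)
  center <- tf_apply(affine9, spec$center)
  mapped <- voxel_spec(spec$study, spec$description, spec$dims, center, ang,
                       spec$orientation)
  rounded <- voxel_spec(spec$study, spec$description, spec$dims,
                        round(center, 1),
                        round(as.numeric(ang), 1), spec$orientation)
  structure(list(spec = mapped, rounded = rounded, rigid = rigid,
                 affine9 = affine9, provenance = provenance),
            class = "prescription")
}

#' @export
print.prescription <- function(x, ...) {
  cat("<prescription>\n  full precision:\n")
  print(x$spec)
  cat(sprintf("  rounded (0.1 mm / 0.1 deg): center (%g, %g, %g), angles (%g, %g, %g)\n",
              x$rounded$center[1], x$rounded$center[2], x$rounded$center[3],
              x$rounded$angulation[1], x$rounded$angulation[2],
              x$rounded$angulation[3]))
  invisible(x)
}

#' Write a prescription as JSON
#'
#' @param p a `prescription`.
#' @param path output `.json` path.
#' @export
write_prescription <- function(p, path) {
  stopifnot(inherits(p, "prescription"))
  as_rec <- function(s) list(study = s$study, description = s$description,
                             dims_mm = s$dims, center_mm = s$center,
                             angulation_deg = as.numeric(s$angulation),
                             orientation = s$orientation)
  jsonlite::write_json(list(spec = as_rec(p$spec),
                            rounded = as_rec(p$rounded),
                            rigid_matrix = as_transform_matrix(p$rigid),
                            affine9_matrix = as_transform_matrix(p$affine9),
                            provenance = p$provenance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
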