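# File formats: NIfTI-1 volumes (via RNifti), JSON voxel sidecars, MR
# spectroscopy DICOM geometry (read-only, standard volume-localization
# fields), the tab-separated template-voxel library, and plain-text 4x4
# transform matrices.

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return an [image_volume()] with the header affine preserved and the
#'   axis-order label derived from it.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3)
    stop("expected a 3D volume, got ", length(d), "D: ", path, call. = FALSE)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4, 4))
  image_volume(array(as.numeric(img), dim = d), aff)
}

#' Write an image volume as NIfTI-1
#'
#' @param img an [image_volume()] (or `voxel_mask`, written via
#'   [mask_as_image()]).
#' @param path output path; `.nii.gz` compresses transparently.
#' @export
write_volume <- function(img, path) {
  if (inherits(img, "voxel_mask")) img <- mask_as_image(img)
  stopifnot(inherits(img, "image_volume"))
  nii <- RNifti::asNifti(img$data)
  RNifti::pixdim(nii) <- image_spacing(img)
  RNifti::sform(nii) <- structure(img$affine, code = 2L)
  RNifti::qform(nii) <- structure(img$affine, code = 2L)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

# ---- voxel sidecar (JSON) --------------------------------------------------

#' Write an acquired-voxel sidecar
#'
#' The sidecar is the portable plain-JSON record of an acquired voxel's
#' geometry (dimensions, centre, angulation, orientation) plus subject and
#' timepoint identifiers; it round-trips losslessly to a [voxel_spec()].
#'
#' @param av an [acquired_voxel()] or a [voxel_spec()] (with `subject_id`
#'   and `timepoint` supplied separately).
#' @param path output `.json` path.
#' @param subject_id,timepoint identifiers when `av` is a bare spec.
#' @export
write_voxel_sidecar <- function(av, path, subject_id = NULL,
                                timepoint = NULL) {
  if (inherits(av, "voxel_spec"))
    av <- acquired_voxel(subject_id %||% "unknown", timepoint %||% "t1", av)
  spec <- av$spec
  rec <- list(subject_id = av$subject_id, timepoint = av$timepoint,
              study = spec$study, description = spec$description,
              dims_mm = spec$dims, center_mm = spec$center,
              angulation_deg = as.numeric(spec$angulation),
              orientation = spec$orientation, source = "manual")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_voxel_sidecar <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("subject_id", "timepoint", "dims_mm", "center_mm",
            "angulation_deg", "orientation")
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0)
    stop("sidecar ", path, " is missing fields: ",
         paste(miss, collapse = ", "), call. = FALSE)
  spec <- voxel_spec(rec$study %||% "unknown",
                     rec$description %||% "unknown",
                     rec$dims_mm, rec$center_mm, rec$angulation_deg,
                     rec$orientation)
  acquired_voxel(rec$subject_id, rec$timepoint, spec,
                 source = rec$source %||% "manual")
}

# ---- DICOM (read-only voxel geometry) --------------------------------------

# Minimal explicit-VR little-endian DICOM walker that extracts the MR
# spectroscopy volume-localization geometry: Volume Localization Sequence
# (0018,9126), whose items carry Slab Thickness (0018,9104), Slab
# Orientation (0018,9105) and Mid Slab Position (0018,9106), plus Patient
# ID (0010,0020) and Study ID (0020,0010) when present. Vendor-private
# fields are not interpreted; the JSON sidecar is the portable path.

read_u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1])
}
read_u32 <- function(raw, pos) {
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1]) +
    65536 * as.numeric(raw[pos + 2]) + 16777216 * as.numeric(raw[pos + 3])
}

# parse one element level; returns list(tags = named list, next_pos)
parse_dicom_elements <- function(raw, pos, end, depth = 0) {
  long_vrs <- c("OB", "OW", "OF", "OD", "SQ", "UT", "UN")
  tags <- list()
  while (pos + 7 <= end) {
    group <- read_u16(raw, pos); elem <- read_u16(raw, pos + 2)
    if (group == 0xFFFE && elem %in% c(0xE00D, 0xE0DD))
      return(list(tags = tags, next_pos = pos + 8))
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% long_vrs) {
      len <- read_u32(raw, pos + 8); body <- pos + 12
    } else {
      len <- read_u16(raw, pos + 6); body <- pos + 8
    }
    key <- sprintf("%04x,%04x", group, elem)
    if (vr == "SQ") {
      sq_end <- if (len == 4294967295) end else body + len - 1
      if (sq_end > length(raw))
        stop("truncated DICOM sequence ", key, call. = FALSE)
      items <- list()
      ipos <- body
      while (ipos + 7 <= sq_end) {
        ig <- read_u16(raw, ipos); ie <- read_u16(raw, ipos + 2)
        ilen <- read_u32(raw, ipos + 4)
        if (ig == 0xFFFE && ie == 0xE0DD) { ipos <- ipos + 8; break }
        if (!(ig == 0xFFFE && ie == 0xE000))
          stop("malformed DICOM sequence at offset ", ipos, call. = FALSE)
        iend <- if (ilen == 4294967295) sq_end else ipos + 8 + ilen - 1
        res <- parse_dicom_elements(raw, ipos + 8, iend, depth + 1)
        items[[length(items) + 1]] <- res$tags
        ipos <- if (ilen == 4294967295) res$next_pos else ipos + 8 + ilen
      }
      tags[[key]] <- items
      pos <- if (len == 4294967295) ipos else body + len
    } else {
      if (len == 4294967295 || body + len - 1 > min(end, length(raw)))
        stop("truncated DICOM element ", key, call. = FALSE)
      bytes <- if (len > 0) raw[body:(body + len - 1)] else raw(0)
      tags[[key]] <- parse_dicom_value(vr, bytes)
      pos <- body + len
    }
  }
  list(tags = tags, next_pos = pos)
}

parse_dicom_value <- function(vr, bytes) {
  if (vr == "FD") return(readBin(bytes, "double", n = length(bytes) / 8,
                                 size = 8, endian = "little"))
  if (vr == "FL") return(readBin(bytes, "double", n = length(bytes) / 4,
                                 size = 4, endian = "little"))
  if (vr %in% c("US")) return(readBin(bytes, "integer", size = 2,
                                      n = length(bytes) / 2, signed = FALSE,
                                      endian = "little"))
  txt <- trimws(rawToChar(bytes))
  if (vr %in% c("DS", "IS")) return(as.numeric(strsplit(txt, "\\\\")[[1]]))
  txt
}

read_dicom_tags <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140)
    stop("truncated DICOM file: ", path, call. = FALSE)
  pos <- 1
  if (length(raw) >= 132 && rawToChar(raw[129:132]) == "DICM") pos <- 133
  parse_dicom_elements(raw, pos, length(raw))$tags
}

read_dicom_voxel <- function(path) {
  tags <- read_dicom_tags(path)
  sq <- tags[["0018,9126"]]
  if (is.null(sq))
    stop("DICOM file lacks the Volume Localization Sequence (0018,9126); ",
         "cannot recover voxel geometry from ", path, call. = FALSE)
  if (length(sq) != 3)
    stop("expected 3 volume-localization slabs, found ", length(sq),
         call. = FALSE)
  need <- c("0018,9104", "0018,9105", "0018,9106")
  for (it in sq) {
    miss <- setdiff(need, names(it))
    if (length(miss) > 0)
      stop("volume-localization item missing tags: ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  dims <- vapply(sq, function(it) it[["0018,9104"]][1], numeric(1))
  Rcols <- vapply(sq, function(it) it[["0018,9105"]][1:3], numeric(3))
  centers <- vapply(sq, function(it) it[["0018,9106"]][1:3], numeric(3))
  if (max(abs(crossprod(Rcols) - diag(3))) > 1e-3)
    stop("slab orientation vectors are not orthonormal (beyond 1e-3)",
         call. = FALSE)
  if (det(Rcols) < 0)
    stop("slab orientation vectors form a left-handed frame", call. = FALSE)
  # re-orthonormalize before Euler decomposition (header vectors are rounded)
  sv <- svd(Rcols)
  R <- sv$u %*% t(sv$v)
  center <- rowMeans(centers)
  ang <- angulation_from_rotation(R)
  subject_id <- if (!is.null(tags[["0010,0020"]])) tags[["0010,0020"]] else
    "unknown"
  timepoint <- if (!is.null(tags[["0020,0010"]])) tags[["0020,0010"]] else "t1"
  spec <- voxel_spec("dicom", "acquired", dims, center, ang, "LAS")
  acquired_voxel(subject_id, timepoint, spec, source = "dicom")
}

#' Read acquired-voxel geometry
#'
#' Reads the geometry of an acquired MRS voxel either from a spectroscopy
#' DICOM header (standard MR volume-localization fields) or from the
#' package's JSON sidecar format, dispatching on the file extension
#' (`.json` for sidecars, anything else is treated as DICOM).
#'
#' @param path path to a sidecar `.json` or a spectroscopy DICOM file.
#' @return an [acquired_voxel()].
#' @export
read_acquired_voxel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    read_voxel_sidecar(path)
  else
    read_dicom_voxel(path)
}

# ---- voxel library (voxel_locations.txt) -----------------------------------

library_columns <- function() {
  c("study", "description", "dx", "dy", "dz", "cx", "cy", "cz",
    "t_s", "t_c", "rot", "orientation", "template_image_path")
}

#' Append (or replace) a template-voxel record in the voxel library
#'
#' The library is a tab-separated append-only file, one record per template
#' voxel, keyed by study + description; `#` lines are comments.
#'
#' @param spec a [voxel_spec()].
#' @param path library file path (created if absent).
#' @param template_image_path path of the template image the voxel was
#'   authored on.
#' @param overwrite replace an existing record with the same
#'   study + description (error otherwise).
#' @export
write_voxel_record <- function(spec, path, template_image_path = "",
                               overwrite = FALSE) {
  stopifnot(inherits(spec, "voxel_spec"))
  lib <- if (file.exists(path)) read_voxel_library(path) else NULL
  rec <- data.frame(study = spec$study, description = spec$description,
                    dx = spec$dims[1], dy = spec$dims[2], dz = spec$dims[3],
                    cx = spec$center[1], cy = spec$center[2],
                    cz = spec$center[3],
                    t_s = spec$angulation[["t_s"]],
                    t_c = spec$angulation[["t_c"]],
                    rot = spec$angulation[["rot"]],
                    orientation = spec$orientation,
                    template_image_path = template_image_path,
                    stringsAsFactors = FALSE)
  if (!is.null(lib)) {
    dup <- lib$study == spec$study & lib$description == spec$description
    if (any(dup) && !overwrite)
      stop("voxel '", spec$study, "/", spec$description,
           "' already in library; use overwrite = TRUE to replace",
           call. = FALSE)
    lib <- rbind(lib[!dup, ], rec)
  } else lib <- rec
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# voxel_locations: ", paste(library_columns(),
                                                 collapse = "\t")), con)
  write.table(lib, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read the template-voxel library
#'
#' @param path library file path.
#' @return data.frame with one row per template voxel.
#' @export
read_voxel_library <- function(path) {
  if (!file.exists(path))
    stop("no such voxel library: ", path, call. = FALSE)
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   col.names = library_columns(),
                   stringsAsFactors = FALSE)
  df
}

#' Look up a template voxel in the library
#'
#' @param path library file path.
#' @param study,description record key.
#' @return a [voxel_spec()]; the template image path is attached as
#'   attribute `template_image_path`.
#' @export
read_voxel_spec <- function(path, study, description) {
  lib <- read_voxel_library(path)
  hit <- lib[lib$study == study & lib$description == description, ]
  if (nrow(hit) == 0)
    stop("voxel '", study, "/", description, "' not found in ", path,
         call. = FALSE)
  hit <- hit[1, ]
  spec <- voxel_spec(hit$study, hit$description,
                     c(hit$dx, hit$dy, hit$dz), c(hit$cx, hit$cy, hit$cz),
                     c(hit$t_s, hit$t_c, hit$rot), hit$orientation)
  attr(spec, "template_image_path") <- hit$template_image_path
  spec
}

# ---- transform files -------------------------------------------------------

#' Write a spatial transform as a text matrix
#'
#' Row-major 4x4 world-to-world matrix (mm) with a `#` comment header
#' naming the moving and fixed images.
#'
#' @param t spatial transform or 4x4 matrix.
#' @param path output path.
#' @param moving,fixed names recorded in the header.
#' @export
write_transform <- function(t, path, moving = "moving", fixed = "fixed") {
  m <- as_transform_matrix(t)
  lines <- c(sprintf("# world-to-world transform: %s -> %s", moving, fixed),
             apply(m, 1, function(r) paste(sprintf("%.10g", r),
                                           collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a spatial transform from a text matrix file
#'
#' @param path file written by [write_transform()].
#' @param rigid interpret as a rigid transform (validates orthonormality);
#'   otherwise as 9-dof rotation + scale.
#' @export
read_transform <- function(path, rigid = TRUE) {
  lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  m <- do.call(rbind, lapply(lines[nzchar(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  stopifnot(all(dim(m) == c(4, 4)))
  if (rigid) rigid_transform(matrix = m) else affine_transform9(matrix = m)
}
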