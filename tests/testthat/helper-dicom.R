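# Synthetic spectroscopy-DICOM writer (explicit VR little endian) used to
# build read-only fixtures for the DICOM geometry reader. Only the fields
# the reader consumes are emitted: Patient ID, Study ID, and the MR volume
# localization sequence (slab thickness / orientation / mid position).

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
f64 <- function(x) writeBin(as.numeric(x), raw(), size = 8, endian = "little")

dcm_element <- function(group, elem, vr, value_raw) {
  long_vrs <- c("OB", "OW", "OF", "OD", "SQ", "UT", "UN")
  hdr <- c(u16(group), u16(elem), charToRaw(vr))
  if (vr %in% long_vrs)
    c(hdr, as.raw(c(0, 0)), u32(length(value_raw)), value_raw)
  else
    c(hdr, u16(length(value_raw)), value_raw)
}

dcm_text <- function(x) {
  r <- charToRaw(x)
  if (length(r) %% 2 == 1) r <- c(r, charToRaw(" "))
  r
}

dcm_item <- function(body) c(u16(0xFFFE), u16(0xE000), u32(length(body)), body)

# build a spectroscopy DICOM file from a voxel_spec
write_spectro_dicom <- function(spec, path, patient_id = "sub01",
                                study_id = "baseline",
                                perturb_orientation = 0) {
  R <- voxplace::rotation_from_angulation(spec$angulation)
  R <- R + perturb_orientation
  items <- raw(0)
  for (ax in 1:3) {
    body <- c(dcm_element(0x0018, 0x9104, "FD", f64(spec$dims[ax])),
              dcm_element(0x0018, 0x9105, "FD", f64(R[, ax])),
              dcm_element(0x0018, 0x9106, "FD", f64(spec$center)))
    items <- c(items, dcm_item(body))
  }
  out <- c(raw(128), charToRaw("DICM"),
           dcm_element(0x0010, 0x0020, "LO", dcm_text(patient_id)),
           dcm_element(0x0018, 0x9126, "SQ", items),
           dcm_element(0x0020, 0x0010, "SH", dcm_text(study_id)))
  writeBin(out, path)
  invisible(path)
}

# same, but dropping one geometry tag from every item (for error paths)
write_spectro_dicom_missing <- function(spec, path, drop = "0018,9106") {
  R <- voxplace::rotation_from_angulation(spec$angulation)
  items <- raw(0)
  for (ax in 1:3) {
    body <- raw(0)
    if (drop != "0018,9104")
      body <- c(body, dcm_element(0x0018, 0x9104, "FD", f64(spec$dims[ax])))
    if (drop != "0018,9105")
      body <- c(body, dcm_element(0x0018, 0x9105, "FD", f64(R[, ax])))
    if (drop != "0018,9106")
      body <- c(body, dcm_element(0x0018, 0x9106, "FD", f64(spec$center)))
    items <- c(items, dcm_item(body))
  }
  out <- c(raw(128), charToRaw("DICM"),
           dcm_element(0x0018, 0x9126, "SQ", items))
  writeBin(out, path)
  invisible(path)
}
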