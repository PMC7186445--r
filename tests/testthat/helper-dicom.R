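# Writes minimal explicit-VR little-endian DICOM files for reader tests.

dcm_elem <- function(group, element, vr, bytes) {
  head <- writeBin(c(as.integer(group %% 256), as.integer(group %/% 256),
                     as.integer(element %% 256), as.integer(element %/% 256)),
                   raw(), size = 1)
  vr_raw <- charToRaw(vr)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  if (vr %in% long_vrs) {
    len <- writeBin(as.integer(length(bytes)), raw(), size = 4,
                    endian = "little")
    c(head, vr_raw, as.raw(c(0, 0)), len, bytes)
  } else {
    len <- writeBin(as.integer(length(bytes)), raw(), size = 2,
                    endian = "little")
    c(head, vr_raw, len, bytes)
  }
}

dcm_str <- function(s) {
  b <- charToRaw(s)
  if (length(b) %% 2 == 1) b <- c(b, charToRaw(" "))
  b
}

dcm_us <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "little")
dcm_u16vec <- function(v) writeBin(as.integer(v), raw(), size = 2,
                                   endian = "little")

write_test_ct_slice <- function(file, pixels, rows, cols, z,
                                pixel_spacing = c(1, 1),
                                slope = 1, intercept = -1024,
                                series_uid = "1.2.3.4") {
  stopifnot(length(pixels) == rows * cols)
  body <- c(
    dcm_elem(0x0008, 0x0060, "CS", dcm_str("CT")),
    dcm_elem(0x0020, 0x000E, "UI", dcm_str(series_uid)),
    dcm_elem(0x0020, 0x0032, "DS", dcm_str(sprintf("0\\0\\%g", z))),
    dcm_elem(0x0020, 0x0037, "DS", dcm_str("1\\0\\0\\0\\1\\0")),
    dcm_elem(0x0028, 0x0010, "US", dcm_us(rows)),
    dcm_elem(0x0028, 0x0011, "US", dcm_us(cols)),
    dcm_elem(0x0028, 0x0030, "DS",
             dcm_str(sprintf("%g\\%g", pixel_spacing[1], pixel_spacing[2]))),
    dcm_elem(0x0028, 0x0100, "US", dcm_us(16)),
    dcm_elem(0x0028, 0x0103, "US", dcm_us(0)),
    dcm_elem(0x0028, 0x1052, "DS", dcm_str(sprintf("%g", intercept))),
    dcm_elem(0x0028, 0x1053, "DS", dcm_str(sprintf("%g", slope))),
    dcm_elem(0x7FE0, 0x0010, "OW", dcm_u16vec(pixels))
  )
  con <- file(file, "wb")
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
  close(con)
  invisible(file)
}

write_test_rtdose <- function(file, stored, dims, scaling = 0.01,
                              pixel_spacing = c(2.5, 2.5), z_step = 2.5,
                              origin = c(0, 0, 0)) {
  stopifnot(length(stored) == prod(dims))
  offsets <- paste(sprintf("%g", (seq_len(dims[3]) - 1) * z_step),
                   collapse = "\\")
  body <- c(
    dcm_elem(0x0008, 0x0060, "CS", dcm_str("RTDOSE")),
    dcm_elem(0x0020, 0x0032, "DS",
             dcm_str(sprintf("%g\\%g\\%g", origin[1], origin[2], origin[3]))),
    dcm_elem(0x0028, 0x0008, "IS", dcm_str(sprintf("%d", dims[3]))),
    dcm_elem(0x0028, 0x0010, "US", dcm_us(dims[2])),
    dcm_elem(0x0028, 0x0011, "US", dcm_us(dims[1])),
    dcm_elem(0x0028, 0x0030, "DS",
             dcm_str(sprintf("%g\\%g", pixel_spacing[1], pixel_spacing[2]))),
    dcm_elem(0x0028, 0x0100, "US", dcm_us(16)),
    dcm_elem(0x0028, 0x0103, "US", dcm_us(0)),
    dcm_elem(0x3004, 0x000C, "DS", dcm_str(offsets)),
    dcm_elem(0x3004, 0x000E, "DS", dcm_str(sprintf("%g", scaling))),
    dcm_elem(0x7FE0, 0x0010, "OW", dcm_u16vec(stored))
  )
  con <- file(file, "wb")
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
  close(con)
  invisible(file)
}
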