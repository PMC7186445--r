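# Minimal DICOM reader (explicit VR, little endian) sufficient for CT image
# series and RTDOSE grids as exported by planning systems. Only the tags the
# pipeline needs are interpreted; everything else is carried as raw strings.

dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

# parse one explicit-VR little-endian element stream; returns named list
parse_dicom <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  raw_all <- readBin(con, "raw", n = file.size(file))
  # optional 128-byte preamble + "DICM"
  pos <- 1L
  if (length(raw_all) > 132L && rawToChar(raw_all[129:132]) == "DICM") pos <- 133L
  out <- list()
  n <- length(raw_all)
  u16 <- function(r) as.integer(r[1]) + 256L * as.integer(r[2])
  u32 <- function(r) as.numeric(u16(r[1:2])) + 65536 * as.numeric(u16(r[3:4]))
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= n) {
    grp <- u16(raw_all[pos:(pos + 1L)])
    ele <- u16(raw_all[(pos + 2L):(pos + 3L)])
    vr <- rawToChar(raw_all[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- u32(raw_all[(pos + 8L):(pos + 11L)])
      pos <- pos + 12L
    } else {
      len <- u16(raw_all[(pos + 6L):(pos + 7L)])
      pos <- pos + 8L
    }
    if (len > 0 && pos + len - 1L > n) {
      stop("truncated DICOM element in ", file)
    }
    bytes <- if (len > 0) raw_all[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    tag <- dcm_tag(grp, ele)
    out[[tag]] <- decode_dicom_value(vr, bytes)
  }
  out
}

decode_dicom_value <- function(vr, bytes) {
  if (length(bytes) == 0) return(NULL)
  switch(vr,
    US = readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
                 signed = FALSE, endian = "little"),
    SS = readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
                 signed = TRUE, endian = "little"),
    UL = readBin(bytes, "integer", n = length(bytes) / 4, size = 4,
                 endian = "little"),
    FL = readBin(bytes, "double", n = length(bytes) / 4, size = 4,
                 endian = "little"),
    FD = readBin(bytes, "double", n = length(bytes) / 8, size = 8,
                 endian = "little"),
    DS = as.numeric(strsplit(trimws(rawToChar(bytes)), "\\\\")[[1]]),
    IS = as.integer(strsplit(trimws(rawToChar(bytes)), "\\\\")[[1]]),
    OW = bytes,  # pixel data: decoded later using BitsAllocated
    OB = bytes,
    trimws(rawToChar(bytes))  # UI, LO, SH, CS, DA, PN, ...
  )
}

dcm_get <- function(ds, group, element, file = "", required = TRUE) {
  v <- ds[[dcm_tag(group, element)]]
  if (is.null(v) && required) {
    stop(sprintf("missing DICOM tag (%04x,%04x) in %s", group, element, file))
  }
  v
}

dcm_pixels <- function(ds, file) {
  bytes <- dcm_get(ds, 0x7FE0, 0x0010, file)
  bits <- dcm_get(ds, 0x0028, 0x0100, file)
  rep0 <- dcm_get(ds, 0x0028, 0x0103, file, required = FALSE) %||% 0L
  size <- bits / 8
  readBin(bytes, "integer", n = length(bytes) / size, size = size,
          signed = (rep0 == 1L || size == 4), endian = "little")
}

#' Read a planning CT series from a directory of DICOM files
#'
#' Slices are sorted by their along-axis position and stacked into a single
#' HU volume; stored pixel values are mapped to Hounsfield units through the
#' rescale slope/intercept of each slice. All slices must belong to one
#' series and share in-plane geometry.
#'
#' @param dir Directory containing the `.dcm` slices of exactly one CT series.
#' @return A [volume_grid()] in HU, axes (column, row, slice).
#' @export
read_ct_series <- function(dir) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0L) stop("no .dcm files in ", dir)
  slices <- lapply(files, parse_dicom)
  uid <- vapply(seq_along(slices), function(i)
    as.character(dcm_get(slices[[i]], 0x0020, 0x000E, files[i])), "")
  if (length(unique(uid)) != 1L) {
    stop("mixed series in ", dir, ": first offending slice ",
         basename(files[which(uid != uid[1])[1]]))
  }
  rows <- vapply(seq_along(slices), function(i)
    dcm_get(slices[[i]], 0x0028, 0x0010, files[i])[1], 0L)
  cols <- vapply(seq_along(slices), function(i)
    dcm_get(slices[[i]], 0x0028, 0x0011, files[i])[1], 0L)
  if (length(unique(rows)) != 1L || length(unique(cols)) != 1L) {
    stop("inconsistent slice dimensions in ", dir)
  }
  zpos <- vapply(seq_along(slices), function(i) {
    ipp <- dcm_get(slices[[i]], 0x0020, 0x0032, files[i])
    if (length(ipp) != 3L) stop("bad ImagePositionPatient in ", files[i])
    ipp[3]
  }, 0)
  ord <- order(zpos)
  slices <- slices[ord]; files <- files[ord]; zpos <- zpos[ord]
  ps <- dcm_get(slices[[1]], 0x0028, 0x0030, files[1])  # (row, col) spacing
  dz <- if (length(zpos) > 1L) {
    dzs <- diff(zpos)
    if (max(dzs) - min(dzs) > 1e-3) stop("non-uniform slice spacing in ", dir)
    mean(dzs)
  } else {
    dcm_get(slices[[1]], 0x0018, 0x0050, files[1], required = FALSE) %||% 1
  }
  vol <- array(0, c(cols[1], rows[1], length(slices)))
  for (i in seq_along(slices)) {
    px <- dcm_pixels(slices[[i]], files[i])
    slope <- dcm_get(slices[[i]], 0x0028, 0x1053, files[i], required = FALSE) %||% 1
    icept <- dcm_get(slices[[i]], 0x0028, 0x1052, files[i], required = FALSE) %||% 0
    # stored row-major (x fastest within a row)
    vol[, , i] <- matrix(px * slope + icept, nrow = cols[1], ncol = rows[1])
  }
  ipp1 <- dcm_get(slices[[1]], 0x0020, 0x0032, files[1])
  volume_grid(vol, spacing = c(ps[2], ps[1], dz),
              origin = c(ipp1[1], ipp1[2], zpos[1]))
}

#' Read an RTDOSE grid from a DICOM file
#'
#' Stored integers are scaled to Gy by the dose-grid scaling tag; the slice
#' axis is reconstructed from the grid frame offset vector.
#'
#' @param file Path to an RTDOSE DICOM file.
#' @return A [volume_grid()] in Gy.
#' @export
read_dose <- function(file) {
  ds <- parse_dicom(file)
  scaling <- dcm_get(ds, 0x3004, 0x000E, file)  # DoseGridScaling: required
  rows <- dcm_get(ds, 0x0028, 0x0010, file)[1]
  cols <- dcm_get(ds, 0x0028, 0x0011, file)[1]
  nframes <- dcm_get(ds, 0x0028, 0x0008, file, required = FALSE) %||% 1L
  nframes <- as.integer(nframes[1])
  offsets <- dcm_get(ds, 0x3004, 0x000C, file, required = FALSE) %||% 0
  ps <- dcm_get(ds, 0x0028, 0x0030, file)
  ipp <- dcm_get(ds, 0x0020, 0x0032, file, required = FALSE) %||% c(0, 0, 0)
  px <- dcm_pixels(ds, file)
  if (length(px) != cols * rows * nframes) {
    stop("pixel data size mismatch in ", file)
  }
  dz <- if (length(offsets) > 1L) mean(diff(offsets)) else ps[1]
  vol <- array(px * scaling, c(cols, rows, nframes))
  volume_grid(vol, spacing = c(ps[2], ps[1], dz),
              origin = c(ipp[1], ipp[2], ipp[3] + offsets[1]))
}
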