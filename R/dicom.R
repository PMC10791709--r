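# Minimal DICOM support: single-frame CT series, explicit VR little endian,
# uncompressed 16-bit pixel data. The reader applies RescaleSlope/Intercept
# to recover HU and orders slices by geometric z position; the writer emits
# one file per slice and exists mainly to build round-trip fixtures.

u16le <- function(bytes, pos) {
  as.integer(bytes[pos]) + 256L * as.integer(bytes[pos + 1L])
}
u32le <- function(bytes, pos) {
  sum(as.numeric(bytes[pos + 0:3]) * 256^(0:3))
}

# Walk a DICOM byte stream into a named list of raw values keyed "GGGG,EEEE".
parse_dicom_elements <- function(bytes) {
  pos <- 1L
  if (length(bytes) >= 132 && rawToChar(bytes[129:132]) == "DICM") pos <- 133L
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  n <- length(bytes)
  while (pos + 7L <= n) {
    group <- u16le(bytes, pos)
    elem <- u16le(bytes, pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      abort("implicit-VR or corrupt DICOM stream; only explicit VR little endian is supported.")
    if (vr %in% long_vrs) {
      len <- u32le(bytes, pos + 8L)
      data_start <- pos + 12L
    } else {
      len <- u16le(bytes, pos + 6L)
      data_start <- pos + 8L
    }
    if (len == 4294967295) abort("undefined-length DICOM elements are not supported.")
    key <- sprintf("%04X,%04X", group, elem)
    tags[[key]] <- if (len > 0) bytes[data_start:(data_start + len - 1L)] else raw(0)
    pos <- data_start + as.integer(len)
  }
  tags
}

dcm_str <- function(tags, key, default = NULL) {
  v <- tags[[key]]
  if (is.null(v)) return(default)
  trimws(rawToChar(v[v != as.raw(0)]))
}
dcm_us <- function(tags, key, default = NULL) {
  v <- tags[[key]]
  if (is.null(v)) return(default)
  u16le(v, 1L)
}
dcm_ds <- function(tags, key, default = NULL) {
  s <- dcm_str(tags, key)
  if (is.null(s)) return(default)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0)
    abort(sprintf("no DICOM (*.dcm) files found in '%s'.", dir))
  slices <- lapply(files, function(f) {
    bytes <- readBin(f, "raw", n = file.size(f))
    tags <- parse_dicom_elements(bytes)
    rows <- dcm_us(tags, "0028,0010")
    cols <- dcm_us(tags, "0028,0011")
    bits <- dcm_us(tags, "0028,0100", 16L)
    signed <- identical(dcm_us(tags, "0028,0103", 0L), 1L)
    if (is.null(rows) || is.null(cols) || bits != 16L)
      abort(sprintf("'%s' lacks 16-bit pixel data.", basename(f)))
    slope <- dcm_ds(tags, "0028,1053", 1)[1]
    intercept <- dcm_ds(tags, "0028,1052", 0)[1]
    pos <- dcm_ds(tags, "0020,0032", c(0, 0, NA_real_))
    px_spacing <- dcm_ds(tags, "0028,0030", c(1, 1))
    pix <- tags[["7FE0,0010"]]
    if (is.null(pix)) abort(sprintf("'%s' has no PixelData.", basename(f)))
    stored <- readBin(pix, "integer", n = as.integer(rows) * cols,
                      size = 2L, signed = signed, endian = "little")
    list(uid = dcm_str(tags, "0020,000E", "<missing>"),
         z = pos[3],
         # PixelSpacing is (row, col) = (y, x)
         spacing_xy = c(px_spacing[2], px_spacing[1]),
         hu = slope * stored + intercept,
         nx = as.integer(cols), ny = as.integer(rows))
  })
  uids <- unique(vapply(slices, `[[`, "", "uid"))
  if (length(uids) > 1)
    abort(paste0("directory mixes multiple DICOM series: ",
                 paste(uids, collapse = ", ")))
  z <- vapply(slices, `[[`, 0, "z")
  slices <- slices[order(z)]
  z <- sort(z)
  nx <- slices[[1]]$nx; ny <- slices[[1]]$ny
  spacing_xy <- slices[[1]]$spacing_xy
  if (abs(spacing_xy[1] - spacing_xy[2]) > 1e-9)
    inform(sprintf("non-isotropic in-plane spacing: %.4g x %.4g mm",
                   spacing_xy[1], spacing_xy[2]))
  dz <- if (length(z) > 1) diff(z)[1] else 1
  vox <- array(NA_real_, c(nx, ny, length(slices)))
  for (k in seq_along(slices)) {
    if (slices[[k]]$nx != nx || slices[[k]]$ny != ny)
      abort("DICOM slices disagree on matrix size.")
    vox[, , k] <- slices[[k]]$hu
  }
  list(voxels = vox, spacing = c(spacing_xy, dz))
}

# --- writer ------------------------------------------------------------

dcm_elem_short <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2 == 1)
    value_raw <- c(value_raw, if (vr == "UI") as.raw(0) else charToRaw(" "))
  c(writeBin(c(group, elem), raw(), size = 2L, endian = "little"),
    charToRaw(vr),
    writeBin(length(value_raw), raw(), size = 2L, endian = "little"),
    value_raw)
}

dcm_elem_long <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2 == 1) value_raw <- c(value_raw, as.raw(0))
  c(writeBin(c(group, elem), raw(), size = 2L, endian = "little"),
    charToRaw(vr), as.raw(c(0, 0)),
    writeBin(length(value_raw), raw(), size = 4L, endian = "little"),
    value_raw)
}

dcm_us_raw <- function(v) writeBin(as.integer(v), raw(), size = 2L,
                                   endian = "little")
dcm_txt_raw <- function(s) charToRaw(s)

write_dicom_series <- function(voxels, spacing, dir,
                               patient_id = NA_character_,
                               series_uid = NULL,
                               rescale_intercept = -1024,
                               rescale_slope = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(series_uid))
    series_uid <- paste0("1.2.826.0.1.3680043.9999.",
                         format(as.integer(Sys.time()) %% 100000L), ".",
                         sample.int(100000L, 1L))
  d <- dim(voxels)
  stored_all <- (voxels - rescale_intercept) / rescale_slope
  if (max(abs(stored_all - round(stored_all))) > 1e-6)
    warn("HU values are not exactly representable with the given rescale; stored values are rounded.")
  for (k in seq_len(d[3])) {
    stored <- as.integer(round(stored_all[, , k]))
    meta_ts <- dcm_elem_short(2L, 16L, "UI",
                              dcm_txt_raw("1.2.840.10008.1.2.1"))
    body <- c(
      dcm_elem_short(8L, 96L, "CS", dcm_txt_raw("CT")),          # Modality
      dcm_elem_short(16L, 32L, "LO",                              # PatientID
                     dcm_txt_raw(if (is.na(patient_id)) "anon" else patient_id)),
      dcm_elem_short(32L, 14L, "UI", dcm_txt_raw(series_uid)),    # SeriesUID
      dcm_elem_short(32L, 19L, "IS", dcm_txt_raw(as.character(k))),
      dcm_elem_short(32L, 50L, "DS",                              # IPP
                     dcm_txt_raw(sprintf("0\\0\\%.6f", (k - 1) * spacing[3]))),
      dcm_elem_short(40L, 16L, "US", dcm_us_raw(d[2])),           # Rows = y
      dcm_elem_short(40L, 17L, "US", dcm_us_raw(d[1])),           # Cols = x
      dcm_elem_short(40L, 48L, "DS",                              # PixelSpacing
                     dcm_txt_raw(sprintf("%.6f\\%.6f", spacing[2], spacing[1]))),
      dcm_elem_short(40L, 256L, "US", dcm_us_raw(16L)),           # BitsAllocated
      dcm_elem_short(40L, 257L, "US", dcm_us_raw(16L)),           # BitsStored
      dcm_elem_short(40L, 259L, "US", dcm_us_raw(1L)),            # signed
      dcm_elem_short(40L, 4178L, "DS",
                     dcm_txt_raw(format(rescale_intercept))),
      dcm_elem_short(40L, 4179L, "DS", dcm_txt_raw(format(rescale_slope))),
      dcm_elem_long(32736L, 16L, "OW",
                    writeBin(stored, raw(), size = 2L, endian = "little")))
    con <- file(file.path(dir, sprintf("slice_%04d.dcm", k)), "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta_ts, body), con)
    close(con)
  }
  invisible(dir)
}
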