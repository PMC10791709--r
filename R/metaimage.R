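# Minimal MetaImage (.mha/.mhd) support: text header plus uncompressed raw
# voxel data, little endian. Covers the element types CT pipelines emit.

mi_types <- c(MET_UCHAR = "uchar", MET_SHORT = "short", MET_INT = "int",
              MET_FLOAT = "float", MET_DOUBLE = "double")
mi_sizes <- c(MET_UCHAR = 1L, MET_SHORT = 2L, MET_INT = 4L,
              MET_FLOAT = 4L, MET_DOUBLE = 8L)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0) abort("MetaImage header ended before ElementDataFile.")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!is.null(hdr$CompressedData) && toupper(hdr$CompressedData) == "TRUE")
    abort("compressed MetaImage data is not supported.")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(dims) != 3) abort("only 3-D MetaImage volumes are supported.")
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  type <- hdr$ElementType
  if (!type %in% names(mi_types))
    abort(sprintf("unsupported MetaImage ElementType '%s'.", type))
  n <- prod(dims)
  what <- if (type %in% c("MET_FLOAT", "MET_DOUBLE")) "double" else "integer"
  if (hdr$ElementDataFile == "LOCAL") {
    raw_data <- readBin(con, what = what, n = n, size = mi_sizes[[type]],
                        signed = type != "MET_UCHAR", endian = "little")
  } else {
    data_path <- file.path(dirname(path), hdr$ElementDataFile)
    con2 <- file(data_path, "rb")
    on.exit(close(con2), add = TRUE)
    raw_data <- readBin(con2, what = what, n = n, size = mi_sizes[[type]],
                        signed = type != "MET_UCHAR", endian = "little")
  }
  if (length(raw_data) != n) abort("MetaImage data shorter than DimSize.")
  list(voxels = array(as.numeric(raw_data), dim = dims), spacing = spacing)
}

write_metaimage <- function(voxels, spacing, path) {
  dims <- dim(voxels)
  is_int <- all(voxels == round(voxels)) && max(abs(voxels)) < 32768
  type <- if (is_int) "MET_SHORT" else "MET_DOUBLE"
  mhd <- grepl("\\.mhd$", tolower(path))
  data_file <- if (mhd) sub("\\.mhd$", ".raw", path, ignore.case = TRUE)
               else path
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", paste(dims, collapse = " ")),
    paste("ElementSpacing =", paste(format(spacing, digits = 15), collapse = " ")),
    paste("ElementType =", type),
    paste("ElementDataFile =", if (mhd) basename(data_file) else "LOCAL"))
  con <- file(path, "wb")
  writeLines(hdr, con)
  if (!mhd) {
    write_mi_data(voxels, type, con)
    close(con)
  } else {
    close(con)
    con2 <- file(data_file, "wb")
    write_mi_data(voxels, type, con2)
    close(con2)
  }
  invisible(path)
}

write_mi_data <- function(voxels, type, con) {
  if (type == "MET_SHORT")
    writeBin(as.integer(voxels), con, size = 2L, endian = "little")
  else
    writeBin(as.numeric(voxels), con, size = 8L, endian = "little")
}
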