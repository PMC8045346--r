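# Minimal MetaImage (.mha / .mhd) support: ASCII key = value header
# followed by (or pointing to) raw little/big-endian voxel data.
# Uncompressed data only; 3D scalar grids only.

.metaTypes <- list(
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_UINT   = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE))

.readMetaImage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) stop("truncated MetaImage header: ", path)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1L]]
    if (length(kv) != 3L) stop("malformed MetaImage header line: ", line)
    hdr[[kv[2L]]] <- trimws(kv[3L])
    if (kv[2L] == "ElementDataFile") break
  }
  ndims <- as.integer(hdr$NDims %||% "3")
  if (ndims != 3L)
    stop("non-3D data: expected 3 dimensions, got ", ndims)
  if (isTRUE(toupper(hdr$CompressedData %||% "FALSE") == "TRUE"))
    stop("compressed MetaImage data is not supported")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1L]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1L]])
  origin <- as.numeric(strsplit(hdr$Offset %||% hdr$Position %||% "0 0 0",
                                "\\s+")[[1L]])
  type <- .metaTypes[[hdr$ElementType %||% "MET_FLOAT"]]
  if (is.null(type)) stop("unsupported MetaImage element type: ", hdr$ElementType)
  endian <- if (toupper(hdr$ElementByteOrderMSB %||% "FALSE") == "TRUE")
    "big" else "little"
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw <- readBin(con, type$what, n = n, size = type$size,
                   signed = type$signed, endian = endian)
  } else {
    rawPath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawPath)) stop("raw data file not found: ", rawPath)
    rcon <- file(rawPath, "rb")
    on.exit(close(rcon), add = TRUE)
    raw <- readBin(rcon, type$what, n = n, size = type$size,
                   signed = type$signed, endian = endian)
  }
  if (length(raw) != n) stop("truncated MetaImage data: ", path)
  list(data = array(raw, dims), spacing = spacing, origin = origin)
}

.writeMetaImage <- function(data, path, spacing, origin, type = "MET_FLOAT") {
  tinfo <- .metaTypes[[type]]
  if (is.null(tinfo)) stop("unsupported MetaImage element type: ", type)
  ext <- tolower(tools::file_ext(path))
  local <- ext == "mha"
  dataFile <- if (local) "LOCAL" else
    paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "ElementByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", paste(dim(data), collapse = " ")),
    paste("ElementSpacing =", paste(format(spacing, digits = 15), collapse = " ")),
    paste("Offset =", paste(format(origin, digits = 15), collapse = " ")),
    paste("ElementType =", type),
    paste("ElementDataFile =", dataFile))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  vals <- if (tinfo$what == "integer") as.integer(data) else as.numeric(data)
  if (local) {
    writeBin(vals, con, size = tinfo$size, endian = "little")
  } else {
    rcon <- file(file.path(dirname(path), dataFile), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(vals, rcon, size = tinfo$size, endian = "little")
  }
  invisible(path)
}
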