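# Volume, image and report I/O.
#
# Volumes are exchanged in four dialects:
#   raw16      headerless little-endian unsigned 16-bit, user-declared shape,
#              optional header-skip bytes; voxel order (z,y,x) with x fastest
#   tiff_stack multi-page TIFF, one z slice per page
#   mha        uncompressed MetaImage (text header + raw block)
#   nifti      NIfTI-1 via RNifti
# Spacing is always carried explicitly, never inferred from pixel data.

#' Read a 3D volume
#'
#' @param path file path.
#' @param format_hint one of `"raw16"`, `"tiff_stack"`, `"mha"`, `"nifti"`.
#' @param spacing_mm isotropic voxel spacing in mm. Required for `raw16` and
#'   `tiff_stack`; for `mha`/`nifti` it overrides the header value when given.
#' @param shape for `raw16`: integer `c(nx, ny, nz)` of the stored grid.
#' @param skip_bytes for `raw16`: header bytes to skip before the voxel block.
#' @return A [volume3d].
#' @export
read_volume <- function(path, format_hint = c("raw16", "tiff_stack", "mha", "nifti"),
                        spacing_mm = NULL, shape = NULL, skip_bytes = 0L) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  switch(format_hint,
    raw16 = {
      if (is.null(shape) || length(shape) != 3L)
        stop("raw16 needs shape = c(nx, ny, nz)")
      if (is.null(spacing_mm)) stop("raw16 needs spacing_mm")
      n <- prod(as.numeric(shape))
      need <- 2 * n + skip_bytes
      have <- file.size(path)
      if (have < need)
        stop(sprintf("raw16 shape mismatch for %s: expected >= %d bytes, found %d",
                     path, need, have))
      con <- file(path, "rb"); on.exit(close(con))
      if (skip_bytes > 0) readBin(con, "raw", n = skip_bytes)
      v <- readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                   endian = "little")
      volume3d(array(as.numeric(v), dim = shape), spacing_mm)
    },
    tiff_stack = {
      if (is.null(spacing_mm)) stop("tiff_stack needs spacing_mm")
      pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      nz <- length(pages)
      # readTIFF returns [row, col] = [y, x]; transpose to our [x, y]
      d <- dim(pages[[1]])
      a <- array(0, dim = c(d[2], d[1], nz))
      for (k in seq_len(nz)) a[, , k] <- t(pages[[k]])
      volume3d(a, spacing_mm)
    },
    mha = {
      m <- read_mha(path)
      volume3d(m$data, if (is.null(spacing_mm)) m$spacing else spacing_mm)
    },
    nifti = {
      img <- RNifti::readNifti(path)
      sp <- RNifti::pixdim(img)[1]
      volume3d(array(as.numeric(img), dim = dim(img)),
               if (is.null(spacing_mm)) sp else spacing_mm)
    })
}

#' Write a 3D volume
#'
#' Integer-valued volumes written as `raw16`/`tiff_stack`/`mha` round-trip
#' bit-exactly through [read_volume].
#'
#' @param vol a [volume3d].
#' @param path output path.
#' @param format one of `"raw16"`, `"tiff_stack"`, `"mha"`, `"nifti"`.
#' @export
write_volume <- function(vol, path, format = c("raw16", "tiff_stack", "mha", "nifti")) {
  format <- match.arg(format)
  stopifnot(inherits(vol, "volume3d"))
  a <- vol$intensities
  switch(format,
    raw16 = {
      con <- file(path, "wb"); on.exit(close(con))
      v <- as.integer(round(a))
      if (any(v < 0 | v > 65535)) stop("raw16 requires values in [0, 65535]")
      # writeBin has no unsigned 16-bit: fold into signed range bit pattern
      v <- ifelse(v > 32767L, v - 65536L, v)
      writeBin(v, con, size = 2L, endian = "little")
    },
    tiff_stack = {
      d <- dim(a)
      pages <- lapply(seq_len(d[3]), function(k) {
        p <- t(a[, , k]) / 65535
        storage.mode(p) <- "double"
        p
      })
      tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    },
    mha = write_mha(a, vol$spacing, path),
    nifti = {
      img <- RNifti::asNifti(a)
      RNifti::pixdim(img) <- rep(vol$spacing, 3)
      RNifti::writeNifti(img, path)
    })
  invisible(path)
}

# Minimal uncompressed MetaImage reader/writer (MET_USHORT / MET_FLOAT /
# MET_DOUBLE, local raw block).
read_mha <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("mha header ended before ElementDataFile: ", path)
    hdr <- c(hdr, line)
    if (grepl("^ElementDataFile", line)) break
  }
  kv <- strsplit(hdr, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  get <- function(k) vals[match(k, keys)]
  if (!identical(get("ElementDataFile"), "LOCAL"))
    stop("only LOCAL ElementDataFile mha supported")
  if (!is.na(get("CompressedData")) && toupper(get("CompressedData")) == "TRUE")
    stop("compressed mha not supported")
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  sp <- as.numeric(strsplit(get("ElementSpacing"), "\\s+")[[1]])[1]
  type <- get("ElementType")
  n <- prod(dims)
  v <- switch(type,
    MET_USHORT = readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                         endian = "little"),
    MET_SHORT  = readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                         endian = "little"),
    MET_FLOAT  = readBin(con, "double", n = n, size = 4L, endian = "little"),
    MET_DOUBLE = readBin(con, "double", n = n, size = 8L, endian = "little"),
    stop("unsupported mha ElementType: ", type))
  list(data = array(as.numeric(v), dim = dims), spacing = sp)
}

write_mha <- function(a, spacing, path) {
  d <- dim(a)
  con <- file(path, "wb"); on.exit(close(con))
  hdr <- paste0(
    "ObjectType = Image\nNDims = 3\nBinaryData = True\n",
    "BinaryDataByteOrderMSB = False\nCompressedData = False\n",
    sprintf("DimSize = %d %d %d\n", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %g %g %g\n", spacing, spacing, spacing),
    "ElementType = MET_USHORT\nElementDataFile = LOCAL\n")
  writeChar(hdr, con, eos = NULL)
  v <- as.integer(round(a))
  if (any(v < 0 | v > 65535)) stop("MET_USHORT requires values in [0, 65535]")
  v <- ifelse(v > 32767L, v - 65536L, v)
  writeBin(v, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an RGB histology section image
#'
#' @param path PNG or TIFF file; must decode to at least three channels
#'   (extra channels such as alpha are dropped).
#' @param pixel_spacing_mm physical pixel pitch in mm.
#' @return A [histology_image].
#' @export
read_histology <- function(path, pixel_spacing_mm) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(img)) < 3L || dim(img)[3] < 3L)
    stop("needs RGB: section image must have three color channels")
  # [row, col, ch] = [y, x, ch] -> [x, y, ch]
  a <- aperm(img[, , 1:3, drop = FALSE], c(2, 1, 3))
  histology_image(a, pixel_spacing_mm)
}

#' Write an RGB histology section image
#'
#' @param img a [histology_image].
#' @param path output PNG or TIFF path (by extension).
#' @export
write_histology <- function(img, path) {
  stopifnot(inherits(img, "histology_image"))
  a <- aperm(img$rgb, c(2, 1, 3))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) tiff::writeTIFF(a, path, bits.per.sample = 8L)
  else png::writePNG(a, path)
  invisible(path)
}

#' Write a machine- and human-readable run report
#'
#' Serializes a result bundle (plane parameters, rigid transform, pixel
#' classification and overlap scores) to JSON with a deterministic field
#' order, plus a plain-text summary next to it.
#'
#' @param report a named list, typically from [run_case].
#' @param path output JSON path; a `.txt` summary is written alongside.
#' @export
write_report <- function(report, path) {
  keys <- c("inputs", "cones", "ellipses", "correspondence", "plane",
            "transform", "classification", "scores", "warnings")
  out <- stats::setNames(vector("list", length(keys)), keys)
  for (k in keys) if (!is.null(report[[k]])) out[[k]] <- report[[k]]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  txt <- sub("\\.json$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  lines <- c("conereg run report", strrep("-", 40))
  if (!is.null(report$plane))
    lines <- c(lines, sprintf("plane point  : %s mm",
                              paste(sprintf("%.4f", report$plane$point), collapse = ", ")),
               sprintf("plane normal : %s",
                       paste(sprintf("%.5f", report$plane$normal), collapse = ", ")))
  if (!is.null(report$scores))
    lines <- c(lines, sprintf("IoU  : %.4f", report$scores$iou),
               sprintf("DSC  : %.4f", report$scores$dsc))
  if (length(report$warnings))
    lines <- c(lines, "warnings:", paste(" -", unlist(report$warnings)))
  writeLines(lines, txt)
  invisible(path)
}
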