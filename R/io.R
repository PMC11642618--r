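# Volume and image I/O: NRRD (raw encoding, spacing in header) and baseline
# uncompressed multi-page TIFF. No reader for these formats ships with the
# supported R stack, so minimal ones live here; they cover exactly the
# subset the package writes plus common grayscale variants.

NRRD_TYPES <- list(
  "double"        = list(size = 8L, what = "double", signed = TRUE),
  "float"         = list(size = 4L, what = "double", signed = TRUE),
  "short"         = list(size = 2L, what = "integer", signed = TRUE),
  "ushort"        = list(size = 2L, what = "integer", signed = FALSE),
  "unsigned short" = list(size = 2L, what = "integer", signed = FALSE),
  "uchar"         = list(size = 1L, what = "integer", signed = FALSE),
  "uint8"         = list(size = 1L, what = "integer", signed = FALSE),
  "unsigned char" = list(size = 1L, what = "integer", signed = FALSE),
  "int"           = list(size = 4L, what = "integer", signed = TRUE)
)

file_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "nrrd") return("nrrd")
  if (ext %in% c("tif", "tiff")) return("tiff")
  stop(sprintf("unsupported file extension '.%s' (use .nrrd or .tif/.tiff)",
               ext), call. = FALSE)
}

#' Read a volume from NRRD or multi-page TIFF
#'
#' NRRD headers carry the voxel spacing; TIFF stacks do not, so
#' `voxel_size_um` must be supplied for them. When both a header spacing and
#' an explicit argument are present they must agree to 1e-6 relative.
#' Anisotropic header spacings are rejected: every measurement downstream
#' assumes cubic voxels.
#'
#' @param path file path (`.nrrd`, `.tif`, `.tiff`).
#' @param voxel_size_um optional isotropic voxel size in um.
#' @return An uncalibrated [voxel_grid()].
#' @export
read_volume <- function(path, voxel_size_um = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  fmt <- file_format(path)
  if (fmt == "nrrd") {
    parsed <- read_nrrd(path)
    header_vs <- parsed$voxel_size_um
    if (!is.null(header_vs) && !is.null(voxel_size_um)) {
      if (abs(header_vs - voxel_size_um) > 1e-6 * abs(header_vs))
        stop(sprintf(
          "voxel size mismatch: header %g um vs argument %g um",
          header_vs, voxel_size_um), call. = FALSE)
    }
    vs <- if (!is.null(header_vs)) header_vs else voxel_size_um
    if (is.null(vs)) stop("no voxel size in header and none supplied", call. = FALSE)
    voxel_grid(parsed$values, vs)
  } else {
    if (is.null(voxel_size_um))
      stop("TIFF carries no voxel size; supply voxel_size_um", call. = FALSE)
    voxel_grid(read_tiff_stack(path), voxel_size_um)
  }
}

#' Write a volume to NRRD or multi-page TIFF
#'
#' NRRD output stores the spacing in the header and round-trips values
#' bit-exactly (raw little-endian doubles). TIFF output is an uncompressed
#' 64-bit float stack (voxel size is not representable in baseline TIFF, so
#' reading it back requires `voxel_size_um`).
#'
#' @param grid a [voxel_grid()].
#' @param path destination path (`.nrrd`, `.tif`, `.tiff`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot_grid(grid)
  fmt <- file_format(path)
  if (fmt == "nrrd") {
    write_nrrd(grid$values, path, grid$voxel_size_um, type = "double")
  } else {
    write_tiff_stack(grid$values, path, bits = 64L, float = TRUE)
  }
  invisible(path)
}

#' Write a mask volume (integer 0/1)
#'
#' @param mask a [voxel_mask()] or logical 3D array.
#' @param path destination (`.nrrd` stores the spacing; TIFF does not).
#' @param voxel_size_um voxel size recorded in NRRD headers.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, voxel_size_um) {
  m <- as_mask_array(mask)
  fmt <- file_format(path)
  if (fmt == "nrrd") {
    write_nrrd(m + 0L, path, voxel_size_um, type = "uint8")
  } else {
    write_tiff_stack(m + 0L, path, bits = 8L, float = FALSE)
  }
  invisible(path)
}

#' Read a mask volume
#'
#' @inheritParams read_volume
#' @param kind mask kind, `"roi"` or `"bone"`.
#' @return A [voxel_mask()].
#' @export
read_mask <- function(path, voxel_size_um = NULL, kind = "roi") {
  g <- read_volume(path, voxel_size_um)
  voxel_mask(g$values != 0, kind = kind)
}

#' Write a 2D radiograph or projection as 16-bit TIFF
#'
#' Values are rounded and clamped to the 16-bit range; rescale beforehand if
#' the dynamic range matters.
#'
#' @param image a [radiograph2d()].
#' @param path destination `.tif`/`.tiff` path.
#' @return `path`, invisibly.
#' @export
write_radiograph <- function(image, path) {
  if (!inherits(image, "radiograph2d"))
    stop("expected a radiograph2d", call. = FALSE)
  v <- pmin(pmax(round(image$values), 0), 65535)
  arr <- array(v, dim = c(dim(v), 1L))
  write_tiff_stack(arr, path, bits = 16L, float = FALSE)
  invisible(path)
}

# ---- NRRD ----

write_nrrd <- function(values, path, voxel_size_um, type = "double") {
  d <- dim(values)
  header <- c(
    "NRRD0004",
    sprintf("type: %s", type),
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("spacings: %.9g %.9g %.9g", voxel_size_um, voxel_size_um,
            voxel_size_um),
    "space units: \"um\" \"um\" \"um\"",
    "encoding: raw",
    "endian: little",
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (type == "double") {
    writeBin(as.numeric(values), con, size = 8L, endian = "little")
  } else if (type == "uint8") {
    writeBin(as.raw(as.integer(values)), con)
  } else stop("unsupported NRRD write type", call. = FALSE)
  invisible(path)
}

read_nrrd <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  # header ends at the first blank line
  nl <- which(bytes == as.raw(10L))
  header_end <- NA_integer_
  prev <- 0L
  for (pos in nl) {
    if (pos == prev + 1L) { header_end <- pos; break }
    # allow \r\n
    if (pos == prev + 2L && bytes[pos - 1L] == as.raw(13L)) {
      header_end <- pos; break
    }
    prev <- pos
  }
  if (is.na(header_end)) stop("malformed NRRD: no end of header", call. = FALSE)
  header <- strsplit(rawToChar(bytes[seq_len(header_end)]), "\r?\n")[[1]]
  if (!grepl("^NRRD", header[1])) stop("not an NRRD file", call. = FALSE)
  fields <- list()
  for (line in header[-1]) {
    if (grepl("^\\s*(#|$)", line)) next
    m <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
    if (length(m) == 3) fields[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  if (!identical(fields[["dimension"]], "3"))
    stop("only 3D NRRD supported", call. = FALSE)
  if (!identical(tolower(fields[["encoding"]]), "raw"))
    stop("only raw NRRD encoding supported", call. = FALSE)
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  type <- tolower(fields[["type"]])
  tinfo <- NRRD_TYPES[[type]]
  if (is.null(tinfo)) stop(sprintf("unsupported NRRD type '%s'", type), call. = FALSE)
  endian <- fields[["endian"]]
  if (is.null(endian)) endian <- "little"
  spac <- NULL
  if (!is.null(fields[["spacings"]])) {
    spac <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    mat <- vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3))
    spac <- sqrt(colSums(mat^2))
  }
  vs <- NULL
  if (!is.null(spac)) {
    if (length(spac) != 3 || any(!is.finite(spac)) || any(spac <= 0))
      stop("invalid spacing in NRRD header", call. = FALSE)
    if (diff(range(spac)) > 1e-6 * max(spac))
      stop("anisotropic voxels unsupported", call. = FALSE)
    vs <- mean(spac)
  }
  n <- prod(sizes)
  data_raw <- bytes[(header_end + 1L):length(bytes)]
  if (length(data_raw) < n * tinfo$size)
    stop("NRRD data shorter than sizes imply", call. = FALSE)
  vals <- readBin(data_raw, what = tinfo$what, n = n, size = tinfo$size,
                  signed = tinfo$signed, endian = endian)
  list(values = array(as.numeric(vals), dim = sizes), voxel_size_um = vs)
}

# ---- baseline TIFF ----

# Pages are slices along array dimension 3; within a page, image rows are
# array dimension 1 and columns dimension 2.

write_tiff_stack <- function(values, path, bits = 64L, float = TRUE) {
  d <- dim(values)
  if (length(d) != 3L) stop("expected a 3D array", call. = FALSE)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  bytes_pp <- bits / 8L
  strip_len <- nx * ny * bytes_pp
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  writeBin(charToRaw("II"), con); w16(42L)
  # layout: [8: page1 strip][page1 IFD][page2 strip][page2 IFD]...
  ifd_size <- 2L + 10L * 12L + 4L
  strip_off <- integer(nz); ifd_off <- integer(nz)
  pos <- 8L
  for (k in seq_len(nz)) {
    strip_off[k] <- pos
    ifd_off[k] <- pos + strip_len
    pos <- pos + strip_len + ifd_size
  }
  w32(ifd_off[1])
  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count)
    if (type == 3L) { w16(value); w16(0L) } else w32(value)
  }
  sample_format <- if (float) 3L else 1L
  for (k in seq_len(nz)) {
    page <- t(values[, , k])        # row-major of the page image
    if (float) {
      writeBin(as.numeric(page), con, size = bytes_pp, endian = "little")
    } else if (bits == 8L) {
      writeBin(as.raw(as.integer(page)), con)
    } else {
      v <- as.integer(page)
      if (bits == 16L) {
        # writeBin size=2 expects signed; map 32768..65535 into negative space
        v <- ifelse(v > 32767L, v - 65536L, v)
      }
      writeBin(v, con, size = bytes_pp, endian = "little")
    }
    w16(10L)
    entry(256L, 4L, 1L, ny)          # ImageWidth (columns)
    entry(257L, 4L, 1L, nx)          # ImageLength (rows)
    entry(258L, 3L, 1L, bits)        # BitsPerSample
    entry(259L, 3L, 1L, 1L)          # Compression: none
    entry(262L, 3L, 1L, 1L)          # Photometric: BlackIsZero
    entry(273L, 4L, 1L, strip_off[k])
    entry(277L, 3L, 1L, 1L)          # SamplesPerPixel
    entry(278L, 4L, 1L, nx)          # RowsPerStrip
    entry(279L, 4L, 1L, strip_len)
    entry(339L, 3L, 1L, sample_format)
    w32(if (k < nz) ifd_off[k + 1] else 0L)
  }
  invisible(path)
}

read_tiff_stack <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  rd <- function(off, what, n, size, signed = TRUE)
    readBin(bytes[(off + 1L):length(bytes)], what = what, n = n, size = size,
            signed = signed, endian = "little")
  if (rawToChar(bytes[1:2]) != "II")
    stop("only little-endian TIFF supported", call. = FALSE)
  if (rd(2L, "integer", 1L, 2L, signed = FALSE) != 42L)
    stop("not a TIFF file", call. = FALSE)
  ifd <- rd(4L, "integer", 1L, 4L)
  pages <- list()
  while (ifd != 0L) {
    nent <- rd(ifd, "integer", 1L, 2L, signed = FALSE)
    tags <- list()
    for (e in seq_len(nent)) {
      off <- ifd + 2L + (e - 1L) * 12L
      tag <- rd(off, "integer", 1L, 2L, signed = FALSE)
      type <- rd(off + 2L, "integer", 1L, 2L, signed = FALSE)
      count <- rd(off + 4L, "integer", 1L, 4L)
      tsize <- c(1L, 1L, 2L, 4L)[match(type, c(1L, 2L, 3L, 4L))]
      if (is.na(tsize)) next
      vals <- if (tsize * count <= 4L) {
        rd(off + 8L, "integer", count, tsize, signed = tsize > 2L)
      } else {
        voff <- rd(off + 8L, "integer", 1L, 4L)
        rd(voff, "integer", count, tsize, signed = tsize > 2L)
      }
      vals[vals < 0] <- vals[vals < 0] + 2^32
      tags[[as.character(tag)]] <- vals
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop(sprintf("TIFF tag %d missing", tag), call. = FALSE)
        default
      } else v
    }
    width <- need(256L); height <- need(257L)
    bits <- need(258L, 1L)[1]
    if (need(259L, 1L)[1] != 1L)
      stop("compressed TIFF unsupported", call. = FALSE)
    if (need(277L, 1L)[1] != 1L)
      stop("multi-sample TIFF unsupported", call. = FALSE)
    fmt <- need(339L, 1L)[1]
    offs <- need(273L); counts <- need(279L)
    bpp <- bits / 8L
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      n <- counts[s] / bpp
      v <- if (fmt == 3L) {
        rd(offs[s], "double", n, bpp)
      } else if (bpp == 1L) {
        as.numeric(rd(offs[s], "integer", n, 1L, signed = fmt == 2L))
      } else if (bpp == 2L) {
        as.numeric(rd(offs[s], "integer", n, 2L, signed = fmt == 2L))
      } else {
        x <- as.numeric(rd(offs[s], "integer", n, 4L, signed = TRUE))
        if (fmt == 1L) x[x < 0] <- x[x < 0] + 2^32
        x
      }
      vals <- c(vals, v)
    }
    pages[[length(pages) + 1L]] <- t(matrix(vals, nrow = width, ncol = height))
    ifd <- rd(ifd + 2L + nent * 12L, "integer", 1L, 4L)
  }
  if (!length(pages)) stop("TIFF contains no pages", call. = FALSE)
  d1 <- nrow(pages[[1]]); d2 <- ncol(pages[[1]])
  arr <- array(0, dim = c(d1, d2, length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  arr
}
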