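# Minimal baseline TIFF 6.0 I/O: little-endian, uncompressed, single-sample
# grayscale, 8- or 16-bit unsigned, one strip per page, multi-page. Enough to
# round-trip exported microscopy channels; compressed/tiled/planar TIFFs are
# rejected with a clear error. No timestamps are written, so output is
# byte-reproducible.

TIFF_TAGS <- c(
  ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
  Compression = 259L, Photometric = 262L, StripOffsets = 273L,
  SamplesPerPixel = 277L, RowsPerStrip = 278L, StripByteCounts = 279L
)

u16_to_raw <- function(v) {
  v <- as.integer(round(v))
  as.raw(as.vector(rbind(v %% 256L, v %/% 256L)))
}
u32_to_raw <- function(v) {
  v <- as.numeric(v)
  as.raw(as.vector(rbind(
    v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256, (v %/% 16777216) %% 256
  )))
}
#' Write grayscale images to a multi-page TIFF
#'
#' Writes one page per image as uncompressed little-endian baseline TIFF.
#' Intensities are rounded and clipped to the unsigned range of `bits`.
#'
#' @param images A [fluor_image()], numeric matrix, or list thereof.
#' @param path Output file path.
#' @param bits Bits per sample: 8 or 16 (default).
#' @return `path`, invisibly.
#' @export
write_tiff_gray <- function(images, path, bits = 16L) {
  if (!is.list(images)) images <- list(images)
  if (!bits %in% c(8L, 16L)) ect_error("bits must be 8 or 16", "ect_invalid_input")
  maxv <- 2^bits - 1
  con <- file(path, "wb")
  on.exit(close(con))
  # header: II, magic 42, offset of first IFD (filled after layout)
  pages <- lapply(images, function(im) {
    m <- unclass(as_fluor_image(im))
    v <- pmin(maxv, pmax(0, round(t(m)))) # TIFF stores rows of the image
    if (bits == 8L) as.raw(as.vector(v)) else u16_to_raw(as.vector(v))
  })
  dims <- lapply(images, function(im) dim(as_fluor_image(im)))
  # layout: 8-byte header, then per page [pixel data][IFD]
  offset <- 8
  ifd_entries <- 9L
  ifd_size <- 2 + ifd_entries * 12 + 4
  pixel_off <- numeric(length(pages))
  ifd_off <- numeric(length(pages))
  for (i in seq_along(pages)) {
    pixel_off[i] <- offset
    ifd_off[i] <- offset + length(pages[[i]])
    offset <- ifd_off[i] + ifd_size
  }
  writeBin(charToRaw("II"), con)
  writeBin(u16_to_raw(42L), con)
  writeBin(u32_to_raw(ifd_off[1]), con)
  entry <- function(tag, type, count, value) {
    c(u16_to_raw(tag), u16_to_raw(type), u32_to_raw(count), u32_to_raw(value))
  }
  for (i in seq_along(pages)) {
    writeBin(pages[[i]], con)
    nr <- dims[[i]][1]
    nc <- dims[[i]][2]
    e <- c(
      entry(TIFF_TAGS["ImageWidth"], 4L, 1L, nc),
      entry(TIFF_TAGS["ImageLength"], 4L, 1L, nr),
      entry(TIFF_TAGS["BitsPerSample"], 3L, 1L, bits),
      entry(TIFF_TAGS["Compression"], 3L, 1L, 1L),
      entry(TIFF_TAGS["Photometric"], 3L, 1L, 1L),
      entry(TIFF_TAGS["StripOffsets"], 4L, 1L, pixel_off[i]),
      entry(TIFF_TAGS["SamplesPerPixel"], 3L, 1L, 1L),
      entry(TIFF_TAGS["RowsPerStrip"], 4L, 1L, nr),
      entry(TIFF_TAGS["StripByteCounts"], 4L, 1L, length(pages[[i]]))
    )
    next_ifd <- if (i < length(pages)) ifd_off[i + 1] else 0
    writeBin(c(u16_to_raw(ifd_entries), e, u32_to_raw(next_ifd)), con)
  }
  invisible(path)
}

#' Read a grayscale multi-page TIFF
#'
#' Supports the subset written by [write_tiff_gray()]: little-endian,
#' uncompressed, single-sample 8/16-bit grayscale.
#'
#' @param path TIFF file path.
#' @param channel Channel label attached to the returned images.
#' @return A list of [fluor_image()] objects, one per page.
#' @export
read_tiff_gray <- function(path, channel = "DAPI") {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8) ect_error("not a TIFF file", "ect_invalid_input")
  if (rawToChar(raw[1:2]) == "MM") ect_error("big-endian TIFF not supported", "ect_io_unsupported")
  if (rawToChar(raw[1:2]) != "II") ect_error("not a TIFF file", "ect_invalid_input")
  rd_u <- function(at, size) sum(as.integer(raw[at + seq_len(size) - 1]) * 256^(seq_len(size) - 1))
  ifd_off <- rd_u(5, 4)
  out <- list()
  while (ifd_off != 0) {
    n_entries <- rd_u(ifd_off + 1, 2)
    tags <- list()
    for (k in seq_len(n_entries)) {
      at <- ifd_off + 2 + (k - 1) * 12 + 1
      tag <- rd_u(at, 2)
      type <- rd_u(at + 2, 2)
      val <- if (type == 3L) rd_u(at + 8, 2) else rd_u(at + 8, 4)
      tags[[as.character(tag)]] <- val
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(TIFF_TAGS[tag])]]
      if (is.null(v)) {
        if (is.null(default)) ect_error(sprintf("TIFF missing tag %s", tag), "ect_io_unsupported")
        v <- default
      }
      v
    }
    if (need("Compression", 1L) != 1L) ect_error("compressed TIFF not supported", "ect_io_unsupported")
    if (need("SamplesPerPixel", 1L) != 1L) ect_error("multi-sample TIFF not supported", "ect_io_unsupported")
    bits <- need("BitsPerSample", 8L)
    if (!bits %in% c(8L, 16L)) ect_error("only 8/16-bit TIFF supported", "ect_io_unsupported")
    nc <- need("ImageWidth")
    nr <- need("ImageLength")
    off <- need("StripOffsets")
    nbytes <- need("StripByteCounts")
    bytes <- raw[off + seq_len(nbytes)]
    vals <- if (bits == 8L) {
      as.integer(bytes)
    } else {
      m <- matrix(as.integer(bytes), nrow = 2)
      m[1, ] + 256L * m[2, ]
    }
    img <- t(matrix(vals, nrow = nc, ncol = nr)) # stored row-wise
    out[[length(out) + 1L]] <- fluor_image(img, channel = channel)
    ifd_off <- rd_u(ifd_off + 2 + n_entries * 12 + 1, 4)
  }
  out
}
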