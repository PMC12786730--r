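#' Read an 8-bit RGB baseline TIFF tile
#'
#' Minimal reader for uncompressed, chunky (interleaved), 8-bit-per-sample
#' RGB baseline TIFF -- the format written by [write_tiff_rgb()] and by most
#' scientific tools when asked for uncompressed RGB TIFF. Both byte orders
#' are supported. The physical pixel size is recovered from the
#' XResolution/ResolutionUnit tags when present.
#'
#' @param path file path.
#' @return list with `rgb` (integer array `h x w x 3`) and `pixel_size_um`
#'   (`NULL` when the file carries no resolution tags).
#' @export
read_tiff_rgb <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  bom <- rawToChar(raw[1:2])
  endian <- if (bom == "II") "little" else if (bom == "MM") "big" else
    stop("not a TIFF file (bad byte-order mark): ", path)
  rd <- function(off, what, size, n = 1, signed = TRUE)
    readBin(raw[(off + 1):(off + size * n)], what, n = n, size = size,
            endian = endian, signed = signed)
  if (rd(2, "integer", 2, signed = FALSE) != 42L)
    stop("not a TIFF file (bad magic): ", path)
  ifd_off <- rd(4, "integer", 4)
  n_entries <- rd(ifd_off, "integer", 2, signed = FALSE)

  tags <- list()
  type_size <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)
  for (e in seq_len(n_entries)) {
    base <- ifd_off + 2 + (e - 1) * 12
    tag <- rd(base, "integer", 2, signed = FALSE)
    type <- rd(base + 2, "integer", 2, signed = FALSE)
    count <- rd(base + 4, "integer", 4)
    nbytes <- type_size[type] * count
    voff <- if (nbytes > 4) rd(base + 8, "integer", 4) else base + 8
    vals <- switch(as.character(type),
      "3" = rd(voff, "integer", 2, n = count, signed = FALSE),
      "4" = rd(voff, "integer", 4, n = count),
      "5" = {  # RATIONAL: pairs of unsigned longs
        v <- rd(voff, "integer", 4, n = 2 * count)
        v[seq(1, 2 * count, 2)] / v[seq(2, 2 * count, 2)]
      },
      "1" = as.integer(raw[(voff + 1):(voff + count)]),
      rd(voff, "integer", 4))
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) stop("TIFF tag ", tag, " missing in ", path)
    v
  }
  w <- need(256); h <- need(257)
  comp <- if (is.null(tags[["259"]])) 1L else tags[["259"]][1]
  if (comp != 1L) stop("only uncompressed TIFF is supported")
  spp <- if (is.null(tags[["277"]])) 1L else tags[["277"]][1]
  if (spp != 3L) stop("expected a 3-sample (RGB) TIFF")
  bps <- tags[["258"]]
  if (!is.null(bps) && any(bps != 8)) stop("expected 8 bits per sample")
  offs <- need(273)
  counts <- need(279)
  px <- raw(0)
  for (s in seq_along(offs))
    px <- c(px, raw[(offs[s] + 1):(offs[s] + counts[s])])
  if (length(px) != w * h * 3) stop("TIFF pixel data size mismatch")
  arr <- aperm(array(as.integer(px), dim = c(3, w, h)), c(3, 2, 1))

  pixel_size_um <- NULL
  if (!is.null(tags[["282"]])) {
    unit <- if (is.null(tags[["296"]])) 2L else tags[["296"]][1]
    per_um <- switch(as.character(unit),
                     "3" = tags[["282"]][1] / 1e4,   # pixels per cm
                     "2" = tags[["282"]][1] / 25400, # pixels per inch
                     NULL)
    if (!is.null(per_um) && per_um > 0) pixel_size_um <- 1 / per_um
  }
  list(rgb = arr, pixel_size_um = pixel_size_um)
}

#' Write an 8-bit RGB array as an uncompressed baseline TIFF
#'
#' Single-strip, little-endian, chunky RGB. The pixel size (um/pixel) is
#' encoded in XResolution/YResolution with ResolutionUnit = cm so that
#' [read_tiff_rgb()] and standard viewers recover it.
#'
#' @param rgb integer array `h x w x 3`, values 0-255.
#' @param path output file path.
#' @param pixel_size_um physical pixel size in micrometres (optional).
#' @return `path`, invisibly.
#' @export
write_tiff_rgb <- function(rgb, path, pixel_size_um = NULL) {
  d <- dim(rgb)
  if (length(d) != 3L || d[3] != 3L) stop("rgb must be h x w x 3")
  h <- d[1]; w <- d[2]
  if (min(rgb) < 0 || max(rgb) > 255) stop("rgb values must be in [0, 255]")

  has_res <- !is.null(pixel_size_um)
  entries <- list(
    list(256L, 4L, 1L, w),                 # ImageWidth
    list(257L, 4L, 1L, h),                 # ImageLength
    list(258L, 3L, 3L, NA),                # BitsPerSample -> ext
    list(259L, 3L, 1L, 1L),                # Compression = none
    list(262L, 3L, 1L, 2L),                # Photometric = RGB
    list(273L, 4L, 1L, NA),                # StripOffsets -> data
    list(277L, 3L, 1L, 3L),                # SamplesPerPixel
    list(278L, 4L, 1L, h),                 # RowsPerStrip
    list(279L, 4L, 1L, w * h * 3L),        # StripByteCounts
    list(284L, 3L, 1L, 1L))                # PlanarConfiguration = chunky
  if (has_res) {
    entries <- c(entries, list(
      list(282L, 5L, 1L, NA),              # XResolution -> ext
      list(283L, 5L, 1L, NA),              # YResolution -> ext
      list(296L, 3L, 1L, 3L)))             # ResolutionUnit = cm
  }
  entries <- entries[order(vapply(entries, function(e) e[[1]], 0L))]
  n <- length(entries)
  ifd_off <- 8L
  ifd_size <- 2L + n * 12L + 4L
  ext_off <- ifd_off + ifd_size
  bps_off <- ext_off                        # 3 shorts = 6 bytes
  xres_off <- ext_off + 6L                  # 8 bytes each rational
  yres_off <- xres_off + 8L
  data_off <- if (has_res) yres_off + 8L else ext_off + 6L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL)
  wr(42L, 2); wr(ifd_off, 4)
  wr(n, 2)
  for (e in entries) {
    wr(e[[1]], 2); wr(e[[2]], 2); wr(e[[3]], 4)
    val <- e[[4]]
    if (e[[1]] == 258L) val <- bps_off
    if (e[[1]] == 273L) val <- data_off
    if (e[[1]] == 282L) val <- xres_off
    if (e[[1]] == 283L) val <- yres_off
    if (e[[2]] == 3L && e[[3]] == 1L) { wr(val, 2); wr(0L, 2) }
    else wr(val, 4)
  }
  wr(0L, 4)                                 # next IFD = none
  wr(c(8L, 8L, 8L), 2)                      # BitsPerSample
  if (has_res) {
    # pixels per cm as a rational with denominator 1000
    num <- round(1e4 / pixel_size_um * 1000)
    wr(c(num, 1000L), 4)                    # XResolution
    wr(c(num, 1000L), 4)                    # YResolution
  }
  writeBin(as.raw(aperm(rgb, c(3, 2, 1))), con)
  invisible(path)
}
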