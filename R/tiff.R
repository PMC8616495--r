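#' Minimal multi-page TIFF writer (16-bit grayscale, uncompressed)
#'
#' The environment this package targets has no TIFF package, so a minimal
#' baseline-TIFF codec is included for the movie interchange format: little
#' endian, one strip per page, 16-bit unsigned grayscale, no compression.
#' This is deliberately the smallest spec-compliant subset; arbitrary TIFFs
#' from other software are outside its scope (the paired reader checks for
#' the subset it writes).
#'
#' @param pages list of numeric matrices with values in `[0, 1]` (quantized
#'   to 16 bits) or integer matrices already on `[0, 65535]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1)
  to_u16 <- function(m) {
    if (is.double(m)) m <- round(pmin(pmax(m, 0), 1) * 65535)
    storage.mode(m) <- "integer"
    m
  }
  pages <- lapply(pages, to_u16)
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L); w4(8L)  # header; first IFD at 8
  offset <- 8
  n_tags <- 8L
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    h <- nrow(m); w <- ncol(m)
    ifd_size <- 2 + n_tags * 12 + 4
    data_off <- offset + ifd_size
    nbytes <- 2 * h * w
    next_ifd <- if (i < length(pages)) data_off + nbytes else 0L
    w2(n_tags)
    tag <- function(id, type, count, value) { w2(id); w2(type); w4(count); w4(value) }
    tag(256L, 3L, 1L, w)            # ImageWidth
    tag(257L, 3L, 1L, h)            # ImageLength
    tag(258L, 3L, 1L, 16L)          # BitsPerSample
    tag(259L, 3L, 1L, 1L)           # Compression: none
    tag(262L, 3L, 1L, 1L)           # Photometric: BlackIsZero
    tag(273L, 4L, 1L, data_off)     # StripOffsets
    tag(278L, 3L, 1L, h)            # RowsPerStrip
    tag(279L, 4L, 1L, nbytes)       # StripByteCounts
    w4(next_ifd)
    # pixel data, row-major as TIFF requires
    writeBin(as.integer(t(m)), con, size = 2, endian = "little")
    offset <- data_off + nbytes
  }
  invisible(path)
}

#' Minimal multi-page TIFF reader (subset paired with [write_tiff()])
#'
#' Reads little-endian, uncompressed, single-strip-per-IFD grayscale TIFFs
#' (8 or 16 bit) such as those produced by [write_tiff()].
#'
#' @param path TIFF file path.
#' @param rescale divide by the dtype maximum so intensities land in
#'   `[0, 1]` (default `TRUE`).
#' @return List of numeric matrices, one per page.
#' @export
read_tiff <- function(path, rescale = TRUE) {
  raw <- readBin(path, "raw", file.size(path))
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1])
  u32 <- function(i) as.integer(raw[i]) + 256 * as.integer(raw[i + 1]) +
    65536 * as.integer(raw[i + 2]) + 16777216 * as.integer(raw[i + 3])
  if (rawToChar(raw[1:2]) != "II" || u16(3) != 42L)
    stop("not a little-endian TIFF file")
  off <- u32(5)
  pages <- list()
  while (off != 0) {
    n <- u16(off + 1)
    tags <- list()
    for (k in seq_len(n)) {
      base <- off + 2 + (k - 1) * 12
      tags[[as.character(u16(base + 1))]] <- u32(base + 9)
    }
    need <- c("256", "257", "273", "279")
    if (!all(need %in% names(tags))) stop("unsupported TIFF structure")
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1)
      stop("compressed TIFFs are not supported")
    w <- tags[["256"]]; h <- tags[["257"]]
    bits <- if (is.null(tags[["258"]])) 1L else tags[["258"]]
    if (!bits %in% c(8L, 16L)) stop("only 8/16-bit grayscale supported")
    dstart <- tags[["273"]]
    npx <- h * w
    if (bits == 16L) {
      v <- readBin(raw[(dstart + 1):(dstart + 2 * npx)], "integer",
                   n = npx, size = 2, endian = "little", signed = FALSE)
    } else {
      v <- as.integer(raw[(dstart + 1):(dstart + npx)])
    }
    m <- matrix(v, nrow = h, ncol = w, byrow = TRUE)
    if (rescale) m <- m / (2^bits - 1)
    pages[[length(pages) + 1L]] <- m
    off <- u32(off + 2 + n * 12 + 1)
  }
  pages
}

#' Write a rendered movie to disk
#'
#' One multi-page TIFF per frame (pages are the focal planes) plus a JSON
#' sidecar with the acquisition geometry, generation parameters and the
#' ground-truth footprint series.
#'
#' @param movie an `agg_movie` from [render_movie()].
#' @param dir output directory (created if needed).
#' @param overwrite allow writing into a non-empty movie directory.
#' @return `dir`, invisibly.
#' @export
write_movie <- function(movie, dir, overwrite = FALSE) {
  stopifnot(inherits(movie, "agg_movie"))
  if (is.null(movie$frames))
    stop("movie was rendered in streaming mode; nothing to write")
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop("output directory is not empty (use overwrite = TRUE)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in seq_along(movie$frames))
    write_tiff(movie$frames[[f]]$planes,
               file.path(dir, sprintf("frame_%04d.tif", f - 1L)))
  sidecar <- list(geometry = unclass(movie$geometry),
                  model = unclass(movie$model), params = movie$params,
                  target = movie$target,
                  truth_footprint_px = movie$truth$footprint_px)
  jsonlite::write_json(sidecar, file.path(dir, "movie.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a movie directory written by [write_movie()]
#'
#' @param dir movie directory containing `frame_*.tif` and `movie.json`.
#' @return List with `stacks` (list of [image_stack]) and `sidecar` (parsed
#'   JSON metadata).
#' @export
read_movie <- function(dir) {
  side_path <- file.path(dir, "movie.json")
  if (!file.exists(side_path))
    stop("missing sidecar 'movie.json' in ", dir)
  sidecar <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.tif$",
                           full.names = TRUE))
  px <- sidecar$geometry$pixel_size
  stacks <- lapply(seq_along(files), function(i)
    image_stack(read_tiff(files[i]), pixel_size = px, time_index = i - 1L))
  list(stacks = stacks, sidecar = sidecar)
}
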