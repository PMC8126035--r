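#' RGB micrograph container
#'
#' Wraps an 8-bit, 3-channel raster together with optional physical pixel
#' size and a source identifier. All pipeline functions consume and return
#' this container.
#'
#' @param pixels numeric or integer array of dimension `height x width x 3`
#'   with intensities in `[0, 255]`.
#' @param pixel_size_um micrometres per pixel, or `NULL` if unknown.
#' @param id source identifier (typically the file stem).
#' @return An object of class `rgb_image`: a list with elements `pixels`
#'   (integer array), `pixel_size_um` and `id`.
#' @export
rgb_image <- function(pixels, pixel_size_um = NULL, id = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("'pixels' must be a height x width x 3 array", call. = FALSE)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("intensities must lie in [0, 255]", call. = FALSE)
  # strip reader metadata attributes and force plain integer storage
  pixels <- array(as.integer(round(as.vector(pixels))), dim = dim(pixels))
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um, id = id),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image> %d x %d px", d[1], d[2]))
  if (!is.null(x$pixel_size_um))
    cat(sprintf(", %.3g um/px", x$pixel_size_um))
  if (!is.null(x$id)) cat(sprintf(", id = %s", x$id))
  cat("\n")
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$pixels)

png_header_info <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", n = 26L)
  if (length(raw) < 26L) stop("file too short to be a PNG: ", path, call. = FALSE)
  list(bit_depth = as.integer(raw[25]), color_type = as.integer(raw[26]))
}

#' Read an 8-bit RGB micrograph
#'
#' Reads a PNG or TIFF file and validates that it is a three-channel, 8-bit
#' image. Greyscale, paletted, alpha-carrying and deeper-than-8-bit inputs
#' are rejected so that downstream intensity assumptions hold.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param pixel_size_um micrometres per pixel to attach, or `NULL`.
#' @param id identifier to attach; defaults to the file stem.
#' @return An [rgb_image].
#' @export
read_image <- function(path, pixel_size_um = NULL, id = NULL) {
  if (!file.exists(path)) stop("cannot read image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  if (ext == "png") {
    hdr <- png_header_info(path)
    if (hdr$bit_depth != 8L)
      stop(sprintf("unsupported PNG bit depth %d (need 8-bit): %s",
                   hdr$bit_depth, path), call. = FALSE)
    if (hdr$color_type != 2L)
      stop(sprintf("unsupported PNG colour type %d (need 8-bit RGB, type 2): %s",
                   hdr$color_type, path), call. = FALSE)
    a <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path, info = TRUE)
    bps <- attr(a, "bits.per.sample")
    if (!is.null(bps) && any(bps != 8L))
      stop(sprintf("unsupported TIFF bit depth %s (need 8-bit): %s",
                   paste(bps, collapse = "/"), path), call. = FALSE)
  } else {
    stop("unsupported image format '", ext, "' (PNG or TIFF expected)",
         call. = FALSE)
  }
  if (length(dim(a)) != 3L || dim(a)[3] != 3L)
    stop(sprintf("image is not 3-channel RGB (channels: %s): %s",
                 if (length(dim(a)) == 3L) dim(a)[3] else 1L, path),
         call. = FALSE)
  rgb_image(round(a * 255), pixel_size_um = pixel_size_um, id = id)
}

#' Write an RGB micrograph
#'
#' @param img an [rgb_image].
#' @param path output path; format chosen from the extension (`.png`,
#'   `.tif`/`.tiff`). PNG writing is lossless and round-trips exactly.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  a <- img$pixels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(a, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(a, path, bits.per.sample = 8L)
  } else {
    stop("unsupported image format '", ext, "'", call. = FALSE)
  }
  invisible(path)
}

#' Background removal configuration
#'
#' Bright, unstained slide regions (empty resin, lumina of blood lacunae)
#' have high green and blue intensities, while eosin-stained tissue has a
#' suppressed green channel. A pixel is classified background when its green
#' AND blue intensities both reach their thresholds.
#'
#' @param green_threshold,blue_threshold intensities in `[0, 255]`.
#' @return An object of class `background_config`.
#' @export
background_config <- function(green_threshold = 200, blue_threshold = 200) {
  for (v in c(green_threshold, blue_threshold))
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 255)
      stop("thresholds must be single numbers in [0, 255]", call. = FALSE)
  structure(list(green_threshold = green_threshold,
                 blue_threshold = blue_threshold),
            class = "background_config")
}

#' Compute the tissue mask of a micrograph
#'
#' @param img an [rgb_image].
#' @param cfg a [background_config].
#' @return A logical `height x width` matrix; `TRUE` marks retained tissue
#'   pixels, `FALSE` marks bright background.
#' @export
background_mask <- function(img, cfg = background_config()) {
  stopifnot(inherits(img, "rgb_image"), inherits(cfg, "background_config"))
  d <- dim(img$pixels)
  g <- matrix(img$pixels[, , 2], d[1], d[2])
  b <- matrix(img$pixels[, , 3], d[1], d[2])
  !(g >= cfg$green_threshold & b >= cfg$blue_threshold)
}
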