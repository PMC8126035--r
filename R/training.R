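#' Load hemocyte annotations
#'
#' Annotations are axis-aligned rectangles marking individual granular
#' hemocytes on calibration micrographs, produced once during the
#' calibration phase in any external editor. The JSON format is
#' `[{"image": "<id>", "rect": [row0, col0, n_rows, n_cols]}, ...]` with
#' 0-based, half-open pixel coordinates.
#'
#' @param path path to the annotation JSON file.
#' @param images optional named list of [rgb_image]s; when given, each
#'   rectangle is checked to lie fully inside its image.
#' @return A data frame with columns `image`, `r0`, `c0`, `nr`, `nc`.
#' @export
load_annotations <- function(path, images = NULL) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(doc) == 0L)
    stop("annotation file contains no annotations: ", path, call. = FALSE)
  rows <- lapply(seq_along(doc), function(i) {
    a <- doc[[i]]
    if (is.null(a$image) || is.null(a$rect) || length(a$rect) != 4L)
      stop(sprintf("annotation %d is malformed (need 'image' and 4-element 'rect')", i),
           call. = FALSE)
    data.frame(image = as.character(a$image),
               r0 = as.integer(a$rect[[1]]), c0 = as.integer(a$rect[[2]]),
               nr = as.integer(a$rect[[3]]), nc = as.integer(a$rect[[4]]),
               stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, rows)
  validate_annotations(ann, images)
  ann
}

#' Validate annotation rectangles
#'
#' @param ann annotation data frame as returned by [load_annotations()].
#' @param images optional named list of [rgb_image]s for bounds checking.
#' @return `ann`, invisibly; stops with an informative error on violation.
#' @export
validate_annotations <- function(ann, images = NULL) {
  stopifnot(is.data.frame(ann),
            all(c("image", "r0", "c0", "nr", "nc") %in% names(ann)))
  bad <- which(ann$nr < 3L | ann$nc < 3L | ann$r0 < 0L | ann$c0 < 0L)
  if (length(bad))
    stop(sprintf("annotation %d on image '%s' is degenerate (rect %d,%d,%d,%d; need nr,nc >= 3 and r0,c0 >= 0)",
                 bad[1], ann$image[bad[1]], ann$r0[bad[1]], ann$c0[bad[1]],
                 ann$nr[bad[1]], ann$nc[bad[1]]), call. = FALSE)
  if (!is.null(images)) {
    for (i in seq_len(nrow(ann))) {
      img <- images[[ann$image[i]]]
      if (is.null(img))
        stop(sprintf("annotation %d references unknown image '%s'", i, ann$image[i]),
             call. = FALSE)
      d <- dim(img$pixels)
      if (ann$r0[i] + ann$nr[i] > d[1] || ann$c0[i] + ann$nc[i] > d[2])
        stop(sprintf("annotation %d on image '%s' exceeds image bounds (%d x %d)",
                     i, ann$image[i], d[1], d[2]), call. = FALSE)
    }
  }
  invisible(ann)
}

#' Assemble the hemocyte-only training mosaic
#'
#' Crops every annotated rectangle from its source image, removes residual
#' bright background inside each crop with the green/blue rule, and packs
#' the tiles row-wise onto a mosaic padded with a pure-white sentinel. The
#' padding between tiles is at least `2 * window_radius + 1` pixels so no
#' unfolding window can span two different cells, and sentinel pixels are
#' marked invalid so they never enter the colour/texture model.
#'
#' @param images named list of [rgb_image]s (names are image ids).
#' @param ann annotation data frame (see [load_annotations()]).
#' @param cfg a [background_config].
#' @param window_radius neighbourhood radius the mosaic must support.
#' @return An object of class `training_image`: list with `mosaic`
#'   ([rgb_image]), `valid` (logical matrix, `TRUE` on hemocyte pixels),
#'   `provenance` (one row per tile) and `window_radius`.
#' @export
assemble_training_image <- function(images, ann, cfg = background_config(),
                                    window_radius = 2) {
  if (is.null(ann) || nrow(ann) == 0L)
    stop("no annotations supplied: cannot assemble an empty training image",
         call. = FALSE)
  validate_annotations(ann, images)
  pad <- 2L * as.integer(window_radius) + 1L
  n <- nrow(ann)

  crops <- vector("list", n)
  for (i in seq_len(n)) {
    img <- images[[ann$image[i]]]
    rs <- (ann$r0[i] + 1L):(ann$r0[i] + ann$nr[i])
    cs <- (ann$c0[i] + 1L):(ann$c0[i] + ann$nc[i])
    px <- img$pixels[rs, cs, , drop = FALSE]
    sub <- rgb_image(px)
    v <- background_mask(sub, cfg)
    if (!any(v))
      warning(sprintf("annotation %d on image '%s' is entirely background; tile contributes no training pixels",
                      i, ann$image[i]), call. = FALSE)
    crops[[i]] <- list(px = px, valid = v)
  }

  # row-wise shelf packing
  widths <- ann$nc
  heights <- ann$nr
  target_w <- max(widths) * ceiling(sqrt(n)) + pad * (ceiling(sqrt(n)) + 1L)
  off <- matrix(0L, n, 2)
  cur_r <- pad; cur_c <- pad; shelf_h <- 0L
  for (i in seq_len(n)) {
    if (cur_c + widths[i] + pad > target_w && cur_c > pad) {
      cur_r <- cur_r + shelf_h + pad
      cur_c <- pad
      shelf_h <- 0L
    }
    off[i, ] <- c(cur_r, cur_c)          # 0-based placement offset
    cur_c <- cur_c + widths[i] + pad
    shelf_h <- max(shelf_h, heights[i])
  }
  H <- cur_r + shelf_h + pad
  W <- target_w

  mosaic <- array(255L, dim = c(H, W, 3L))
  valid <- matrix(FALSE, H, W)
  for (i in seq_len(n)) {
    rs <- (off[i, 1] + 1L):(off[i, 1] + heights[i])
    cs <- (off[i, 2] + 1L):(off[i, 2] + widths[i])
    mosaic[rs, cs, ] <- crops[[i]]$px
    valid[rs, cs] <- crops[[i]]$valid
  }

  prov <- cbind(ann, off_r = off[, 1], off_c = off[, 2])
  structure(list(mosaic = rgb_image(mosaic, id = "training-mosaic"),
                 valid = valid, provenance = prov,
                 window_radius = as.integer(window_radius)),
            class = "training_image")
}

#' @export
print.training_image <- function(x, ...) {
  d <- dim(x$mosaic$pixels)
  cat(sprintf("<training_image> %d tiles, mosaic %d x %d px, %d hemocyte pixels\n",
              nrow(x$provenance), d[1], d[2], sum(x$valid)))
  invisible(x)
}
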