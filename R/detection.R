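#' Consolidate a thresholded score mask
#'
#' Granule-level thresholding fragments cell interiors; morphological
#' closing with a disk followed by hole filling consolidates each cell into
#' one countable object. Radius 0 with hole filling off is the identity.
#'
#' @param mask logical matrix.
#' @param closing_radius disk radius in pixels (`>= 0`).
#' @param fill_holes fill enclosed holes after closing?
#' @return Logical matrix.
#' @export
clean_mask <- function(mask, closing_radius = 1, fill_holes = TRUE) {
  stopifnot(is.logical(mask), closing_radius >= 0)
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  if (closing_radius > 0) {
    kern <- EBImage::makeBrush(2L * as.integer(closing_radius) + 1L, "disc")
    m <- EBImage::closing(m, kern)
  }
  if (fill_holes) m <- EBImage::fillHull(m)
  matrix(as.vector(m) > 0, nrow(mask), ncol(mask))
}

#' Label connected components
#'
#' Maximal connected regions of `TRUE` pixels under 4- or 8-connectivity,
#' labelled 1..K in column-major scan order of first encounter.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of labels (0 = background).
#' @export
label_objects <- function(mask, connectivity = 8) {
  stopifnot(is.logical(mask), connectivity %in% c(4, 8))
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, h, w)
  if (length(idx) == 0L) return(lab)
  pid <- matrix(0L, h, w)
  pid[idx] <- seq_along(idx)

  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- vector("list", length(offs))
  for (k in seq_along(offs)) {
    dy <- offs[[k]][1]; dx <- offs[[k]][2]
    r1 <- seq_len(h - abs(dy) * (dy != 0))
    if (dy > 0) r1 <- seq_len(h - dy)
    c1 <- if (dx >= 0) seq_len(w - dx) else (1L - dx):w
    a <- pid[r1, c1, drop = FALSE]
    b <- pid[r1 + dy, c1 + dx, drop = FALSE]
    keep <- a > 0L & b > 0L
    edges[[k]] <- cbind(a[keep], b[keep])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(el) > 0) g <- igraph::add_edges(g, t(el))
  memb <- igraph::components(g)$membership
  relab <- match(memb, unique(memb))      # idx is ascending column-major
  lab[idx] <- relab
  lab
}

# Perimeter estimate: (pi/4) * number of exposed pixel edges (crack edges).
# Each unit crack edge is weighted pi/4, the Cauchy-Crofton correction that
# makes the estimate unbiased for smooth convex outlines (a digital disk of
# radius r has about 8r crack edges and true perimeter 2*pi*r).
crack_perimeter <- function(obj) {
  h <- nrow(obj); w <- ncol(obj)
  p <- matrix(FALSE, h + 2L, w + 2L)
  p[2:(h + 1), 2:(w + 1)] <- obj
  core <- p[2:(h + 1), 2:(w + 1)]
  exposed <- (core & !p[1:h, 2:(w + 1)]) + (core & !p[3:(h + 2), 2:(w + 1)]) +
             (core & !p[2:(h + 1), 1:w]) + (core & !p[2:(h + 1), 3:(w + 2)])
  (pi / 4) * sum(exposed)
}

# Pixel count of the filled convex hull of a set of pixel centres.
convex_fill_area <- function(rows, cols) {
  n <- length(rows)
  pts <- unique(cbind(rows, cols))
  if (nrow(pts) < 3L) return(n)
  hull <- grDevices::chull(pts[, 2], pts[, 1])   # x = col, y = row
  if (length(hull) < 3L) return(n)
  hx <- pts[hull, 2]; hy <- pts[hull, 1]
  rr <- seq(min(rows), max(rows)); cc <- seq(min(cols), max(cols))
  gy <- rep(rr, times = length(cc)); gx <- rep(cc, each = length(rr))
  inside <- rep(TRUE, length(gy))
  m <- length(hull)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    # chull returns vertices clockwise in (x, y); interior has cross <= 0
    cross <- (hx[j] - hx[i]) * (gy - hy[i]) - (hy[j] - hy[i]) * (gx - hx[i])
    inside <- inside & cross <= 1e-9
  }
  max(sum(inside), n)
}

#' Shape descriptors of labelled objects
#'
#' Computes, per connected component: pixel area, bounding-box width and
#' height, perimeter (weighted crack-edge estimator, see source),
#' circularity `4*pi*area / perimeter^2`, convex-hull fill area, solidity
#' `area / convex_area`, and centroid. Circularity is reported raw; the
#' rasterization overshoot of very small objects is absorbed by clipping at
#' 1.15 inside [filter_objects()].
#'
#' @param labels integer label matrix from [label_objects()].
#' @return A data frame with one row per object, ordered by label.
#' @export
shape_descriptors <- function(labels) {
  stopifnot(is.matrix(labels))
  K <- max(labels)
  empty <- data.frame(label = integer(), area = integer(), width = integer(),
                      height = integer(), perimeter = numeric(),
                      circularity = numeric(), convex_area = numeric(),
                      solidity = numeric(), centroid_row = numeric(),
                      centroid_col = numeric())
  if (K == 0L) return(empty)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  ri <- ((idx - 1L) %% nrow(labels)) + 1L
  ci <- ((idx - 1L) %/% nrow(labels)) + 1L
  out <- vector("list", K)
  for (k in seq_len(K)) {
    sel <- lab == k
    rows <- ri[sel]; cols <- ci[sel]
    r1 <- min(rows); r2 <- max(rows); c1 <- min(cols); c2 <- max(cols)
    obj <- matrix(FALSE, r2 - r1 + 1L, c2 - c1 + 1L)
    obj[cbind(rows - r1 + 1L, cols - c1 + 1L)] <- TRUE
    area <- sum(sel)
    per <- crack_perimeter(obj)
    conv <- convex_fill_area(rows, cols)
    out[[k]] <- data.frame(
      label = k, area = area,
      width = c2 - c1 + 1L, height = r2 - r1 + 1L,
      perimeter = per,
      circularity = if (per > 0) 4 * pi * area / per^2 else Inf,
      convex_area = conv,
      solidity = min(area / conv, 1),
      centroid_row = mean(rows), centroid_col = mean(cols))
  }
  do.call(rbind, out)
}

#' Shape filter for candidate objects
#'
#' Interval bounds on area, bounding-box width and height, plus lower
#' bounds on circularity and solidity. `NULL` disables a criterion.
#'
#' @param min_area,max_area,min_width,max_width,min_height,max_height
#'   interval bounds in pixels.
#' @param min_circularity,min_solidity lower bounds in `[0, 1]`.
#' @return An object of class `shape_filter`.
#' @export
shape_filter <- function(min_area = NULL, max_area = NULL,
                         min_width = NULL, max_width = NULL,
                         min_height = NULL, max_height = NULL,
                         min_circularity = NULL, min_solidity = NULL) {
  f <- list(min_area = min_area, max_area = max_area,
            min_width = min_width, max_width = max_width,
            min_height = min_height, max_height = max_height,
            min_circularity = min_circularity, min_solidity = min_solidity)
  for (p in c("area", "width", "height")) {
    lo <- f[[paste0("min_", p)]]; hi <- f[[paste0("max_", p)]]
    if (!is.null(lo) && !is.null(hi) && lo > hi)
      stop(sprintf("min_%s exceeds max_%s", p, p), call. = FALSE)
  }
  for (p in c("min_circularity", "min_solidity"))
    if (!is.null(f[[p]]) && (f[[p]] < 0 || f[[p]] > 1))
      stop(p, " must lie in [0, 1]", call. = FALSE)
  structure(f, class = "shape_filter")
}

#' Apply a shape filter to object descriptors
#'
#' Criteria are evaluated in the fixed order area, width, height,
#' circularity, solidity; a rejected object records the first criterion it
#' failed. Circularity is clipped at 1.15 before comparison to absorb the
#' rasterization overshoot of small objects.
#'
#' @param objects data frame from [shape_descriptors()].
#' @param filter a [shape_filter].
#' @param image_id identifier stored in the result.
#' @return An object of class `detection_result` with `kept`, `rejected`
#'   (with a `criterion` column) and `count`.
#' @export
filter_objects <- function(objects, filter = shape_filter(), image_id = NULL) {
  stopifnot(inherits(filter, "shape_filter"))
  n <- nrow(objects)
  reason <- rep(NA_character_, n)
  if (n > 0) {
    circ <- pmin(objects$circularity, 1.15)
    checks <- list(
      area = c("min_area", "max_area"),
      width = c("min_width", "max_width"),
      height = c("min_height", "max_height"))
    for (p in names(checks)) {
      lo <- filter[[checks[[p]][1]]]; hi <- filter[[checks[[p]][2]]]
      fail <- rep(FALSE, n)
      if (!is.null(lo)) fail <- fail | objects[[p]] < lo
      if (!is.null(hi)) fail <- fail | objects[[p]] > hi
      reason[is.na(reason) & fail] <- p
    }
    if (!is.null(filter$min_circularity))
      reason[is.na(reason) & circ < filter$min_circularity] <- "circularity"
    if (!is.null(filter$min_solidity))
      reason[is.na(reason) & objects$solidity < filter$min_solidity] <- "solidity"
  }
  kept <- objects[is.na(reason), , drop = FALSE]
  rejected <- objects[!is.na(reason), , drop = FALSE]
  if (nrow(rejected)) rejected$criterion <- reason[!is.na(reason)]
  else rejected$criterion <- character(0)
  structure(list(image_id = image_id, kept = kept, rejected = rejected,
                 count = nrow(kept)),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result>%s %d hemocytes (%d candidates rejected)\n",
              if (!is.null(x$image_id)) paste0(" ", x$image_id, ":") else "",
              x$count, nrow(x$rejected)))
  invisible(x)
}

#' Calibrate a shape filter from training-cell descriptors
#'
#' Area, width and height bounds are the observed training minima/maxima
#' widened by `margin` (lower bound scaled by `1 - margin`, upper by
#' `1 + margin`); circularity and solidity minima are the observed minima
#' scaled by `1 - margin`.
#'
#' @param descriptors data frame of descriptors of annotated training
#'   cells (see [shape_descriptors()]).
#' @param margin widening fraction; default 0.5.
#' @return A [shape_filter].
#' @export
calibrate_filter <- function(descriptors, margin = 0.5) {
  if (is.null(descriptors) || nrow(descriptors) == 0L)
    stop("no training-cell descriptors supplied", call. = FALSE)
  if (nrow(descriptors) < 2L)
    warning("only one training cell: calibrated bounds are degenerate",
            call. = FALSE)
  lo <- function(v) min(v) * (1 - margin)
  hi <- function(v) max(v) * (1 + margin)
  circ <- pmin(descriptors$circularity, 1.15)
  shape_filter(
    min_area = lo(descriptors$area), max_area = hi(descriptors$area),
    min_width = lo(descriptors$width), max_width = hi(descriptors$width),
    min_height = lo(descriptors$height), max_height = hi(descriptors$height),
    min_circularity = min(1, max(0, min(circ) * (1 - margin))),
    min_solidity = min(1, max(0, min(descriptors$solidity) * (1 - margin))))
}

#' Detect and count granular hemocytes in a micrograph
#'
#' Composes the full per-image protocol: background removal, projection on
#' the selected principal component, score thresholding, mask
#' consolidation, connected-component labelling, shape description and
#' shape filtering.
#'
#' @param img an [rgb_image].
#' @param model a fitted [hemocyte_model].
#' @param filter optional [shape_filter] overriding the model's calibrated
#'   filter.
#' @return A `detection_result` (see [filter_objects()]); kept objects are
#'   the counted hemocytes.
#' @export
count_hemocytes <- function(img, model, filter = NULL) {
  stopifnot(inherits(img, "rgb_image"), inherits(model, "hemocyte_model"))
  valid <- background_mask(img, model$background)
  sc <- score_image(img, valid, model$pca, model$selected_pc)
  m <- threshold_scores(sc, model$score_threshold)
  m <- clean_mask(m, model$closing_radius, model$fill_holes)
  m <- m & valid
  labels <- label_objects(m, model$connectivity)
  desc <- shape_descriptors(labels)
  filter_objects(desc, if (is.null(filter)) model$shape_filter else filter,
                 image_id = img$id)
}

#' Draw kept detections onto the raw image
#'
#' Marks each counted hemocyte with a green bounding box, mirroring a
#' visual-verification overlay.
#'
#' @param img an [rgb_image].
#' @param result a `detection_result` for that image.
#' @param color RGB triple of the box colour.
#' @return A new [rgb_image] with boxes drawn.
#' @export
overlay_detections <- function(img, result, color = c(0, 255, 0)) {
  stopifnot(inherits(img, "rgb_image"), inherits(result, "detection_result"))
  px <- img$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  k <- result$kept
  for (i in seq_len(nrow(k))) {
    r1 <- max(1L, k$centroid_row[i] - k$height[i] / 2 - 1)
    r2 <- min(h, k$centroid_row[i] + k$height[i] / 2 + 1)
    c1 <- max(1L, k$centroid_col[i] - k$width[i] / 2 - 1)
    c2 <- min(w, k$centroid_col[i] + k$width[i] / 2 + 1)
    rs <- round(r1):round(r2); cs <- round(c1):round(c2)
    for (ch in 1:3) {
      px[rs[1], cs, ch] <- color[ch]
      px[rs[length(rs)], cs, ch] <- color[ch]
      px[rs, cs[1], ch] <- color[ch]
      px[rs, cs[length(cs)], ch] <- color[ch]
    }
  }
  rgb_image(px, pixel_size_um = img$pixel_size_um, id = img$id)
}

#' Match detections against planted ground truth
#'
#' Greedy nearest-neighbour matching of kept-object centroids to true
#' hemocyte centres within `max_dist` pixels; each truth record matches at
#' most one detection.
#'
#' @param results a `detection_result` or list of them.
#' @param truths a ground-truth data frame (see [generate_field()]) or list
#'   of them, aligned with `results`.
#' @param max_dist maximum centre distance in pixels for a match.
#' @return A list with `tp`, `fp`, `fn`, `sensitivity`, `precision`.
#' @export
evaluate_detections <- function(results, truths, max_dist = 5) {
  if (inherits(results, "detection_result")) results <- list(results)
  if (is.data.frame(truths)) truths <- list(truths)
  stopifnot(length(results) == length(truths))
  tp <- fp <- fn <- 0L
  for (i in seq_along(results)) {
    k <- results[[i]]$kept
    tr <- truths[[i]]
    tr <- tr[tr$type == "hemocyte", , drop = FALSE]
    used <- rep(FALSE, nrow(tr))
    matched <- 0L
    if (nrow(k) > 0 && nrow(tr) > 0) {
      for (j in seq_len(nrow(k))) {
        d <- sqrt((tr$center_row - k$centroid_row[j])^2 +
                  (tr$center_col - k$centroid_col[j])^2)
        d[used] <- Inf
        m <- which.min(d)
        if (length(m) && d[m] <= max_dist) {
          used[m] <- TRUE
          matched <- matched + 1L
        }
      }
    }
    tp <- tp + matched
    fp <- fp + (nrow(k) - matched)
    fn <- fn + (nrow(tr) - matched)
  }
  list(tp = tp, fp = fp, fn = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}
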