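#' Fit a granular-hemocyte detection model
#'
#' The trained protocol behind marker-free hemocyte counting. Fitting
#' (needed once per staining/microscope configuration) proceeds in four
#' steps: (1) annotated hemocyte rectangles are cropped and packed into a
#' hemocyte-only training mosaic, with bright background removed by the
#' green/blue rule; (2) the mosaic is unfolded into pixel-neighbourhood
#' colour features and a principal component model is fitted; (3) the
#' score-image component is chosen (fixed index, or automatically as the
#' component with the largest standardized hemocyte-versus-tissue
#' contrast) and oriented so hemocytes score high, and the score threshold
#' is set at a low quantile of training hemocyte scores; (4) a shape filter
#' is calibrated from the detected training cells.
#'
#' @param images named list of [rgb_image]s (names must match annotation
#'   image ids).
#' @param annotations annotation data frame (see [load_annotations()]).
#' @param background a [background_config].
#' @param window_radius neighbourhood radius in pixels; radius 2 gives a
#'   5x5 window and 75 colour features per pixel.
#' @param n_components principal components to retain.
#' @param selected_pc `"auto"` (default) to pick the component with the
#'   largest absolute hemocyte-versus-tissue contrast, or a fixed 1-based
#'   index for a known configuration.
#' @param threshold_quantile quantile of training hemocyte scores used as
#'   the score threshold; default 0.05 keeps ~95% of hemocyte pixels.
#' @param filter_margin widening fraction for the calibrated shape filter.
#' @param closing_radius,fill_holes mask consolidation parameters (see
#'   [clean_mask()]).
#' @param connectivity object connectivity, 4 or 8.
#' @param shape_filter optional pre-specified [shape_filter]; skips
#'   calibration.
#' @return An object of class `hemocyte_model`.
#' @seealso [count_hemocytes()], [predict.hemocyte_model()],
#'   [write_hemocyte_model()]
#' @export
hemocyte_model <- function(images, annotations,
                           background = background_config(),
                           window_radius = 2, n_components = 10,
                           selected_pc = "auto",
                           threshold_quantile = 0.05,
                           filter_margin = 0.5,
                           closing_radius = 1, fill_holes = TRUE,
                           connectivity = 8,
                           shape_filter = NULL) {
  stopifnot(inherits(background, "background_config"),
            threshold_quantile > 0, threshold_quantile < 1,
            connectivity %in% c(4, 8))
  train <- assemble_training_image(images, annotations, background,
                                   window_radius)
  pca <- fit_pixel_pca(train, window_radius, n_components)

  diag_tbl <- rank_components(pca, images, annotations, background)
  if (identical(selected_pc, "auto")) {
    pc <- diag_tbl$component[which.max(abs(diag_tbl$contrast))]
  } else {
    pc <- as.integer(selected_pc)
    if (pc < 1L || pc > pca$n_components)
      stop(sprintf("selected_pc = %d out of range (1..%d)", pc,
                   pca$n_components), call. = FALSE)
  }
  # orient the selected component so hemocyte pixels score high
  if (diag_tbl$contrast[pc] < 0) {
    pca$loadings[, pc] <- -pca$loadings[, pc]
    diag_tbl$contrast[pc] <- -diag_tbl$contrast[pc]
    diag_tbl$hemocyte_mean[pc] <- -diag_tbl$hemocyte_mean[pc]
    diag_tbl$other_mean[pc] <- -diag_tbl$other_mean[pc]
  }

  tau <- calibrate_threshold(pca, train, pc, threshold_quantile)

  model <- structure(list(
    background = background,
    window_radius = as.integer(window_radius),
    pca = pca,
    selected_pc = pc,
    pc_auto = identical(selected_pc, "auto"),
    pc_diagnostic = diag_tbl,
    score_threshold = tau,
    threshold_quantile = threshold_quantile,
    closing_radius = closing_radius,
    fill_holes = fill_holes,
    connectivity = as.integer(connectivity),
    shape_filter = shape_filter,
    training = list(n_tiles = nrow(train$provenance),
                    n_hemocyte_pixels = sum(train$valid),
                    n_rows_used = pca$n_rows_used)),
    class = "hemocyte_model")

  if (is.null(shape_filter)) {
    desc <- training_cell_descriptors(model, images, annotations)
    if (nrow(desc) == 0L) {
      warning("no detectable training cells; shape filter left permissive",
              call. = FALSE)
      model$shape_filter <- shape_filter()
    } else {
      model$shape_filter <- calibrate_filter(desc, filter_margin)
      model$training$n_calibration_cells <- nrow(desc)
    }
  }
  model
}

# Descriptors of the annotated training cells: for each annotation
# rectangle (which marks exactly one hemocyte) take the largest thresholded
# object whose centroid lies inside it, so stray granule fragments inside
# the rectangle do not contaminate the calibration, and pool over images.
training_cell_descriptors <- function(model, images, annotations) {
  out <- list()
  for (id in unique(annotations$image)) {
    img <- images[[id]]
    valid <- background_mask(img, model$background)
    sc <- score_image(img, valid, model$pca, model$selected_pc)
    m <- threshold_scores(sc, model$score_threshold)
    m <- clean_mask(m, model$closing_radius, model$fill_holes) & valid
    desc <- shape_descriptors(label_objects(m, model$connectivity))
    if (nrow(desc) == 0L) next
    a <- annotations[annotations$image == id, , drop = FALSE]
    for (j in seq_len(nrow(a))) {
      inside <- desc$centroid_row > a$r0[j] &
        desc$centroid_row <= a$r0[j] + a$nr[j] &
        desc$centroid_col > a$c0[j] &
        desc$centroid_col <= a$c0[j] + a$nc[j]
      if (any(inside)) {
        cand <- desc[inside, , drop = FALSE]
        out[[length(out) + 1L]] <- cand[which.max(cand$area), , drop = FALSE]
      }
    }
  }
  if (length(out) == 0L) return(shape_descriptors(matrix(0L, 1, 1)))
  do.call(rbind, out)
}

#' @export
print.hemocyte_model <- function(x, ...) {
  cat("Granular-hemocyte detection model\n")
  cat(sprintf("  window radius : %d (%d features/pixel)\n", x$window_radius,
              length(x$pca$mean)))
  cat(sprintf("  components    : %d; score component PC%d%s\n",
              x$pca$n_components, x$selected_pc,
              if (isTRUE(x$pc_auto)) " (auto-selected)" else ""))
  cat(sprintf("  score threshold: %.4g (quantile %.2g of training scores)\n",
              x$score_threshold, x$threshold_quantile))
  cat(sprintf("  background    : green >= %g & blue >= %g\n",
              x$background$green_threshold, x$background$blue_threshold))
  cat(sprintf("  training      : %d tiles, %d hemocyte pixels, %d feature rows\n",
              x$training$n_tiles, x$training$n_hemocyte_pixels,
              x$training$n_rows_used))
  f <- x$shape_filter
  if (!is.null(f$min_area))
    cat(sprintf("  shape filter  : area [%.0f, %.0f], width [%.0f, %.0f], height [%.0f, %.0f], circ >= %.2f, solidity >= %.2f\n",
                f$min_area, f$max_area, f$min_width, f$max_width,
                f$min_height, f$max_height, f$min_circularity, f$min_solidity))
  invisible(x)
}

#' @export
summary.hemocyte_model <- function(object, ...) {
  print(object)
  ev <- object$pca$eigenvalues
  cat("\nEigenvalue spectrum (% of total variance):\n")
  pct <- 100 * ev / sum(ev)
  for (i in seq_along(ev))
    cat(sprintf("  PC%-2d %12.4g  (%5.1f%%)%s\n", i, ev[i], pct[i],
                if (i == object$selected_pc) "  <- score component" else ""))
  cat("\nHemocyte-versus-tissue contrast by component:\n")
  print(object$pc_diagnostic, row.names = FALSE, digits = 3)
  invisible(object)
}

#' Scree and contrast plot of a fitted model
#'
#' @param x a [hemocyte_model].
#' @param ... ignored.
#' @export
plot.hemocyte_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  ev <- x$pca$eigenvalues
  graphics::barplot(100 * ev / sum(ev), names.arg = seq_along(ev),
                    xlab = "component", ylab = "% variance",
                    main = "Training variance")
  ct <- x$pc_diagnostic$contrast
  cols <- ifelse(seq_along(ct) == x$selected_pc, "forestgreen", "grey60")
  graphics::barplot(ct, names.arg = x$pc_diagnostic$component, col = cols,
                    xlab = "component", ylab = "standardized contrast",
                    main = "Hemocyte vs tissue")
  invisible(x)
}

#' Detect hemocytes in new micrographs
#'
#' @param object a fitted [hemocyte_model].
#' @param newdata an [rgb_image] or a list of them.
#' @param type `"result"` for full `detection_result`s, `"count"` for a
#'   numeric vector of counts.
#' @param ... ignored.
#' @return A `detection_result` (single image), a list of them, or a named
#'   numeric vector of counts.
#' @export
predict.hemocyte_model <- function(object, newdata, type = c("result", "count"),
                                   ...) {
  type <- match.arg(type)
  single <- inherits(newdata, "rgb_image")
  imgs <- if (single) list(newdata) else newdata
  res <- lapply(imgs, count_hemocytes, model = object)
  if (type == "count") {
    counts <- vapply(res, function(r) r$count, numeric(1))
    names(counts) <- vapply(res, function(r)
      if (is.null(r$image_id)) "" else r$image_id, character(1))
    return(if (single) unname(counts) else counts)
  }
  if (single) res[[1]] else res
}

#' Persist a fitted model as JSON
#'
#' Numeric fields are written with 17 significant digits so that a reload
#' reproduces the model bit-exactly; refitting from identical inputs also
#' reproduces the file byte-for-byte (no timestamps are stored).
#'
#' @param model a [hemocyte_model].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hemocyte_model <- function(model, path) {
  stopifnot(inherits(model, "hemocyte_model"))
  doc <- list(
    format = "hemocount-model",
    format_version = 1L,
    package_version = as.character(utils::packageVersion("hemocount")),
    background = unclass(model$background),
    window_radius = model$window_radius,
    n_components = model$pca$n_components,
    mean = model$pca$mean,
    loadings = model$pca$loadings,
    eigenvalues = model$pca$eigenvalues,
    selected_pc = model$selected_pc,
    pc_auto = model$pc_auto,
    pc_diagnostic = model$pc_diagnostic,
    score_threshold = model$score_threshold,
    threshold_quantile = model$threshold_quantile,
    closing_radius = model$closing_radius,
    fill_holes = model$fill_holes,
    connectivity = model$connectivity,
    shape_filter = Filter(Negate(is.null), unclass(model$shape_filter)),
    training = model$training)
  json <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                           dataframe = "columns", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Reload a persisted model
#'
#' @param path path to a JSON file written by [write_hemocyte_model()].
#' @return A [hemocyte_model].
#' @export
read_hemocyte_model <- function(path) {
  doc <- jsonlite::fromJSON(path)
  if (!identical(doc$format, "hemocount-model"))
    stop("not a hemocount model file: ", path, call. = FALSE)
  pca <- structure(list(mean = doc$mean,
                        loadings = matrix(doc$loadings, ncol = doc$n_components),
                        eigenvalues = doc$eigenvalues,
                        n_components = as.integer(doc$n_components),
                        window_radius = as.integer(doc$window_radius),
                        n_rows_used = doc$training$n_rows_used),
                   class = "pixel_pca")
  sf <- do.call(shape_filter, doc$shape_filter)
  structure(list(
    background = do.call(background_config, doc$background),
    window_radius = as.integer(doc$window_radius),
    pca = pca,
    selected_pc = as.integer(doc$selected_pc),
    pc_auto = isTRUE(doc$pc_auto),
    pc_diagnostic = as.data.frame(doc$pc_diagnostic),
    score_threshold = doc$score_threshold,
    threshold_quantile = doc$threshold_quantile,
    closing_radius = doc$closing_radius,
    fill_holes = isTRUE(doc$fill_holes),
    connectivity = as.integer(doc$connectivity),
    shape_filter = sf,
    training = doc$training),
    class = "hemocyte_model")
}
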