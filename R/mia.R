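#' Unfold a micrograph into a pixel-neighbourhood feature matrix
#'
#' Multivariate image analysis represents every pixel by the colour
#' intensities of its `(2r+1) x (2r+1)` spatial neighbourhood across all
#' three channels, giving `3 * (2r+1)^2` features per pixel. Columns are
#' ordered channel-major (R, G, B), then window row-major; image borders
#' are handled by edge replication.
#'
#' @param img an [rgb_image].
#' @param valid logical matrix selecting which pixels contribute rows;
#'   `NULL` means all pixels. Validity governs only which rows exist:
#'   invalid neighbours still contribute their raster values.
#' @param window_radius neighbourhood radius in pixels (`r >= 0`).
#' @return A list of class `unfolded_matrix` with `X` (one row per selected
#'   pixel), `pixel_index` (n x 2 matrix of 1-based row/col of each row's
#'   centre pixel) and `window_radius`.
#' @export
unfold <- function(img, valid = NULL, window_radius = 2) {
  stopifnot(inherits(img, "rgb_image"), window_radius >= 0)
  r <- as.integer(window_radius)
  d <- dim(img$pixels)
  h <- d[1]; w <- d[2]
  if (is.null(valid)) valid <- matrix(TRUE, h, w)
  stopifnot(is.logical(valid), all(dim(valid) == c(h, w)))
  idx <- which(valid)
  n <- length(idx)
  side <- 2L * r + 1L
  X <- matrix(0, n, 3L * side * side)
  k <- 0L
  rows <- seq_len(h); cols <- seq_len(w)
  for (ch in 1:3) {
    for (dy in -r:r) {
      rr <- pmin(pmax(rows + dy, 1L), h)
      for (dx in -r:r) {
        cc <- pmin(pmax(cols + dx, 1L), w)
        k <- k + 1L
        sl <- img$pixels[rr, cc, ch]
        X[, k] <- sl[idx]
      }
    }
  }
  structure(list(X = X,
                 pixel_index = arrayInd(idx, c(h, w)),
                 window_radius = r,
                 dim = c(h, w)),
            class = "unfolded_matrix")
}

# TRUE where the full (2r+1)^2 window around a pixel, clamped to the image,
# contains only valid pixels. Uses a summed-area table over the invalid mask.
window_all_valid <- function(valid, r) {
  h <- nrow(valid); w <- ncol(valid)
  if (r == 0L) return(valid)
  inv <- matrix(as.numeric(!valid), h, w)
  cum <- inv
  if (h > 1L) cum <- apply(cum, 2, cumsum)
  if (w > 1L) cum <- t(apply(cum, 1, cumsum))
  cum <- matrix(cum, h, w)
  S <- matrix(0, h + 1L, w + 1L)
  S[-1, -1] <- cum
  ri <- as.vector(row(valid)); ci <- as.vector(col(valid))
  i1 <- pmax(ri - r, 1L); i2 <- pmin(ri + r, h)
  j1 <- pmax(ci - r, 1L); j2 <- pmin(ci + r, w)
  cnt <- S[cbind(i2 + 1L, j2 + 1L)] - S[cbind(i1, j2 + 1L)] -
         S[cbind(i2 + 1L, j1)] + S[cbind(i1, j1)]
  matrix(cnt == 0, h, w)
}

#' Principal component model of a pixel-feature matrix
#'
#' Mean-centres the rows (no variance scaling: all features share the 0-255
#' intensity scale) and extracts principal axes with a deterministic
#' singular value decomposition. Loading signs are fixed by orienting each
#' column so its largest-magnitude element is positive.
#'
#' @param X numeric matrix, one row per pixel, one column per feature.
#' @param n_components number of components to retain (capped at
#'   `min(dim(X))`).
#' @return A list of class `pixel_pca` with `mean`, `loadings`
#'   (orthonormal columns), `eigenvalues` (variances along each component,
#'   non-increasing) and `n_components`.
#' @export
pixel_pca <- function(X, n_components = 10) {
  stopifnot(is.matrix(X), nrow(X) >= 1L)
  k <- min(as.integer(n_components), ncol(X), nrow(X))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- La.svd(Xc, nu = 0L, nv = min(dim(Xc)))
  ev <- sv$d^2 / max(nrow(X) - 1L, 1L)
  load <- t(sv$vt)[, seq_len(k), drop = FALSE]
  ev <- ev[seq_len(k)]
  for (j in seq_len(k)) {
    m <- which.max(abs(load[, j]))
    if (load[m, j] < 0) load[, j] <- -load[, j]
  }
  structure(list(mean = mu, loadings = load, eigenvalues = ev,
                 n_components = k),
            class = "pixel_pca")
}

#' Fit the neighbourhood PCA on a training mosaic
#'
#' Unfolds the hemocyte-only training mosaic and fits [pixel_pca()].
#' Rows whose window overlaps sentinel padding or background-removed pixels
#' are dropped so that white padding never leaks into the colour/texture
#' model.
#'
#' @param train a `training_image` from [assemble_training_image()].
#' @param window_radius neighbourhood radius in pixels.
#' @param n_components components to retain.
#' @return A `pixel_pca` with attribute `window_radius`, plus `n_rows_used`.
#' @export
fit_pixel_pca <- function(train, window_radius = 2, n_components = 10) {
  stopifnot(inherits(train, "training_image"))
  if (!any(train$valid))
    stop("training image has no valid hemocyte pixels", call. = FALSE)
  core <- window_all_valid(train$valid, as.integer(window_radius))
  if (!any(core))
    stop("no training pixel has a fully valid neighbourhood window; annotate larger regions or reduce window_radius",
         call. = FALSE)
  uf <- unfold(train$mosaic, core, window_radius)
  if (nrow(uf$X) < ncol(uf$X))
    warning(sprintf("training matrix has fewer rows (%d) than features (%d); trailing components are unstable",
                    nrow(uf$X), ncol(uf$X)), call. = FALSE)
  p <- pixel_pca(uf$X, n_components)
  p$window_radius <- as.integer(window_radius)
  p$n_rows_used <- nrow(uf$X)
  p
}

#' Project a micrograph onto one principal component
#'
#' Scores every valid pixel on the requested component and refolds the
#' score vector to image geometry ("score image").
#'
#' @param img an [rgb_image].
#' @param valid logical tissue mask (see [background_mask()]); `NULL` for
#'   all pixels.
#' @param model a `pixel_pca` (with `window_radius`) or a `hemocyte_model`.
#' @param component 1-based component index.
#' @return A list of class `score_image` with `values` (matrix, `NA` where
#'   invalid), `valid` and `component`.
#' @export
score_image <- function(img, valid = NULL, model, component = NULL) {
  pca <- if (inherits(model, "hemocyte_model")) model$pca else model
  stopifnot(inherits(pca, "pixel_pca"))
  if (is.null(component))
    component <- if (inherits(model, "hemocyte_model")) model$selected_pc else 1L
  if (component < 1L || component > pca$n_components)
    stop(sprintf("component %d out of range (model has %d components)",
                 component, pca$n_components), call. = FALSE)
  r <- pca$window_radius
  if (is.null(r)) stop("model carries no window_radius", call. = FALSE)
  uf <- unfold(img, valid, r)
  s <- as.vector(sweep(uf$X, 2L, pca$mean) %*% pca$loadings[, component])
  vals <- matrix(NA_real_, uf$dim[1], uf$dim[2])
  vals[uf$pixel_index] <- s
  v <- if (is.null(valid)) matrix(TRUE, uf$dim[1], uf$dim[2]) else valid
  structure(list(values = vals, valid = v, component = as.integer(component)),
            class = "score_image")
}

#' Calibrate the score threshold from training hemocyte pixels
#'
#' Returns a low quantile of the training hemocyte-pixel scores on the
#' selected component, so that thresholding at the returned value retains
#' approximately `1 - quantile` of hemocyte pixels while rejecting tissue
#' classes that score lower.
#'
#' @param pca a `pixel_pca` with `window_radius`.
#' @param train a `training_image`.
#' @param component component on which to threshold.
#' @param quantile fraction in (0, 1); default 0.05.
#' @return The threshold (scalar score).
#' @export
calibrate_threshold <- function(pca, train, component, quantile = 0.05) {
  stopifnot(inherits(pca, "pixel_pca"), inherits(train, "training_image"),
            quantile > 0, quantile < 1)
  core <- window_all_valid(train$valid, pca$window_radius)
  uf <- unfold(train$mosaic, core, pca$window_radius)
  s <- as.vector(sweep(uf$X, 2L, pca$mean) %*% pca$loadings[, component])
  stats::quantile(s, quantile, names = FALSE)
}

#' Threshold a score image
#'
#' @param scores a `score_image`.
#' @param tau scalar threshold; pixels with score `>= tau` are selected.
#' @return Logical matrix, `TRUE` where valid and at or above threshold.
#' @export
threshold_scores <- function(scores, tau) {
  stopifnot(inherits(scores, "score_image"))
  m <- scores$valid & !is.na(scores$values) & scores$values >= tau
  m[is.na(m)] <- FALSE
  m
}

#' Rank components by hemocyte-versus-tissue contrast
#'
#' For each principal component, computes the standardized contrast between
#' scores of annotated hemocyte pixels and all other tissue pixels on the
#' training source images:
#' `(mean_hemocyte - mean_other) / sqrt((var_hemocyte + var_other) / 2)`.
#' The component with the largest absolute contrast is the recommended
#' score-image component for a given staining/microscope configuration.
#'
#' @param pca a `pixel_pca` with `window_radius`.
#' @param images named list of [rgb_image]s used for training.
#' @param ann annotation data frame.
#' @param cfg a [background_config].
#' @return A data frame with one row per component: `component`,
#'   `hemocyte_mean`, `other_mean`, `pooled_sd`, `contrast`, ordered by
#'   component index.
#' @export
rank_components <- function(pca, images, ann, cfg = background_config()) {
  stopifnot(inherits(pca, "pixel_pca"))
  k <- pca$n_components
  sh <- so <- s2h <- s2o <- rep(0, k)
  nh <- no <- 0
  for (id in unique(ann$image)) {
    img <- images[[id]]
    v <- background_mask(img, cfg)
    uf <- unfold(img, v, pca$window_radius)
    S <- sweep(uf$X, 2L, pca$mean) %*% pca$loadings
    hemo <- rep(FALSE, nrow(S))
    a <- ann[ann$image == id, , drop = FALSE]
    pr <- uf$pixel_index[, 1]; pc <- uf$pixel_index[, 2]
    for (j in seq_len(nrow(a))) {
      hemo <- hemo | (pr > a$r0[j] & pr <= a$r0[j] + a$nr[j] &
                      pc > a$c0[j] & pc <= a$c0[j] + a$nc[j])
    }
    if (any(hemo)) {
      sh <- sh + colSums(S[hemo, , drop = FALSE])
      s2h <- s2h + colSums(S[hemo, , drop = FALSE]^2)
      nh <- nh + sum(hemo)
    }
    if (any(!hemo)) {
      so <- so + colSums(S[!hemo, , drop = FALSE])
      s2o <- s2o + colSums(S[!hemo, , drop = FALSE]^2)
      no <- no + sum(!hemo)
    }
  }
  if (nh == 0 || no == 0)
    stop("need both hemocyte and non-hemocyte pixels to rank components",
         call. = FALSE)
  mh <- sh / nh; mo <- so / no
  vh <- pmax(s2h / nh - mh^2, 0); vo <- pmax(s2o / no - mo^2, 0)
  sd <- sqrt((vh + vo) / 2)
  data.frame(component = seq_len(k), hemocyte_mean = mh, other_mean = mo,
             pooled_sd = sd, contrast = (mh - mo) / pmax(sd, .Machine$double.eps))
}
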