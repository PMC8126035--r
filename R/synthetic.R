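# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic HE-stained micrograph
#'
#' Describes the appearance of a hematoxylin-eosin stained tissue field
#' with planted Group II-like granular hemocytes and the confounders that
#' challenge their detection: small smooth dark nuclei (same hue, no
#' granular texture), elongated smooth pink muscle fibres (tissue hue,
#' wrong shape), and bright empty lacuna lumina. Hemocytes are rendered as
#' purple disks carrying a dense speckle of darker cytoplasmic granules --
#' the discriminative colour/texture signature -- and are surrounded by a
#' thin bright halo emulating the hemolymph space / retraction artefact
#' seen around cells in HE sections.
#'
#' Default geometry: 256 x 256 pixels at 0.86 um/px, i.e. a field of
#' 0.0485 mm^2 as produced by a 40x plan-apochromat acquisition; hemocyte
#' radii 6-9 px (12-18 um cell diameters), nucleus radii 1.5-2.5 px.
#'
#' @param size `c(rows, cols)` in pixels.
#' @param pixel_size_um micrometres per pixel.
#' @param bg_color eosin base colour (RGB, 0-255).
#' @param bg_texture_amp standard deviation of the smooth background
#'   texture (intensity units).
#' @param bright_fraction approximate area fraction of bright lacuna
#'   lumina.
#' @param bright_color colour of bright empty regions.
#' @param hemocyte_lambda Poisson mean of planted hemocytes per field.
#' @param hemocyte_radius radius range in pixels.
#' @param hemocyte_color cell body colour (purple).
#' @param granule_density target fraction of the cell body covered by
#'   granule speckle.
#' @param granule_color granule colour (darker purple).
#' @param granule_jitter per-granule colour jitter SD.
#' @param halo_color colour of the perinuclear bright halo.
#' @param n_nuclei nucleus confounders per field.
#' @param nucleus_radius nucleus semi-major-axis range in pixels.
#' @param nucleus_color nucleus colour (dark blue).
#' @param n_fibers fibre confounders per field.
#' @param fiber_width fibre width range in pixels.
#' @param fiber_length fibre length range in pixels.
#' @param fiber_color fibre colour (pink/red).
#' @param min_separation minimum centre-to-centre distance between planted
#'   cells (hemocytes and nuclei) in pixels.
#' @param noise_sd per-pixel Gaussian camera noise SD.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(size = c(256, 256),
                           pixel_size_um = 0.86,
                           bg_color = c(230, 170, 185),
                           bg_texture_amp = 6,
                           bright_fraction = 0.10,
                           bright_color = c(250, 248, 250),
                           hemocyte_lambda = 5,
                           hemocyte_radius = c(6, 9),
                           hemocyte_color = c(140, 90, 150),
                           granule_density = 0.35,
                           granule_color = c(85, 40, 105),
                           granule_jitter = 15,
                           halo_color = c(252, 250, 252),
                           n_nuclei = 30,
                           nucleus_radius = c(1.5, 2.5),
                           nucleus_color = c(70, 60, 130),
                           n_fibers = 5,
                           fiber_width = c(3, 5),
                           fiber_length = c(60, 120),
                           fiber_color = c(215, 120, 140),
                           min_separation = 24,
                           noise_sd = 2) {
  spec <- mget(names(formals()), envir = environment())
  stopifnot(length(size) == 2L, all(size >= 32),
            hemocyte_lambda >= 0,
            hemocyte_radius[1] >= 2, diff(hemocyte_radius) >= 0,
            min_separation > 0, granule_density >= 0, granule_density <= 1)
  for (col in list(bg_color, bright_color, hemocyte_color, granule_color,
                   halo_color, nucleus_color, fiber_color))
    stopifnot(length(col) == 3L, all(col >= 0), all(col <= 255))
  structure(spec, class = "synthetic_spec")
}

# sequential placement with per-object margin and global min separation
place_center <- function(placed, margin, minsep, h, w, tries = 500L) {
  for (t in seq_len(tries)) {
    cr <- stats::runif(1, margin + 1, h - margin)
    cc <- stats::runif(1, margin + 1, w - margin)
    if (length(placed) == 0L) return(c(cr, cc))
    d2 <- vapply(placed, function(p) (p[1] - cr)^2 + (p[2] - cc)^2, numeric(1))
    if (min(d2) >= minsep^2) return(c(cr, cc))
  }
  NULL
}

paint_disk <- function(px, cr, cc, r, color) {
  h <- dim(px)[1]; w <- dim(px)[2]
  rs <- max(1L, floor(cr - r)):min(h, ceiling(cr + r))
  cs <- max(1L, floor(cc - r)):min(w, ceiling(cc + r))
  d2 <- outer((rs - cr)^2, (cs - cc)^2, "+")
  sel <- d2 <= r^2
  for (ch in 1:3) {
    sl <- px[rs, cs, ch]
    sl[sel] <- color[ch]
    px[rs, cs, ch] <- sl
  }
  px
}

#' Generate one synthetic HE micrograph with ground truth
#'
#' Deterministic for a fixed `(spec, seed)` pair. The random stream is
#' consumed in a fixed order -- hemocytes, nuclei, fibres, background
#' texture, lacunae, pixel noise -- so switching confounders on or off
#' never perturbs hemocyte placement.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed.
#' @param id identifier for the generated image.
#' @return A list with `image` (an [rgb_image]) and `truth` (data frame
#'   with one row per planted object: `type`, `center_row`, `center_col`,
#'   `radius`, and a 0-based half-open bounding rectangle `r0`, `c0`,
#'   `nr`, `nc`).
#' @export
generate_field <- function(spec = synthetic_spec(), seed = 1L, id = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$size[1]; w <- spec$size[2]
  with_seed(seed, {
    placed <- list()
    truth <- list()

    # --- 1. hemocytes ----------------------------------------------------
    n_h <- stats::rpois(1L, spec$hemocyte_lambda)
    hemo <- vector("list", n_h)
    for (i in seq_len(n_h)) {
      r <- stats::runif(1, spec$hemocyte_radius[1], spec$hemocyte_radius[2])
      halo_w <- ceiling(0.45 * r) + 1
      ctr <- place_center(placed, r + halo_w + 2, spec$min_separation, h, w)
      if (is.null(ctr))
        stop(sprintf("placement failed after %d of %d hemocytes; field too crowded for min_separation = %g",
                     i - 1L, n_h, spec$min_separation), call. = FALSE)
      placed[[length(placed) + 1L]] <- ctr
      body_jit <- stats::rnorm(3, 0, 5)
      # granule speckle: seed pixels inside the body, each painted as a
      # 5-pixel plus; seed probability ~ density/4 gives the target cover
      rs <- floor(ctr[1] - r):ceiling(ctr[1] + r)
      cs <- floor(ctr[2] - r):ceiling(ctr[2] + r)
      d2 <- outer((rs - ctr[1])^2, (cs - ctr[2])^2, "+")
      body_idx <- which(d2 <= r^2, arr.ind = TRUE)
      u <- stats::runif(nrow(body_idx))
      seeds <- body_idx[u < spec$granule_density / 4, , drop = FALSE]
      gjit <- matrix(stats::rnorm(3 * nrow(seeds), 0, spec$granule_jitter),
                     ncol = 3)
      hemo[[i]] <- list(ctr = ctr, r = r, halo_w = halo_w,
                        body_jit = body_jit,
                        seeds = cbind(rs[seeds[, 1]], cs[seeds[, 2]]),
                        gjit = gjit)
      truth[[length(truth) + 1L]] <- data.frame(
        type = "hemocyte", center_row = ctr[1], center_col = ctr[2],
        radius = r,
        r0 = max(0L, floor(ctr[1] - r) - 1L),
        c0 = max(0L, floor(ctr[2] - r) - 1L),
        nr = ceiling(2 * r) + 2L, nc = ceiling(2 * r) + 2L)
    }

    # --- 2. nuclei -------------------------------------------------------
    nuc <- vector("list", spec$n_nuclei)
    for (i in seq_len(spec$n_nuclei)) {
      a <- stats::runif(1, spec$nucleus_radius[1], spec$nucleus_radius[2])
      b <- a * stats::runif(1, 0.6, 1)
      ang <- stats::runif(1, 0, pi)
      ctr <- place_center(placed, a + 2, spec$min_separation, h, w)
      if (is.null(ctr))
        stop(sprintf("placement failed after %d of %d nuclei; field too crowded for min_separation = %g",
                     i - 1L, spec$n_nuclei, spec$min_separation), call. = FALSE)
      placed[[length(placed) + 1L]] <- ctr
      jit <- stats::rnorm(3, 0, 4)
      nuc[[i]] <- list(ctr = ctr, a = a, b = b, ang = ang, jit = jit)
      truth[[length(truth) + 1L]] <- data.frame(
        type = "nucleus", center_row = ctr[1], center_col = ctr[2],
        radius = a,
        r0 = max(0L, floor(ctr[1] - a) - 1L),
        c0 = max(0L, floor(ctr[2] - a) - 1L),
        nr = ceiling(2 * a) + 2L, nc = ceiling(2 * a) + 2L)
    }

    # --- 3. fibres -------------------------------------------------------
    fib <- vector("list", spec$n_fibers)
    for (i in seq_len(spec$n_fibers)) {
      ctr <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
      ang <- stats::runif(1, 0, pi)
      len <- stats::runif(1, spec$fiber_length[1], spec$fiber_length[2])
      wd <- stats::runif(1, spec$fiber_width[1], spec$fiber_width[2])
      jit <- stats::rnorm(3, 0, 4)
      fib[[i]] <- list(ctr = ctr, ang = ang, len = len, wd = wd, jit = jit)
      truth[[length(truth) + 1L]] <- data.frame(
        type = "fiber", center_row = ctr[1], center_col = ctr[2],
        radius = wd / 2,
        r0 = max(0L, floor(ctr[1] - len / 2) - 1L),
        c0 = max(0L, floor(ctr[2] - len / 2) - 1L),
        nr = min(h, ceiling(len)) + 2L, nc = min(w, ceiling(len)) + 2L)
    }

    # --- 4. background texture ------------------------------------------
    blur <- function(m, s) matrix(as.numeric(EBImage::gblur(m, sigma = s)),
                                  nrow(m), ncol(m))
    z <- matrix(stats::rnorm(h * w), h, w)
    z <- blur(z, 4)
    z <- (z - mean(z)) / stats::sd(z) * spec$bg_texture_amp

    # --- 5. bright lacunae ----------------------------------------------
    mean_blob <- pi * 35^2
    n_lac <- max(0L, round(spec$bright_fraction * h * w / mean_blob))
    lac_mask <- matrix(0, h, w)
    for (i in seq_len(n_lac)) {
      ctr <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
      ra <- stats::runif(1, 25, 45); rb <- ra * stats::runif(1, 0.5, 1)
      ang <- stats::runif(1, 0, pi)
      ri <- row(lac_mask) - ctr[1]; ci <- col(lac_mask) - ctr[2]
      u <- ri * cos(ang) + ci * sin(ang)
      v <- -ri * sin(ang) + ci * cos(ang)
      lac_mask[(u / ra)^2 + (v / rb)^2 <= 1] <- 1
    }
    alpha <- if (n_lac > 0) pmin(pmax(blur(lac_mask, 5), 0), 1)
             else lac_mask

    # --- 6. pixel noise --------------------------------------------------
    eps <- array(stats::rnorm(h * w * 3, 0, spec$noise_sd), dim = c(h, w, 3))

    # --- render ----------------------------------------------------------
    px <- array(0, dim = c(h, w, 3))
    for (ch in 1:3)
      px[, , ch] <- spec$bg_color[ch] + z +
        alpha * (spec$bright_color[ch] - spec$bg_color[ch] - z)

    for (f in fib) {
      dr <- c(cos(f$ang), sin(f$ang))
      half <- f$len / 2
      rs <- max(1L, floor(f$ctr[1] - half - f$wd)):min(h, ceiling(f$ctr[1] + half + f$wd))
      cs <- max(1L, floor(f$ctr[2] - half - f$wd)):min(w, ceiling(f$ctr[2] + half + f$wd))
      ri <- matrix(rs - f$ctr[1], length(rs), length(cs))
      ci <- matrix(cs - f$ctr[2], length(rs), length(cs), byrow = TRUE)
      t <- pmin(pmax(ri * dr[1] + ci * dr[2], -half), half)
      d2 <- (ri - t * dr[1])^2 + (ci - t * dr[2])^2
      sel <- d2 <= (f$wd / 2)^2
      for (ch in 1:3) {
        sl <- px[rs, cs, ch]
        sl[sel] <- spec$fiber_color[ch] + f$jit[ch]
        px[rs, cs, ch] <- sl
      }
    }

    for (nu in nuc) {
      rs <- max(1L, floor(nu$ctr[1] - nu$a)):min(h, ceiling(nu$ctr[1] + nu$a))
      cs <- max(1L, floor(nu$ctr[2] - nu$a)):min(w, ceiling(nu$ctr[2] + nu$a))
      ri <- matrix(rs - nu$ctr[1], length(rs), length(cs))
      ci <- matrix(cs - nu$ctr[2], length(rs), length(cs), byrow = TRUE)
      u <- ri * cos(nu$ang) + ci * sin(nu$ang)
      v <- -ri * sin(nu$ang) + ci * cos(nu$ang)
      sel <- (u / nu$a)^2 + (v / nu$b)^2 <= 1
      for (ch in 1:3) {
        sl <- px[rs, cs, ch]
        sl[sel] <- spec$nucleus_color[ch] + nu$jit[ch]
        px[rs, cs, ch] <- sl
      }
    }

    for (hc in hemo) {
      px <- paint_disk(px, hc$ctr[1], hc$ctr[2], hc$r + hc$halo_w,
                       spec$halo_color)
      px <- paint_disk(px, hc$ctr[1], hc$ctr[2], hc$r,
                       spec$hemocyte_color + hc$body_jit)
      for (s in seq_len(nrow(hc$seeds))) {
        gr <- hc$seeds[s, 1]; gc <- hc$seeds[s, 2]
        col <- spec$granule_color + hc$gjit[s, ]
        pts <- rbind(c(gr, gc), c(gr - 1, gc), c(gr + 1, gc),
                     c(gr, gc - 1), c(gr, gc + 1))
        d2 <- (pts[, 1] - hc$ctr[1])^2 + (pts[, 2] - hc$ctr[2])^2
        pts <- pts[d2 <= hc$r^2 & pts[, 1] >= 1 & pts[, 1] <= h &
                     pts[, 2] >= 1 & pts[, 2] <= w, , drop = FALSE]
        for (ch in 1:3) px[cbind(pts, ch)] <- col[ch]
      }
    }

    px <- px + eps
    px <- pmin(pmax(round(px), 0), 255)

    truth <- if (length(truth)) do.call(rbind, truth)
             else data.frame(type = character(), center_row = numeric(),
                             center_col = numeric(), radius = numeric(),
                             r0 = integer(), c0 = integer(),
                             nr = integer(), nc = integer())
    list(image = rgb_image(px, pixel_size_um = spec$pixel_size_um, id = id),
         truth = truth)
  })
}

#' Derive training annotations from ground truth
#'
#' Emits the bounding rectangles of planted hemocytes as annotations,
#' standing in for the manual singling-out of the calibration phase.
#'
#' @param truth ground-truth data frame from [generate_field()].
#' @param image_id id to record on each annotation.
#' @return Annotation data frame (see [load_annotations()]).
#' @export
auto_annotate <- function(truth, image_id) {
  hc <- truth[truth$type == "hemocyte", , drop = FALSE]
  if (nrow(hc) == 0L)
    stop("ground truth contains no hemocytes; cannot derive training annotations",
         call. = FALSE)
  data.frame(image = image_id, r0 = hc$r0, c0 = hc$c0, nr = hc$nr, nc = hc$nc,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic two-condition counting study
#'
#' Mirrors a control-versus-regenerating design: the first group receives
#' `control_lambda` planted hemocytes per field on average, every other
#' group `regen_lambda`. Per-image seeds are drawn once from `seed`, so
#' the whole study is reproducible.
#'
#' @param control_lambda,regen_lambda Poisson means of planted hemocytes.
#' @param n_per_group fields per group.
#' @param groups group labels; first label is the control condition.
#' @param spec a [synthetic_spec()].
#' @param seed integer master seed.
#' @param dir output directory; when non-`NULL`, writes `images/*.png`,
#'   `groups.csv`, `truth.csv` and `spec.json` there.
#' @return A list with `images` (named list of [rgb_image]), `truth`
#'   (combined data frame with `image_id`), `groups` (data frame
#'   `image_id`, `group`, `field_area_mm2`), and `counts` (a
#'   [count_table()] of true planted hemocyte counts).
#' @export
generate_study <- function(control_lambda = 2, regen_lambda = 14,
                           n_per_group = 30, groups = c("control", "regen"),
                           spec = synthetic_spec(), seed = 1L, dir = NULL) {
  stopifnot(n_per_group >= 1, length(groups) >= 2)
  total <- n_per_group * length(groups)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, total))
  field_area <- prod(spec$size) * spec$pixel_size_um^2 / 1e6

  images <- list(); truth <- list(); grp <- list()
  k <- 0L
  for (g in seq_along(groups)) {
    lam <- if (g == 1L) control_lambda else regen_lambda
    sp <- spec
    sp$hemocyte_lambda <- lam
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      id <- sprintf("%s_%03d", groups[g], i)
      fld <- generate_field(sp, seeds[k], id = id)
      images[[id]] <- fld$image
      if (nrow(fld$truth)) fld$truth$image_id <- id
      truth[[id]] <- fld$truth
      grp[[id]] <- data.frame(image_id = id, group = groups[g],
                              field_area_mm2 = field_area,
                              stringsAsFactors = FALSE)
    }
  }
  truth_all <- do.call(rbind, truth)
  rownames(truth_all) <- NULL
  groups_df <- do.call(rbind, grp)
  rownames(groups_df) <- NULL
  true_counts <- vapply(names(images), function(id) {
    tr <- truth[[id]]
    if (is.null(tr) || nrow(tr) == 0L) 0L else sum(tr$type == "hemocyte")
  }, integer(1))
  counts <- count_table(groups_df$image_id, groups_df$group,
                        unname(true_counts[groups_df$image_id]),
                        field_area)

  if (!is.null(dir)) {
    dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
    for (id in names(images))
      write_image(images[[id]], file.path(dir, "images", paste0(id, ".png")))
    utils::write.csv(groups_df, file.path(dir, "groups.csv"), row.names = FALSE)
    utils::write.csv(truth_all, file.path(dir, "truth.csv"), row.names = FALSE)
    writeLines(jsonlite::toJSON(c(unclass(spec),
                                  list(control_lambda = control_lambda,
                                       regen_lambda = regen_lambda,
                                       n_per_group = n_per_group,
                                       groups = groups, seed = seed)),
                                digits = I(17), auto_unbox = TRUE,
                                pretty = TRUE),
               file.path(dir, "spec.json"))
  }
  list(images = images, truth = truth_all, groups = groups_df,
       counts = counts, dir = dir)
}
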