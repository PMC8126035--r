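#' Read a pipeline configuration file
#'
#' A flat JSON key-value document; recognized keys mirror the arguments of
#' [hemocyte_model()], [synthetic_spec()] and [generate_study()]
#' (`green_threshold`, `blue_threshold`, `window_radius`, `n_components`,
#' `selected_pc`, `threshold_quantile`, `filter_margin`, `closing_radius`,
#' `fill_holes`, `connectivity`, `alpha`, `pixel_size_um`,
#' `control_lambda`, `regen_lambda`, `n_per_group`, `groups`). Unknown
#' keys are rejected to catch typos.
#'
#' @param path JSON file path, or `NULL` for an empty configuration.
#' @return A named list.
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) return(list())
  cfg <- jsonlite::fromJSON(path)
  known <- c("green_threshold", "blue_threshold", "window_radius",
             "n_components", "selected_pc", "threshold_quantile",
             "filter_margin", "closing_radius", "fill_holes", "connectivity",
             "alpha", "pixel_size_um", "control_lambda", "regen_lambda",
             "n_per_group", "groups", "hemocyte_lambda")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg
}

read_image_dir <- function(dir, pixel_size_um = NULL) {
  paths <- list.files(dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(paths) == 0L)
    stop("no PNG/TIFF images found in ", dir, call. = FALSE)
  imgs <- lapply(paths, read_image, pixel_size_um = pixel_size_um)
  names(imgs) <- vapply(imgs, function(x) x$id, character(1))
  imgs
}

cfg_get <- function(cfg, key, default) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

#' Train a detection model from files
#'
#' @param images_dir directory of calibration micrographs.
#' @param annotations_file annotation JSON (see [load_annotations()]).
#' @param out_model output path for the persisted model JSON.
#' @param config configuration list or JSON path (see [read_config()]).
#' @return The fitted [hemocyte_model], invisibly.
#' @export
run_train <- function(images_dir, annotations_file, out_model,
                      config = list()) {
  if (is.character(config)) config <- read_config(config)
  imgs <- read_image_dir(images_dir, cfg_get(config, "pixel_size_um", NULL))
  ann <- load_annotations(annotations_file, imgs)
  model <- hemocyte_model(
    imgs, ann,
    background = background_config(cfg_get(config, "green_threshold", 200),
                                   cfg_get(config, "blue_threshold", 200)),
    window_radius = cfg_get(config, "window_radius", 2),
    n_components = cfg_get(config, "n_components", 10),
    selected_pc = cfg_get(config, "selected_pc", "auto"),
    threshold_quantile = cfg_get(config, "threshold_quantile", 0.05),
    filter_margin = cfg_get(config, "filter_margin", 0.5),
    closing_radius = cfg_get(config, "closing_radius", 1),
    fill_holes = cfg_get(config, "fill_holes", TRUE),
    connectivity = cfg_get(config, "connectivity", 8))
  write_hemocyte_model(model, out_model)
  invisible(model)
}

#' Count hemocytes in a directory of micrographs
#'
#' @param model_file persisted model JSON, or a [hemocyte_model].
#' @param images_dir directory of micrographs to analyse.
#' @param out_csv output counts CSV (`image_id`, `group`, `count`,
#'   `field_area_mm2`); `group` is joined from `groups_csv` when given.
#' @param groups_csv optional CSV with `image_id` and `group` columns.
#' @param overlays_dir optional directory for overlay PNGs with green
#'   boxes around counted cells.
#' @param config configuration list or JSON path.
#' @return The counts [count_table()], invisibly.
#' @export
run_count <- function(model_file, images_dir, out_csv, groups_csv = NULL,
                      overlays_dir = NULL, config = list()) {
  if (is.character(config)) config <- read_config(config)
  model <- if (inherits(model_file, "hemocyte_model")) model_file
           else read_hemocyte_model(model_file)
  px_um <- cfg_get(config, "pixel_size_um", NULL)
  imgs <- read_image_dir(images_dir, px_um)
  groups <- NULL
  if (!is.null(groups_csv)) {
    groups <- utils::read.csv(groups_csv, stringsAsFactors = FALSE)
    stopifnot(all(c("image_id", "group") %in% names(groups)))
  }
  rows <- lapply(names(imgs), function(id) {
    res <- count_hemocytes(imgs[[id]], model)
    if (!is.null(overlays_dir)) {
      dir.create(overlays_dir, recursive = TRUE, showWarnings = FALSE)
      write_image(overlay_detections(imgs[[id]], res),
                  file.path(overlays_dir, paste0(id, "_overlay.png")))
    }
    area <- NA_real_
    if (!is.null(groups) && "field_area_mm2" %in% names(groups)) {
      hit <- match(id, groups$image_id)
      if (!is.na(hit)) area <- groups$field_area_mm2[hit]
    } else if (!is.null(px_um)) {
      d <- dim(imgs[[id]]$pixels)
      area <- d[1] * d[2] * px_um^2 / 1e6
    }
    grp <- if (!is.null(groups)) groups$group[match(id, groups$image_id)]
           else NA_character_
    data.frame(image_id = id, group = grp, count = res$count,
               field_area_mm2 = area, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, out_csv, row.names = FALSE)
  invisible(count_table(tab))
}

#' Group comparison of a counts table from files
#'
#' Runs the one-way ANOVA and the Tukey-Kramer pairwise test and writes a
#' JSON report with the ANOVA table, the pairwise matrix, and per-group
#' mean, SD and n.
#'
#' @param counts_csv counts CSV as written by [run_count()].
#' @param out_json output JSON path.
#' @param alpha significance level.
#' @param config configuration list or JSON path.
#' @return A list with elements `anova` and `tukey`, invisibly.
#' @export
run_stats <- function(counts_csv, out_json, alpha = 0.05, config = list()) {
  if (is.character(config)) config <- read_config(config)
  alpha <- cfg_get(config, "alpha", alpha)
  df <- utils::read.csv(counts_csv, stringsAsFactors = FALSE)
  tab <- count_table(df)
  a <- one_way_anova(tab)
  tk <- tukey_kramer(tab, alpha = alpha)
  doc <- list(
    anova = list(F = a$F, df_between = a$df_between, df_within = a$df_within,
                 p = a$p, ss_between = a$ss_between, ss_within = a$ss_within,
                 grand_mean = a$grand_mean),
    groups = data.frame(group = names(a$group_means),
                        mean = as.numeric(a$group_means),
                        sd = as.numeric(a$group_sds),
                        n = a$group_n),
    tukey_kramer = tk$pairs,
    alpha = alpha)
  writeLines(jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                              dataframe = "rows", pretty = TRUE), out_json)
  invisible(list(anova = a, tukey = tk))
}

#' Generate a synthetic study on disk
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param config configuration list or JSON path; `control_lambda`,
#'   `regen_lambda`, `n_per_group` and `groups` override the study
#'   defaults, other keys feed [synthetic_spec()].
#' @return The study list from [generate_study()], invisibly.
#' @export
run_simulate <- function(out_dir, seed = 1L, config = list()) {
  if (is.character(config)) config <- read_config(config)
  spec_args <- config[intersect(names(config),
                                c("pixel_size_um", "hemocyte_lambda"))]
  spec <- do.call(synthetic_spec, spec_args)
  study <- generate_study(
    control_lambda = cfg_get(config, "control_lambda", 2),
    regen_lambda = cfg_get(config, "regen_lambda", 14),
    n_per_group = cfg_get(config, "n_per_group", 30),
    groups = cfg_get(config, "groups", c("control", "regen")),
    spec = spec, seed = seed, dir = out_dir)
  invisible(study)
}
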