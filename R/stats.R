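#' Per-image hemocyte count table
#'
#' @param image_id character vector of image identifiers, or a data frame
#'   already holding the columns `image_id`, `group`, `count` (and
#'   optionally `field_area_mm2`).
#' @param group group label per image (e.g. control vs regenerating
#'   animals).
#' @param count non-negative integer hemocyte count per image.
#' @param field_area_mm2 imaged field area in mm^2 (optional; a 40x field
#'   of the reference acquisition setup covers 0.048 mm^2).
#' @return A data frame of class `count_table`.
#' @export
count_table <- function(image_id, group = NULL, count = NULL,
                        field_area_mm2 = NA_real_) {
  if (is.data.frame(image_id)) {
    df <- image_id
    stopifnot(all(c("image_id", "group", "count") %in% names(df)))
    if (!"field_area_mm2" %in% names(df)) df$field_area_mm2 <- NA_real_
  } else {
    df <- data.frame(image_id = as.character(image_id),
                     group = as.character(group),
                     count = count,
                     field_area_mm2 = field_area_mm2,
                     stringsAsFactors = FALSE)
  }
  if (any(df$count < 0) || any(df$count != round(df$count)))
    stop("counts must be non-negative integers", call. = FALSE)
  class(df) <- c("count_table", "data.frame")
  df
}

check_inference_table <- function(tab) {
  g <- factor(tab$group)
  if (nlevels(g) < 2L)
    stop("need at least 2 groups for inference", call. = FALSE)
  n <- table(g)
  if (any(n < 2L))
    stop(sprintf("every group needs >= 2 images (group '%s' has %d)",
                 names(n)[which.min(n)], min(n)), call. = FALSE)
  g
}

#' One-way analysis of variance on hemocyte counts
#'
#' Classical fixed-effects decomposition of per-image counts into
#' between-group and within-group sums of squares, with each image one
#' observation within its group. Backed by [stats::aov()].
#'
#' @param tab a [count_table()].
#' @param transform `"none"` (default; counts analysed untransformed) or
#'   `"log1p"`.
#' @return An object of class `hemocyte_anova` with elements `F`,
#'   `df_between`, `df_within`, `p`, `group_means`, `group_sds`,
#'   `group_n`, `grand_mean`, `ss_between`, `ss_within`.
#' @export
one_way_anova <- function(tab, transform = c("none", "log1p")) {
  transform <- match.arg(transform)
  g <- check_inference_table(tab)
  y <- if (transform == "log1p") log1p(tab$count) else as.numeric(tab$count)
  within_var <- tapply(y, g, stats::var)
  if (all(within_var == 0)) {
    if (stats::var(y) == 0)
      stop("degenerate variance: all counts identical", call. = FALSE)
    stop("degenerate variance: counts are constant within every group",
         call. = FALSE)
  }
  fit <- stats::aov(y ~ g)
  s <- summary(fit)[[1]]
  structure(list(
    F = s[1, "F value"],
    df_between = as.integer(s[1, "Df"]),
    df_within = as.integer(s[2, "Df"]),
    p = s[1, "Pr(>F)"],
    ss_between = s[1, "Sum Sq"],
    ss_within = s[2, "Sum Sq"],
    group_means = tapply(y, g, mean),
    group_sds = tapply(y, g, stats::sd),
    group_n = as.integer(table(g)),
    grand_mean = mean(y),
    transform = transform),
    class = "hemocyte_anova")
}

#' @export
print.hemocyte_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA on hemocyte counts%s\n",
              if (x$transform != "none") paste0(" (", x$transform, ")") else ""))
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n", x$df_between, x$df_within,
              x$F, x$p))
  m <- x$group_means; s <- x$group_sds
  for (i in seq_along(m))
    cat(sprintf("  %-12s mean %.3f +/- %.3f (n = %d)\n", names(m)[i], m[i],
                s[i], x$group_n[i]))
  invisible(x)
}

#' Tukey-Kramer pairwise comparison of group means
#'
#' All pairwise mean differences with the Kramer unequal-sample-size
#' standard error `sqrt(MSW/2 * (1/n_i + 1/n_j))`; adjusted p-values come
#' from the studentized-range distribution with `k` groups and the ANOVA
#' within-group degrees of freedom. With equal group sizes the standard
#' error reduces to the classical Tukey HSD form.
#'
#' @param tab a [count_table()].
#' @param alpha significance level for the `significant` flag.
#' @param transform as in [one_way_anova()].
#' @return An object of class `hemocyte_tukey` with a `pairs` data frame
#'   (`group_i`, `group_j`, `diff` = mean_j - mean_i, `se`, `q`,
#'   `p_adj`, `significant`).
#' @export
tukey_kramer <- function(tab, alpha = 0.05, transform = c("none", "log1p")) {
  stopifnot(alpha > 0, alpha < 1)
  transform <- match.arg(transform)
  aov_res <- one_way_anova(tab, transform)
  g <- check_inference_table(tab)
  k <- nlevels(g)
  msw <- aov_res$ss_within / aov_res$df_within
  lev <- levels(g)
  n <- as.integer(table(g))
  m <- aov_res$group_means
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    diff <- m[j] - m[i]
    se <- sqrt(msw / 2 * (1 / n[i] + 1 / n[j]))
    q <- abs(diff) / se
    p <- stats::ptukey(q, k, aov_res$df_within, lower.tail = FALSE)
    data.frame(group_i = lev[i], group_j = lev[j], diff = diff, se = se,
               q = q, p_adj = p, significant = p < alpha,
               stringsAsFactors = FALSE)
  })
  structure(list(pairs = do.call(rbind, rows), alpha = alpha, k = k,
                 df_within = aov_res$df_within, msw = msw,
                 anova = aov_res),
            class = "hemocyte_tukey")
}

#' @export
print.hemocyte_tukey <- function(x, ...) {
  cat(sprintf("Tukey-Kramer pairwise comparisons (k = %d, df = %d, alpha = %g)\n",
              x$k, x$df_within, x$alpha))
  print(x$pairs, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Hemocyte density per unit tissue area
#'
#' @param tab a [count_table()] with a positive `field_area_mm2` column.
#' @return The table with an added `density_per_mm2` column.
#' @export
density_per_area <- function(tab) {
  if (!"field_area_mm2" %in% names(tab) || anyNA(tab$field_area_mm2))
    stop("field_area_mm2 is missing; cannot compute densities", call. = FALSE)
  if (any(tab$field_area_mm2 <= 0))
    stop("field_area_mm2 must be positive", call. = FALSE)
  tab$density_per_mm2 <- tab$count / tab$field_area_mm2
  tab
}
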