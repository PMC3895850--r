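#' Polygon area (shoelace formula)
#'
#' Absolute enclosed area of a simple polygon; independent of vertex
#' orientation and of which vertex starts the ring.
#'
#' @param contour n x 2 matrix of vertices (mm), not repeated at the
#'   end; n >= 3.
#' @return area in mm^2.
#' @export
polygon_area <- function(contour) {
  p <- as.matrix(contour)
  if (nrow(p) < 3) abort("polygon needs at least 3 vertices", "parameter_error")
  if (polygon_self_intersects(p))
    abort("polygon self-intersects", "geometry_error")
  q <- p[c(2:nrow(p), 1), , drop = FALSE]
  abs(sum(p[, 1] * q[, 2] - q[, 1] * p[, 2]) / 2)
}

#' Relative cross-sectional area change of a cine series
#'
#' `(A_max - A_min) / A_min` over the frames of an [make_cine_series()]
#' result (or any list with an `areas` field / numeric vector of
#' areas).
#'
#' @param series an `area_series`, or a numeric vector of areas.
#' @return dimensionless fraction.
#' @export
relative_area_change <- function(series) {
  areas <- if (is.numeric(series)) series else series$areas
  if (length(areas) < 2) abort("need at least 2 frames", "validation_error")
  if (min(areas) <= 0) abort("areas must be positive", "validation_error")
  (max(areas) - min(areas)) / min(areas)
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper over [stats::cor()].
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero
#'   variance.
#' @return correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    abort("x and y must have equal length >= 3", "parameter_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort("zero variance in input", "statistics_error")
  stats::cor(x, y, method = "pearson")
}

#' Build a cohort table of per-subject quadrant stretch
#'
#' @param summaries named list of [quadrant_summary()] objects, one per
#'   subject.
#' @param groups character vector of group labels, one per subject.
#' @param area_change optional numeric vector of per-subject relative
#'   area changes.
#' @return data frame with columns subject, group, quadrant, stretch,
#'   s_overall (and area_change when supplied); 4 rows per subject.
#' @export
cohort_table <- function(summaries, groups, area_change = NULL) {
  stopifnot(length(summaries) == length(groups))
  ids <- names(summaries) %||% paste0("S", seq_along(summaries))
  rows <- lapply(seq_along(summaries), function(i) {
    qs <- summaries[[i]]
    data.frame(subject = ids[i], group = groups[i],
               quadrant = names(qs$s_quadrant),
               stretch = as.numeric(qs$s_quadrant),
               s_overall = qs$s_overall,
               area_change = if (is.null(area_change)) NA_real_
                             else area_change[i])
  })
  out <- do.call(rbind, rows)
  out$quadrant <- factor(out$quadrant, levels = c("A", "R", "P", "L"))
  out$group <- factor(out$group)
  out
}

#' Two-way ANOVA with Tukey contrasts on quadrant stretch
#'
#' Fits `stretch ~ group * quadrant` on the per-subject per-quadrant
#' mean stretch (4 rows per subject) with [stats::aov()] and reports
#' the F table plus Tukey honest-significant-difference comparisons
#' within each factor. The unit of observation is the subject-quadrant
#' cell; no within-quadrant nesting is modelled.
#'
#' @param table a [cohort_table()] (columns group, quadrant, stretch).
#' @return list of class `stretch_anova` with `effects` (data frame:
#'   term, df, F, p), `tukey_group`, `tukey_quadrant` and the fitted
#'   `aov` object.
#' @export
stretch_anova <- function(table) {
  need <- c("group", "quadrant", "stretch")
  if (!all(need %in% names(table)))
    abort("cohort table needs columns group, quadrant, stretch",
          "validation_error")
  table$group <- factor(table$group)
  table$quadrant <- factor(table$quadrant)
  if (nlevels(table$group) < 2)
    abort("need at least 2 groups", "parameter_error")
  cells <- table(table$group, table$quadrant)
  if (any(cells == 0)) {
    miss <- which(cells == 0, arr.ind = TRUE)
    abort(paste0("empty cells: ",
                 paste(sprintf("%s:%s", rownames(cells)[miss[, 1]],
                               colnames(cells)[miss[, 2]]), collapse = ", ")),
          "statistics_error")
  }
  if (min(table(table$group)) / nlevels(table$quadrant) < 2)
    abort("need at least 2 subjects per group", "parameter_error")
  fit <- stats::aov(stretch ~ group * quadrant, data = table)
  sm <- summary(fit)[[1]]
  k <- seq_len(nrow(sm) - 1)
  effects <- data.frame(
    term = trimws(rownames(sm))[k],
    df = sm$Df[k],
    F = sm$`F value`[k],
    p = sm$`Pr(>F)`[k])
  # an exactly zero effect sum of squares is no evidence of an effect,
  # even when the residual variance is also zero (0/0 in the F ratio)
  zero <- sm$`Sum Sq`[k] == 0
  effects$F[zero] <- 0
  effects$p[zero] <- 1
  tk <- stats::TukeyHSD(fit, which = c("group", "quadrant"))
  structure(list(effects = effects,
                 tukey_group = tk$group,
                 tukey_quadrant = tk$quadrant,
                 fit = fit),
            class = "stretch_anova")
}

#' @export
print.stretch_anova <- function(x, ...) {
  cat("<stretch_anova> two-way ANOVA (group x quadrant)\n")
  print(x$effects, row.names = FALSE)
  invisible(x)
}

#' Write / read a cohort table as delimited text
#' @param table a [cohort_table()].
#' @param path file path (tab-separated, header row).
#' @export
write_cohort <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  out$quadrant <- factor(out$quadrant, levels = c("A", "R", "P", "L"))
  out$group <- factor(out$group)
  out
}
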