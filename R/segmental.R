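#' Normal native T1 range
#'
#' Institutional-style normal range for native myocardial T1 at 1.5 T.
#' Segmental values strictly above `upper` are flagged abnormal.
#'
#' @param lower,upper bounds in ms.
#' @return A `normal_range` object.
#' @export
normal_range <- function(lower = 900, upper = 1050) {
  if (!(lower < upper)) stop("lower must be < upper")
  structure(list(lower = lower, upper = upper), class = "normal_range")
}

# Angular sector definitions of the analyzed AHA segments, per slice level.
# Only septal and lateral walls are analyzed; anterior and inferior sectors
# are excluded (partial-volume-prone in small patients). Basal/mid slices
# contribute two septal segments and one combined lateral region; apical
# slices one septal and one lateral segment.
segment_definitions <- function(rv_insertion_angle = 0) {
  r <- rv_insertion_angle
  list(
    basal = list(
      list(segment_id = "2",     from = r + 30,  to = r + 90),
      list(segment_id = "3",     from = r + 90,  to = r + 150),
      list(segment_id = "5+6",   from = r + 210, to = r + 330)),
    mid = list(
      list(segment_id = "8",     from = r + 30,  to = r + 90),
      list(segment_id = "9",     from = r + 90,  to = r + 150),
      list(segment_id = "11+12", from = r + 210, to = r + 330)),
    apical = list(
      list(segment_id = "14",    from = r + 45,  to = r + 135),
      list(segment_id = "16",    from = r + 225, to = r + 315))
  )
}

#' Build segmental ROI masks for one phantom slice
#'
#' Automated analogue of manual ROI tracing for phantom geometry: full-wall
#' angular sectors of the myocardial annulus. Basal and mid slices yield
#' three ROIs (AHA segments 2 and 3 or 8 and 9, plus the combined lateral
#' region 5+6 or 11+12); apical slices yield two (segments 14 and 16).
#' Anterior and inferior sectors are never included. For real images,
#' user-drawn masks can be supplied directly to [segmental_t1()] instead.
#'
#' @param map a `t1_map` with a non-`"excluded"` slice level.
#' @param geometry the [phantom_config()] describing the slice geometry.
#' @return List of `segment_roi` objects (`segment_id`, `slice_index`,
#'   `level`, logical `mask`).
#' @export
build_segment_masks <- function(map, geometry) {
  stopifnot(inherits(map, "t1_map"), inherits(geometry, "phantom_config"))
  if (map$slice_level == "excluded") {
    stop("slice ", map$slice_index, " is tagged 'excluded'")
  }
  if (!all(dim(map$pixels) == geometry$image_size)) {
    stop("map dimensions do not match phantom geometry")
  }
  g <- phantom_geometry(geometry)
  defs <- segment_definitions(geometry$rv_insertion_angle)[[map$slice_level]]
  lapply(defs, function(d) {
    mask <- g$myo & in_sector(g$angle, d$from, d$to)
    if (!any(mask)) stop("empty mask for segment ", d$segment_id)
    structure(list(segment_id = d$segment_id,
                   slice_index = map$slice_index,
                   level = map$slice_level, mask = mask),
              class = "segment_roi")
  })
}

#' Restrict an ROI to the radial middle third of the wall
#'
#' Keeps only pixels whose distance r from the LV center satisfies
#' `endo + w/3 <= r < endo + 2w/3` with `w = epi - endo`. This avoids
#' blood-pool contamination at the endocardial border and partial-volume
#' artifact at the epicardial border.
#'
#' @param roi a `segment_roi`.
#' @param endo_radius,epi_radius wall radii in pixels.
#' @param center LV center, 0-based `(row, col)`.
#' @return A `segment_roi` whose mask is a subset of the input mask.
#' @export
extract_middle_third <- function(roi, endo_radius, epi_radius, center) {
  stopifnot(inherits(roi, "segment_roi"))
  d <- dim(roi$mask)
  rows <- matrix(0:(d[1] - 1), d[1], d[2])
  cols <- matrix(0:(d[2] - 1), d[1], d[2], byrow = TRUE)
  dist <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
  w <- epi_radius - endo_radius
  keep <- roi$mask & dist >= endo_radius + w / 3 & dist < endo_radius + 2 * w / 3
  if (!any(keep)) {
    stop("middle-third mask is empty for segment ", roi$segment_id,
         " (wall too thin at this resolution)")
  }
  roi$mask <- keep
  roi
}

#' Build the 16 middle-third segmental ROIs for a study
#'
#' Convenience wrapper: for each of the six analyzed slices, builds the
#' segment masks and restricts each to the radial middle third of the wall,
#' yielding the 16 ROIs consumed by [segmental_t1()].
#'
#' @param study a `t1_study`.
#' @param config the [phantom_config()] used to generate it.
#' @param middle_third apply [extract_middle_third()] (default `TRUE`).
#' @return List of 16 `segment_roi` objects.
#' @export
study_rois <- function(study, config, middle_third = TRUE) {
  stopifnot(inherits(study, "t1_study"))
  rois <- list()
  for (map in study$maps) {
    if (map$slice_level == "excluded") next
    slice_rois <- build_segment_masks(map, config)
    if (middle_third) {
      slice_rois <- lapply(slice_rois, extract_middle_third,
                           endo_radius = config$endo_radius,
                           epi_radius = config$epi_radius,
                           center = config$center)
    }
    rois <- c(rois, slice_rois)
  }
  rois
}

#' Segmental, global mean and peak native T1
#'
#' Averages T1 over each of the 16 segmental ROIs, then summarizes:
#' the global mean is the unweighted arithmetic mean of the 16 segmental
#' values (not pixel-weighted) and the peak is their maximum. A segmental
#' value is flagged abnormal when strictly above the upper normal bound.
#'
#' @param study a `t1_study`.
#' @param rois list of exactly 16 `segment_roi` objects covering the six
#'   analyzed slices (see [study_rois()]); for real images these are the
#'   user-drawn masks, assumed already restricted to the middle third.
#' @param normal a [normal_range()].
#' @return A `segmental_t1_result`: `segments` data frame (slice_index,
#'   level, segment_id, mean_t1, abnormal), `global_mean_t1`, `peak_t1`,
#'   `n_abnormal`, `normal`.
#' @export
segmental_t1 <- function(study, rois, normal = normal_range()) {
  stopifnot(inherits(study, "t1_study"), inherits(normal, "normal_range"))
  if (length(rois) != 16L) {
    stop("expected exactly 16 ROIs, got ", length(rois))
  }
  vals <- vapply(rois, function(roi) {
    stopifnot(inherits(roi, "segment_roi"))
    if (!any(roi$mask)) stop("empty ROI mask (segment ", roi$segment_id, ")")
    mean(study$maps[[roi$slice_index]]$pixels[roi$mask])
  }, numeric(1))
  seg <- data.frame(
    slice_index = vapply(rois, `[[`, integer(1), "slice_index"),
    level = vapply(rois, `[[`, character(1), "level"),
    segment_id = vapply(rois, `[[`, character(1), "segment_id"),
    mean_t1 = vals,
    abnormal = vals > normal$upper,
    stringsAsFactors = FALSE)
  structure(list(segments = seg,
                 global_mean_t1 = mean(vals),
                 peak_t1 = max(vals),
                 n_abnormal = sum(seg$abnormal),
                 normal = normal),
            class = "segmental_t1_result")
}

#' @export
print.segmental_t1_result <- function(x, ...) {
  cat(sprintf("<segmental_t1_result> global mean %.1f ms, peak %.1f ms, %d/16 abnormal (> %g ms)\n",
              x$global_mean_t1, x$peak_t1, x$n_abnormal, x$normal$upper))
  invisible(x)
}

#' Interobserver agreement: intraclass correlation coefficient
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC
#' (ICC(A,1) in the McGraw & Wong nomenclature), computed from the two-way
#' ANOVA mean squares of the subject-by-reader table, with an F-based 95%
#' confidence interval. This specific ICC form is recorded in the result
#' since "intraclass correlation" alone is ambiguous.
#'
#' @param reader1,reader2 numeric vectors of paired measurements (same
#'   cases, two readers), length >= 3.
#' @param conf_level confidence level for the interval.
#' @return List: `icc`, `lower`, `upper`, `model`, and the mean squares.
#' @export
interobserver_icc <- function(reader1, reader2, conf_level = 0.95) {
  if (length(reader1) != length(reader2)) stop("readers must have equal length")
  n <- length(reader1)
  if (n < 3L) stop("need at least 3 paired measurements")
  y <- cbind(reader1, reader2)
  k <- 2L
  grand <- mean(y)
  row_m <- rowMeans(y)
  col_m <- colMeans(y)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((y - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom <= 0 || (msr == 0 && mse == 0 && msc == 0)) {
    stop("ICC undefined: no variance in either reader")
  }
  icc <- (msr - mse) / denom
  alpha <- 1 - conf_level
  lower <- upper <- NA_real_
  if (mse > 0 && icc < 1) {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- qf(1 - alpha / 2, n - 1, v)
    f_u <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  }
  list(icc = icc, lower = lower, upper = upper,
       model = "two-way random effects, absolute agreement, single measure (ICC(A,1))",
       msr = msr, msc = msc, mse = mse, n = n, k = k)
}
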