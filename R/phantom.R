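#' Phantom configuration for synthetic short-axis T1 maps
#'
#' Describes the geometry and signal model of a circular left-ventricular
#' phantom: an annular myocardium (between `endo_radius` and `epi_radius`)
#' with baseline native T1, a blood pool inside the endocardial radius, and
#' zero-valued background. Pixel coordinates are 0-based `(row, col)`;
#' angles are measured in degrees counterclockwise from the anterior
#' direction ("up" as displayed). The septal arc used for segment masks is
#' the 120 degrees centered on `rv_insertion_angle + 90`.
#'
#' @param image_size pixels per side (square image).
#' @param endo_radius,epi_radius endocardial / epicardial radii in pixels.
#' @param center `(row, col)` of the LV center, 0-based; defaults to the
#'   image center.
#' @param baseline_t1 myocardial T1 in ms.
#' @param blood_t1 blood-pool T1 in ms.
#' @param noise_sd amplitude (ms) of the Gaussian noise field added to
#'   myocardial and blood pixels. When `noise_smooth_sigma > 0` the white
#'   field is smoothed with a Gaussian kernel of that width before scaling,
#'   emulating the spatially correlated noise of fitted parametric maps
#'   (the per-pixel SD is then below `noise_sd`).
#' @param noise_smooth_sigma spatial correlation length of the noise field
#'   in pixels (0 = independent per-pixel noise).
#' @param quantize_ms round pixel values to integer milliseconds, as
#'   scanner-exported parametric maps are stored (default TRUE).
#' @param rv_insertion_angle degrees; anterior RV insertion reference fixing
#'   the segment layout.
#' @param n_slices number of short-axis slices in a study (>= 6).
#' @param pixel_spacing mm per pixel.
#' @return A `phantom_config` object (validated list).
#' @export
phantom_config <- function(image_size = 128L,
                           endo_radius = 20,
                           epi_radius = 34,
                           center = NULL,
                           baseline_t1 = 1000,
                           blood_t1 = 1600,
                           noise_sd = 20,
                           noise_smooth_sigma = 1.5,
                           quantize_ms = TRUE,
                           rv_insertion_angle = 0,
                           n_slices = 8L,
                           pixel_spacing = 1.4) {
  if (is.null(center)) center <- c((image_size - 1) / 2, (image_size - 1) / 2)
  cfg <- list(image_size = as.integer(image_size),
              endo_radius = endo_radius, epi_radius = epi_radius,
              center = as.numeric(center), baseline_t1 = baseline_t1,
              blood_t1 = blood_t1, noise_sd = noise_sd,
              noise_smooth_sigma = noise_smooth_sigma,
              quantize_ms = isTRUE(quantize_ms),
              rv_insertion_angle = rv_insertion_angle,
              n_slices = as.integer(n_slices),
              pixel_spacing = pixel_spacing)
  if (!(endo_radius > 0 && epi_radius > endo_radius &&
        epi_radius < image_size / 2)) {
    stop("invalid phantom geometry: need 0 < endo_radius < epi_radius < image_size/2")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (noise_smooth_sigma < 0) stop("noise_smooth_sigma must be >= 0")
  if (cfg$n_slices < 6L) stop("n_slices must be >= 6")
  if (length(center) != 2L) stop("center must be (row, col)")
  class(cfg) <- "phantom_config"
  cfg
}

#' Focal high-T1 hotspot specification
#'
#' A wedge-shaped region of altered T1 inside the myocardial wall, used to
#' emulate the focal elevations ("hotspots") that make rejection maps
#' spatially heterogeneous. The wedge spans `angular_width` degrees around
#' `center_angle` and extends radially from the endocardium across
#' `radial_span` of the wall thickness.
#'
#' @param center_angle degrees (see [phantom_config()] for the convention).
#' @param angular_width degrees, > 0.
#' @param radial_span fraction of wall thickness in (0, 1].
#' @param delta_t1 ms added to the baseline inside the wedge (any sign;
#'   rejection emulation uses positive values).
#' @return A `hotspot_spec` object.
#' @export
hotspot_spec <- function(center_angle, angular_width, radial_span = 1,
                         delta_t1 = 150) {
  if (angular_width <= 0) stop("angular_width must be > 0")
  if (radial_span <= 0 || radial_span > 1) stop("radial_span must be in (0, 1]")
  structure(list(center_angle = center_angle, angular_width = angular_width,
                 radial_span = radial_span, delta_t1 = delta_t1),
            class = "hotspot_spec")
}

# Cached pixel-center geometry for a phantom configuration: distance and
# angle of every pixel from the LV center, plus myocardium/blood masks.
phantom_geometry <- function(config) {
  key <- paste0("geom_", paste(config$image_size, config$center[1],
                               config$center[2], config$endo_radius,
                               config$epi_radius, config$rv_insertion_angle,
                               collapse = "_", sep = "_"))
  g <- .t1tex_cache[[key]]
  if (!is.null(g)) return(g)
  s <- config$image_size
  rows <- matrix(0:(s - 1), s, s)          # 0-based row index
  cols <- matrix(0:(s - 1), s, s, byrow = TRUE)
  dr <- rows - config$center[1]
  dc <- cols - config$center[2]
  dist <- sqrt(dr^2 + dc^2)
  # 0 deg = anterior (up); increases counterclockwise as displayed
  angle <- (atan2(-dc, -dr) * 180 / pi) %% 360
  g <- list(dist = dist, angle = angle,
            myo = dist >= config$endo_radius & dist < config$epi_radius,
            blood = dist < config$endo_radius)
  .t1tex_cache[[key]] <- g
  g
}

# Banded row-normalized 1-D Gaussian convolution matrix (cached); the noise
# field is smoothed as K %*% X %*% t(K).
smoothing_matrix <- function(size, sigma) {
  key <- paste0("smooth_", size, "_", sigma)
  K <- .t1tex_cache[[key]]
  if (!is.null(K)) return(K)
  half <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-half:half)^2) / (2 * sigma^2))
  K <- matrix(0, size, size)
  for (i in seq_len(size)) {
    idx <- (i - half):(i + half)
    ok <- idx >= 1 & idx <= size
    K[i, idx[ok]] <- kern[ok]
    K[i, ] <- K[i, ] / sum(K[i, ])
  }
  .t1tex_cache[[key]] <- K
  K
}

#' Generate one synthetic short-axis T1 map
#'
#' Builds a square T1 map (values in ms): annular myocardium at
#' `baseline_t1` plus any hotspot deltas, blood pool at `blood_t1`, zero
#' background, with independent Gaussian noise of SD `noise_sd` added to
#' myocardial and blood pixels. Deterministic for a fixed seed.
#'
#' @param config a [phantom_config()].
#' @param hotspots list of [hotspot_spec()] objects (possibly empty).
#' @param slice_level one of `"basal"`, `"mid"`, `"apical"`, `"excluded"`.
#' @param seed integer seed (required).
#' @param slice_index position of the slice in its stack.
#' @return A `t1_map`: list with `pixels` (matrix, ms), `pixel_spacing`,
#'   `slice_index`, `slice_level`.
#' @export
generate_t1_slice <- function(config, hotspots = list(),
                              slice_level = "mid", seed,
                              slice_index = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  if (missing(seed)) stop("seed must be given")
  slice_level <- match.arg(slice_level, c("basal", "mid", "apical", "excluded"))
  if (inherits(hotspots, "hotspot_spec")) hotspots <- list(hotspots)
  g <- phantom_geometry(config)
  s <- config$image_size
  px <- matrix(0, s, s)
  px[g$myo] <- config$baseline_t1
  for (h in hotspots) {
    stopifnot(inherits(h, "hotspot_spec"))
    wall <- config$epi_radius - config$endo_radius
    hit <- g$myo &
      in_wedge(g$angle, h$center_angle, h$angular_width) &
      g$dist < config$endo_radius + h$radial_span * wall
    px[hit] <- px[hit] + h$delta_t1
  }
  px[g$blood] <- config$blood_t1
  if (config$noise_sd > 0) {
    signal <- g$myo | g$blood
    with_seed(seed, {
      if (config$noise_smooth_sigma > 0) {
        K <- smoothing_matrix(s, config$noise_smooth_sigma)
        field <- K %*% matrix(rnorm(s * s), s, s) %*% t(K)
        px[signal] <- px[signal] + config$noise_sd * field[signal]
      } else {
        px[signal] <- px[signal] + rnorm(sum(signal), 0, config$noise_sd)
      }
    })
  }
  if (config$quantize_ms) px <- round(px)
  structure(list(pixels = px, pixel_spacing = config$pixel_spacing,
                 slice_index = as.integer(slice_index),
                 slice_level = slice_level),
            class = "t1_map")
}

# Slice-level tags for an n-slice base->apex stack: the middle six slices
# are analyzed (2 basal, 2 mid, 2 apical); extra basal/apical slices are
# tagged "excluded".
slice_levels <- function(n_slices) {
  if (n_slices < 6L) stop("n_slices must be >= 6")
  k1 <- (n_slices - 6L) %/% 2L
  k2 <- n_slices - 6L - k1
  c(rep("excluded", k1),
    rep(c("basal", "mid", "apical"), each = 2L),
    rep("excluded", k2))
}

#' Generate a synthetic short-axis T1 study (slice stack)
#'
#' Produces an ordered base-to-apex stack of [generate_t1_slice()] maps.
#' The middle six slices are tagged 2 basal / 2 mid / 2 apical for
#' downstream segmental analysis; with an 8-slice stack the most basal and
#' most apical slices are tagged `"excluded"`.
#'
#' @param config a [phantom_config()].
#' @param hotspots_per_slice list of length `n_slices`, each element a list
#'   of [hotspot_spec()]s for that slice; `NULL` means no hotspots anywhere.
#' @param seed integer seed; per-slice seeds are derived from it.
#' @param case_id identifier stored on the study.
#' @return A `t1_study`: list with `maps` (list of `t1_map`) and `case_id`.
#' @export
generate_t1_study <- function(config, hotspots_per_slice = NULL, seed,
                              case_id = "case") {
  stopifnot(inherits(config, "phantom_config"))
  if (missing(seed)) stop("seed must be given")
  n <- config$n_slices
  if (is.null(hotspots_per_slice)) {
    hotspots_per_slice <- rep(list(list()), n)
  }
  if (length(hotspots_per_slice) != n) {
    stop("hotspots_per_slice must have one entry per slice (", n, ")")
  }
  levels <- slice_levels(n)
  slice_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  maps <- vector("list", n)
  for (i in seq_len(n)) {
    maps[[i]] <- generate_t1_slice(config, hotspots_per_slice[[i]],
                                   slice_level = levels[i],
                                   seed = slice_seeds[i], slice_index = i)
  }
  structure(list(maps = maps, case_id = case_id), class = "t1_study")
}

#' @export
print.t1_study <- function(x, ...) {
  lv <- vapply(x$maps, `[[`, "", "slice_level")
  cat("<t1_study> ", x$case_id, ": ", length(x$maps), " slices (",
      paste(lv, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Index of the slice used for texture analysis
#'
#' Texture is computed on a single mid-ventricular slice; by convention the
#' lower-indexed of the two mid-tagged slices.
#'
#' @param study a `t1_study`.
#' @return Integer slice index within the stack.
#' @export
texture_slice_index <- function(study) {
  lv <- vapply(study$maps, `[[`, "", "slice_level")
  idx <- which(lv == "mid")
  if (length(idx) == 0L) stop("study has no mid-tagged slice")
  idx[1L]
}
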