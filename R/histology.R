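#' Construct a histology image object
#'
#' @param rgb integer array `h x w x 3`, channels in 0..255.
#' @param exclusion_mask optional logical matrix (`h x w`) of manually
#'   excluded regions (endocardial collagen, artifacts).
#' @param pixel_size optional micrometers per pixel.
#' @return A `histology_image`.
#' @export
histology_image <- function(rgb, exclusion_mask = NULL, pixel_size = NULL) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  if (min(rgb) < 0 || max(rgb) > 255) stop("channels must be in 0..255")
  if (!is.null(exclusion_mask) &&
      !all(dim(exclusion_mask) == dim(rgb)[1:2])) {
    stop("exclusion_mask shape must match the image")
  }
  structure(list(rgb = rgb, exclusion_mask = exclusion_mask,
                 pixel_size = pixel_size),
            class = "histology_image")
}

#' Tissue mask of a trichrome slide image
#'
#' Pixels are tissue when their mean channel value is below the background
#' luminance cutoff (i.e. not white slide background) and they are not in
#' the exclusion mask. The tissue mask is the denominator of the fibrosis
#' percentage.
#'
#' @param img a `histology_image`.
#' @param background_luminance_cutoff mean-channel level (0..255) above
#'   which a pixel is background; default 240.
#' @return Logical matrix.
#' @export
tissue_mask <- function(img, background_luminance_cutoff = 240) {
  stopifnot(inherits(img, "histology_image"))
  lum <- (img$rgb[, , 1] + img$rgb[, , 2] + img$rgb[, , 3]) / 3
  m <- lum < background_luminance_cutoff
  if (!is.null(img$exclusion_mask)) m <- m & !img$exclusion_mask
  if (!any(m)) stop("no tissue pixels found")
  m
}

#' Colorimetric blue-collagen mask
#'
#' Identifies collagen pixels on a Masson-trichrome slide by a recorded,
#' parameterized colorimetric rule. The default RGB channel-margin rule
#' calls a pixel collagen when it is tissue, its blue channel is at least
#' `blue_min`, and blue exceeds both red and green by at least `margin`.
#' An HSV hue-window variant is available behind `rule = "hsv"` (hue in
#' `hue_window`, saturation at least `sat_min`).
#'
#' @param img a `histology_image`.
#' @param blue_min minimum blue level (default 100).
#' @param margin minimum blue-over-red and blue-over-green excess
#'   (default 20).
#' @param rule `"rgb_margin"` (default) or `"hsv"`.
#' @param hue_window hue interval in \[0, 1\] for the HSV rule (blue is
#'   around 2/3).
#' @param sat_min minimum saturation for the HSV rule.
#' @param tissue optional precomputed tissue mask.
#' @param background_luminance_cutoff passed to [tissue_mask()] when
#'   `tissue` is not supplied.
#' @return Logical matrix, a subset of the tissue mask.
#' @export
blue_collagen_mask <- function(img, blue_min = 100, margin = 20,
                               rule = c("rgb_margin", "hsv"),
                               hue_window = c(0.5, 0.83), sat_min = 0.15,
                               tissue = NULL,
                               background_luminance_cutoff = 240) {
  stopifnot(inherits(img, "histology_image"))
  rule <- match.arg(rule)
  if (is.null(tissue)) tissue <- tissue_mask(img, background_luminance_cutoff)
  r <- img$rgb[, , 1]; g <- img$rgb[, , 2]; b <- img$rgb[, , 3]
  if (rule == "rgb_margin") {
    tissue & b >= blue_min & (b - r) >= margin & (b - g) >= margin
  } else {
    hsv <- grDevices::rgb2hsv(r = as.vector(r), g = as.vector(g),
                              b = as.vector(b), maxColorValue = 255)
    hue <- matrix(hsv[1, ], nrow(r), ncol(r))
    sat <- matrix(hsv[2, ], nrow(r), ncol(r))
    tissue & hue >= hue_window[1] & hue <= hue_window[2] & sat >= sat_min
  }
}

#' Percentage tissue fibrosis of a trichrome slide
#'
#' Fibrosis percent = 100 x collagen pixels / tissue pixels, with manual
#' exclusion regions removed from both numerator and denominator. The
#' colorimetric parameters used are recorded in the result.
#'
#' @param img a `histology_image`.
#' @param blue_min,margin,rule,background_luminance_cutoff see
#'   [blue_collagen_mask()] and [tissue_mask()].
#' @return A `fibrosis_result`: `fibrosis_percent`, `n_collagen`,
#'   `n_tissue`, `threshold_params`.
#' @export
fibrosis_percentage <- function(img, blue_min = 100, margin = 20,
                                rule = "rgb_margin",
                                background_luminance_cutoff = 240) {
  tissue <- tissue_mask(img, background_luminance_cutoff)
  collagen <- blue_collagen_mask(img, blue_min = blue_min, margin = margin,
                                 rule = rule, tissue = tissue)
  n_tissue <- sum(tissue)
  n_collagen <- sum(collagen)
  structure(list(fibrosis_percent = 100 * n_collagen / n_tissue,
                 n_collagen = n_collagen, n_tissue = n_tissue,
                 threshold_params = list(
                   rule = rule, blue_min = blue_min, margin = margin,
                   background_luminance_cutoff = background_luminance_cutoff)),
            class = "fibrosis_result")
}

#' @export
print.fibrosis_result <- function(x, ...) {
  cat(sprintf("<fibrosis_result> %.2f%% fibrosis (%d collagen / %d tissue pixels)\n",
              x$fibrosis_percent, x$n_collagen, x$n_tissue))
  invisible(x)
}

#' Generate a synthetic trichrome slide image with known collagen fraction
#'
#' Builds an RGB slide emulating a Masson-trichrome-stained biopsy section:
#' a disc of tissue on a white background in which exactly
#' `round(collagen_fraction * n_tissue)` randomly placed pixels take a
#' blue-dominant collagen palette and the remainder a red-dominant
#' cytoplasm palette. The default palettes lie strictly inside (collagen)
#' and outside (cytoplasm) the default colorimetric rule, so recovery by
#' [fibrosis_percentage()] is exact. Ground-truth masks are returned
#' alongside the image.
#'
#' @param collagen_fraction proportion in \[0, 1\].
#' @param size image side in pixels.
#' @param seed integer seed.
#' @return List: `image` (a `histology_image`), `tissue_truth` and
#'   `collagen_truth` logical matrices, and `collagen_fraction`.
#' @export
generate_trichrome_image <- function(collagen_fraction, size = 200L, seed) {
  if (collagen_fraction < 0 || collagen_fraction > 1) {
    stop("collagen_fraction must be in [0, 1]")
  }
  if (missing(seed)) stop("seed must be given")
  s <- as.integer(size)
  rows <- matrix(0:(s - 1), s, s)
  cols <- matrix(0:(s - 1), s, s, byrow = TRUE)
  ctr <- (s - 1) / 2
  tissue <- sqrt((rows - ctr)^2 + (cols - ctr)^2) < 0.45 * s
  n_tissue <- sum(tissue)
  n_coll <- round(collagen_fraction * n_tissue)
  r <- matrix(255L, s, s); g <- matrix(255L, s, s); b <- matrix(255L, s, s)
  coll_idx <- integer(0)
  with_seed(seed, {
    tissue_idx <- which(tissue)
    coll_idx <- if (n_coll > 0) sample(tissue_idx, n_coll) else integer(0)
    cyto_idx <- setdiff(tissue_idx, coll_idx)
    # collagen: blue-dominant; cytoplasm: red-dominant (muscle)
    r[coll_idx] <- sample(40:80, n_coll, replace = TRUE)
    g[coll_idx] <- sample(40:90, n_coll, replace = TRUE)
    b[coll_idx] <- sample(150:220, n_coll, replace = TRUE)
    r[cyto_idx] <- sample(150:220, length(cyto_idx), replace = TRUE)
    g[cyto_idx] <- sample(40:90, length(cyto_idx), replace = TRUE)
    b[cyto_idx] <- sample(40:80, length(cyto_idx), replace = TRUE)
  })
  collagen <- matrix(FALSE, s, s)
  collagen[coll_idx] <- TRUE
  img <- histology_image(array(c(r, g, b), dim = c(s, s, 3)))
  list(image = img, tissue_truth = tissue, collagen_truth = collagen,
       collagen_fraction = collagen_fraction)
}
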