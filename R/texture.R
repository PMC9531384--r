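#' Otsu threshold of a set of intensities
#'
#' Exact Otsu threshold on the empirical value histogram: the cut that
#' maximizes the between-class variance \eqn{w_1 w_2 (\mu_1 - \mu_2)^2}
#' over all cuts between consecutive distinct values. Every distinct value
#' is its own histogram bin, so the search is exhaustive and deterministic;
#' ties are broken towards the lowest cut. The returned threshold is the
#' midpoint between the two distinct values straddling the optimal cut
#' (class 1 is `value <= threshold`).
#'
#' @param values numeric vector with at least 2 distinct finite values.
#' @return Scalar threshold.
#' @export
otsu_threshold <- function(values) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  u <- sort(unique(v))
  if (length(u) < 2L) stop("Otsu threshold undefined: fewer than 2 distinct values")
  w <- tabulate(match(v, u), nbins = length(u))
  n <- length(v)
  w1 <- cumsum(w)
  s1 <- cumsum(w * u)
  total <- s1[length(s1)]
  k <- seq_len(length(u) - 1L)
  w2 <- n - w1[k]
  mu1 <- s1[k] / w1[k]
  mu2 <- (total - s1[k]) / w2
  between <- w1[k] * w2 * (mu1 - mu2)^2
  kstar <- which.max(between)
  (u[kstar] + u[kstar + 1L]) / 2
}

# TRUE where a 4-neighbor of `m` is TRUE (no wraparound).
neighbor4_any <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  out[-nr, ] <- out[-nr, ] | m[-1, ]   # neighbor below
  out[-1, ]  <- out[-1, ]  | m[-nr, ]  # neighbor above
  out[, -nc] <- out[, -nc] | m[, -1]   # neighbor right
  out[, -1]  <- out[, -1]  | m[, -nc]  # neighbor left
  out
}

#' Segment LV myocardium from a T1 map
#'
#' Semiautomatic myocardial segmentation: a first Otsu threshold separates
#' signal (myocardium + blood) from background, a second Otsu threshold on
#' the signal pixels separates myocardium from the higher-T1 blood pool,
#' the largest connected myocardial component is retained, and a one-pixel
#' erosion is applied at the outer (epicardial) boundary to exclude
#' epicardial partial-volume pixels. The blood pool and background are
#' thereby excluded from the mask.
#'
#' @param map a `t1_map` containing myocardium, blood pool and background.
#' @param erode_outer apply the one-pixel epicardial erosion (default TRUE).
#' @return A `myocardium_mask`: logical `mask` plus `provenance` (both Otsu
#'   thresholds and the cleanup steps applied).
#' @export
segment_myocardium <- function(map, erode_outer = TRUE) {
  stopifnot(inherits(map, "t1_map"))
  px <- map$pixels
  thr_bg <- otsu_threshold(px)
  fg <- px > thr_bg
  if (!any(fg)) stop("no foreground above background threshold")

  # largest connected component below the tissue/blood threshold, plus the
  # region of background enclosed by it (the blood-pool hole)
  candidate <- function(thr_tissue) {
    myo <- fg & px <= thr_tissue
    if (!any(myo)) return(NULL)
    labels <- EBImage::bwlabel(myo)
    mask <- labels == which.max(tabulate(labels[labels > 0]))
    out_lab <- EBImage::bwlabel(!mask)
    border_ids <- unique(c(out_lab[1, ], out_lab[nrow(out_lab), ],
                           out_lab[, 1], out_lab[, ncol(out_lab)]))
    outside <- matrix(out_lab %in% border_ids[border_ids > 0],
                      nrow(mask), ncol(mask))
    list(mask = mask, outside = outside,
         annular = any(!outside & !mask))
  }

  thr_tissue <- otsu_threshold(px[fg])
  cand <- candidate(thr_tissue)
  if (is.null(cand) || !cand$annular) {
    # a focal elevation can pull the Otsu cut below bright myocardium and
    # break the annulus; re-split the upper class to separate blood only
    thr_hi <- tryCatch(otsu_threshold(px[fg & px > thr_tissue]),
                       error = function(e) NULL)
    if (!is.null(thr_hi)) {
      cand_hi <- candidate(thr_hi)
      if (!is.null(cand_hi) && cand_hi$annular) {
        thr_tissue <- thr_hi
        cand <- cand_hi
      }
    }
  }
  if (is.null(cand) || !cand$annular) {
    stop("no annular myocardial component found (no enclosed blood pool)")
  }
  mask <- cand$mask
  if (erode_outer) {
    mask <- mask & !neighbor4_any(cand$outside)
  }
  if (!any(mask)) stop("myocardial mask empty after cleanup")
  structure(list(mask = mask,
                 provenance = list(threshold_background = thr_bg,
                                   threshold_tissue = thr_tissue,
                                   largest_component = TRUE,
                                   outer_erosion = erode_outer)),
            class = "myocardium_mask")
}

as_mask_matrix <- function(mask) {
  if (inherits(mask, "myocardium_mask")) mask$mask else mask
}

#' Min-max quantization of in-mask T1 values to 256 gray levels
#'
#' Maps in-mask values to integer levels `floor(255 * (v - min) / (max -
#' min))` so the in-mask minimum becomes level 0 and the maximum level 255.
#' The quantization is invariant to any positive affine transform of the
#' pixel values, which is what makes downstream texture features depend on
#' relative rather than absolute T1. A constant region quantizes to all
#' zeros with a recorded degenerate flag.
#'
#' @param map a `t1_map`.
#' @param mask a `myocardium_mask` or logical matrix.
#' @param n_levels number of gray levels (default 256).
#' @return A `quantized_image`: integer `levels` matrix (NA outside the
#'   mask), `mask`, `n_levels`, `scaling` = c(min, max), `degenerate`.
#' @export
normalize_intensities <- function(map, mask, n_levels = 256L) {
  stopifnot(inherits(map, "t1_map"))
  m <- as_mask_matrix(mask)
  if (!any(m)) stop("mask is empty")
  v <- map$pixels[m]
  mn <- min(v); mx <- max(v)
  lv <- matrix(NA_integer_, nrow(m), ncol(m))
  degenerate <- mx == mn
  if (degenerate) {
    lv[m] <- 0L
  } else {
    # the 1e-7 guard keeps exact-integer ratios (common for integer-ms
    # maps) stable under floating-point jitter from upstream transforms
    lv[m] <- pmin(as.integer(floor((n_levels - 1) * (v - mn) / (mx - mn) + 1e-7)),
                  n_levels - 1L)
  }
  structure(list(levels = lv, mask = m, n_levels = as.integer(n_levels),
                 scaling = c(min = mn, max = mx), degenerate = degenerate),
            class = "quantized_image")
}

#' Gray-level co-occurrence matrix of a quantized image
#'
#' Accumulates, over the given pixel offsets, the number of times a pixel
#' of level i neighbors a pixel of level j, counting only pairs where both
#' pixels are inside the mask (no padding, so background never mixes into
#' the texture). In symmetric mode each pair is counted in both (i, j) and
#' (j, i). The count matrix is normalized to sum to 1.
#'
#' @param q a `quantized_image`.
#' @param offsets list of integer `(dr, dc)` offsets; the default is the
#'   four distance-1 directions (0 deg, 90 deg, 45 deg, 135 deg) accumulated
#'   into one matrix.
#' @param symmetric count each pair in both orders (default TRUE).
#' @return A `glcm`: probability matrix `P` (`n_levels` x `n_levels`),
#'   `offsets`, `symmetric`, raw pair count `n_pairs`, `n_levels`.
#' @export
compute_glcm <- function(q,
                         offsets = list(c(0L, 1L), c(1L, 0L),
                                        c(1L, 1L), c(1L, -1L)),
                         symmetric = TRUE) {
  stopifnot(inherits(q, "quantized_image"))
  n <- q$n_levels
  lv <- q$levels
  nr <- nrow(lv); nc <- ncol(lv)
  counts <- numeric(n * n)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    ri <- seq(max(1L, 1L - dr), min(nr, nr - dr))
    ci <- seq(max(1L, 1L - dc), min(nc, nc - dc))
    if (length(ri) == 0L || length(ci) == 0L) next
    a <- lv[ri, ci, drop = FALSE]
    b <- lv[ri + dr, ci + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    idx <- a[ok] * n + b[ok] + 1
    counts <- counts + tabulate(idx, nbins = n * n)
  }
  cm <- matrix(counts, n, n, byrow = TRUE)  # row i = level i, col j = level j
  if (symmetric) cm <- cm + t(cm)
  n_pairs <- sum(cm)
  if (n_pairs == 0) stop("no valid in-mask neighboring pairs for the given offsets")
  structure(list(P = cm / n_pairs, offsets = offsets, symmetric = symmetric,
                 n_pairs = n_pairs, n_levels = n),
            class = "glcm")
}

glcm_index_matrices <- function(n) {
  key <- paste0("glcm_idx_", n)
  idx <- .t1tex_cache[[key]]
  if (is.null(idx)) {
    I <- matrix(0:(n - 1), n, n)             # varies down rows (level i)
    J <- matrix(0:(n - 1), n, n, byrow = TRUE)
    idx <- list(I = I, J = J, absdiff = abs(I - J), sqdiff = (I - J)^2)
    .t1tex_cache[[key]] <- idx
  }
  idx
}

#' The nine GLCM texture features
#'
#' With p(i, j) the normalized co-occurrence entries (levels indexed from
#' 0), marginal means/SDs \eqn{\mu_x, \mu_y, \sigma_x, \sigma_y} and grand
#' mean \eqn{\mu = (\mu_x + \mu_y)/2}:
#' energy \eqn{= \sum p^2}; contrast \eqn{= \sum p (i-j)^2}; entropy
#' \eqn{= -\sum p \log p} (base `log_base`, with 0 log 0 = 0); homogeneity
#' \eqn{= \sum p / (1 + |i-j|)}; correlation
#' \eqn{= \sum (i-\mu_x)(j-\mu_y) p / (\sigma_x \sigma_y)}; sum average
#' \eqn{= \sum_k k\, p_{x+y}(k)} (k = 0..2(n-1)); variance
#' \eqn{= \sum (i-\mu)^2 p}; dissimilarity \eqn{= \sum p |i-j|};
#' autocorrelation \eqn{= \sum i j\, p}.
#'
#' Energy is high for homogeneous images; entropy and variance rise with
#' spatial heterogeneity. The log base, homogeneity variant and 0-based
#' level indexing are recorded in the result, since index origin shifts
#' sum average and autocorrelation by constants.
#'
#' @param g a `glcm`.
#' @param log_base base of the entropy logarithm (default 2, bits).
#' @param homogeneity `"inverse_abs"` (1/(1+|i-j|), default) or
#'   `"inverse_square"` (1/(1+(i-j)^2)); both forms circulate in texture
#'   toolboxes.
#' @return A `texture_features` list of the nine named scalars, with a
#'   `provenance` attribute. Correlation is `NA` (with a warning) for a
#'   degenerate single-level image.
#' @export
glcm_features <- function(g, log_base = 2,
                          homogeneity = c("inverse_abs", "inverse_square")) {
  stopifnot(inherits(g, "glcm"))
  homogeneity <- match.arg(homogeneity)
  P <- g$P
  n <- g$n_levels
  idx <- glcm_index_matrices(n)
  lev <- 0:(n - 1)
  px <- rowSums(P)
  py <- colSums(P)
  mux <- sum(lev * px)
  muy <- sum(lev * py)
  sx <- sqrt(sum((lev - mux)^2 * px))
  sy <- sqrt(sum((lev - muy)^2 * py))
  pz <- P[P > 0]
  corr <- if (sx * sy == 0) {
    warning("correlation undefined for a single-level (degenerate) image")
    NA_real_
  } else {
    sum((idx$I - mux) * (idx$J - muy) * P) / (sx * sy)
  }
  hom <- if (homogeneity == "inverse_abs") {
    sum(P / (1 + idx$absdiff))
  } else {
    sum(P / (1 + idx$sqdiff))
  }
  mu <- (mux + muy) / 2
  feats <- list(
    energy = sum(P^2),
    contrast = sum(P * idx$sqdiff),
    entropy = -sum(pz * log(pz)) / log(log_base),
    homogeneity = hom,
    correlation = corr,
    sum_average = sum((idx$I + idx$J) * P),
    variance = sum((idx$I - mu)^2 * P),
    dissimilarity = sum(P * idx$absdiff),
    autocorrelation = sum(idx$I * idx$J * P))
  attr(feats, "provenance") <- list(log_base = log_base,
                                    homogeneity = homogeneity,
                                    offsets = g$offsets,
                                    symmetric = g$symmetric,
                                    index_origin = 0L)
  class(feats) <- "texture_features"
  feats
}

#' @export
print.texture_features <- function(x, ...) {
  cat("<texture_features>\n")
  for (nm in names(x)) cat(sprintf("  %-15s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

#' Full texture pipeline for one T1 map
#'
#' Segments the myocardium (unless a mask is supplied), quantizes to 256
#' levels within the mask, builds the co-occurrence matrix and returns the
#' nine texture features.
#'
#' @param map a `t1_map` (typically a mid-ventricular slice).
#' @param mask optional precomputed mask (`myocardium_mask` or logical
#'   matrix); if `NULL` the map is segmented with [segment_myocardium()].
#' @param offsets,symmetric passed to [compute_glcm()].
#' @param log_base,homogeneity passed to [glcm_features()].
#' @inheritParams compute_glcm
#' @return A `texture_features` object.
#' @export
t1_texture <- function(map, mask = NULL,
                       offsets = list(c(0L, 1L), c(1L, 0L),
                                      c(1L, 1L), c(1L, -1L)),
                       symmetric = TRUE, log_base = 2,
                       homogeneity = "inverse_abs") {
  if (is.null(mask)) mask <- segment_myocardium(map)
  q <- normalize_intensities(map, mask)
  g <- compute_glcm(q, offsets = offsets, symmetric = symmetric)
  glcm_features(g, log_base = log_base, homogeneity = homogeneity)
}
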