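# Independent brute-force oracles. These deliberately share no code with
# the package implementations: plain double loops and direct formula
# evaluation on small inputs.

# GLCM by explicit pair enumeration over every pixel and offset.
oracle_glcm <- function(levels, n_levels, offsets, symmetric) {
  counts <- matrix(0, n_levels, n_levels)
  nr <- nrow(levels); nc <- ncol(levels)
  for (off in offsets) {
    for (r in seq_len(nr)) {
      for (c in seq_len(nc)) {
        r2 <- r + off[1]; c2 <- c + off[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        a <- levels[r, c]; b <- levels[r2, c2]
        if (is.na(a) || is.na(b)) next
        counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
        if (symmetric) counts[b + 1, a + 1] <- counts[b + 1, a + 1] + 1
      }
    }
  }
  counts / sum(counts)
}

# The nine texture features by direct double loops over the matrix.
oracle_features <- function(P, log_base = 2) {
  n <- nrow(P)
  energy <- contrast <- entropy <- homog <- dissim <- autoc <- 0
  mux <- muy <- 0
  for (i in 1:n) for (j in 1:n) {
    p <- P[i, j]
    mux <- mux + (i - 1) * p
    muy <- muy + (j - 1) * p
  }
  sx2 <- sy2 <- 0
  for (i in 1:n) for (j in 1:n) {
    p <- P[i, j]
    sx2 <- sx2 + (i - 1 - mux)^2 * p
    sy2 <- sy2 + (j - 1 - muy)^2 * p
  }
  corr_num <- 0
  mu <- (mux + muy) / 2
  variance <- 0
  sum_avg <- 0
  for (i in 1:n) for (j in 1:n) {
    p <- P[i, j]
    d <- (i - 1) - (j - 1)
    energy <- energy + p^2
    contrast <- contrast + p * d^2
    if (p > 0) entropy <- entropy - p * log(p) / log(log_base)
    homog <- homog + p / (1 + abs(d))
    dissim <- dissim + p * abs(d)
    autoc <- autoc + (i - 1) * (j - 1) * p
    corr_num <- corr_num + (i - 1 - mux) * (j - 1 - muy) * p
    variance <- variance + (i - 1 - mu)^2 * p
    sum_avg <- sum_avg + ((i - 1) + (j - 1)) * p
  }
  list(energy = energy, contrast = contrast, entropy = entropy,
       homogeneity = homog,
       correlation = if (sx2 * sy2 == 0) NA_real_
                     else corr_num / sqrt(sx2 * sy2),
       sum_average = sum_avg, variance = variance,
       dissimilarity = dissim, autocorrelation = autoc)
}

# AUC by exhaustive concordant/tied pair counting.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Otsu by brute-force search over all cuts between consecutive distinct
# values, computing class weights and means directly each time.
oracle_otsu <- function(values) {
  u <- sort(unique(values))
  best <- -Inf; best_thr <- NA_real_
  for (k in seq_len(length(u) - 1)) {
    thr <- (u[k] + u[k + 1]) / 2
    c1 <- values[values <= thr]; c2 <- values[values > thr]
    bc <- length(c1) * length(c2) * (mean(c1) - mean(c2))^2
    if (bc > best) { best <- bc; best_thr <- thr }
  }
  best_thr
}

# Pixel-center distance/angle computed independently of the package
# geometry cache (same stated convention: 0-based, 0 deg anterior, CCW).
oracle_polar <- function(size, center) {
  rows <- matrix(0:(size - 1), size, size)
  cols <- matrix(0:(size - 1), size, size, byrow = TRUE)
  dr <- rows - center[1]; dc <- cols - center[2]
  list(dist = sqrt(dr^2 + dc^2),
       angle = (atan2(-dc, -dr) * 180 / pi) %% 360)
}

# Small fast geometries shared across tests.
small_config <- function(...) {
  phantom_config(image_size = 64L, endo_radius = 10, epi_radius = 17,
                 n_slices = 6L, ...)
}
tiny_config <- function(...) {
  phantom_config(image_size = 48L, endo_radius = 8, epi_radius = 16,
                 n_slices = 6L, ...)
}

quantized_from_matrix <- function(levels, n_levels) {
  structure(list(levels = levels, mask = !is.na(levels),
                 n_levels = as.integer(n_levels),
                 scaling = c(min = 0, max = n_levels - 1),
                 degenerate = FALSE),
            class = "quantized_image")
}

glcm_from_matrix <- function(P) {
  structure(list(P = P, offsets = list(c(0L, 1L)), symmetric = TRUE,
                 n_pairs = 1, n_levels = nrow(P)),
            class = "glcm")
}
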