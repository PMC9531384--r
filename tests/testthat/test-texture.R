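test_that("Otsu threshold separates two-valued data and matches brute force", {
  v <- c(rep(100, 40), rep(200, 60))
  thr <- otsu_threshold(v)
  expect_gt(thr, 100)
  expect_lt(thr, 200)
  set.seed(11)
  for (i in 1:25) {
    vals <- sample(0:20, 60, replace = TRUE) + round(rnorm(60), 2)
    expect_equal(otsu_threshold(vals), oracle_otsu(vals))
  }
  expect_error(otsu_threshold(rep(5, 10)), "distinct")
})

test_that("Otsu separates a well-split bimodal mixture with <1% misclassification", {
  set.seed(7)
  truth <- rep(c(FALSE, TRUE), each = 5000)
  vals <- c(rnorm(5000, 950, 30), rnorm(5000, 1400, 30))
  thr <- otsu_threshold(vals)
  expect_lt(mean((vals > thr) != truth), 0.01)
})

test_that("myocardium segmentation recovers the annulus minus the outer one-pixel rim", {
  cfg <- phantom_config(noise_sd = 0)
  m <- generate_t1_slice(cfg, seed = 1)
  res <- segment_myocardium(m)
  pol <- oracle_polar(cfg$image_size, cfg$center)
  annulus <- pol$dist >= cfg$endo_radius & pol$dist < cfg$epi_radius
  # expected: annulus minus pixels 4-adjacent to the outside region
  outside <- pol$dist >= cfg$epi_radius
  rim <- annulus & FALSE
  for (r in seq_len(nrow(annulus))) for (c in seq_len(ncol(annulus))) {
    if (!annulus[r, c]) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr >= 1 && rr <= nrow(annulus) && cc >= 1 && cc <= ncol(annulus) &&
          outside[rr, cc]) rim[r, c] <- TRUE
    }
  }
  expect_identical(res$mask, annulus & !rim)
  expect_false(any(res$mask & pol$dist < cfg$endo_radius))  # no blood pool
})

test_that("segmentation stays accurate under map-level noise", {
  cfg <- phantom_config(noise_sd = 20)
  pol <- oracle_polar(cfg$image_size, cfg$center)
  annulus <- pol$dist >= cfg$endo_radius & pol$dist < cfg$epi_radius
  blood <- pol$dist < cfg$endo_radius
  for (seed in 1:3) {
    m <- generate_t1_slice(cfg, seed = seed)
    res <- segment_myocardium(m)
    dice <- 2 * sum(res$mask & annulus) / (sum(res$mask) + sum(annulus))
    expect_gt(dice, 0.95)
    expect_false(any(res$mask & blood))
  }
})

test_that("min-max quantization maps endpoints to 0 and 255 and is affine-invariant", {
  cfg <- small_config()
  m <- generate_t1_slice(cfg, seed = 3)
  mask <- segment_myocardium(m)
  q <- normalize_intensities(m, mask)
  v <- q$levels[q$mask]
  expect_equal(min(v), 0L)
  expect_equal(max(v), 255L)
  expect_true(all(v >= 0 & v <= 255))
  m2 <- m
  m2$pixels <- 3.7 * m$pixels + 215
  q2 <- normalize_intensities(m2, mask)
  expect_identical(q2$levels, q$levels)
  # direct formula evaluation on known values
  m3 <- m
  m3$pixels[] <- 0
  m3$pixels[1, 1:3] <- c(1000, 1128, 1255)
  mask3 <- matrix(FALSE, nrow(m3$pixels), ncol(m3$pixels))
  mask3[1, 1:3] <- TRUE
  q3 <- normalize_intensities(m3, mask3)
  expect_equal(q3$levels[1, 1:3], c(0L, 128L, 255L))
  # constant in-mask region: degenerate, all level 0
  m4 <- m3; m4$pixels[1, 1:3] <- 1000
  q4 <- normalize_intensities(m4, mask3)
  expect_true(q4$degenerate)
  expect_equal(q4$levels[1, 1:3], c(0L, 0L, 0L))
})

test_that("GLCM of the worked 2x2 example matches the hand enumeration", {
  lv <- matrix(c(0L, 0L, 0L, 1L), 2, 2, byrow = TRUE)
  q <- quantized_from_matrix(lv, 2L)
  g <- compute_glcm(q, offsets = list(c(0L, 1L)), symmetric = TRUE)
  expect_equal(g$P, matrix(c(0.5, 0.25, 0.25, 0), 2, 2, byrow = TRUE))
  expect_equal(g$n_pairs, 4)
  f <- glcm_features(g)
  expect_equal(f$energy, 0.375)
  expect_equal(f$entropy, 1.5)
  expect_equal(f$contrast, 0.5)
  expect_equal(f$homogeneity, 0.75)
  expect_equal(f$dissimilarity, 0.5)
})

test_that("constant images give a delta GLCM with the analytic feature limits", {
  lv <- matrix(0L, 4, 4)
  q <- quantized_from_matrix(lv, 256L)
  g <- compute_glcm(q)
  expect_equal(sum(g$P), 1)
  expect_equal(g$P[1, 1], 1)
  f <- suppressWarnings(glcm_features(g))
  expect_equal(f$energy, 1)
  expect_equal(f$entropy, 0)
  expect_equal(f$contrast, 0)
  expect_equal(f$homogeneity, 1)
  expect_equal(f$variance, 0)
  expect_equal(f$dissimilarity, 0)
  expect_true(is.na(f$correlation))  # single-level image: undefined
})

test_that("a uniform GLCM attains maximum entropy of 16 bits at 256 levels", {
  P <- matrix(1 / 256^2, 256, 256)
  f <- glcm_features(glcm_from_matrix(P))
  expect_equal(f$entropy, 16)
  expect_equal(f$energy, 256^-2)
})

test_that("GLCM matches exhaustive pair enumeration, including masked pixels", {
  set.seed(5)
  offset_sets <- list(list(c(0L, 1L)),
                      list(c(0L, 1L), c(1L, 0L)),
                      list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L)))
  for (i in 1:20) {
    n_lev <- sample(2:4, 1)
    nr <- sample(3:8, 1); nc <- sample(3:8, 1)
    lv <- matrix(sample(0:(n_lev - 1), nr * nc, replace = TRUE), nr, nc)
    lv[matrix(runif(nr * nc) < 0.25, nr, nc)] <- NA  # random mask holes
    if (sum(!is.na(lv)) < 4) next
    offs <- offset_sets[[sample(3, 1)]]
    sym <- sample(c(TRUE, FALSE), 1)
    q <- quantized_from_matrix(lv, n_lev)
    g <- tryCatch(compute_glcm(q, offsets = offs, symmetric = sym),
                  error = function(e) NULL)
    if (is.null(g)) next  # no valid pairs under this mask
    expect_equal(g$P, oracle_glcm(lv, n_lev, offs, sym), tolerance = 1e-14)
    expect_equal(sum(g$P), 1, tolerance = 1e-12)
    if (sym) expect_equal(g$P, t(g$P))
  }
})

test_that("all nine features agree with the brute-force formulas on random GLCMs", {
  set.seed(9)
  for (i in 1:10) {
    n_lev <- sample(3:6, 1)
    C <- matrix(rpois(n_lev^2, 2), n_lev, n_lev)
    C <- C + t(C)
    if (sum(C) == 0) next
    g <- glcm_from_matrix(C / sum(C))
    f <- glcm_features(g)
    o <- oracle_features(g$P)
    for (nm in names(o)) expect_equal(f[[nm]], o[[nm]], tolerance = 1e-10)
  }
})

test_that("spatial clumping raises energy and lowers entropy at fixed histogram", {
  # same pixel values (half 0, half 255), different arrangement
  block <- matrix(0L, 8, 8); block[, 5:8] <- 255L
  checker <- matrix(0L, 8, 8)
  checker[(row(checker) + col(checker)) %% 2 == 0] <- 255L
  fb <- glcm_features(compute_glcm(quantized_from_matrix(block, 256L)))
  fc <- glcm_features(compute_glcm(quantized_from_matrix(checker, 256L)))
  expect_gt(fb$energy, fc$energy)
  expect_lt(fb$entropy, fc$entropy)
})

test_that("hotspot-bearing slices are more heterogeneous than clean ones", {
  # the directional texture effect: focal T1 elevations raise entropy and
  # variance and lower energy at equal noise
  cfg <- small_config(noise_sd = 20)
  hits <- 0L; n_rep <- 40L
  for (seed in seq_len(n_rep)) {
    clean <- t1_texture(generate_t1_slice(cfg, seed = seed))
    h <- hotspot_spec(center_angle = (seed * 53) %% 360, angular_width = 70,
                      radial_span = 1, delta_t1 = 180)
    hot <- t1_texture(generate_t1_slice(cfg, hotspots = list(h), seed = seed))
    if (hot$entropy > clean$entropy && hot$variance > clean$variance &&
        hot$energy < clean$energy) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("degenerate GLCM inputs are rejected", {
  lv <- matrix(c(0L, NA, NA, 1L), 2, 2)  # diagonal mask, no 4-neighbor pairs
  q <- quantized_from_matrix(lv, 2L)
  expect_error(compute_glcm(q, offsets = list(c(0L, 1L))), "pairs")
})
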