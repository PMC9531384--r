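test_that("an 8-slice study yields 16 disjoint ROIs avoiding anterior and inferior sectors", {
  cfg <- phantom_config(noise_sd = 0)
  study <- generate_t1_study(cfg, seed = 1)
  rois <- study_rois(study, cfg, middle_third = FALSE)
  expect_length(rois, 16L)
  lv <- vapply(rois, `[[`, "", "level")
  expect_equal(unname(table(lv)[c("basal", "mid", "apical")]), c(6L, 6L, 4L),
               ignore_attr = TRUE)
  pol <- oracle_polar(cfg$image_size, cfg$center)
  anterior <- abs(((pol$angle + 180) %% 360) - 180) <= 30
  inferior <- abs(((pol$angle - 180 + 180) %% 360) - 180) <= 30
  for (slice in unique(vapply(rois, `[[`, 1L, "slice_index"))) {
    on_slice <- rois[vapply(rois, `[[`, 1L, "slice_index") == slice]
    overlap <- Reduce(`+`, lapply(on_slice, `[[`, "mask"))
    expect_true(all(overlap <= 1))           # pairwise disjoint
    for (roi in on_slice) {
      expect_false(any(roi$mask & anterior))
      expect_false(any(roi$mask & inferior))
      expect_gt(sum(roi$mask), 0)
    }
  }
})

test_that("excluded slices cannot produce segment masks", {
  cfg <- phantom_config(noise_sd = 0)
  study <- generate_t1_study(cfg, seed = 1)
  expect_error(build_segment_masks(study$maps[[1]], cfg), "excluded")
})

test_that("middle-third extraction keeps exactly the stated radial band", {
  cfg <- phantom_config(noise_sd = 0, endo_radius = 20, epi_radius = 32)
  study <- generate_t1_study(cfg, seed = 1)
  rois <- study_rois(study, cfg, middle_third = FALSE)
  mt <- extract_middle_third(rois[[1]], 20, 32, cfg$center)
  pol <- oracle_polar(cfg$image_size, cfg$center)
  d <- pol$dist[mt$mask]
  expect_true(all(d >= 24 & d < 28))
  expect_true(all(!mt$mask | rois[[1]]$mask))  # subset of the input mask
  # idempotence: a mask already inside the middle third is unchanged
  mt2 <- extract_middle_third(mt, 20, 32, cfg$center)
  expect_identical(mt2$mask, mt$mask)
})

test_that("middle-third retains about one third of the full-wall sector area", {
  # radial middle third of an annulus sector holds exactly 1/3 of its area
  # in the continuum; pixel counting at fine resolution approaches that
  cfg <- phantom_config(image_size = 400L, endo_radius = 100,
                        epi_radius = 160, noise_sd = 0)
  study <- generate_t1_study(cfg, seed = 1)
  rois <- study_rois(study, cfg, middle_third = FALSE)
  full <- sum(rois[[1]]$mask)
  third <- sum(extract_middle_third(rois[[1]], 100, 160, cfg$center)$mask)
  expect_lt(abs(third / full - 1 / 3), 0.1 / 3)
})

test_that("middle-third errors when no pixel falls in the radial band", {
  cfg <- small_config(noise_sd = 0)
  study <- generate_t1_study(cfg, seed = 1)
  rois <- study_rois(study, cfg, middle_third = FALSE)
  # a band outside the ROI's annulus retains nothing
  expect_error(extract_middle_third(rois[[1]], 1000, 1003, cfg$center),
               "empty")
})

test_that("segmental values, global mean, peak and abnormality flags follow the definitions", {
  cfg <- phantom_config(noise_sd = 0)
  study <- generate_t1_study(cfg, seed = 1)
  rois <- study_rois(study, cfg)
  seg <- segmental_t1(study, rois)
  expect_equal(seg$segments$mean_t1, rep(1000, 16))
  expect_equal(seg$global_mean_t1, 1000)
  expect_equal(seg$peak_t1, 1000)
  expect_equal(seg$n_abnormal, 0L)

  # elevate exactly the basal anteroseptal sector of slice 2 by 150 ms
  pol <- oracle_polar(cfg$image_size, cfg$center)
  myo <- pol$dist >= cfg$endo_radius & pol$dist < cfg$epi_radius
  wedge <- myo & ((pol$angle - 30) %% 360) < 60
  study$maps[[2]]$pixels[wedge] <- study$maps[[2]]$pixels[wedge] + 150
  seg2 <- segmental_t1(study, rois)
  expect_equal(seg2$peak_t1, 1150)
  expect_equal(seg2$global_mean_t1, (15 * 1000 + 1150) / 16) # 1009.375
  expect_equal(seg2$n_abnormal, 1L)                          # 1150 > 1050

  # strict abnormality: values at exactly the upper bound are normal
  cfg1050 <- phantom_config(noise_sd = 0, baseline_t1 = 1050)
  s1050 <- generate_t1_study(cfg1050, seed = 1)
  seg3 <- segmental_t1(s1050, study_rois(s1050, cfg1050))
  expect_true(all(seg3$segments$mean_t1 == 1050))
  expect_equal(seg3$n_abnormal, 0L)
})

test_that("peak >= mean, ROI order does not matter, and constant shifts propagate exactly", {
  cfg <- small_config()
  for (seed in 1:5) {
    study <- generate_t1_study(cfg, seed = seed)
    rois <- study_rois(study, cfg)
    seg <- segmental_t1(study, rois)
    expect_gte(seg$peak_t1, seg$global_mean_t1)
    perm <- segmental_t1(study, rois[sample(16)])
    expect_equal(perm$global_mean_t1, seg$global_mean_t1)
    expect_equal(perm$peak_t1, seg$peak_t1)
    shifted <- study
    for (i in seq_along(shifted$maps)) {
      shifted$maps[[i]]$pixels <- shifted$maps[[i]]$pixels + 37.5
    }
    seg_s <- segmental_t1(shifted, rois)
    expect_equal(seg_s$segments$mean_t1, seg$segments$mean_t1 + 37.5)
    expect_equal(seg_s$global_mean_t1, seg$global_mean_t1 + 37.5)
    expect_equal(seg_s$peak_t1, seg$peak_t1 + 37.5)
  }
})

test_that("segmental_t1 validates its ROI set", {
  cfg <- small_config()
  study <- generate_t1_study(cfg, seed = 2)
  rois <- study_rois(study, cfg)
  expect_error(segmental_t1(study, rois[1:15]), "16")
  bad <- rois
  bad[[1]]$mask[] <- FALSE
  expect_error(segmental_t1(study, bad), "empty")
})

test_that("ICC(A,1) behaves like an absolute-agreement coefficient", {
  set.seed(42)
  x <- rnorm(30, 1000, 30)
  expect_equal(interobserver_icc(x, x)$icc, 1)
  # offsets reduce absolute agreement, monotonically in the offset
  iccs <- vapply(c(5, 20, 60), function(off) {
    interobserver_icc(x, x + off)$icc
  }, numeric(1))
  expect_true(all(iccs < 1))
  expect_true(all(diff(iccs) < 0))
  # independent readers agree only by chance
  r1 <- rnorm(200); r2 <- rnorm(200)
  expect_lt(abs(interobserver_icc(r1, r2)$icc), 0.15)
  # degenerate: no variance anywhere
  expect_error(interobserver_icc(rep(1, 5), rep(1, 5)), "variance")
  expect_error(interobserver_icc(1:4, 1:3), "equal length")
})
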