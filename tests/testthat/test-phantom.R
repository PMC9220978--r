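test_that("identical seeds give bit-identical phantoms", {
  a <- generate_phantom(tiny_phantom_config(seed = 7))
  b <- generate_phantom(tiny_phantom_config(seed = 7))
  expect_identical(a$series$data, b$series$data)
  expect_identical(a$rois$enhancement, b$rois$enhancement)
  expect_identical(unclass(a$nuisance), unclass(b$nuisance))
  c <- generate_phantom(tiny_phantom_config(seed = 8))
  expect_false(identical(a$series$data, c$series$data))
})

test_that("subregion masks are disjoint, non-empty, inside the brain, sized as configured", {
  ph <- generate_phantom(tiny_phantom_config())
  m <- ph$rois
  expect_s3_class(m, "roi_set")
  counts <- vapply(unclass(m), sum, integer(1))
  expect_equal(unname(counts), c(27L, 27L, 27L))  # 3x3x3 blocks
  expect_equal(sum(roi_union(m) & !ph$series$brain_mask), 0L)
  overlap <- m$enhancement & m$non_enhancement
  expect_false(any(overlap))
})

test_that("with noise off, voxel spectral power stays inside the configured band", {
  specs <- list(
    background = list(list(band = frequency_band(0.045, 0.055), amplitude = 1)),
    enhancement = list(list(band = frequency_band(0.045, 0.055), amplitude = 1)),
    non_enhancement = list(list(band = frequency_band(0.045, 0.055), amplitude = 1)),
    edema = list(list(band = frequency_band(0.045, 0.055), amplitude = 1))
  )
  cfg <- tiny_phantom_config(tissue_specs = specs, noise_sd = 0, hurst_sd = 0,
                             nuisance_weight = 0)
  ph <- generate_phantom(cfg)
  vox <- series_matrix(ph$series)[, 1]
  vox <- vox - mean(vox)
  n <- length(vox)
  power <- Mod(stats::fft(vox))^2
  f <- (0:(n - 1)) / n
  inband <- (f >= 0.04 & f <= 0.06) | (f >= 1 - 0.06 & f <= 1 - 0.04)
  expect_gt(sum(power[inband]) / sum(power), 0.99)
})

test_that("planted region lags are recovered by cross-correlation with the reference", {
  cfg <- tiny_phantom_config(
    lag_field = c(background = 0, enhancement = 2, non_enhancement = 0, edema = 0),
    noise_sd = 0, hurst_sd = 0, nuisance_weight = 0
  )
  ph <- generate_phantom(cfg)
  ref <- global_signal(ph$series, exclude = ph$rois)
  vox <- series_matrix(ph$series, ph$rois$enhancement)[, 1]
  cc <- vapply(-3:3, function(l) {
    n <- length(vox)
    if (l >= 0) cor(vox[(1 + l):n], ref[1:(n - l)]) else cor(vox[1:(n + l)], ref[(1 - l):n])
  }, numeric(1))
  expect_equal((-3:3)[which.max(cc)], 2)
})

test_that("bands above Nyquist and bad geometry are rejected", {
  specs <- default_tissue_specs()
  specs$edema[[1]]$band <- frequency_band(0.4, 0.8, name = "badband")
  expect_error(tiny_phantom_config(tissue_specs = specs), "badband")
  expect_error(phantom_config(grid_shape = c(4, 8, 8)), "grid_shape")
  expect_error(phantom_config(n_volumes = 8), "n_volumes")
  expect_error(
    tiny_phantom_config(hurst_target = c(background = 1.5, enhancement = 0.5,
                                         non_enhancement = 0.5, edema = 0.5)),
    "hurst_target"
  )
})

test_that("cohort labels honor the requested balance and seed-derived determinism", {
  cfg <- tiny_phantom_config(seed = 11)
  coh <- generate_cohort(cfg, n_subjects = 20, effects = list())
  expect_equal(sum(coh$labels), 10L)
  coh2 <- generate_cohort(cfg, n_subjects = 20, effects = list())
  expect_identical(coh$labels, coh2$labels)
  expect_identical(coh$subjects[[3]]$series$data, coh2$subjects[[3]]$series$data)
  expect_error(generate_cohort(cfg, 3), "n_subjects")
  expect_error(generate_cohort(cfg, 10, label_balance = 1), "label_balance")
  expect_error(
    generate_cohort(cfg, 4, effects = list(list(feature = "nope_s_gsr_x_y", delta = 1))),
    "nope"
  )
})

test_that("a null cohort shows only sampling noise across features", {
  cfg <- tiny_phantom_config(seed = 12)
  coh <- generate_cohort(cfg, n_subjects = 20, effects = list())
  tab <- cohort_feature_table(coh$subjects, coh$labels)
  feats <- setdiff(names(tab), c("subject_id", "label"))
  p <- vapply(feats, function(f) {
    x <- tab[[f]]
    if (stats::sd(x) == 0) return(1)
    stats::t.test(x[tab$label == 1], x[tab$label == 0])$p.value
  }, numeric(1))
  expect_gt(mean(p > 0.05), 0.9)
})

test_that("a planted ALFF effect separates the groups on that feature", {
  cfg <- tiny_phantom_config(seed = 13)
  feat <- "alff_s_nogsr_0.04-0.05_enhancement"
  coh <- generate_cohort(cfg, n_subjects = 20,
                         effects = list(list(feature = feat, delta = 0.5)))
  tab <- cohort_feature_table(coh$subjects, coh$labels)
  expect_gt(auroc(tab[[feat]], tab$label), 0.9)
})

test_that("phantom files are written in plain interoperable formats", {
  ph <- generate_phantom(tiny_phantom_config())
  dir <- tempfile("phantom")
  paths <- write_phantom(ph, dir)
  expect_true(all(file.exists(paths)))
  back <- read_bold(paths["series"], tr = 1)
  expect_equal(as.vector(back$data), as.vector(ph$series$data), tolerance = 1e-6)
  rois <- read_roi_labels(paths["rois"])
  expect_identical(rois$edema, ph$rois$edema)
  gt <- jsonlite::read_json(paths["ground_truth"])
  expect_equal(gt$seed, ph$ground_truth$seed)
})
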