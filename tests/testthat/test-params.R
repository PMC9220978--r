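test_that("the 14 admissible variants exist in a stable order", {
  v <- admissible_variants()
  expect_length(v, 14L)
  labels <- vapply(v, variant_label, character(1))
  expect_false(anyDuplicated(labels) > 0)
  expect_equal(labels[1:2], c("alff_s_nogsr", "alff_s_gsr"))
  expect_error(parameter_variant("alff", smoothed = FALSE, global_regressed = FALSE))
  expect_error(parameter_variant("reho", smoothed = TRUE, global_regressed = FALSE))
})

test_that("ALFF of a pure tone at an exact bin equals amplitude over band width", {
  n <- 400
  amp <- 2.7
  x <- slopefree_tone(n, 20, amp)  # 0.05 Hz
  band <- frequency_band(0.04, 0.06)
  m <- length(band_bin_indices(n, 1, band))
  s <- series_from_cols(cbind(x, 0 * x))
  map <- compute_alff(s, band)
  expect_equal(map$values[1, 1, 1], amp / m, tolerance = 1e-10)
  expect_equal(map$values[2, 1, 1], 0)  # zero series
  # homogeneity of degree 1
  map2 <- compute_alff(series_from_cols(cbind(-3 * x)), band)
  expect_equal(map2$values[1, 1, 1], 3 * amp / m, tolerance = 1e-10)
})

test_that("ALFF and fALFF match the direct-DFT oracle on random series", {
  set.seed(20)
  n <- 128
  band <- frequency_band(0.05, 0.12)
  y <- matrix(rnorm(5 * n), n, 5)
  s <- series_from_cols(y)
  alff_map <- compute_alff(s, band)
  falff_map <- compute_falff(s, band)
  for (j in 1:5) {
    expect_equal(alff_map$values[j, 1, 1], oracle_alff(y[, j], 1, band),
                 tolerance = 1e-8)
    expect_equal(falff_map$values[j, 1, 1], oracle_falff(y[, j], 1, band),
                 tolerance = 1e-8)
  }
})

test_that("fALFF is 1 for band-limited signals, 0 for zero series, ~0.185 for white noise", {
  n <- 400
  band <- frequency_band(0.01, 0.10, closed_high = TRUE)
  # band-limited synthesis: sum of slope-free in-band bin tones
  bins <- band_bin_indices(n, 1, band)
  x <- rowSums(sapply(bins[c(3, 10, 20)], function(k) slopefree_tone(n, k)))
  s <- series_from_cols(cbind(x, 0 * x))
  map <- compute_falff(s, band)
  expect_equal(map$values[1, 1, 1], 1, tolerance = 1e-6)
  expect_equal(map$values[2, 1, 1], 0)
  set.seed(21)
  noise <- matrix(rnorm(n * 1000), n, 1000)
  vals <- boldomics:::falff_matrix(noise, 1, band)
  expect_equal(mean(vals), 37 / 200, tolerance = 0.02)
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("ReHo is 1 for identical neighbors and matches the exhaustive rank formula", {
  n <- 40
  set.seed(22)
  x <- rnorm(n)
  same <- matrix(rep(x, 4), n, 4)
  w_same <- boldomics:::reho_matrix(
    same, matrix(c(0:3, 0:3, 0:3, 0:3), 4, 4, byrow = TRUE)
  )
  expect_equal(w_same, rep(1, 4), tolerance = 1e-12, ignore_attr = TRUE)
  # K = 2 exact rank reversal, even n -> W = 0, against the raw formula
  rev2 <- cbind(x, -x)
  w_rev <- boldomics:::reho_matrix(rev2, matrix(c(0L, 1L, 0L, 1L), 2, 2, byrow = TRUE))
  expect_equal(w_rev[1], oracle_kendall_w(rev2), tolerance = 1e-12)
  expect_equal(w_rev[1], 0, tolerance = 1e-12)
  # random neighborhoods against the oracle, including ties
  set.seed(23)
  for (rep in 1:5) {
    k <- sample(2:6, 1)
    m <- matrix(sample(1:8, 30 * k, replace = TRUE), 30, k)  # heavy ties
    w <- boldomics:::reho_matrix(m, matrix(seq_len(k) - 1L, 1, k))
    expect_equal(w[1], oracle_kendall_w(m), tolerance = 1e-12)
  }
})

test_that("ReHo of independent noise concentrates near 1/K", {
  s <- noise_series(c(10, 10, 10), n = 400, seed = 24)
  map <- compute_reho(s, neighborhood = 27)
  interior <- array(FALSE, dim = c(10, 10, 10))
  interior[2:9, 2:9, 2:9] <- TRUE
  vals <- map$values[interior]
  expect_gte(length(vals), 500)
  expect_lt(abs(mean(vals) - 1 / 27), 0.01)
  expect_true(all(map$values >= 0 & map$values <= 1))
})

test_that("DFA recovers the white-noise exponent and is sign-invariant", {
  set.seed(25)
  y <- matrix(rnorm(400 * 200), 400, 200)
  he <- boldomics:::hurst_matrix(y)
  expect_equal(median(he), 0.5, tolerance = 0.1)
  he_neg <- boldomics:::hurst_matrix(-y)
  expect_equal(he, he_neg, tolerance = 1e-12)
  # constant voxels get the missing code
  ycst <- cbind(y[, 1], rep(2, 400))
  he2 <- boldomics:::hurst_matrix(ycst)
  expect_true(is.na(he2[2]) && !is.na(he2[1]))
})

test_that("DFA recovers a persistent exponent from shaped noise", {
  y <- sapply(1:100, function(i) oracle_fgn_like(400, h = 0.8, seed = 300 + i))
  he <- boldomics:::hurst_matrix(y)
  expect_equal(median(he), 0.8, tolerance = 0.1)
})

test_that("DFA preconditions are enforced", {
  y <- matrix(rnorm(400 * 2), 400, 2)
  expect_error(boldomics:::hurst_matrix(y, scales = c(4, 8, 16)), "4 scales")
  expect_error(boldomics:::hurst_matrix(y, scales = c(4, 8, 16, 200)), "n/4")
})

test_that("TSA recovers planted integer lags and matches the exhaustive oracle", {
  set.seed(26)
  n <- 300
  ref <- as.vector(arima.sim(list(ar = 0.9), n))
  shift <- function(x, l) c(tail(x, l), head(x, n - l))  # delay by +l
  y <- cbind(shift(ref, 2), ref, shift(ref, 1))
  out <- boldomics:::tsa_matrix(y, ref, max_lag = 3)
  expect_equal(out, c(2, 0, 1), ignore_attr = TRUE)
  # random series, including a negated delayed copy, against the oracle
  for (rep in 1:10) {
    x <- rnorm(n) + 0.5 * ref
    if (rep == 1) x <- -shift(ref, 1)
    expect_equal(
      boldomics:::tsa_matrix(cbind(x), ref, max_lag = 3)[1],
      oracle_tsa(x, ref, 3)
    )
  }
  # degenerate inputs yield the missing code
  expect_true(is.na(boldomics:::tsa_matrix(cbind(rep(1, n)), ref, 3)[1]))
  expect_true(all(is.na(boldomics:::tsa_matrix(cbind(ref), rep(0, n), 3))))
})

test_that("scale bounds hold for every engine on arbitrary input", {
  ph <- generate_phantom(tiny_phantom_config(seed = 27))
  b <- subject_bundle(ph$series, ph$nuisance, ph$rois)
  maps <- compute_variant_stack(b)
  for (m in maps) {
    v <- m$values[!is.na(m$values)]
    if (m$variant$base %in% c("falff", "reho")) {
      expect_true(all(v >= 0 & v <= 1))
    } else if (m$variant$base == "tsa") {
      expect_true(all(v >= -3 & v <= 3))
    } else {
      expect_true(all(is.finite(v)))
    }
  }
})

test_that("fALFF, ReHo and HE are invariant to affine rescaling; ALFF scales; TSA needs c > 0", {
  set.seed(28)
  n <- 200
  y <- matrix(rnorm(3 * n), n, 3)
  cpos <- 2.7; d <- 5
  band <- frequency_band(0.05, 0.15)
  f1 <- boldomics:::falff_matrix(y, 1, band)
  f2 <- boldomics:::falff_matrix(-cpos * y + d, 1, band)
  expect_equal(f1, f2, tolerance = 1e-10)
  a1 <- boldomics:::alff_matrix(y, 1, band)
  a2 <- boldomics:::alff_matrix(cpos * y + d, 1, band)
  expect_equal(a2, cpos * a1, tolerance = 1e-10)
  nbr <- matrix(c(0L, 1L, 2L), 3, 3, byrow = TRUE)
  w1 <- boldomics:::reho_matrix(y, nbr)
  w2 <- boldomics:::reho_matrix(-cpos * y + d, nbr)
  expect_equal(w1, w2, tolerance = 1e-12)
  h1 <- boldomics:::hurst_matrix(y)
  h2 <- boldomics:::hurst_matrix(-cpos * y + d)
  expect_equal(h1, h2, tolerance = 1e-10)
  ref <- rowMeans(y)
  t1 <- boldomics:::tsa_matrix(y, ref, 3)
  t2 <- boldomics:::tsa_matrix(cpos * y + d, ref, 3)
  expect_equal(t1, t2)
})

test_that("the variant stack yields 140 tagged maps in deterministic order", {
  ph <- generate_phantom(tiny_phantom_config(seed = 29))
  b <- subject_bundle(ph$series, ph$nuisance, ph$rois)
  maps <- compute_variant_stack(b)
  expect_length(maps, 140L)
  tags <- vapply(maps, function(m) paste(variant_label(m$variant), m$band$name),
                 character(1))
  expected <- unlist(lapply(admissible_variants(), function(v) {
    vapply(make_band_set(1), function(bd) paste(variant_label(v), bd$name), character(1))
  }))
  expect_equal(tags, expected)
  reho_only <- compute_variant_stack(
    b, variants = admissible_variants("reho")
  )
  expect_length(reho_only, 20L)
  # missing nuisance is rejected before any computation
  b2 <- subject_bundle(ph$series, NULL, ph$rois)
  expect_error(compute_variant_stack(b2), "nuisance")
})

test_that("restricting the engines to ROI voxels reproduces whole-brain ROI features", {
  ph <- generate_phantom(tiny_phantom_config(seed = 30))
  b <- subject_bundle(ph$series, ph$nuisance, ph$rois)
  full <- extract_roi_means(compute_variant_stack(b), ph$rois)
  fast <- extract_roi_means(
    compute_variant_stack(b, options = stack_options(voxels = "roi")), ph$rois
  )
  expect_equal(fast, full, tolerance = 1e-12)
})

test_that("parameter maps serialize with their provenance sidecar", {
  ph <- generate_phantom(tiny_phantom_config(seed = 31))
  b <- subject_bundle(ph$series, ph$nuisance, ph$rois)
  map <- compute_alff(discard_initial_volumes(ph$series, 5), make_band_set(1)[[1]])
  path <- file.path(tempfile("maps"), "alff.nii.gz")
  dir.create(dirname(path))
  write_parameter_map(map, path)
  side <- jsonlite::read_json(sub("\\.nii\\.gz$", ".json", path))
  expect_equal(side$variant, "alff_s_nogsr")
  expect_equal(side$band$name, "0.01-0.10")
})
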