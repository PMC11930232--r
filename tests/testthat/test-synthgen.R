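test_that("generator is deterministic and validates parameters", {
  p <- cstart_params(seed = 7)
  k1 <- make_cstart_kinematics(p)
  k2 <- make_cstart_kinematics(p)
  expect_identical(k1$midlines, k2$midlines)
  expect_identical(k1$gt, k2$gt)
  expect_error(cstart_params(frame_rate = 0), "frame_rate")
  expect_error(cstart_params(cbend_duration = -1), "cbend_duration")
})

test_that("zero amplitudes give the straight rest midline and zero curvature", {
  p <- cstart_params(frame_rate = 1000, cbend_amplitude = 0,
                     counterbend_amplitude = 0, fastswim_amplitude = 0)
  k <- make_cstart_kinematics(p)
  expect_true(all(abs(k$head_tail_angle) < 1e-12))
  expect_true(all(abs(k$midlines[, , 2]) < 1e-12))
  for (j in c(1, 25)) expect_equal(k$midlines[j, , ], k$midlines[1, , ])
})

test_that("fast-swim head-tail angle peaks spectrally at beat_frequency", {
  p <- cstart_params(beat_frequency = 30, n_fast_beats = 4)
  k <- make_cstart_kinematics(p)
  seg <- k$head_tail_angle[k$stage == 3]
  n <- length(seg)
  sp <- Mod(fft(seg - mean(seg)))[2:(n %/% 2)]
  freqs <- (1:(n %/% 2 - 1)) / (n * k$dt)
  bin <- freqs[1]
  expect_lt(abs(freqs[which.max(sp)] - 30), bin + 1e-9)
})

test_that("default sequence has six curvature maxima (C-bend, counterbend, four beats)", {
  k <- make_cstart_kinematics(cstart_params())
  pk <- zfescape:::find_peaks(abs(k$head_tail_angle), prominence = 10,
                              min_sep = round(0.002 / k$dt))
  expect_identical(length(pk), 6L)
  # maxima at the stage turning points: C-bend and counterbend ends, then
  # one per fast-swim beat (half-period spacing)
  pk_ms <- k$times[pk] * 1000
  expect_equal(pk_ms[1], 11, tolerance = 0.1)
  expect_equal(pk_ms[2], 21, tolerance = 0.1)
  half_period <- 1000 / (2 * 60)
  expect_equal(diff(pk_ms[2:6]), rep(half_period, 4), tolerance = 0.05)
})

test_that("rasterized silhouette area matches the analytic swept area within 2%", {
  p <- fx_track_params()
  kin <- make_cstart_kinematics(p)
  prof <- body_profile()
  fs <- rasterize_swimmer(kin, prof, p, frames = c(1, 40))
  a_true <- zfescape:::analytic_silhouette_area(prof)
  for (m in fs$gt_masks) {
    a <- sum(m) * p$pixel_scale^2
    expect_lt(abs(a / a_true - 1), 0.02)
  }
})

test_that("static body with no superposed motion rasterizes to identical frames", {
  p <- cstart_params(frame_rate = 500, cbend_amplitude = 0,
                     counterbend_amplitude = 0, fastswim_amplitude = 0,
                     superposed_translation = 0, superposed_rotation = 0,
                     noise_level = 0, image_size = c(256, 220),
                     pixel_scale = 0.025)
  k <- make_cstart_kinematics(p)
  fs <- rasterize_swimmer(k, body_profile(), p, frames = c(1, 5, 9))
  expect_identical(fs$frames[[2]], fs$frames[[1]])
  expect_identical(fs$frames[[3]], fs$frames[[1]])
})

test_that("default image geometry matches the acquisition window", {
  p <- cstart_params()
  expect_identical(p$image_size, c(512L, 420L))
  expect_equal(p$image_size[1] * p$pixel_scale, 13.0)
  expect_equal(p$image_size[2] * p$pixel_scale, 10.66, tolerance = 0.01)
  expect_equal(1 / p$frame_rate, 1e-4)
})

test_that("a fish leaving the window raises an error naming the frame", {
  p <- cstart_params(frame_rate = 2000, superposed_translation = 400,
                     superposed_rotation = 0, image_size = c(220, 200),
                     pixel_scale = 0.025)
  k <- make_cstart_kinematics(p)
  expect_error(rasterize_swimmer(k, body_profile(), p),
               "exits the image window at frame [0-9]+")
})

test_that("slice stack has the right count, width and symmetry", {
  prof <- body_profile()
  st <- make_slice_stack(prof, spacing_um = 100, pixel_um = 10)
  expect_length(st$slices, floor(prof$standard_length * 1000 / 100) + 1)
  wmax_px <- max(vapply(st$slices, function(s)
    if (any(s)) diff(range(which(colSums(s) > 0))) + 1 else 0, numeric(1)))
  w_true_px <- 2 * max(prof$half_width(seq(0, prof$standard_length,
                                           length.out = 500))) * 1000 / 10
  expect_lt(abs(wmax_px - w_true_px), 1 + 1)
  for (s in st$slices) expect_identical(s, s[, ncol(s):1])
})

test_that("missing slices are removed reproducibly from the interior", {
  prof <- body_profile()
  st <- make_slice_stack(prof, spacing_um = 100, pixel_um = 10,
                         missing_fraction = 0.3, seed = 5)
  st2 <- make_slice_stack(prof, spacing_um = 100, pixel_um = 10,
                          missing_fraction = 0.3, seed = 5)
  expect_identical(st$positions_um, st2$positions_um)
  n_nom <- length(st$positions_nominal_um)
  expect_length(st$slices, n_nom - floor(0.3 * n_nom))
  # first and last positions always kept
  expect_true(0 %in% st$positions_um)
  expect_true(max(st$positions_nominal_um) %in% st$positions_um)
  expect_error(make_slice_stack(prof, missing_fraction = 1), "missing_fraction")
})
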