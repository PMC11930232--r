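test_that("segmentation thresholds exactly the dark population", {
  img <- matrix(1, 420, 512)
  img[101:110, 201:210] <- 0           # 100 zero-intensity pixels
  m <- segment_frame(img, percentile = 5)
  expect_identical(sum(m), 100L)
  expect_true(all(m[101:110, 201:210]))
})

test_that("a uniform image has no foreground", {
  expect_error(segment_frame(matrix(0.5, 50, 50), 5), "no foreground")
})

test_that("segmentation recovers the generator mask with IoU >= 0.95", {
  tk <- fx_tracking()
  for (i in c(1, 40, 80)) {
    m <- segment_frame(tk$stack$frames[[i]], 5)
    expect_gte(mask_iou_fx(m, tk$stack$gt_masks[[i]]), 0.95)
  }
})

test_that("center of mass matches symmetry and brute force", {
  m <- matrix(FALSE, 21, 21); m[9:13, 9:13] <- TRUE
  expect_equal(unname(center_of_mass(m, 1)), c(10, 10))
  # two equal squares at x offsets 0 and 10 -> centroid midway
  m2 <- matrix(FALSE, 15, 30)
  m2[6:8, 3:5] <- TRUE; m2[6:8, 13:15] <- TRUE
  expect_equal(unname(center_of_mass(m2, 1))[1], mean(c(2:4, 12:14)))
  # random blob vs exhaustive pixel average
  set.seed(42)
  m3 <- matrix(runif(900) < 0.3, 30, 30)
  idx <- which(m3, arr.ind = TRUE)
  expect_equal(unname(center_of_mass(m3, 1)),
               c(mean(idx[, 2] - 1), mean(30 - idx[, 1])))
  expect_error(center_of_mass(matrix(FALSE, 5, 5)), "empty")
})

test_that("body angle tracks the principal axis with smooth continuation", {
  # rasterize an ellipse mask in the (row, col) convention
  mk <- function(a, b, ang) {
    nr <- 101; nc <- 101
    m <- matrix(FALSE, nr, nc)
    for (r in 1:nr) {
      y <- nr - r; x <- 0:(nc - 1)
      R <- zfescape:::rot2(-ang)
      xr <- R[1, 1] * (x - 50) + R[1, 2] * (y - 50)
      yr <- R[2, 1] * (x - 50) + R[2, 2] * (y - 50)
      m[r, ] <- (xr / a)^2 + (yr / b)^2 <= 1
    }
    m
  }
  expect_lt(abs(body_angle(mk(40, 12, 0))), 0.5)
  a30 <- body_angle(mk(40, 12, 30))
  expect_lt(abs(a30 - 30), 0.5)
  # circle: degenerate, returns the previous angle with a flag
  circ <- mk(20, 20, 0)
  a <- body_angle(circ, previous_alpha = 17)
  expect_equal(as.numeric(a), 17)
  expect_true(attr(a, "degenerate"))
  # continuation picks the representative nearest the previous angle
  expect_lt(abs(body_angle(mk(40, 12, 100), previous_alpha = 95) - 100), 0.5)
})

test_that("rigid motion of a static shape is fully removed (IoU >= 0.98)", {
  p <- cstart_params(frame_rate = 2000, cbend_amplitude = 0,
                     counterbend_amplitude = 0, fastswim_amplitude = 0,
                     superposed_translation = 40, superposed_rotation = 4000,
                     image_size = c(360, 300), noise_level = 0.005, seed = 3)
  k <- make_cstart_kinematics(p)
  fs <- rasterize_swimmer(k, body_profile(), p)
  iso <- procrustes_isolate(fs)
  n <- length(iso$frames)
  # skip the Savitzky-Golay startup transient at both ends (half window)
  core <- 6:(n - 5)
  ref <- iso$frames[[round(n / 2)]]
  ious <- vapply(core, function(i) mask_iou_fx(iso$frames[[i]], ref),
                 numeric(1))
  expect_gte(min(ious), 0.98)
  # recovered rotation parallels the ground truth
  d_alpha <- iso$rigid$alpha_deg - k$gt$alpha_deg
  expect_lt(max(abs(d_alpha - mean(d_alpha))), 1)
})

test_that("recomposing the rigid trace reproduces the input masks (IoU >= 0.98)", {
  tk <- fx_tracking()
  rec <- recompose_rigid(tk$iso)
  seg <- lapply(tk$stack$frames, segment_frame, percentile = 5)
  ious <- vapply(seq_along(rec), function(i) mask_iou_fx(rec[[i]], seg[[i]]),
                 numeric(1))
  expect_gte(min(ious), 0.98)
})

test_that("an already centered, non-moving stack passes through unchanged", {
  p <- cstart_params(frame_rate = 500, cbend_amplitude = 0,
                     counterbend_amplitude = 0, fastswim_amplitude = 0,
                     superposed_translation = 0, superposed_rotation = 0,
                     noise_level = 0, image_size = c(256, 220),
                     pixel_scale = 0.025)
  k <- make_cstart_kinematics(p)
  fs <- rasterize_swimmer(k, body_profile(), p, frames = 1:12)
  iso <- procrustes_isolate(fs)
  expect_lt(diff(range(iso$rigid$alpha_deg)), 0.1)
  expect_lt(max(dist(cbind(iso$rigid$cm_x_mm, iso$rigid$cm_y_mm))), 0.01)
  # isolation centers the silhouette on its mass center; align the input
  # mask by that (integer) shift before comparing
  seg1 <- segment_frame(fs$frames[[1]], 5)
  cm_px <- iso$rigid[1, c("cm_x_mm", "cm_y_mm")] / p$pixel_scale
  dx <- round(iso$origin_px[1] - cm_px[[1]])
  dy <- round(iso$origin_px[2] - cm_px[[2]])
  shifted <- matrix(FALSE, nrow(seg1), ncol(seg1))
  tr <- seq_len(nrow(seg1)) - dy; tc <- seq_len(ncol(seg1)) + dx
  okr <- tr >= 1 & tr <= nrow(seg1); okc <- tc >= 1 & tc <= ncol(seg1)
  shifted[tr[okr], tc[okc]] <- seg1[which(okr), which(okc)]
  # integer-pixel alignment is only good to +/- 0.5 px, which on a body
  # this thin costs ~10% IoU; the sub-pixel identity is covered by the
  # frame-to-frame comparison below
  expect_gte(mask_iou_fx(iso$frames[[1]], shifted), 0.85)
  # and the isolated frames themselves are mutually identical
  expect_gte(mask_iou_fx(iso$frames[[1]], iso$frames[[10]]), 0.98)
})

test_that("isolation is equivariant under an extra constant rotation", {
  p <- fx_track_params()
  k <- make_cstart_kinematics(p)
  fs1 <- rasterize_swimmer(k, body_profile(), p, frames = 1:30)
  k2 <- k; k2$gt$alpha_deg <- k$gt$alpha_deg + 25
  fs2 <- rasterize_swimmer(k2, body_profile(), p, frames = 1:30)
  iso1 <- procrustes_isolate(fs1)
  iso2 <- procrustes_isolate(fs2)
  ious <- vapply(6:25, function(i)
    mask_iou_fx(iso1$frames[[i]], iso2$frames[[i]]), numeric(1))
  expect_gte(min(ious), 0.97)
})
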