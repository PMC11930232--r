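#' Parameters of a synthetic C-start escape sequence
#'
#' Bundles the kinematic and imaging parameters of the synthetic escape-swim
#' generator. The defaults emulate the acquisition and behaviour conditions
#' of an electric-field-pulse triggered escape of a 5 dpf zebrafish
#' eleutheroembryo: a high-amplitude C-bend (~11 ms), a counterbend (~10 ms)
#' and four fast-swimming tail beats, filmed at 10,000 frames per second on
#' a 512 x 420 px window covering 13.0 x 10.7 mm^2.
#'
#' A "beat" is one unilateral tail flick (half an oscillation cycle);
#' `beat_frequency` is the full-cycle frequency of the fast-swim
#' oscillation, so the fast-swimming stage lasts
#' `n_fast_beats / (2 * beat_frequency)` seconds.
#'
#' @param frame_rate frames per second of the virtual camera.
#' @param n_fast_beats number of fast-swim tail beats (half cycles).
#' @param beat_frequency full-cycle fast-swim oscillation frequency (Hz).
#' @param cbend_amplitude,counterbend_amplitude,fastswim_amplitude peak
#'   head-tail angles (degrees) of the three stages.
#' @param cbend_duration,counterbend_duration stage durations (ms).
#' @param superposed_translation peak rigid swimming speed (mm/s), ramped
#'   smoothly from rest.
#' @param superposed_rotation peak rigid yaw rate (deg/s) during the bend
#'   stages.
#' @param pixel_scale mm per pixel.
#' @param image_size image width and height in pixels.
#' @param noise_level standard deviation of additive Gaussian intensity
#'   noise (fraction of full scale).
#' @param seed integer seed; identical parameters and seed give
#'   bit-identical output.
#' @return an object of class `cstart_params`.
#' @export
cstart_params <- function(frame_rate = 10000,
                          n_fast_beats = 4,
                          beat_frequency = 60,
                          cbend_amplitude = 110,
                          counterbend_amplitude = 80,
                          fastswim_amplitude = 35,
                          cbend_duration = 11,
                          counterbend_duration = 10,
                          superposed_translation = 80,
                          superposed_rotation = 10000,
                          pixel_scale = 13.0 / 512,
                          image_size = c(512, 420),
                          noise_level = 0.01,
                          seed = 1L) {
  check_scalar(frame_rate, "frame_rate", positive = TRUE)
  check_scalar(beat_frequency, "beat_frequency", positive = TRUE)
  check_scalar(cbend_duration, "cbend_duration", positive = TRUE)
  check_scalar(counterbend_duration, "counterbend_duration", positive = TRUE)
  for (nm in c("cbend_amplitude", "counterbend_amplitude", "fastswim_amplitude",
               "superposed_translation", "superposed_rotation", "noise_level"))
    check_scalar(get(nm), nm, nonneg = TRUE)
  if (n_fast_beats < 1) stop("`n_fast_beats` must be >= 1", call. = FALSE)
  check_scalar(pixel_scale, "pixel_scale", positive = TRUE)
  fast_duration <- 1000 * n_fast_beats / (2 * beat_frequency) # ms
  structure(list(
    frame_rate = frame_rate,
    n_fast_beats = as.integer(n_fast_beats),
    beat_frequency = beat_frequency,
    cbend_amplitude = cbend_amplitude,
    counterbend_amplitude = counterbend_amplitude,
    fastswim_amplitude = fastswim_amplitude,
    stage_durations = c(cbend = cbend_duration,
                        counterbend = counterbend_duration,
                        fast_swim = fast_duration),
    superposed_translation = superposed_translation,
    superposed_rotation = superposed_rotation,
    pixel_scale = pixel_scale,
    image_size = as.integer(image_size),
    noise_level = noise_level,
    seed = as.integer(seed)
  ), class = "cstart_params")
}

#' Reference larval body profile
#'
#' Half-width (dorsal view) and half-height (lateral view) of a 5 dpf
#' zebrafish eleutheroembryo as smooth functions of arclength, plus the
#' extent of the median fin fold. The profile is bilaterally symmetric by
#' construction and vanishes at the snout and tail tip.
#'
#' @param standard_length snout to end-of-vertebral-column length (mm);
#'   the reference value for a live 5 dpf eleutheroembryo is 3.829 mm.
#' @param fin_fold_extent caudal fin-fold length (mm).
#' @return an object of class `body_profile` with functions `half_width(s)`,
#'   `half_height(s)` and `fin_fold_height(s)` of arclength s in mm.
#' @export
body_profile <- function(standard_length = 3.829, fin_fold_extent = 0.247) {
  check_scalar(standard_length, "standard_length", positive = TRUE)
  L <- standard_length
  # control points (fraction of SL -> half width / SL), dorsal silhouette:
  # snout, eyes/head bulge, trunk taper, tail, tip
  u_w <- c(0, 0.04, 0.10, 0.18, 0.30, 0.45, 0.60, 0.75, 0.90, 1)
  w_u <- c(0, 0.028, 0.048, 0.055, 0.042, 0.030, 0.020, 0.013, 0.007, 0)
  # lateral half height (body incl. yolk/swim bladder), peaks near 25% SL
  u_h <- c(0, 0.05, 0.15, 0.25, 0.40, 0.55, 0.70, 0.85, 1)
  h_u <- c(0, 0.045, 0.072, 0.081, 0.060, 0.042, 0.028, 0.015, 0)
  wf <- splinefun(u_w * L, w_u * L, method = "monoH.FC")
  hf <- splinefun(u_h * L, h_u * L, method = "monoH.FC")
  # median fin fold: thin membrane above/below the tail, strongest caudally
  ff <- function(s) {
    u <- s / L
    amp <- fin_fold_extent * exp(-((u - 0.85) / 0.22)^2)
    ifelse(u > 0.45 & u < 0.995, amp, 0)
  }
  half_width <- function(s) pmax(0, wf(pmin(pmax(s, 0), L)))
  half_height <- function(s) pmax(0, hf(pmin(pmax(s, 0), L)))
  structure(list(
    standard_length = L,
    fin_fold_extent = fin_fold_extent,
    half_width = half_width,
    half_height = half_height,
    fin_fold_height = ff,
    # depth-averaged half-width for the planar solver: the tail's thrust
    # surface is its height (body + median fin fold), which a dorsal-view
    # silhouette misses entirely; without it the sub-grid tail produces
    # almost no thrust in 2D
    effective_half_width = function(s)
      pmax(half_width(s), 0.35 * (half_height(s) + ff(s)))
  ), class = "body_profile")
}

# head-tail angle programme H(t) (deg) and stage id for one time point;
# vectorized over t (seconds)
cstart_head_tail_programme <- function(t, p) {
  T1 <- p$stage_durations[["cbend"]] / 1000
  T2 <- p$stage_durations[["counterbend"]] / 1000
  T12 <- T1 + T2
  f <- p$beat_frequency
  Ac <- p$cbend_amplitude; Acb <- p$counterbend_amplitude
  Af <- p$fastswim_amplitude
  H <- numeric(length(t))
  stage <- integer(length(t))
  i1 <- t <= T1
  H[i1] <- Ac * smoothstep(t[i1] / T1); stage[i1] <- 1L
  i2 <- t > T1 & t <= T12
  H[i2] <- Ac - (Ac + Acb) * smoothstep((t[i2] - T1) / T2); stage[i2] <- 2L
  i3 <- t > T12
  tp <- t[i3] - T12
  # blend from the counterbend posture into the travelling wave over the
  # first half beat period, keeping the midline shape continuous in time
  beta <- smoothstep(2 * f * tp)
  H[i3] <- (1 - beta) * (-Acb) + beta * (-Af * cos(2 * pi * f * tp))
  stage[i3] <- 3L
  list(H = H, stage = stage)
}

#' Generate synthetic C-start midline kinematics
#'
#' Builds per-frame body-frame midlines realizing the three escape stages
#' (C-bend, counterbend, fast swimming with a posterior travelling wave),
#' together with the ground-truth curvature, head-tail angle and rigid
#' translation/rotation traces used as oracles by the downstream recovery
#' steps. Bending is distributed along arclength as `(s/L)^2`, so the tail
#' carries most of the curvature; the fast stage superposes one body
#' wavelength travelling tailward.
#'
#' @param params a [cstart_params()] object.
#' @param standard_length body standard length in mm.
#' @param n_segments number of midline segments (301 points).
#' @return an object of class `cstart_kinematics`: per-frame midlines
#'   (mm, body frame, centroid at the origin), ground-truth head-tail angle
#'   and mean joint angle traces (deg), and a tibble `gt` with the rigid
#'   motion (frame, t, cm_x_mm, cm_y_mm, alpha_deg).
#' @export
make_cstart_kinematics <- function(params, standard_length = 3.829,
                                   n_segments = 300) {
  stopifnot(inherits(params, "cstart_params"))
  check_scalar(standard_length, "standard_length", positive = TRUE)
  p <- params
  L <- standard_length
  dt <- 1 / p$frame_rate
  # a quarter beat period of margin keeps the last fast-swim curvature
  # maximum interior to the recorded sequence
  T_total <- sum(p$stage_durations) / 1000 + 0.25 / p$beat_frequency
  n <- floor(T_total / dt) + 1
  times <- (seq_len(n) - 1) * dt
  T12 <- sum(p$stage_durations[c("cbend", "counterbend")]) / 1000
  f <- p$beat_frequency

  ns <- n_segments
  u_mid <- (seq_len(ns) - 0.5) / ns     # segment midpoints (fraction of L)
  # bending envelope: rises smoothly along the trunk and saturates at the
  # tail so the (optically sub-pixel) fin-fold tip carries no curvature
  g <- 3 * u_mid^2 - 2 * u_mid^3
  ds <- L / ns

  prog <- cstart_head_tail_programme(times, p)
  H <- prog$H

  midlines <- array(NA_real_, c(n, ns + 1, 2))
  for (k in seq_len(n)) {
    tk <- times[k]
    if (prog$stage[k] < 3L) {
      theta <- H[k] * g
    } else {
      tp <- tk - T12
      beta <- smoothstep(2 * f * tp)
      theta <- (1 - beta) * (-p$counterbend_amplitude * g) +
        beta * (-p$fastswim_amplitude * g *
                  cos(2 * pi * f * tp - 2 * pi * (u_mid - 1)))
    }
    phi <- deg2rad(theta)
    x <- c(0, cumsum(ds * cos(phi)))
    y <- c(0, cumsum(ds * sin(phi)))
    x <- x - mean(x); y <- y - mean(y)
    midlines[k, , 1] <- x
    midlines[k, , 2] <- y
  }

  # rigid ground truth: yaw burst during the bend stages, speed ramping
  # from rest along the current heading
  rate <- p$superposed_rotation * sin(pi * pmin(times / T12, 1))^2
  alpha <- cumsum(rate) * dt
  v <- p$superposed_translation * smoothstep(times / T12)
  heading <- deg2rad(alpha)
  cm <- cbind(cumsum(v * cos(heading)) * dt, cumsum(v * sin(heading)) * dt)
  win_mm <- p$image_size * p$pixel_scale
  cm[, 1] <- cm[, 1] + win_mm[1] / 2
  cm[, 2] <- cm[, 2] + win_mm[2] / 2

  # head-tail angle of the generated midline (equals the programme by
  # construction); mean joint angle telescopes to H / n_segments
  structure(list(
    times = times, dt = dt, midlines = midlines,
    head_tail_angle = H,
    mean_joint_angle = H / ns,
    stage = prog$stage,
    gt = tibble::tibble(frame = seq_len(n), t = times,
                        cm_x_mm = cm[, 1], cm_y_mm = cm[, 2],
                        alpha_deg = alpha),
    standard_length = L,
    params = p
  ), class = "cstart_kinematics")
}

#' Rasterize a swimming body into a silhouette movie
#'
#' Sweeps the dorsal half-width profile along each lab-frame midline (body
#' frame midline carried by the ground-truth rigid motion) and renders a
#' dark fish on a bright background with an anti-aliased (one pixel wide)
#' edge and seeded additive Gaussian noise. The exact generator masks are
#' returned alongside as segmentation oracles.
#'
#' @param kin a [make_cstart_kinematics()] result.
#' @param profile a [body_profile()]; must share the kinematics' standard
#'   length.
#' @param params the [cstart_params()] used for the kinematics.
#' @param frames optional integer vector of frame indices to render
#'   (default: all).
#' @return an object of class `frame_stack`: list of grayscale matrices in
#'   `[0, 1]`, `dt`, `pixel_scale`, ground-truth masks and rigid trace.
#' @export
rasterize_swimmer <- function(kin, profile, params, frames = NULL) {
  stopifnot(inherits(kin, "cstart_kinematics"), inherits(profile, "body_profile"))
  if (abs(profile$standard_length - kin$standard_length) > 1e-9)
    stop("kinematics and profile must share the same standard length", call. = FALSE)
  p <- params
  ps <- p$pixel_scale
  nc <- p$image_size[1]; nr <- p$image_size[2]
  idx <- frames %||% seq_along(kin$times)
  set.seed(p$seed)
  L <- kin$standard_length
  ns <- dim(kin$midlines)[2]
  s_arc <- seq(0, L, length.out = ns)
  # fine resampling for disc stamping (about half-pixel spacing)
  n_fine <- max(ns, ceiling((L / ps) / 0.5))
  u_fine <- seq(0, 1, length.out = n_fine)
  w_fine_mm <- profile$half_width(u_fine * L)

  out_frames <- vector("list", length(idx))
  gt_masks <- vector("list", length(idx))
  bg <- 0.9; fg <- 0.08

  for (j in seq_along(idx)) {
    k <- idx[j]
    ml <- kin$midlines[k, , ]
    R <- rot2(kin$gt$alpha_deg[k])
    lab <- t(R %*% t(ml))
    lab[, 1] <- lab[, 1] + kin$gt$cm_x_mm[k]
    lab[, 2] <- lab[, 2] + kin$gt$cm_y_mm[k]
    fine <- resample_polyline(lab, n_fine)
    xs <- fine[, 1] / ps; ys <- fine[, 2] / ps
    wpx <- w_fine_mm / ps
    if (any(xs - wpx < 0.5) || any(xs + wpx > nc - 1.5) ||
        any(ys - wpx < 0.5) || any(ys + wpx > nr - 1.5))
      stop(sprintf("fish exits the image window at frame %d", k), call. = FALSE)
    mask <- matrix(FALSE, nr, nc)
    for (i in seq_len(n_fine)) {
      w <- wpx[i]
      if (w <= 0) next
      c0 <- max(1, floor(xs[i] - w) + 1); c1 <- min(nc, ceiling(xs[i] + w) + 1)
      r0 <- max(1, nr - ceiling(ys[i] + w)); r1 <- min(nr, nr - floor(ys[i] - w))
      if (c1 < c0 || r1 < r0) next
      px <- (c0:c1) - 1
      py <- nr - (r0:r1)
      d2 <- outer((py - ys[i])^2, (px - xs[i])^2, "+")
      mask[r0:r1, c0:c1] <- mask[r0:r1, c0:c1] | (d2 <= w * w)
    }
    rr <- range(which(rowSums(mask) > 0)); cc <- range(which(colSums(mask) > 0))
    r0 <- max(1, rr[1] - 4); r1 <- min(nr, rr[2] + 4)
    c0 <- max(1, cc[1] - 4); c1 <- min(nc, cc[2] + 4)
    crop <- mask[r0:r1, c0:c1, drop = FALSE]
    sd <- sdf_from_mask(crop)
    # the stamped mask is pixel-quantized; recompute the exact signed
    # distance (union-of-discs: min_i |p - c_i| - w_i) in a band around
    # the boundary so both the edge ramp and the ground-truth mask are
    # sub-pixel accurate
    band <- which(abs(sd) <= 2, arr.ind = TRUE)
    if (nrow(band)) {
      bx <- (band[, 2] + c0 - 2)          # 0-based x
      by <- nr - (band[, 1] + r0 - 1)     # 0-based y
      dd <- sqrt(outer(bx, xs, "-")^2 + outer(by, ys, "-")^2)
      dd <- sweep(dd, 2, wpx)
      dmin <- rep(Inf, nrow(band))
      for (jj in seq_len(ncol(dd))) dmin <- pmin(dmin, dd[, jj])
      sd[band] <- dmin
      crop_true <- crop
      crop_true[band] <- dmin < 0
      mask[r0:r1, c0:c1] <- crop_true
    }
    # one-pixel linear edge ramp centred on the true boundary: the
    # mid-edge intensity contour is the exact silhouette outline, and a
    # linear ramp survives bilinear resampling without bias
    img <- matrix(bg, nr, nc)
    img[r0:r1, c0:c1] <- fg + (bg - fg) * pmin(pmax(sd + 0.5, 0), 1)
    if (p$noise_level > 0)
      img <- img + matrix(rnorm(nr * nc, 0, p$noise_level), nr, nc)
    out_frames[[j]] <- pmin(pmax(img, 0), 1)
    gt_masks[[j]] <- mask
  }

  structure(list(
    frames = out_frames,
    dt = kin$dt,
    pixel_scale = ps,
    frame_index = idx,
    gt_masks = gt_masks,
    gt = kin$gt[idx, , drop = FALSE],
    params = p
  ), class = "frame_stack")
}

# analytic silhouette area of the swept profile (mm^2): integral of the
# full width along arclength (end caps vanish with the width)
analytic_silhouette_area <- function(profile, n = 4000) {
  L <- profile$standard_length
  s <- seq(0, L, length.out = n)
  pracma::trapz(s, 2 * profile$half_width(s))
}

#' Generate a synthetic transverse cross-section stack
#'
#' Emulates a histology-derived stack of binary transverse body sections:
#' superellipse body cross-sections plus a thin median fin-fold blade in
#' the tail, uniformly spaced along the body axis, bilaterally symmetric by
#' construction, with an optional seeded random subset of interior slices
#' removed (emulating missing sections).
#'
#' @param profile a [body_profile()].
#' @param spacing_um inter-slice spacing in micrometres.
#' @param missing_fraction fraction of interior slices removed (0 <= f < 1).
#' @param pixel_um in-plane pixel size in micrometres.
#' @param seed integer seed for the removal draw.
#' @return an object of class `slice_stack`: binary slice matrices, their
#'   axial positions (um), pixel size, and the nominal complete-position
#'   grid (`positions_nominal_um`) for oracle comparisons.
#' @export
make_slice_stack <- function(profile, spacing_um = 19, missing_fraction = 0,
                             pixel_um = 4.8, seed = 1L) {
  stopifnot(inherits(profile, "body_profile"))
  check_scalar(spacing_um, "spacing_um", positive = TRUE)
  check_scalar(pixel_um, "pixel_um", positive = TRUE)
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("`missing_fraction` must be in [0, 1)", call. = FALSE)
  L_um <- profile$standard_length * 1000
  n <- floor(L_um / spacing_um) + 1
  pos <- (seq_len(n) - 1) * spacing_um
  s_mm <- pos / 1000

  a_mm <- profile$half_width(s_mm)
  b_mm <- profile$half_height(s_mm)
  ff_mm <- profile$fin_fold_height(s_mm)
  half_w <- ceiling(max(a_mm) * 1000 / pixel_um) + 4
  half_h <- ceiling(max(b_mm + ff_mm) * 1000 / pixel_um) + 4
  ncx <- 2 * half_w + 1; nry <- 2 * half_h + 1
  xo <- ((1:ncx) - (half_w + 1)) # pixel offsets from the symmetry axis
  yo <- ((1:nry) - (half_h + 1))

  slices <- vector("list", n)
  pexp <- 2.2
  for (i in seq_len(n)) {
    a <- a_mm[i] * 1000 / pixel_um
    b <- b_mm[i] * 1000 / pixel_um
    m <- matrix(FALSE, nry, ncx)
    if (a > 0 && b > 0)
      m <- outer(abs(yo / b)^pexp, abs(xo / a)^pexp, "+") <= 1
    if (ff_mm[i] > 0 && b > 0) {
      aff <- max(1, 0.006 * profile$standard_length * 1000 / pixel_um)
      bff <- (b_mm[i] + ff_mm[i]) * 1000 / pixel_um
      blade <- outer(abs(yo) <= bff, abs(xo) <= aff, "&")
      m <- m | blade
    }
    slices[[i]] <- m
  }

  keep <- rep(TRUE, n)
  if (missing_fraction > 0 && n > 2) {
    set.seed(seed)
    interior <- 2:(n - 1)
    drop <- sample(interior, size = floor(missing_fraction * n))
    keep[drop] <- FALSE
  }

  structure(list(
    slices = slices[keep],
    positions_um = pos[keep],
    positions_nominal_um = pos,
    complete_slices = if (missing_fraction > 0) slices else NULL,
    spacing_um = spacing_um,
    pixel_um = pixel_um,
    standard_length = profile$standard_length
  ), class = "slice_stack")
}
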