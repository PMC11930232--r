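# Midline extraction and kinematic descriptors.

# Zhang-Suen morphological thinning of a logical matrix (vectorized over
# whole-image shifts; the mask must not touch the border)
zhang_suen_thin <- function(mask) {
  m <- mask
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(a, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- a[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbours P2..P9 clockwise from north (row-1 = north)
      p2 <- shift(m, 1, 0);  p3 <- shift(m, 1, -1)
      p4 <- shift(m, 0, -1); p5 <- shift(m, -1, -1)
      p6 <- shift(m, -1, 0); p7 <- shift(m, -1, 1)
      p8 <- shift(m, 0, 1);  p9 <- shift(m, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- matrix(0L, nr, nc)
      for (i in 1:8) a <- a + (!seqs[[i]] & seqs[[i + 1]])
      if (pass == 1) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# longest path through the skeleton's 8-connected pixel graph
skeleton_longest_path <- function(skel) {
  idx <- which(skel, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < 2) stop("skeleton too small", call. = FALSE)
  key <- idx[, 1] + (idx[, 2] - 1) * nrow(skel)
  lookup <- seq_len(n); names(lookup) <- as.character(key)
  edges <- NULL; weights <- NULL
  offs <- cbind(dr = c(1, -1, 0, 0, 1, 1, -1, -1),
                dc = c(0, 0, 1, -1, 1, -1, 1, -1))
  for (o in seq_len(8)) {
    nb_key <- (idx[, 1] + offs[o, 1]) + (idx[, 2] + offs[o, 2] - 1) * nrow(skel)
    j <- lookup[as.character(nb_key)]
    ok <- !is.na(j) & j > seq_len(n) # each undirected edge once
    if (any(ok)) {
      edges <- rbind(edges, cbind(which(ok), j[ok]))
      weights <- c(weights, rep(if (o <= 4) 1 else sqrt(2), sum(ok)))
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- weights
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  deg <- igraph::degree(g)
  ends <- which(deg == 1)
  if (length(ends) < 2) stop("branching skeleton irresolvable", call. = FALSE)
  # farthest endpoint pair by geodesic distance
  dmat <- igraph::distances(g, v = ends, to = ends)
  best <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
  path <- igraph::shortest_paths(g, from = ends[best[1]], to = ends[best[2]],
                                 output = "vpath")$vpath[[1]]
  idx[as.integer(path), , drop = FALSE]
}

#' Extract the body midline from a silhouette mask
#'
#' Skeletonizes the mask (morphological thinning), keeps the longest
#' skeleton path, extends it to the snout and tail tip along the end
#' tangents, lightly smooths the pixelated path and resamples it to 300
#' equal-arclength segments. The head end is identified as the end with
#' the larger local body width (distance-transform value), or by nearest
#' distance to a previous frame's head when `prev` is given.
#'
#' @param mask logical silhouette matrix (single connected component).
#' @param n_segments number of midline segments (default 300).
#' @param pixel_scale mm per pixel (default: the mask's calibration).
#' @param prev optional previous frame's midline (for head continuity).
#' @param frame optional frame index used in error messages.
#' @return an object of class `midline`: a `(n_segments + 1) x 2` matrix
#'   of head-to-tail coordinates in mm, with the pixel-space path and
#'   calibration as attributes.
#' @export
extract_midline <- function(mask, n_segments = 300, pixel_scale = NULL,
                            prev = NULL, frame = NA) {
  ps <- pixel_scale %||% attr(mask, "pixel_scale") %||% 1
  rs <- which(rowSums(mask) > 0); cs <- which(colSums(mask) > 0)
  if (!length(rs)) stop("empty mask", call. = FALSE)
  r0 <- max(1, min(rs) - 2); r1 <- min(nrow(mask), max(rs) + 2)
  c0 <- max(1, min(cs) - 2); c1 <- min(ncol(mask), max(cs) + 2)
  crop <- mask[r0:r1, c0:c1, drop = FALSE]
  skel <- zhang_suen_thin(crop)
  path_rc <- tryCatch(skeleton_longest_path(skel), error = function(e)
    stop(sprintf("%s (frame %s)", conditionMessage(e), frame), call. = FALSE))

  # pixel coords (0-based, y up) in the full image frame
  px <- cbind(x = path_rc[, 2] + c0 - 2, y = nrow(mask) - (path_rc[, 1] + r0 - 1))

  # light smoothing of the pixelated path before extension/resampling
  if (nrow(px) >= 7) {
    px <- cbind(moving_average(px[, 1], 5), moving_average(px[, 2], 5))
  }

  # extend both ends to the mask boundary along the end tangent
  dist_in <- as.matrix(EBImage::distmap(matrix(as.numeric(crop), nrow(crop), ncol(crop))))
  sdf <- function(x, y) {
    v <- bilinear_sample(dist_in, x - (c0 - 1), y - (nrow(mask) - r1), fill = 0)
    v
  }
  extend_end <- function(pts, head_end = TRUE) {
    if (head_end) { a <- pts[min(6, nrow(pts)), ]; b <- pts[1, ] }
    else { a <- pts[nrow(pts) - min(5, nrow(pts) - 1), ]; b <- pts[nrow(pts), ] }
    dir <- b - a; nd <- sqrt(sum(dir^2)); if (nd == 0) return(NULL)
    dir <- dir / nd
    steps <- seq(0.5, 30, by = 0.5)
    cand <- cbind(b[1] + steps * dir[1], b[2] + steps * dir[2])
    inside <- sdf(cand[, 1], cand[, 2]) > 0.25
    if (!any(inside)) return(NULL)
    last <- max(which(inside))
    cand[seq_len(last), , drop = FALSE]
  }
  ext_h <- extend_end(px, TRUE); ext_t <- extend_end(px, FALSE)
  if (!is.null(ext_h)) px <- rbind(ext_h[rev(seq_len(nrow(ext_h))), ], px)
  if (!is.null(ext_t)) px <- rbind(px, ext_t)

  # head = wider end (mean local width over the outer 15% of the path)
  n <- nrow(px)
  k <- max(3, round(0.15 * n))
  w_a <- mean(sdf(px[1:k, 1], px[1:k, 2]))
  w_b <- mean(sdf(px[(n - k + 1):n, 1], px[(n - k + 1):n, 2]))
  if (!is.null(prev)) {
    prev_px <- attr(prev, "px") %||% (unclass(prev) / ps)
    head_prev <- prev_px[1, ]
    d_a <- sum((px[1, ] - head_prev)^2); d_b <- sum((px[n, ] - head_prev)^2)
    if (d_b < d_a) px <- px[n:1, ]
  } else if (w_b > w_a) {
    px <- px[n:1, ]
  }

  res <- resample_polyline(px, n_segments + 1)
  out <- res * ps
  colnames(out) <- c("x_mm", "y_mm")
  structure(out, px = res, pixel_scale = ps, class = c("midline", "matrix"))
}

#' Midline curvature descriptors
#'
#' Signed turning angle between consecutive midline segments, averaged
#' over all joints (the "midline curvature" amplitude indicator), and the
#' total head-to-tail angle (cumulative turning, not wrapped to 180
#' degrees). Positive angles are leftward bends in the fish frame.
#'
#' @param m a [extract_midline()] result or an `(n+1) x 2` matrix.
#' @return list with `mean_joint_angle` and `head_tail_angle`, in degrees.
#' @export
midline_curvature <- function(m) {
  pts <- unclass(m)
  v <- diff(pts)
  ang <- atan2(v[, 2], v[, 1])
  turn <- diff(ang)
  turn <- ((turn + pi) %% (2 * pi)) - pi
  list(mean_joint_angle = rad2deg(mean(turn)),
       head_tail_angle = rad2deg(sum(turn)))
}

# tail-beat peak structure shared by descriptor code: local maxima of the
# rectified head-tail angle trace
curvature_peaks <- function(trace, dt, prominence = 10, min_sep_ms = 2) {
  find_peaks(abs(trace), prominence = prominence,
             min_sep = max(1, round(min_sep_ms / 1000 / dt)))
}

#' Kinematic descriptors of an escape sequence
#'
#' Locates the six bend/beat curvature maxima (C-bend, counterbend, four
#' fast-swim beats), delimits the six-movement window as the sixth maximum
#' plus half a beat period, and computes the distance traveled, velocities,
#' rotation amplitude, tail-beat frequency and bending amplitudes.
#'
#' The tail-beat frequency is the full oscillation-cycle rate, computed
#' from the intervals between same-side beat peaks (alternate peaks of the
#' rectified head-tail angle trace).
#'
#' @param rigid tibble with `t`, `cm_x_mm`, `cm_y_mm`, `alpha_deg`
#'   (see [procrustes_isolate()]).
#' @param curvature_trace head-tail angle per frame, degrees.
#' @param dt frame interval (s).
#' @param prominence,min_sep_ms peak-detection configuration.
#' @return one-row tibble (class `kinematics_summary`).
#' @export
kinematic_descriptors <- function(rigid, curvature_trace, dt,
                                  prominence = 10, min_sep_ms = 2) {
  # tracked curvature carries frame-to-frame skeletonization jitter;
  # smooth over ~4 ms before locating the bend/beat maxima
  win <- max(5, round(0.004 / dt))
  if (win < length(curvature_trace))
    curvature_trace <- sg_smooth(curvature_trace, win, 3)
  pk <- curvature_peaks(curvature_trace, dt, prominence, min_sep_ms)
  if (length(pk) < 6)
    stop(sprintf("expected six curvature maxima, found %d", length(pk)),
         call. = FALSE)
  pk <- pk[1:6]
  t <- rigid$t
  beat_interval <- mean(diff(t[pk[3:6]]))      # half-cycle interval
  t_end <- min(t[pk[6]] + 0.5 * beat_interval, t[length(t)])
  i_end <- max(which(t <= t_end))

  step_len <- sqrt(diff(rigid$cm_x_mm)^2 + diff(rigid$cm_y_mm)^2)
  cum <- c(0, cumsum(step_len))
  distance <- cum[i_end]
  mean_velocity <- distance / (t[i_end] - t[1])

  # fast-swimming velocity: from the first fast-swim beat peak on
  i_fast <- pk[3]
  fast_velocity <- (cum[i_end] - cum[i_fast]) / (t[i_end] - t[i_fast])

  # same-side (alternate) peak intervals give the full-cycle rate
  cycle <- mean(c(t[pk[5]] - t[pk[3]], t[pk[6]] - t[pk[4]]))
  tail_beat_frequency <- 1 / cycle

  # rotation amplitude: average of |alpha| local maxima (interpretation:
  # absolute-rotation maxima; see package vignette)
  a <- abs(rigid$alpha_deg - rigid$alpha_deg[1])
  apk <- find_peaks(a, prominence = 1, min_sep = max(1, round(0.002 / dt)))
  rotation_amplitude <- if (length(apk)) mean(a[apk]) else max(a)

  tibble::tibble(
    distance_traveled_mm = distance,
    fast_swim_velocity_mm_s = fast_velocity,
    rotation_amplitude_deg = rotation_amplitude,
    tail_beat_frequency_hz = tail_beat_frequency,
    max_head_tail_angle_deg = max(abs(curvature_trace[seq_len(i_end)])),
    fast_swim_beat_amplitude_deg = mean(abs(curvature_trace[pk[3:6]])),
    total_duration_six_movements_ms = (t_end - t[1]) * 1000,
    mean_velocity_mm_s = mean_velocity
  )
}
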