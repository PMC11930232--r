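#' Segment a movie frame by lower-percentile thresholding
#'
#' Pixels darker than the given intensity percentile are foreground (the
#' fish silhouette is dark on a bright background). Isolated noise pixels
#' are discarded by keeping the largest connected component, and interior
#' holes are filled.
#'
#' @param image grayscale matrix in `[0, 1]`.
#' @param percentile percentile (0-50) of pixel intensity below which a
#'   pixel is considered foreground.
#' @param pixel_scale optional mm-per-pixel calibration stored on the mask.
#' @return a logical matrix (TRUE = fish) with attribute `pixel_scale`.
#' @export
segment_frame <- function(image, percentile = 5, pixel_scale = NULL) {
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  if (percentile <= 0 || percentile >= 50)
    stop("`percentile` must be in (0, 50)", call. = FALSE)
  thr <- as.numeric(stats::quantile(image, percentile / 100))
  detect <- clean_mask(image < thr)
  # refine the boundary at the mid-edge intensity: the percentile cut sits
  # just under the background level, i.e. at the outer edge of the blur
  # ramp; the fg/bg midpoint contour tracks the true silhouette outline
  fg <- stats::median(image[detect])
  bg <- stats::median(image[!detect])
  mask <- detect
  if (bg > fg) mask <- clean_mask(image < (fg + bg) / 2)
  attr(mask, "pixel_scale") <- pixel_scale
  mask
}

# largest connected component + hole filling
clean_mask <- function(raw) {
  if (!any(raw)) stop("no foreground: no pixels below the threshold", call. = FALSE)
  lab <- as.matrix(EBImage::bwlabel(matrix(as.numeric(raw), nrow(raw), ncol(raw))))
  tab <- tabulate(lab[lab > 0])
  if (!length(tab)) stop("no foreground after cleanup", call. = FALSE)
  mask <- lab == which.max(tab)
  as.matrix(EBImage::fillHull(matrix(as.numeric(mask), nrow(mask), ncol(mask)))) > 0
}

# binarize a rigidly resampled frame at the mid-edge intensity (the same
# contour segment_frame refines to), estimating fg from the darkest pixels
binarize_resampled <- function(img) {
  bg <- stats::median(img)
  fg <- as.numeric(stats::quantile(img, 0.002))
  clean_mask(img < (fg + bg) / 2)
}

#' Center of mass of a binary mask
#'
#' Area centroid of the foreground pixels in calibrated units, using the
#' package's pixel-center convention (x rightward, y upward, 0-based).
#'
#' @param mask logical matrix.
#' @param pixel_scale mm per pixel; defaults to the mask's stored
#'   calibration, else 1 (pixel units).
#' @return numeric `c(x, y)` in mm.
#' @export
center_of_mass <- function(mask, pixel_scale = NULL) {
  ps <- pixel_scale %||% attr(mask, "pixel_scale") %||% 1
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask", call. = FALSE)
  x <- mean(idx[, 2] - 1)
  y <- mean(nrow(mask) - idx[, 1])
  c(x = x * ps, y = y * ps)
}

# second-moment tensor about the centroid, in pixel coordinates; `w` is an
# optional nonnegative mass weight per pixel (default: binary mask)
mask_moments <- function(mask, w = NULL) {
  idx <- which(mask > 0, arr.ind = TRUE)
  x <- idx[, 2] - 1; y <- nrow(mask) - idx[, 1]
  ww <- if (is.null(w)) rep(1, nrow(idx)) else w[idx]
  W <- sum(ww)
  cx <- sum(ww * x) / W; cy <- sum(ww * y) / W
  x <- x - cx; y <- y - cy
  list(Ixx = sum(ww * x * x) / W, Iyy = sum(ww * y * y) / W,
       Ixy = sum(ww * x * y) / W, cx = cx, cy = cy)
}

# sub-pixel mass weights from image darkness under the mask (the linear
# edge ramp makes darkness proportional to silhouette coverage)
darkness_weights <- function(image, mask) {
  vals <- image[mask]
  bg <- stats::median(image[!mask])
  fg <- stats::quantile(vals, 0.2, names = FALSE)
  w <- matrix(0, nrow(image), ncol(image))
  w[mask] <- pmin(pmax((bg - image[mask]) / max(bg - fg, 1e-6), 0), 1)
  w
}

#' Body orientation from the momentum (second-moment) equation
#'
#' Orientation of the principal second-moment axis of a centered mask,
#' continued smoothly from the previous frame's angle: the principal-axis
#' angle is defined modulo 180 degrees, and the representative within
#' +/- 90 degrees of `previous_alpha` is returned (the closed-form
#' equivalent of rotating the silhouette by the previous angle and
#' measuring the residual).
#'
#' @param mask logical matrix.
#' @param previous_alpha previous frame's angle (deg); also the fallback
#'   for a rotationally degenerate mask.
#' @param tol relative anisotropy below which the mask is declared
#'   degenerate (principal moments equal within tolerance).
#' @return angle in degrees (counterclockwise from +x) with attribute
#'   `degenerate` set TRUE when the fallback was used.
#' @export
body_angle <- function(mask, previous_alpha = 0, tol = 1e-3, weights = NULL) {
  mom <- mask_moments(mask, weights)
  aniso <- sqrt((mom$Ixx - mom$Iyy)^2 + 4 * mom$Ixy^2) / (mom$Ixx + mom$Iyy)
  if (!is.finite(aniso) || aniso < tol) {
    out <- previous_alpha
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  raw <- rad2deg(0.5 * atan2(2 * mom$Ixy, mom$Ixx - mom$Iyy))
  delta <- ((raw - previous_alpha + 90) %% 180) - 90
  out <- previous_alpha + delta
  attr(out, "degenerate") <- FALSE
  out
}

# resample a grayscale frame at positions cm + R(alpha) %*% (p - out_center)
# (pixel coordinates, 0-based, y up), returning the rigidly transformed
# image; pixels outside the sampled span take the background value
resample_frame_rigid <- function(img, cm_px, alpha_deg, out_dim, out_center,
                                 halfspan, fill) {
  nr <- out_dim[1]; nc <- out_dim[2]
  r_lo <- max(1, floor(nr - (out_center[2] + halfspan)))
  r_hi <- min(nr, ceiling(nr - (out_center[2] - halfspan)))
  c_lo <- max(1, floor(out_center[1] - halfspan) + 1)
  c_hi <- min(nc, ceiling(out_center[1] + halfspan) + 1)
  rs <- r_lo:r_hi; cs <- c_lo:c_hi
  xo <- rep(cs - 1, each = length(rs)) - out_center[1]
  yo <- rep(nr - rs, times = length(cs)) - out_center[2]
  R <- rot2(alpha_deg)
  xs <- cm_px[1] + R[1, 1] * xo + R[1, 2] * yo
  ys <- cm_px[2] + R[2, 1] * xo + R[2, 2] * yo
  vals <- bilinear_sample(img, xs, ys, fill = fill)
  out <- matrix(fill, nr, nc)
  out[rs, cs] <- matrix(vals, length(rs), length(cs))
  out
}

#' Isolate body movement by iterative Procrustes analysis
#'
#' Segments every frame, tracks the center of mass and the body rotation
#' (differential principal-axis scheme), temporally smooths both traces,
#' and subtracts the rigid motion so the output frames show pure body
#' deformation centered at the image center. Resampling is done on the
#' signed-distance field of each mask for sub-pixel boundary accuracy.
#'
#' @param stack a `frame_stack` (see [rasterize_swimmer()]) or a list with
#'   `frames`, `dt`, `pixel_scale`.
#' @param percentile segmentation percentile (see [segment_frame()]).
#' @param smoothing list with Savitzky-Golay `window` (frames) and `order`.
#' @return an object of class `isolated_frames`: derotated masks, the
#'   removed rigid trace as a tibble (`frame, t, cm_x_mm, cm_y_mm,
#'   alpha_deg`), calibration, and the output-frame origin.
#' @export
procrustes_isolate <- function(stack, percentile = 5,
                               smoothing = list(window = 11, order = 3)) {
  frames <- stack$frames
  n <- length(frames)
  if (n < 2) stop("need at least two frames", call. = FALSE)
  ps <- stack$pixel_scale
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])

  masks <- vector("list", n)
  thrs <- numeric(n)
  cm <- matrix(NA_real_, n, 2)
  alpha <- numeric(n)
  radius <- 0
  for (k in seq_len(n)) {
    m <- segment_frame(frames[[k]], percentile, pixel_scale = ps)
    masks[[k]] <- m
    thrs[k] <- as.numeric(stats::quantile(frames[[k]], percentile / 100))
    # sub-pixel mass properties from image darkness under the mask
    w <- darkness_weights(frames[[k]], m)
    mom <- mask_moments(m, w)
    cm[k, ] <- c(mom$cx, mom$cy)
    rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
    corners_x <- c(cc - 1); corners_y <- c(nr - rr)
    radius <- max(radius, sqrt(max(outer((corners_x - cm[k, 1])^2,
                                         (corners_y - cm[k, 2])^2, "+"))))
    prev <- if (k == 1) 0 else alpha[k - 1]
    a <- body_angle(m, previous_alpha = prev, weights = w)
    if (k > 1 && abs(a - alpha[k - 1]) > 90)
      stop(sprintf("rotation jump > 90 degrees between frames %d and %d",
                   k - 1, k), call. = FALSE)
    alpha[k] <- a
  }

  cm_s <- cbind(sg_smooth(cm[, 1], smoothing$window, smoothing$order),
                sg_smooth(cm[, 2], smoothing$window, smoothing$order))
  alpha_s <- sg_smooth(alpha, smoothing$window, smoothing$order)

  center <- c((nc - 1) / 2, (nr - 1) / 2)
  halfspan <- radius + 5
  iso <- vector("list", n)
  iso_img <- vector("list", n)
  for (k in seq_len(n)) {
    bgv <- stats::median(frames[[k]][!masks[[k]]])
    gi <- resample_frame_rigid(frames[[k]], cm_s[k, ], alpha_s[k],
                               c(nr, nc), center, halfspan, fill = bgv)
    iso_img[[k]] <- gi
    iso[[k]] <- binarize_resampled(gi)
    attr(iso[[k]], "pixel_scale") <- ps
  }

  structure(list(
    frames = iso,
    images = iso_img,
    thresholds = thrs,
    percentile = percentile,
    rigid = tibble::tibble(
      frame = seq_len(n), t = (seq_len(n) - 1) * stack$dt,
      cm_x_mm = cm_s[, 1] * ps, cm_y_mm = cm_s[, 2] * ps,
      alpha_deg = alpha_s
    ),
    dt = stack$dt,
    pixel_scale = ps,
    origin_px = center,
    radius_px = radius,
    dim = c(nr, nc)
  ), class = "isolated_frames")
}

#' Recompose rigid motion onto isolated frames
#'
#' Applies the stored rigid trace back onto the isolated body frames,
#' reconstructing the original silhouette sequence. Used to validate that
#' isolation is information-preserving (per-frame IoU against the input).
#'
#' @param iso an [procrustes_isolate()] result.
#' @return list of logical masks in the original frame geometry.
#' @export
recompose_rigid <- function(iso) {
  stopifnot(inherits(iso, "isolated_frames"))
  n <- length(iso$frames)
  nr <- iso$dim[1]; nc <- iso$dim[2]
  ps <- iso$pixel_scale
  out <- vector("list", n)
  for (k in seq_len(n)) {
    cm_px <- c(iso$rigid$cm_x_mm[k], iso$rigid$cm_y_mm[k]) / ps
    bgv <- stats::median(iso$images[[k]][!iso$frames[[k]]])
    # inverse map: input pixel p -> body offset R(-alpha) (p - cm)
    gi <- resample_frame_rigid(iso$images[[k]], iso$origin_px,
                               -iso$rigid$alpha_deg[k], c(nr, nc), cm_px,
                               halfspan = (iso$radius_px %||% (max(nr, nc) / 2)) + 5,
                               fill = bgv)
    out[[k]] <- binarize_resampled(gi)
  }
  out
}
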