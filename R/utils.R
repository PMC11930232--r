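# Shared internal helpers: coordinate conventions, interpolation, peaks.
#
# Convention used throughout the package (stated once, used everywhere):
# image matrices are indexed [row, col] with row 1 at the top; pixel (r, c)
# maps to physical coordinates x = (c - 1) * pixel_scale (rightward) and
# y = (nrow - r) * pixel_scale (upward), i.e. 0-based indices at pixel
# centers. Angles are in degrees, counterclockwise-positive from +x.

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# cubic smoothstep on [0, 1], clamped outside
smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

rot2 <- function(theta_deg) {
  th <- deg2rad(theta_deg)
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# pixel-center coordinate grids (0-based, y upward) for a matrix
pixel_grid <- function(nr, nc) {
  list(
    x = matrix(rep(0:(nc - 1), each = nr), nr, nc),
    y = matrix(rep((nr - 1):0, times = nc), nr, nc)
  )
}

px_to_rc <- function(x, y, nr) list(r = nr - y, c = x + 1)

# vectorized bilinear sampling of a matrix at fractional (x, y) pixel
# coordinates (0-based, y upward); out-of-range points take `fill`
bilinear_sample <- function(mat, x, y, fill = NA_real_) {
  nr <- nrow(mat); nc <- ncol(mat)
  cc <- x + 1
  rr <- nr - y
  c0 <- floor(cc); r0 <- floor(rr)
  fc <- cc - c0; fr <- rr - r0
  ok <- c0 >= 1 & c0 <= nc - 1 & r0 >= 1 & r0 <= nr - 1
  out <- rep(fill, length(x))
  if (!any(ok)) return(out)
  c0 <- c0[ok]; r0 <- r0[ok]; fc <- fc[ok]; fr <- fr[ok]
  i00 <- (c0 - 1) * nr + r0
  v <- (1 - fr) * (1 - fc) * mat[i00] +
    fr * (1 - fc) * mat[i00 + 1] +
    (1 - fr) * fc * mat[i00 + nr] +
    fr * fc * mat[i00 + nr + 1]
  out[ok] <- v
  out
}

# signed distance (in pixels) to the mask boundary: negative inside
sdf_from_mask <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  dout <- as.matrix(EBImage::distmap(1 - m))
  din <- as.matrix(EBImage::distmap(m))
  dout - din
}

mask_iou <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# local maxima with prominence and minimum separation (in samples).
# Returns indices ordered by position.
find_peaks <- function(x, prominence = 0, min_sep = 1) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(x))) < 0) + 1
  # plateau-safe: keep strict local maxima versus nearest distinct neighbours
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    # walk left/right until a higher value; prominence = peak - max(min_l, min_r)
    lmin <- x[i]; j <- i
    while (j > 1 && x[j - 1] <= x[i]) { j <- j - 1; lmin <- min(lmin, x[j]) }
    if (j == 1) lmin <- min(x[1:i])
    rmin <- x[i]; j <- i
    while (j < n && x[j + 1] <= x[i]) { j <- j + 1; rmin <- min(rmin, x[j]) }
    if (j == n) rmin <- min(x[i:n])
    x[i] - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= prominence]
  if (!length(keep)) return(integer(0))
  # enforce separation, keeping higher peaks first
  ord <- keep[order(x[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (i in ord) if (!length(sel) || all(abs(sel - i) >= min_sep)) sel <- c(sel, i)
  sort(sel)
}

# Savitzky-Golay smoothing tolerant of short series
sg_smooth <- function(x, window = 11, order = 3) {
  n <- length(x)
  if (window %% 2 == 0) window <- window + 1
  if (window > n) window <- if (n %% 2 == 1) n else n - 1
  if (window <= order + 1) return(x)
  as.numeric(signal::sgolayfilt(x, p = order, n = window))
}

moving_average <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window > length(x)) window <- length(x)
  if (window == 1L) return(x)
  k <- rep(1 / window, window)
  sm <- stats::filter(x, k, sides = 2)
  sm <- as.numeric(sm)
  # shrink the window near the edges instead of dropping samples
  na <- which(is.na(sm))
  for (i in na) {
    h <- (window - 1) %/% 2
    lo <- max(1, i - h); hi <- min(length(x), i + h)
    sm[i] <- mean(x[lo:hi])
  }
  sm
}

# resample a polyline (n x 2) to m points uniformly spaced in arclength
resample_polyline <- function(pts, m) {
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L <= 0) return(matrix(rep(pts[1, ], each = m), m, 2))
  si <- seq(0, L, length.out = m)
  cbind(approx(s, pts[, 1], xout = si)$y, approx(s, pts[, 2], xout = si)$y)
}

polyline_length <- function(pts) sum(sqrt(rowSums(diff(pts)^2)))

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0) stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0) stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}
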