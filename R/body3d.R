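# 3D body reconstruction: cross-section normalization, entropic
# optimal-transport interpolation, surface meshing, midline-driven bending.

#' Normalize raw cross-section images into a binary symmetric stack
#'
#' Binarizes each transverse image (Otsu threshold for grayscale input),
#' keeps the largest connected component, fills holes and imposes
#' bilateral symmetry by union with the mirror image about the vertical
#' center axis. Empty slices are dropped with a warning and recorded as
#' gaps.
#'
#' @param raw_images list of matrices (logical or grayscale).
#' @param positions_um axial position of each image (um).
#' @param pixel_um in-plane pixel size (um).
#' @return a `slice_stack`.
#' @export
normalize_slices <- function(raw_images, positions_um = NULL, pixel_um = 1) {
  if (!length(raw_images)) stop("no slices", call. = FALSE)
  positions_um <- positions_um %||% (seq_along(raw_images) - 1)
  slices <- vector("list", length(raw_images))
  keep <- logical(length(raw_images))
  for (i in seq_along(raw_images)) {
    img <- raw_images[[i]]
    if (is.logical(img)) {
      m <- img
    } else {
      thr <- EBImage::otsu(EBImage::Image(img), range = range(img))
      dark_fg <- mean(img < thr) < 0.5
      m <- if (dark_fg) img < thr else img > thr
    }
    if (!any(m)) {
      warning(sprintf("slice %d empty; dropped (gap recorded)", i))
      next
    }
    m <- clean_mask(m)
    m <- m | m[, ncol(m):1]  # bilateral symmetry: union with mirror
    slices[[i]] <- m
    keep[i] <- TRUE
  }
  if (!any(keep)) stop("all slices empty", call. = FALSE)
  sp <- if (sum(keep) > 1) min(diff(positions_um[keep])) else NA_real_
  structure(list(
    slices = slices[keep],
    positions_um = positions_um[keep],
    positions_nominal_um = positions_um,
    spacing_um = sp,
    pixel_um = pixel_um
  ), class = "slice_stack")
}

# separable Gaussian heat kernel application (entropic OT kernel
# exp(-d^2/epsilon) on the pixel grid)
make_heat_kernel <- function(nr, nc, epsilon) {
  g1 <- function(n) {
    d <- outer(seq_len(n), seq_len(n), "-")
    exp(-(d * d) / epsilon)
  }
  Kr <- g1(nr); Kc <- g1(nc)
  function(x) Kr %*% x %*% Kc
}

#' Entropic Wasserstein barycenter of two cross-sections
#'
#' Computes the entropy-regularized Wasserstein barycenter of two binary
#' (or nonnegative) slices with weights `(1 - w, w)` by iterative Sinkhorn
#' (iterative Bregman projection) scaling with a separable Gaussian heat
#' kernel, then renormalizes and thresholds the barycenter density to a
#' binary slice.
#'
#' @param sliceA,sliceB matrices of equal size, nonnegative, nonempty.
#' @param w interpolation weight in `[0, 1]` (0 returns approximately
#'   `sliceA`).
#' @param epsilon entropic regularization in squared pixels; default
#'   `1e-3 * diag^2` where `diag` is the slice diagonal.
#' @param max_iter,tol iteration cap and marginal L1 tolerance.
#' @param threshold binarization level as a fraction of the density
#'   maximum.
#' @return logical matrix with the continuous density as attribute
#'   `density` and iterations used as `iterations`.
#' @export
sinkhorn_barycenter <- function(sliceA, sliceB, w, epsilon = NULL,
                                max_iter = 2000, tol = 1e-6,
                                threshold = 0.5) {
  if (!all(dim(sliceA) == dim(sliceB))) stop("slice sizes differ", call. = FALSE)
  if (w < 0 || w > 1) stop("`w` must be in [0, 1]", call. = FALSE)
  p1 <- matrix(as.numeric(sliceA), nrow(sliceA), ncol(sliceA))
  p2 <- matrix(as.numeric(sliceB), nrow(sliceB), ncol(sliceB))
  if (sum(p1) <= 0 || sum(p2) <= 0) stop("slices must be nonempty", call. = FALSE)
  p1 <- p1 / sum(p1); p2 <- p2 / sum(p2)
  nr <- nrow(p1); nc <- ncol(p1)
  epsilon <- epsilon %||% (1e-3 * (nr^2 + nc^2))
  K <- make_heat_kernel(nr, nc, epsilon)
  lam <- c(1 - w, w)
  v <- list(matrix(1, nr, nc), matrix(1, nr, nc))
  p <- list(p1, p2)
  tiny <- 1e-300
  res <- Inf
  for (it in seq_len(max_iter)) {
    d <- vector("list", 2)
    mu <- matrix(1, nr, nc)
    for (k in 1:2) {
      Kv <- pmax(K(v[[k]]), tiny)
      d[[k]] <- v[[k]] * K(p[[k]] / Kv)
      if (lam[k] > 0) mu <- mu * pmax(d[[k]], tiny)^lam[k]
    }
    for (k in 1:2) v[[k]] <- v[[k]] * mu / pmax(d[[k]], tiny)
    res <- max(sum(abs(d[[1]] - mu)), sum(abs(d[[2]] - mu)))
    if (res < tol) break
  }
  if (res >= tol && max_iter > 10)
    stop(sprintf("Sinkhorn barycenter did not converge: marginal residual %.3g after %d iterations",
                 res, max_iter), call. = FALSE)
  mu <- mu / max(mu)
  out <- mu >= threshold
  attr(out, "density") <- mu
  attr(out, "iterations") <- it
  out
}

#' Interpolate a cross-section stack to uniform spacing
#'
#' Fills a uniform axial grid with entropic Wasserstein barycenters of the
#' bracketing key slices, with linear axial weight. Positions coinciding
#' with a key slice reproduce that slice exactly.
#'
#' @param stack a `slice_stack` (possibly with gaps).
#' @param target_spacing_um output spacing (um).
#' @param epsilon,max_iter,tol passed to [sinkhorn_barycenter()].
#' @return a uniform `slice_stack`.
#' @export
interpolate_stack <- function(stack, target_spacing_um, epsilon = NULL,
                              max_iter = 2000, tol = 1e-6) {
  stopifnot(inherits(stack, "slice_stack"))
  # empty key slices (zero-width body ends) cannot anchor a barycenter
  ne <- vapply(stack$slices, any, logical(1))
  stack$slices <- stack$slices[ne]
  stack$positions_um <- stack$positions_um[ne]
  pos <- stack$positions_um
  span <- max(pos) - min(pos)
  if (target_spacing_um > span)
    stop("`target_spacing_um` larger than the key-slice span", call. = FALSE)
  new_pos <- seq(min(pos), max(pos), by = target_spacing_um)
  out <- vector("list", length(new_pos))
  for (i in seq_along(new_pos)) {
    z <- new_pos[i]
    j <- findInterval(z, pos, rightmost.closed = TRUE)
    if (abs(z - pos[j]) < 1e-9 * max(1, abs(z))) {
      out[[i]] <- stack$slices[[j]]
    } else if (j < length(pos) && abs(z - pos[j + 1]) < 1e-9 * max(1, abs(z))) {
      out[[i]] <- stack$slices[[j + 1]]
    } else {
      w <- (z - pos[j]) / (pos[j + 1] - pos[j])
      out[[i]] <- sinkhorn_barycenter(stack$slices[[j]], stack$slices[[j + 1]],
                                      w, epsilon = epsilon,
                                      max_iter = max_iter, tol = tol)
    }
  }
  structure(list(
    slices = out,
    positions_um = new_pos,
    positions_nominal_um = new_pos,
    spacing_um = target_spacing_um,
    pixel_um = stack$pixel_um
  ), class = "slice_stack")
}

# sub-pixel boundary radius of a slice along rays from its center
ring_radii <- function(slice, center_rc, angles, pixel_um) {
  sd <- sdf_from_mask(slice)
  rmax <- max(dim(slice))
  steps <- seq(0, rmax, by = 0.5)
  vapply(angles, function(a) {
    dx <- cos(a); dy <- sin(a)
    cc <- center_rc[2] + steps * dx
    rr <- center_rc[1] - steps * dy
    v <- bilinear_sample(sd, cc - 1, nrow(slice) - rr, fill = rmax)
    ix <- which(v > 0)
    if (!length(ix) || ix[1] == 1) return(0)
    i0 <- ix[1] - 1
    # linear zero crossing between the last inside and first outside sample
    f <- v[i0] / (v[i0] - v[i0 + 1])
    (steps[i0] + f * (steps[i0 + 1] - steps[i0])) * pixel_um
  }, numeric(1))
}

#' Build a Lagrangian-marker surface mesh from a uniform slice stack
#'
#' Samples the zero level set of each slice's signed-distance field along
#' `n_circ` rays, at `n_axial` axial stations (each station associated to
#' its nearest transverse slice), producing the `n_axial x n_circ` marker
#' grid. The enclosed volume is computed from the voxel count.
#'
#' @param stack uniform `slice_stack`.
#' @param n_axial,n_circ marker grid size (defaults 300 x 180).
#' @return an object of class `body_mesh`: `markers` array
#'   `(n_axial, n_circ, 3)` in mm (x axial, y lateral, z dorsoventral),
#'   axial stations `s_mm`, volume `Vs_mm3`, `standard_length`.
#' @export
build_surface_mesh <- function(stack, n_axial = 300, n_circ = 180) {
  stopifnot(inherits(stack, "slice_stack"))
  ne <- vapply(stack$slices, function(s) sum(s) > 0, logical(1))
  rng <- range(which(ne))
  if (any(!ne[rng[1]:rng[2]]))
    stop("disconnected volume: empty interior slice", call. = FALSE)
  slices <- stack$slices[rng[1]:rng[2]]
  pos <- stack$positions_um[rng[1]:rng[2]]
  px <- stack$pixel_um
  L_mm <- (max(pos) - min(pos)) / 1000

  vox <- sum(vapply(slices, sum, numeric(1)))
  Vs <- vox * (px / 1000)^2 * (stack$spacing_um / 1000)

  s_mm <- seq(0, L_mm, length.out = n_axial)
  angles <- seq(0, 2 * pi, length.out = n_circ + 1)[-(n_circ + 1)]
  markers <- array(0, c(n_axial, n_circ, 3))
  slice_of <- integer(n_axial)
  for (i in seq_len(n_axial)) {
    j <- which.min(abs(pos - (min(pos) + s_mm[i] * 1000)))
    slice_of[i] <- j
    s <- slices[[j]]
    idx <- which(s, arr.ind = TRUE)
    ctr <- c(mean(idx[, 1]), (ncol(s) + 1) / 2) # symmetry axis is center col
    r <- ring_radii(s, ctr, angles, px) / 1000  # mm
    markers[i, , 1] <- s_mm[i]
    markers[i, , 2] <- r * cos(angles)
    markers[i, , 3] <- r * sin(angles)
  }
  structure(list(
    markers = markers, s_mm = s_mm, slice_of = slice_of,
    Vs_mm3 = Vs, standard_length = L_mm,
    n_axial = n_axial, n_circ = n_circ
  ), class = "body_mesh")
}

#' Rescale a body mesh to a target standard length
#'
#' Uniform isotropic scaling; the enclosed volume scales with the cube of
#' the length ratio.
#'
#' @param mesh a `body_mesh`.
#' @param standard_length target snout-to-vertebral-column-end length (mm).
#' @return the rescaled `body_mesh`.
#' @export
scale_to_length <- function(mesh, standard_length) {
  stopifnot(inherits(mesh, "body_mesh"))
  check_scalar(standard_length, "standard_length", positive = TRUE)
  s <- standard_length / mesh$standard_length
  mesh$markers <- mesh$markers * s
  mesh$s_mm <- mesh$s_mm * s
  mesh$Vs_mm3 <- mesh$Vs_mm3 * s^3
  mesh$standard_length <- standard_length
  mesh
}

# lateral surface area of the marker grid (sum of quad areas)
mesh_surface_area <- function(mesh) {
  mk <- mesh$markers
  na <- dim(mk)[1]; nc <- dim(mk)[2]
  area <- 0
  for (i in seq_len(na - 1)) {
    jn <- c(seq_len(nc)[-1], 1)
    a <- mk[i, , ]; b <- mk[i + 1, , ]
    # two triangles per quad (j, j+1, i/i+1)
    v1 <- b - a; v2 <- a[jn, ] - a; v3 <- b[jn, ] - b
    cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                               u[, 3] * v[, 1] - u[, 1] * v[, 3],
                               u[, 1] * v[, 2] - u[, 2] * v[, 1])
    area <- area + 0.5 * sum(sqrt(rowSums(cr(v1, v2)^2))) +
      0.5 * sum(sqrt(rowSums(cr(v3, a[jn, ] - b)^2)))
  }
  area
}

#' Bend the reference mesh along per-frame midlines
#'
#' Deforms the rest mesh so that each transverse marker ring lies in the
#' plane orthogonal to the local midline tangent at matched arclength
#' (Euler-Bernoulli assumption; slices are transported rigidly in-plane).
#' A second (3D) Procrustes pass removes the residual mass center and
#' net rotation of the deformation, marker positions are mean-filtered
#' over `smooth_ms`, and the deformation velocity is the smoothed
#' finite-difference marker velocity.
#'
#' @param mesh a `body_mesh` (rescaled to the midline length if needed).
#' @param midlines list of `(n+1) x 2` midline matrices in mm (head to
#'   tail), one per frame, or a 3D array `(frames, points, 2)`.
#' @param dt frame interval (s).
#' @param smooth_ms temporal mean-filter window (ms), default 0.5.
#' @return an object of class `body_motion`: per-frame marker arrays
#'   (mm, centered), deformation velocity `utilde` (mm/s), `dt`.
#' @export
deform_to_midline <- function(mesh, midlines, dt, smooth_ms = 0.5) {
  stopifnot(inherits(mesh, "body_mesh"))
  if (is.array(midlines) && length(dim(midlines)) == 3)
    midlines <- lapply(seq_len(dim(midlines)[1]), function(k) midlines[k, , ])
  nfr <- length(midlines)
  L_mid <- polyline_length(midlines[[1]])
  if (abs(L_mid - mesh$standard_length) / mesh$standard_length > 1e-3)
    mesh <- scale_to_length(mesh, L_mid)
  mk0 <- mesh$markers
  na <- mesh$n_axial; ncirc <- mesh$n_circ
  ring_r_max <- apply(sqrt(mk0[, , 2]^2 + mk0[, , 3]^2), 1, max)

  frames <- vector("list", nfr)
  for (k in seq_len(nfr)) {
    ml <- resample_polyline(midlines[[k]], na)
    seg <- diff(ml)
    tang <- rbind(seg, seg[nrow(seg), , drop = FALSE])
    tang <- tang / sqrt(rowSums(tang^2))
    # self-intersection guard: in-plane radius of curvature vs ring radius
    turn <- abs(diff(atan2(tang[, 2], tang[, 1])))
    turn <- pmin(turn, 2 * pi - turn)
    ds <- sqrt(rowSums(seg^2))
    bad <- which(turn > 1e-12 & ds / turn < ring_r_max[-1])
    if (length(bad))
      stop(sprintf("self-intersecting deformation at frame %d, arclength %.2f mm",
                   k, sum(ds[seq_len(bad[1])])), call. = FALSE)
    nrm <- cbind(-tang[, 2], tang[, 1])
    out <- array(0, c(na, ncirc, 3))
    out[, , 1] <- ml[, 1] + mk0[, , 2] * nrm[, 1]
    out[, , 2] <- ml[, 2] + mk0[, , 2] * nrm[, 2]
    out[, , 3] <- mk0[, , 3]
    frames[[k]] <- out
  }

  # second Procrustes: remove mass center and net planar rotation of the
  # deformation sequence (weights: ring mean squared radius as area proxy)
  wgt <- rowMeans(sqrt(mk0[, , 2]^2 + mk0[, , 3]^2))
  wgt <- pmax(wgt, 1e-6); wgt <- wgt / sum(wgt)
  theta_cum <- 0
  raw_prev <- NULL
  for (k in seq_len(nfr)) {
    fr <- frames[[k]]
    cx <- sum(wgt * rowMeans(fr[, , 1])); cy <- sum(wgt * rowMeans(fr[, , 2]))
    fr[, , 1] <- fr[, , 1] - cx; fr[, , 2] <- fr[, , 2] - cy
    if (k > 1) {
      pr <- raw_prev
      num <- sum(wgt * rowMeans(pr[, , 1] * fr[, , 2] - pr[, , 2] * fr[, , 1]))
      den <- sum(wgt * rowMeans(pr[, , 1] * fr[, , 1] + pr[, , 2] * fr[, , 2]))
      theta_cum <- theta_cum + atan2(num, den)
    }
    raw_prev <- fr
    if (abs(theta_cum) > 1e-12) {
      co <- cos(-theta_cum); si <- sin(-theta_cum)
      x <- fr[, , 1] * co - fr[, , 2] * si
      y <- fr[, , 1] * si + fr[, , 2] * co
      fr[, , 1] <- x; fr[, , 2] <- y
      cx2 <- sum(wgt * rowMeans(fr[, , 1])); cy2 <- sum(wgt * rowMeans(fr[, , 2]))
      fr[, , 1] <- fr[, , 1] - cx2; fr[, , 2] <- fr[, , 2] - cy2
    }
    frames[[k]] <- fr
  }

  # temporal mean filter over smooth_ms
  win <- max(1L, round(smooth_ms / 1000 / dt))
  if (win > 1 && nfr > 2) {
    arr <- array(unlist(frames), c(na, ncirc, 3, nfr))
    flat <- matrix(arr, ncol = nfr)
    flat <- t(apply(flat, 1, moving_average, window = win))
    arr <- array(flat, c(na, ncirc, 3, nfr))
    frames <- lapply(seq_len(nfr), function(k) arr[, , , k])
  }

  utilde <- vector("list", nfr)
  for (k in seq_len(nfr)) {
    k0 <- max(1, k - 1); k1 <- min(nfr, k + 1)
    utilde[[k]] <- (frames[[k1]] - frames[[k0]]) / ((k1 - k0) * dt)
  }

  structure(list(
    frames = frames, utilde = utilde, dt = dt,
    mesh = mesh, n_axial = na, n_circ = ncirc
  ), class = "body_motion")
}
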