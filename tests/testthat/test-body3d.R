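disc_mask <- function(r, n = 41) {
  g <- expand.grid(row = 1:n, col = 1:n)
  matrix((g$col - (n + 1) / 2)^2 + (g$row - (n + 1) / 2)^2 <= r^2, n, n)
}

test_that("slice normalization symmetrizes and binarizes", {
  s <- disc_mask(10)
  st <- normalize_slices(list(s), pixel_um = 5)
  expect_identical(st$slices[[1]], st$slices[[1]][, ncol(s):1])
  # one asymmetric lobe -> union with its mirror
  lob <- s; lob[15:20, 31:38] <- TRUE
  st2 <- normalize_slices(list(lob), pixel_um = 5)
  expect_identical(st2$slices[[1]], lob | lob[, ncol(lob):1])
  # grayscale bimodal input: foreground area equals the brute-force count
  g <- matrix(0.9, 41, 41); g[disc_mask(12)] <- 0.1
  g <- g + matrix(seq(-0.02, 0.02, length.out = 41 * 41), 41, 41)
  st3 <- normalize_slices(list(g), pixel_um = 5)
  thr <- 0.5
  expect_equal(sum(st3$slices[[1]]),
               sum(disc_mask(12) | disc_mask(12)[, 41:1]))
  # empty slice dropped with warning
  expect_warning(st4 <- normalize_slices(list(s, matrix(FALSE, 5, 5)),
                                         positions_um = c(0, 10), pixel_um = 5),
                 "dropped")
  expect_length(st4$slices, 1)
})

test_that("Sinkhorn barycenter honours its limiting cases", {
  A <- disc_mask(10)
  b_id <- sinkhorn_barycenter(A, A, 0.5)
  expect_gte(mask_iou_fx(b_id, A), 0.95)
  B <- disc_mask(18)
  b0 <- sinkhorn_barycenter(A, B, 0)
  expect_gte(mask_iou_fx(b0, A), 0.9)
  b1 <- sinkhorn_barycenter(A, B, 1)
  expect_gte(mask_iou_fx(b1, B), 0.9)
  expect_error(sinkhorn_barycenter(A, B, 1.5), "w")
  expect_error(sinkhorn_barycenter(A, matrix(FALSE, 41, 41), 0.5), "nonempty")
})

test_that("the barycenter of two point masses concentrates at the midpoint", {
  P1 <- matrix(FALSE, 41, 41); P1[21, 6] <- TRUE
  P2 <- matrix(FALSE, 41, 41); P2[21, 36] <- TRUE
  b <- sinkhorn_barycenter(P1, P2, 0.5, epsilon = 20)
  dens <- attr(b, "density")
  peak <- which(dens == max(dens), arr.ind = TRUE)[1, ]
  expect_lt(abs(peak["row"] - 21), 2)
  expect_lt(abs(peak["col"] - 21), 2)
})

test_that("stack interpolation reproduces keys and fills gaps", {
  A <- disc_mask(12)
  st <- structure(list(slices = list(A, A, A),
                       positions_um = c(0, 50, 100),
                       spacing_um = 50, pixel_um = 5),
                  class = "slice_stack")
  out <- interpolate_stack(st, 25)
  expect_length(out$slices, 5)
  for (s in out$slices) expect_gte(mask_iou_fx(s, A), 0.95)
  # key positions are copied exactly
  expect_identical(out$slices[[1]], A)
  expect_identical(out$slices[[3]], A)
  # midpoint of two discs: area strictly between the two
  B <- disc_mask(20)
  st2 <- structure(list(slices = list(A, B), positions_um = c(0, 100),
                        spacing_um = 100, pixel_um = 5),
                   class = "slice_stack")
  mid <- interpolate_stack(st2, 50)$slices[[2]]
  expect_gt(sum(mid), sum(A))
  expect_lt(sum(mid), sum(B))
  expect_error(interpolate_stack(st2, 500), "span")
})

test_that("a synthetic stack with missing slices is reconstructed (mean IoU >= 0.9)", {
  prof <- body_profile()
  full <- make_slice_stack(prof, spacing_um = 100, pixel_um = 10)
  holey <- make_slice_stack(prof, spacing_um = 100, pixel_um = 10,
                            missing_fraction = 0.3, seed = 7)
  rec <- interpolate_stack(holey, 100)
  ious <- vapply(seq_along(rec$slices), function(i) {
    j <- match(rec$positions_um[i], full$positions_um)
    mask_iou_fx(rec$slices[[i]], full$slices[[j]])
  }, numeric(1))
  expect_gte(mean(ious), 0.9)
})

test_that("the surface mesh of a cylinder matches closed forms within 5%", {
  slices <- replicate(21, disc_mask(30, 81), simplify = FALSE)
  st <- structure(list(slices = slices, positions_um = seq(0, 2000, by = 100),
                       spacing_um = 100, pixel_um = 10),
                  class = "slice_stack")
  mesh <- build_surface_mesh(st, n_axial = 50, n_circ = 64)
  r <- 0.30; L <- 2
  expect_lt(abs(mesh$Vs_mm3 / (pi * r^2 * L) - 1), 0.05)
  expect_lt(abs(zfescape:::mesh_surface_area(mesh) / (2 * pi * r * L) - 1), 0.05)
  expect_identical(dim(mesh$markers), c(50L, 64L, 3L))
  # markers on the zero level set: radial distance within half a voxel
  rad <- sqrt(mesh$markers[25, , 2]^2 + mesh$markers[25, , 3]^2)
  expect_lt(max(abs(rad - r)), 0.5 * 10 / 1000 + 1e-6)
  # disconnected volume errors
  broken <- st; broken$slices[[10]] <- matrix(FALSE, 81, 81)
  expect_error(build_surface_mesh(broken, 10, 16), "disconnected")
})

test_that("the default marker grid is 300 x 180", {
  expect_identical(formals(build_surface_mesh)$n_axial, 300)
  expect_identical(formals(build_surface_mesh)$n_circ, 180)
})

test_that("scaling to a standard length is exact and cubes the volume", {
  slices <- replicate(11, disc_mask(20, 51), simplify = FALSE)
  st <- structure(list(slices = slices, positions_um = seq(0, 2000, by = 200),
                       spacing_um = 200, pixel_um = 10),
                  class = "slice_stack")
  mesh <- build_surface_mesh(st, 20, 32)
  m_id <- scale_to_length(mesh, mesh$standard_length)
  expect_equal(m_id$markers, mesh$markers)
  m2 <- scale_to_length(mesh, 3.829)
  expect_equal(m2$standard_length, 3.829)
  expect_equal(max(m2$s_mm) - min(m2$s_mm), 3.829)
  s <- 3.829 / mesh$standard_length
  expect_equal(m2$Vs_mm3, mesh$Vs_mm3 * s^3)
})

test_that("midline-driven bending is volume-aware and removes rigid motion", {
  slices <- replicate(21, disc_mask(12, 41), simplify = FALSE)
  st <- structure(list(slices = slices, positions_um = seq(0, 2000, by = 100),
                       spacing_um = 100, pixel_um = 10),
                  class = "slice_stack")
  mesh <- build_surface_mesh(st, 40, 48)
  straight <- cbind(seq(0, 2, length.out = 301), 0)
  # constant midline -> static motion, zero deformation velocity
  mot <- deform_to_midline(mesh, list(straight, straight, straight), dt = 1e-4)
  expect_lt(max(abs(unlist(mot$utilde))), 1e-9)
  # rigidly rotated midlines -> identical frames after the 3D Procrustes
  rot_ml <- function(a) t(zfescape:::rot2(a) %*% t(straight))
  mot2 <- deform_to_midline(mesh, list(straight, rot_ml(20), rot_ml(40)),
                            dt = 1e-4, smooth_ms = 0)
  expect_lt(max(abs(mot2$frames[[3]] - mot2$frames[[1]])), 1e-9)
  # bent midline: each ring plane orthogonal to the local tangent
  th <- seq(0, pi / 3, length.out = 301)
  Rc <- 2 / (pi / 3)
  bent <- cbind(Rc * sin(th), Rc * (1 - cos(th)))
  mot3 <- deform_to_midline(mesh, list(bent, bent), dt = 1e-4)
  fr <- mot3$frames[[1]]
  for (i in c(10, 20, 30)) {
    ring <- fr[i, , ]
    sv <- svd(scale(ring, scale = FALSE))
    nrm <- sv$v[, 3]
    ang <- (i - 1) / 39 * pi / 3
    tg3 <- c(cos(ang), sin(ang), 0)
    expect_gt(abs(sum(nrm * tg3)), cos(zfescape:::deg2rad(2)))
  }
  # an impossible bend (radius of curvature below the body radius) errors
  tight <- cbind(0.2 * sin(seq(0, 6 * pi, length.out = 301)),
                 0.2 * (1 - cos(seq(0, 6 * pi, length.out = 301))))
  expect_error(deform_to_midline(mesh, list(tight), dt = 1e-4),
               "self-intersecting")
})
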