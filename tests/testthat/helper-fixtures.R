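# Shared fixtures, built once per test run and memoised.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fx)) assign(name, force(expr), envir = .fx)
  get(name, envir = .fx)
}

# a short (2 kHz) default-amplitude escape movie on a compact window,
# with rigid swimming superposed: the common tracking fixture
fx_track_params <- function() {
  cstart_params(frame_rate = 2000, superposed_translation = 40,
                superposed_rotation = 4000, image_size = c(360, 300),
                noise_level = 0.01, seed = 3)
}

fx_tracking <- function() fixture("tracking", {
  p <- fx_track_params()
  kin <- make_cstart_kinematics(p)
  prof <- body_profile()
  stack <- rasterize_swimmer(kin, prof, p)
  iso <- procrustes_isolate(stack)
  list(params = p, kin = kin, profile = prof, stack = stack, iso = iso)
})

# midlines and curvature trace extracted from the isolated frames
fx_midlines <- function() fixture("midlines", {
  tk <- fx_tracking()
  mls <- vector("list", length(tk$iso$frames))
  prev <- NULL
  for (i in seq_along(mls)) {
    prev <- extract_midline(tk$iso$frames[[i]], prev = prev, frame = i)
    mls[[i]] <- prev
  }
  curv <- vapply(mls, function(m) midline_curvature(m)$head_tail_angle,
                 numeric(1))
  list(midlines = mls, curvature = curv)
})

# default synthetic C-start body motion for the solver
fx_motion <- function() fixture("motion", {
  p <- cstart_params()
  motion_from_kinematics(make_cstart_kinematics(p), body_profile())
})

# water escape simulation at the acceptance grid
fx_sim_water <- function() fixture("sim_water", {
  simulate_escape(fx_motion(), fluid_params(1000, 0.83e-3),
                  grid = list(nx = 128, lx = 0.012), save_every = 1000)
})

# the fixed-kinematics virtual viscosity sweep at the acceptance grid
fx_virtual_sweep <- function() fixture("virtual_sweep", {
  run_virtual_sweep(fx_motion(), c(0.83, 1.1, 2.3, 5, 10, 15),
                    cfg = list(grid = list(nx = 128, lx = 0.012),
                               save_every = 1000, keep_sims = TRUE))
})

# Taylor-Green decay error at 128^2 (periodic, nu = 0.5, half a unit time)
fx_taylor_green <- function() fixture("taylor_green", {
  nx <- 128; L <- 2 * pi; nu <- 0.5
  fl <- flow_state(nx, nx, L, L, bc = "periodic")
  h <- fl$h
  par <- fluid_params(rho = 1, mu = nu)
  xs_u <- (0:nx) * h; ys_c <- ((1:nx) - 0.5) * h
  xs_c <- ((1:nx) - 0.5) * h; ys_v <- (0:nx) * h
  fl$u <- outer(xs_u, ys_c, function(x, y) sin(x) * cos(y))
  fl$v <- outer(xs_c, ys_v, function(x, y) -cos(x) * sin(y))
  basis <- fl$u
  dt <- 5e-4
  for (i in 1:1000) fl <- ns_step(fl, NULL, par, dt)
  amp <- sum(fl$u[1:nx, ] * basis[1:nx, ]) / sum(basis[1:nx, ]^2)
  list(flow = fl, rel_err = abs(amp / exp(-2 * nu * fl$t) - 1))
})

mask_iou_fx <- function(a, b) {
  u <- sum(a | b); if (u == 0) return(1); sum(a & b) / u
}

# static disc in an initially uniform stream; returns the largest interior
# velocity after 20 penalized steps (for the lambda-monotonicity checks)
penalized_interior <- function(lambda) {
  nx <- 96; L <- 0.01
  fl <- flow_state(nx, nx, L, L, bc = "periodic")
  fl$u[] <- 0.05
  par <- fluid_params(1000, 5e-3)
  h <- fl$h
  xs_u <- (0:nx) * h; ys_c <- ((1:nx) - 0.5) * h
  xs_c <- ((1:nx) - 0.5) * h; ys_v <- (0:nx) * h
  r0 <- 0.002
  chi_of <- function(xs, ys) {
    d <- sqrt(outer((xs - L / 2)^2, (ys - L / 2)^2, "+")) - r0
    pmin(pmax(0.5 - d / h, 0), 1)
  }
  solid <- list(chi_u = chi_of(xs_u, ys_c), chi_v = chi_of(xs_c, ys_v),
                us_u = matrix(0, nx + 1, nx), us_v = matrix(0, nx, nx + 1),
                lambda = lambda)
  for (i in 1:20) fl <- ns_step(fl, solid, par, 2e-5)
  core <- sqrt(outer((xs_u - L / 2)^2, (ys_c - L / 2)^2, "+")) < r0 - 2 * h
  max(abs(fl$u[core]))
}

# brute-force enstrophy of a stored snapshot (independent of the
# packaged vorticity helper: plain centred differences written out)
snapshot_enstrophy <- function(sn) {
  h <- sn$h; nx <- nrow(sn$p)
  uc <- 0.5 * (sn$u[1:nx, ] + sn$u[2:(nx + 1), ])
  vc <- 0.5 * (sn$v[, 1:nx] + sn$v[, 2:(nx + 1)])
  om <- (vc[c(2:nx, nx), ] - vc[c(1, 1:(nx - 1)), ]) / (2 * h) -
    (uc[, c(2:nx, nx)] - uc[, c(1, 1:(nx - 1))]) / (2 * h)
  sum(om^2) * h^2
}
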