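test_that("total energy integrates power correctly", {
  dt <- 1e-3
  expect_equal(total_energy(rep(2.5, 101), dt), 2.5 * 101 * dt)
  expect_equal(total_energy(rep(0, 50), dt), 0)
  # sin^2 over one period -> T/2
  n <- 1000; T <- 0.1; dt2 <- T / n
  P <- sin(2 * pi * (0:(n - 1)) / n)^2
  expect_equal(total_energy(P, dt2, method = "riemann"), T / 2,
               tolerance = 1e-3)
  expect_error(total_energy(rep(1, 10), dt, ti = 1, tf = 2), "empty")
  # additivity over a partition
  set.seed(2); P2 <- runif(200)
  E_full <- total_energy(P2, dt)
  E_split <- total_energy(P2[1:120], dt) + total_energy(P2[121:200], dt)
  expect_equal(E_full, E_split)
})

test_that("cost of transport is the energy per unit path and scale free", {
  expect_equal(cost_of_transport(2, 4), 0.5)
  expect_equal(cost_of_transport(4, 8), cost_of_transport(2, 4))
  expect_error(cost_of_transport(1, 0), "d_total")
  # for constant speed: CoT equals mean power over mean velocity
  P <- rep(3e-5, 500); dt <- 1e-4; v <- 0.05
  E <- total_energy(P, dt); d <- v * 500 * dt
  expect_equal(cost_of_transport(E, d), mean(P) / v, tolerance = 0.005)
})

test_that("Froude efficiency is a guarded ratio", {
  expect_equal(froude_efficiency(1, 1), 1)
  expect_equal(froude_efficiency(0, 1), 0)
  expect_error(froude_efficiency(1, 0), "W_total")
})

test_that("Reynolds number follows rho V L / mu", {
  expect_equal(reynolds(fluid_params(1000, 0.83e-3), 0, 4e-3), 0)
  expect_equal(reynolds(fluid_params(1000, 0.83e-3), 0.1, 4e-3),
               1000 * 0.1 * 4e-3 / 0.83e-3)
  expect_equal(round(reynolds(fluid_params(1000, 0.83e-3), 0.1, 4e-3)), 482)
  # fixed kinematics: Re strictly decreasing in mu
  res <- vapply(c(0.83, 2.3, 5, 15) * 1e-3, function(mu)
    reynolds(fluid_params(1000, mu), 0.05, 3.83e-3), numeric(1))
  expect_true(all(diff(res) < 0))
})

test_that("vorticity and Q-criterion match analytic velocity-gradient cases", {
  nx <- 64; L <- 1
  fl <- flow_state(nx, nx, L, L, bc = "periodic")
  h <- fl$h
  ys_c <- ((1:nx) - 0.5) * h; xs_u <- (0:nx) * h
  xs_c <- ((1:nx) - 0.5) * h; ys_v <- (0:nx) * h
  core <- 5:(nx - 5)
  # solid-body rotation u = (-w y, w x): Q = w^2, vorticity = 2w
  w <- 3
  fl$u <- outer(xs_u, ys_c, function(x, y) -w * (y - L / 2))
  fl$v <- outer(xs_c, ys_v, function(x, y) w * (x - L / 2))
  expect_equal(max(abs(vorticity(fl)[core, core] - 2 * w)), 0,
               tolerance = 1e-9)
  expect_equal(max(abs(q_criterion(fl)[core, core] - w^2)), 0,
               tolerance = 1e-9)
  # pure shear u = (g y, 0): Q = 0
  g <- 2
  fl$u <- outer(xs_u, ys_c, function(x, y) g * y)
  fl$v[] <- 0
  expect_lt(max(abs(q_criterion(fl)[core, core])), 1e-9)
  # irrotational strain u = (g x, -g y): Q = -g^2, vorticity = 0
  fl$u <- outer(xs_u, ys_c, function(x, y) g * x)
  fl$v <- outer(xs_c, ys_v, function(x, y) -g * y)
  expect_equal(max(abs(q_criterion(fl)[core, core] + g^2)), 0,
               tolerance = 1e-9)
  expect_lt(max(abs(vorticity(fl)[core, core])), 1e-9)
  # both vanish identically on a uniform stream
  fl$u[] <- 0.3; fl$v[] <- 0
  expect_lt(max(abs(vorticity(fl)[core, core])), 1e-12)
  expect_lt(max(abs(q_criterion(fl)[core, core])), 1e-12)
})

test_that("trace smoothing preserves polynomials and suppresses noise", {
  dt <- 1e-4
  cst <- rep(4, 200)
  expect_equal(smooth_trace(cst, dt), cst, tolerance = 1e-9)
  ramp <- seq(0, 1, length.out = 200)
  expect_equal(smooth_trace(ramp, dt), ramp, tolerance = 1e-6)
  set.seed(9)
  t <- (0:999) * dt
  clean <- sin(2 * pi * 40 * t)
  noisy <- clean + rnorm(1000, 0, 0.3)
  sm <- smooth_trace(noisy, dt)
  expect_gt(var(noisy - clean) / var(sm - clean), 5)
  expect_error(smooth_trace(1:5, dt, window = 11), "window")
})

test_that("towed-plate power equals drag times speed within 2%", {
  # plate dragged at constant speed through initially still fluid
  nx <- 96; L <- 0.01
  fl <- flow_state(nx, nx, L)
  par <- fluid_params(1000, 3e-3)
  h <- fl$h; U <- 0.03
  xs_u <- (0:nx) * h; ys_c <- ((1:nx) - 0.5) * h
  xs_c <- ((1:nx) - 0.5) * h; ys_v <- (0:nx) * h
  chi_of <- function(xs, ys) {
    dx <- abs(outer(xs - L / 2, rep(1, length(ys)))) - 0.0018
    dy <- abs(outer(rep(1, length(xs)), ys - L / 2)) - 0.0004
    d <- pmax(dx, dy)
    pmin(pmax(0.5 - d / h, 0), 1)
  }
  solid <- list(chi_u = chi_of(xs_u, ys_c), chi_v = chi_of(xs_c, ys_v),
                us_u = chi_of(xs_u, ys_c) * 0 + U,
                us_v = matrix(0, nx, nx + 1), lambda = 1e8)
  for (i in 1:60) fl <- ns_step(fl, solid, par, 2e-5)
  th <- seq(0, 2 * pi, length.out = 241)[-241]
  a <- 0.0018; b <- 0.0004
  # rectangle outline markers
  per <- rbind(cbind(seq(-a, a, length.out = 60), -b),
               cbind(a, seq(-b, b, length.out = 20)),
               cbind(seq(a, -a, length.out = 60), b),
               cbind(-a, seq(b, -b, length.out = 20)))
  nrm <- rbind(cbind(0, rep(-1, 60)), cbind(rep(1, 20), 0),
               cbind(0, rep(1, 60)), cbind(rep(-1, 20), 0))
  ds <- c(rep(2 * a / 59, 60), rep(2 * b / 19, 20),
          rep(2 * a / 59, 60), rep(2 * b / 19, 20))
  mk <- list(markers = sweep(per, 2, c(L / 2, L / 2), "+"), normals = nrm,
             ds = ds, cm = c(L / 2, L / 2),
             us = cbind(rep(U, nrow(per)), 0))
  P <- instantaneous_power(fl, mk, par)
  ld <- hydrodynamic_loads(fl, mk, par)
  expect_lt(abs(P - (-ld$F[1]) * U) / abs(P), 0.02)
  expect_gt(P, 0)  # the towed plate does work on the fluid
})

test_that("a static body in still fluid exerts zero power", {
  fl <- flow_state(32, 32, 0.01)
  mk <- list(markers = cbind(rep(0.005, 10), seq(0.004, 0.006, length.out = 10)),
             normals = cbind(rep(1, 10), 0), ds = rep(1e-4, 10),
             cm = c(0.005, 0.005), us = matrix(0, 10, 2))
  expect_equal(instantaneous_power(fl, mk, fluid_params()), 0)
})
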