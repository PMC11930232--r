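# Penalized incompressible Navier-Stokes on a staggered (MAC) Cartesian
# grid, two-way coupled to the rigid-body equations of a deforming
# swimmer. Velocities in m/s, lengths in m, pressure in Pa. Fields are
# indexed [i, j] with i along +x and j along +y:
#   u: (nx+1) x ny  at x-faces;  v: nx x (ny+1) at y-faces;  p: nx x ny.

#' Fluid parameters
#'
#' @param rho fluid density (kg/m^3); the solid density is approximated by
#'   the same value (neutrally buoyant larva).
#' @param mu dynamic viscosity (Pa s); water at 28 C is 0.83e-3.
#' @return object of class `fluid_params`.
#' @export
fluid_params <- function(rho = 1000, mu = 0.83e-3) {
  check_scalar(rho, "rho", positive = TRUE)
  check_scalar(mu, "mu", positive = TRUE)
  structure(list(rho = rho, mu = mu, nu = mu / rho), class = "fluid_params")
}

#' Create a flow state on a uniform MAC grid
#'
#' @param nx,ny cells per direction.
#' @param lx,ly domain extents (m).
#' @param bc `"noslip"` (homogeneous no-slip on all outer boundaries) or
#'   `"periodic"`.
#' @return object of class `flow_state` (velocity faces `u`, `v`, cell
#'   pressure `p`, spacing `h`, time `t`).
#' @export
flow_state <- function(nx, ny, lx, ly = lx, bc = c("noslip", "periodic")) {
  bc <- match.arg(bc)
  h <- lx / nx
  if (abs(ly / ny - h) > 1e-12 * h) stop("grid must be square (dx = dy)", call. = FALSE)
  structure(list(
    u = matrix(0, nx + 1, ny), v = matrix(0, nx, ny + 1),
    p = matrix(0, nx, ny),
    nx = nx, ny = ny, h = h, lx = lx, ly = ly, bc = bc, t = 0,
    poisson = make_poisson_solver(nx, ny, h, bc)
  ), class = "flow_state")
}

# --- staggered-grid helpers -------------------------------------------------

# pad u with two ghost layers per side. For no-slip walls tangential
# ghosts mirror negatively; normal ghosts are antisymmetric about the
# boundary face (where u = 0). Periodic wraps (u[1,] and u[nx+1,] are the
# same physical face).
pad_u <- function(u, bc) {
  nxp <- nrow(u); ny <- ncol(u) # nxp = nx + 1
  if (bc == "periodic") {
    rows <- rbind(u[nxp - 2, ], u[nxp - 1, ], u, u[2, ], u[3, ])
    cbind(rows[, ny - 1], rows[, ny], rows, rows[, 1], rows[, 2])
  } else {
    rows <- rbind(-u[3, ], -u[2, ], u, -u[nxp - 1, ], -u[nxp - 2, ])
    cbind(-rows[, 2], -rows[, 1], rows, -rows[, ny], -rows[, ny - 1])
  }
}

pad_v <- function(v, bc) {
  nx <- nrow(v); nyp <- ncol(v) # nyp = ny + 1
  if (bc == "periodic") {
    rows <- rbind(v[nx - 1, ], v[nx, ], v, v[1, ], v[2, ])
    cbind(rows[, nyp - 2], rows[, nyp - 1], rows, rows[, 2], rows[, 3])
  } else {
    rows <- rbind(-v[2, ], -v[1, ], v, -v[nx, ], -v[nx - 1, ])
    cbind(-rows[, 3], -rows[, 2], rows, -rows[, nyp - 1], -rows[, nyp - 2])
  }
}

mac_divergence <- function(flow) {
  u <- flow$u; v <- flow$v; h <- flow$h
  nx <- flow$nx; ny <- flow$ny
  (u[2:(nx + 1), , drop = FALSE] - u[1:nx, , drop = FALSE]) / h +
    (v[, 2:(ny + 1), drop = FALSE] - v[, 1:ny, drop = FALSE]) / h
}

# cell-centered velocity components
cc_velocity <- function(flow) {
  nx <- flow$nx; ny <- flow$ny
  list(u = 0.5 * (flow$u[1:nx, , drop = FALSE] + flow$u[2:(nx + 1), , drop = FALSE]),
       v = 0.5 * (flow$v[, 1:ny, drop = FALSE] + flow$v[, 2:(ny + 1), drop = FALSE]))
}

# bilinear interpolation on a field indexed [i, j] at fractional 1-based
# indices (xi along dim 1, yi along dim 2)
interp_ij <- function(F, xi, yi) {
  n1 <- nrow(F); n2 <- ncol(F)
  xi <- pmin(pmax(xi, 1), n1 - 1e-9)
  yi <- pmin(pmax(yi, 1), n2 - 1e-9)
  i0 <- pmin(floor(xi), n1 - 1); j0 <- pmin(floor(yi), n2 - 1)
  fx <- xi - i0; fy <- yi - j0
  idx <- (j0 - 1) * n1 + i0
  (1 - fx) * (1 - fy) * F[idx] + fx * (1 - fy) * F[idx + 1] +
    (1 - fx) * fy * F[idx + n1] + fx * fy * F[idx + n1 + 1]
}

# --- time stepping ----------------------------------------------------------

#' Advance the penalized Navier-Stokes equations one time step
#'
#' Incremental pressure projection: explicit central advection and
#' diffusion, implicit volume penalization driving the velocity toward the
#' solid's velocity inside its characteristic function, then an exact
#' discrete projection (DCT/FFT Poisson solve). Errors out when `dt`
#' violates the advective CFL or the explicit diffusive stability limit,
#' proposing the largest admissible step.
#'
#' @param flow a [flow_state()].
#' @param solid optional solid fields: list with `chi_u`, `chi_v`
#'   (mollified characteristic function at faces), `us_u`, `us_v` (solid
#'   velocity at faces) and `lambda` (penalty, 1/s).
#' @param params [fluid_params()].
#' @param dt time step (s).
#' @param torque_center optional c(x, y) (m) about which the penalty
#'   torque is accumulated.
#' @param advection `"upwind2"` (second-order upwind biased, default) or
#'   `"central"`.
#' @param pen_iters penalization/projection cycles per step when a solid
#'   is present (default 2).
#' @return the advanced `flow_state`; attributes `penalty_force` (N/m,
#'   force exerted on the fluid by penalization, per unit depth) and
#'   `penalty_torque` about `torque_center`.
#' @export
ns_step <- function(flow, solid = NULL, params, dt, torque_center = NULL,
                    advection = c("upwind2", "central"), pen_iters = 2) {
  advection <- match.arg(advection)
  nx <- flow$nx; ny <- flow$ny; h <- flow$h; bc <- flow$bc
  nu <- params$nu; rho <- params$rho
  umax <- max(abs(flow$u), abs(flow$v), 1e-12)
  dt_adv <- h / umax
  dt_dif <- 0.25 * h^2 / nu
  if (dt > min(dt_adv, dt_dif))
    stop(sprintf("dt = %.3g violates stability; use dt <= %.3g (advective %.3g, diffusive %.3g)",
                 dt, min(dt_adv, dt_dif), dt_adv, dt_dif), call. = FALSE)

  up <- pad_u(flow$u, bc)   # (nx+5) x (ny+4); u[i,j] = up[i+2, j+2]
  vp <- pad_v(flow$v, bc)   # (nx+4) x (ny+5); v[i,j] = vp[i+2, j+2]

  iu <- 3:(nx + 3); ju <- 3:(ny + 2)    # all u faces in padded indexing
  iv <- 3:(nx + 2); jv <- 3:(ny + 3)

  # derivative of a padded field: central or second-order upwind biased by
  # the advecting velocity a
  deriv <- function(P, ii, jj, along, a) {
    e1 <- if (along == 1) function(s) P[ii + s, jj] else function(s) P[ii, jj + s]
    if (advection == "central") {
      (e1(1) - e1(-1)) / (2 * h)
    } else {
      dpos <- (3 * e1(0) - 4 * e1(-1) + e1(-2)) / (2 * h)
      dneg <- (-3 * e1(0) + 4 * e1(1) - e1(2)) / (2 * h)
      ifelse(a >= 0, dpos, dneg)
    }
  }

  # u faces: advection + diffusion
  u0 <- up[iu, ju]
  lap_u <- (up[iu + 1, ju] + up[iu - 1, ju] + up[iu, ju + 1] + up[iu, ju - 1] -
              4 * u0) / h^2
  # v averaged to u-faces: neighbouring cells (i-1, i), y-faces (j, j+1)
  v_at_u <- 0.25 * (vp[2:(nx + 2), 3:(ny + 2)] + vp[2:(nx + 2), 4:(ny + 3)] +
                      vp[3:(nx + 3), 3:(ny + 2)] + vp[3:(nx + 3), 4:(ny + 3)])
  adv_u <- u0 * deriv(up, iu, ju, 1, u0) + v_at_u * deriv(up, iu, ju, 2, v_at_u)

  # v faces
  v0 <- vp[iv, jv]
  lap_v <- (vp[iv + 1, jv] + vp[iv - 1, jv] + vp[iv, jv + 1] + vp[iv, jv - 1] -
              4 * v0) / h^2
  u_at_v <- 0.25 * (up[3:(nx + 2), 2:(ny + 2)] + up[4:(nx + 3), 2:(ny + 2)] +
                      up[3:(nx + 2), 3:(ny + 3)] + up[4:(nx + 3), 3:(ny + 3)])
  adv_v <- u_at_v * deriv(vp, iv, jv, 1, u_at_v) + v0 * deriv(vp, iv, jv, 2, v0)

  # incremental projection: keep the current pressure gradient
  gpx <- matrix(0, nx + 1, ny); gpy <- matrix(0, nx, ny + 1)
  p <- flow$p
  if (bc == "periodic") {
    gpx[1:nx, ] <- (p - p[c(nx, 1:(nx - 1)), , drop = FALSE]) / h
    gpx[nx + 1, ] <- gpx[1, ]
    gpy[, 1:ny] <- (p - p[, c(ny, 1:(ny - 1)), drop = FALSE]) / h
    gpy[, ny + 1] <- gpy[, 1]
  } else {
    gpx[2:nx, ] <- (p[2:nx, , drop = FALSE] - p[1:(nx - 1), , drop = FALSE]) / h
    gpy[, 2:ny] <- (p[, 2:ny, drop = FALSE] - p[, 1:(ny - 1), drop = FALSE]) / h
  }

  u_star <- flow$u + dt * (-adv_u + nu * lap_u - gpx / rho)
  v_star <- flow$v + dt * (-adv_v + nu * lap_v - gpy / rho)

  enforce_bc <- function() {
    if (bc == "noslip") {
      u_star[1, ] <<- 0; u_star[nx + 1, ] <<- 0
      v_star[, 1] <<- 0; v_star[, ny + 1] <<- 0
    } else {
      u_star[nx + 1, ] <<- u_star[1, ]
      v_star[, ny + 1] <<- v_star[, 1]
    }
  }
  project <- function() {
    div <- (u_star[2:(nx + 1), , drop = FALSE] - u_star[1:nx, , drop = FALSE]) / h +
      (v_star[, 2:(ny + 1), drop = FALSE] - v_star[, 1:ny, drop = FALSE]) / h
    rhs <- rho / dt * div
    rhs <- rhs - mean(rhs)
    phi <- flow$poisson(rhs)
    if (bc == "periodic") {
      gfx <- (phi - phi[c(nx, 1:(nx - 1)), , drop = FALSE]) / h
      u_star[1:nx, ] <<- u_star[1:nx, , drop = FALSE] - dt / rho * gfx
      u_star[nx + 1, ] <<- u_star[1, ]
      gfy <- (phi - phi[, c(ny, 1:(ny - 1)), drop = FALSE]) / h
      v_star[, 1:ny] <<- v_star[, 1:ny, drop = FALSE] - dt / rho * gfy
      v_star[, ny + 1] <<- v_star[, 1]
    } else {
      u_star[2:nx, ] <<- u_star[2:nx, , drop = FALSE] -
        dt / rho * (phi[2:nx, , drop = FALSE] - phi[1:(nx - 1), , drop = FALSE]) / h
      v_star[, 2:ny] <<- v_star[, 2:ny, drop = FALSE] -
        dt / rho * (phi[, 2:ny, drop = FALSE] - phi[, 1:(ny - 1), drop = FALSE]) / h
    }
    phi
  }

  pen_fx <- 0; pen_fy <- 0; pen_tq <- 0
  phi_tot <- 0
  if (is.null(solid)) {
    enforce_bc()
    phi_tot <- project()
  } else {
    lam <- solid$lambda
    fac_u <- lam * dt * solid$chi_u
    fac_v <- lam * dt * solid$chi_v
    xs_u <- (seq_len(nx + 1) - 1) * h
    ys_u <- (seq_len(ny) - 0.5) * h
    xs_v <- (seq_len(nx) - 0.5) * h
    ys_v <- (seq_len(ny + 1) - 1) * h
    # two penalization/projection cycles: the second suppresses the
    # projection kick inside the body so the interior velocity error keeps
    # decreasing with lambda
    for (cycle in 1:pen_iters) {
      u_new_pen <- (u_star + fac_u * solid$us_u) / (1 + fac_u)
      v_new_pen <- (v_star + fac_v * solid$us_v) / (1 + fac_v)
      du <- u_new_pen - u_star; dv <- v_new_pen - v_star
      pen_fx <- pen_fx + rho * h^2 * sum(du) / dt
      pen_fy <- pen_fy + rho * h^2 * sum(dv) / dt
      if (!is.null(torque_center)) {
        ru_y <- matrix(ys_u, nx + 1, ny, byrow = TRUE) - torque_center[2]
        rv_x <- matrix(xs_v, nx, ny + 1) - torque_center[1]
        pen_tq <- pen_tq + rho * h^2 * (sum(rv_x * dv) - sum(ru_y * du)) / dt
      }
      u_star <- u_new_pen; v_star <- v_new_pen
      enforce_bc()
      phi_tot <- phi_tot + project()
    }
  }

  if (any(!is.finite(u_star)) || any(!is.finite(v_star)))
    stop("solver diverged: non-finite velocity field", call. = FALSE)

  flow$u <- u_star; flow$v <- v_star
  flow$p <- flow$p + phi_tot
  flow$t <- flow$t + dt
  attr(flow, "penalty_force") <- c(pen_fx, pen_fy)
  attr(flow, "penalty_torque") <- pen_tq
  flow
}

# --- loads and rigid dynamics ----------------------------------------------

#' Hydrodynamic force and torque from the stress-tensor surface integral
#'
#' Integrates the traction `T n` of the fluid stress tensor
#' `T = -p I + mu (grad u + grad u^T)` over the body's Lagrangian surface
#' markers. The stress is evaluated a small offset outside the penalized
#' region (default 1.5 grid cells along the outward normal). Returns the
#' force exerted by the fluid on the body, per unit depth.
#'
#' @param flow a [flow_state()].
#' @param solid list with `markers` (M x 2, m), `normals` (M x 2, outward
#'   unit), `ds` (M, element lengths, m) and `cm` (c(x, y), m).
#' @param params [fluid_params()].
#' @param offset stress evaluation offset in grid cells.
#' @return list with `F` (c(Fx, Fy), N/m) and `M` (N m/m, about `cm`),
#'   plus the per-marker tractions as attribute `traction`.
#' @export
hydrodynamic_loads <- function(flow, solid, params, offset = 1.5) {
  h <- flow$h; nx <- flow$nx; ny <- flow$ny
  mk <- solid$markers; nrm <- solid$normals; ds <- solid$ds
  if (any(mk[, 1] < 0 | mk[, 1] > flow$lx | mk[, 2] < 0 | mk[, 2] > flow$ly))
    stop("markers outside the grid", call. = FALSE)
  pe <- mk + offset * h * nrm
  cc <- cc_velocity(flow)
  # cell-centered gradients (central differences, clamped at borders)
  ddx <- function(F) (F[c(2:nx, nx), ] - F[c(1, 1:(nx - 1)), ]) / (2 * h)
  ddy <- function(F) (F[, c(2:ny, ny)] - F[, c(1, 1:(ny - 1))]) / (2 * h)
  dudx <- ddx(cc$u); dudy <- ddy(cc$u)
  dvdx <- ddx(cc$v); dvdy <- ddy(cc$v)
  xi <- pe[, 1] / h + 0.5; yi <- pe[, 2] / h + 0.5
  pm <- interp_ij(flow$p, xi, yi)
  g11 <- interp_ij(dudx, xi, yi); g12 <- interp_ij(dudy, xi, yi)
  g21 <- interp_ij(dvdx, xi, yi); g22 <- interp_ij(dvdy, xi, yi)
  mu <- params$mu
  t11 <- -pm + 2 * mu * g11
  t22 <- -pm + 2 * mu * g22
  t12 <- mu * (g12 + g21)
  tx <- t11 * nrm[, 1] + t12 * nrm[, 2]
  ty <- t12 * nrm[, 1] + t22 * nrm[, 2]
  Fx <- sum(tx * ds); Fy <- sum(ty * ds)
  rx <- mk[, 1] - solid$cm[1]; ry <- mk[, 2] - solid$cm[2]
  M <- sum((rx * ty - ry * tx) * ds)
  out <- list(F = c(Fx, Fy), M = M)
  attr(out, "traction") <- cbind(tx, ty)
  out
}

#' Advance the rigid-body translation and rotation equations
#'
#' Explicit update of the equations of motion: `rho_s Vs du/dt = F` and
#' `d(J w)/dt = M`, with the angular velocity recovered using the current
#' (possibly shape-dependent) inertia.
#'
#' @param solid list with `ubar` (c(ux, uy), m/s), `omega` (rad/s),
#'   `theta` (rad), `cm` (m), `Vs` (volume or area per depth), `J`
#'   (moment of inertia about cm), `rho_s` (kg/m^3).
#' @param loads list with `F` and `M` (as [hydrodynamic_loads()]).
#' @param params [fluid_params()] (supplies the solid density default).
#' @param dt time step (s).
#' @param J_new inertia of the new shape (default: unchanged).
#' @return the advanced solid state.
#' @export
advance_rigid <- function(solid, loads, params, dt, J_new = NULL) {
  rho_s <- solid$rho_s %||% params$rho
  m <- rho_s * solid$Vs
  if (!is.finite(solid$J) || solid$J <= 0) stop("singular inertia", call. = FALSE)
  solid$ubar <- solid$ubar + loads$F * dt / m
  Jw <- solid$J * solid$omega + loads$M * dt
  solid$J <- J_new %||% solid$J
  solid$omega <- Jw / solid$J
  solid$theta <- solid$theta + solid$omega * dt
  solid$cm <- solid$cm + solid$ubar * dt
  solid
}
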