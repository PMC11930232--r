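# Mechanical power, work, cost of transport, Reynolds number, and wake
# fields derived from simulation traces.

#' Instantaneous mechanical power from traction and surface velocity
#'
#' Surface integral of the fluid traction against the body-surface
#' velocity, `P = -sum((T n) . us) dS`, positive when the body does work
#' on the fluid. In 2D the result is per unit depth (W/m).
#'
#' @param flow a [flow_state()].
#' @param solid marker list as in [hydrodynamic_loads()], plus `us`
#'   (M x 2 surface velocity at markers).
#' @param params [fluid_params()].
#' @return power (W per unit depth).
#' @export
instantaneous_power <- function(flow, solid, params) {
  loads <- hydrodynamic_loads(flow, solid, params)
  tr <- attr(loads, "traction")
  -sum((tr[, 1] * solid$us[, 1] + tr[, 2] * solid$us[, 2]) * solid$ds)
}

#' Total mechanical work from a power series
#'
#' Integrates instantaneous power over `[ti, tf]` by a Riemann sum
#' (optionally trapezoidal).
#'
#' @param P power samples (W).
#' @param dt sample interval (s).
#' @param ti,tf integration window (s), defaults to the whole series.
#' @param method `"riemann"` (default) or `"trapezoid"`.
#' @return energy (J).
#' @export
total_energy <- function(P, dt, ti = 0, tf = (length(P) - 1) * dt,
                         method = c("riemann", "trapezoid")) {
  method <- match.arg(method)
  t <- (seq_along(P) - 1) * dt
  sel <- t >= ti - 1e-12 & t <= tf + 1e-12
  if (!any(sel)) stop("empty integration window", call. = FALSE)
  x <- P[sel]
  if (method == "riemann") sum(x) * dt else pracma::trapz(t[sel], x)
}

#' Cost of transport
#'
#' Total mechanical energy divided by the cumulative distance traveled.
#'
#' @param E energy (J).
#' @param d_total cumulative center-of-mass path length (m).
#' @return CoT (J/m).
#' @export
cost_of_transport <- function(E, d_total) {
  if (d_total <= 0) stop("undefined CoT: d_total must be > 0", call. = FALSE)
  E / d_total
}

#' Froude efficiency
#'
#' Useful work over total work for a propulsive motion.
#'
#' @param W_useful useful (thrust) work (J).
#' @param W_total total work (J); must be positive.
#' @return dimensionless efficiency.
#' @export
froude_efficiency <- function(W_useful, W_total) {
  if (W_total <= 0) stop("W_total must be > 0", call. = FALSE)
  W_useful / W_total
}

#' Reynolds number of a swim
#'
#' `Re = rho * V_mean * L / mu` with `V_mean` the mean speed over the six
#' simulated tail beats and `L` the body length.
#'
#' @param params [fluid_params()].
#' @param V_mean mean speed (m/s).
#' @param L body length (m).
#' @return dimensionless Reynolds number.
#' @export
reynolds <- function(params, V_mean, L) {
  if (params$mu <= 0) stop("mu must be > 0", call. = FALSE)
  params$rho * V_mean * L / params$mu
}

# cell-centered velocity gradients of a flow state
velocity_gradients <- function(flow) {
  cc <- cc_velocity(flow)
  nx <- flow$nx; ny <- flow$ny; h <- flow$h
  ddx <- function(F) (F[c(2:nx, nx), ] - F[c(1, 1:(nx - 1)), ]) / (2 * h)
  ddy <- function(F) (F[, c(2:ny, ny)] - F[, c(1, 1:(ny - 1))]) / (2 * h)
  list(dudx = ddx(cc$u), dudy = ddy(cc$u),
       dvdx = ddx(cc$v), dvdy = ddy(cc$v))
}

#' Vorticity field
#'
#' Out-of-plane vorticity `dv/dx - du/dy` on cell centers (centered
#' differences).
#'
#' @param flow a [flow_state()].
#' @return matrix (1/s).
#' @export
vorticity <- function(flow) {
  g <- velocity_gradients(flow)
  g$dvdx - g$dudy
}

#' Q-criterion field
#'
#' `Q = (||Omega||^2 - ||Phi||^2) / 2` with `Omega` and `Phi` the
#' antisymmetric and symmetric parts of the velocity gradient (Frobenius
#' norms); positive where rotation dominates strain.
#'
#' @param flow a [flow_state()].
#' @return matrix (1/s^2), per unit depth in 2D.
#' @export
q_criterion <- function(flow) {
  g <- velocity_gradients(flow)
  om <- 0.5 * (g$dvdx - g$dudy)          # antisymmetric part entry
  s12 <- 0.5 * (g$dudy + g$dvdx)
  norm_Om2 <- 2 * om^2
  norm_Ph2 <- g$dudx^2 + g$dvdy^2 + 2 * s12^2
  0.5 * (norm_Om2 - norm_Ph2)
}

# integral of squared vorticity over the domain (wake strength)
enstrophy <- function(flow) {
  sum(vorticity(flow)^2) * flow$h^2
}

#' Smooth a sampled kinematic or energetic trace
#'
#' Savitzky-Golay filtering followed by spline re-interpolation on the
#' original time base; for power traces an additional moving average over
#' one millisecond is applied.
#'
#' @param series numeric samples.
#' @param dt sample interval (s).
#' @param kind `"default"` or `"power"` (adds the 1 ms moving average).
#' @param window,order Savitzky-Golay window (samples) and order.
#' @return smoothed series, same length.
#' @export
smooth_trace <- function(series, dt, kind = c("default", "power"),
                         window = 11, order = 3) {
  kind <- match.arg(kind)
  if (window > length(series))
    stop("window longer than series", call. = FALSE)
  sg <- sg_smooth(series, window, order)
  t <- (seq_along(series) - 1) * dt
  sp <- spline(t, sg, xout = t)$y
  if (kind == "power") sp <- moving_average(sp, round(0.001 / dt))
  sp
}

#' Energetic and kinematic summary of an escape simulation
#'
#' Computes the six-movement energetic descriptors from an `escape_sim`:
#' total work E, mean power, cumulative distance, mean velocity, cost of
#' transport and Reynolds number. 2D per-depth quantities are converted
#' to watts/joules with an effective body depth.
#'
#' @param sim an [simulate_escape()] result.
#' @param depth_mm effective body depth (mm); default 0.6, about the
#'   maximum body height of a 5 dpf eleutheroembryo.
#' @param window optional c(ti, tf) in seconds; default: the six-movement
#'   window from the motion's curvature trace (sixth maximum plus half a
#'   beat period).
#' @return one-row tibble.
#' @export
energetics_summary <- function(sim, depth_mm = 0.6, window = NULL) {
  stopifnot(inherits(sim, "escape_sim"))
  tr <- sim$trace
  dt <- tr$t[2] - tr$t[1]
  if (is.null(window)) {
    hta <- sim$motion$head_tail_angle
    pk <- curvature_peaks(hta, sim$motion$dt)
    if (length(pk) >= 6) {
      beat <- mean(diff(sim$motion$times[pk[3:6]]))
      tf <- min(sim$motion$times[pk[6]] + beat / 2, max(tr$t))
    } else tf <- max(tr$t)
    window <- c(0, tf)
  }
  sel <- tr$t >= window[1] & tr$t <= window[2]
  depth <- depth_mm * 1e-3
  P <- tr$P[sel] * depth
  Ps <- smooth_trace(P, dt, "power")
  E <- sum(Ps) * dt
  d <- sum(sqrt(diff(tr$cm_x[sel])^2 + diff(tr$cm_y[sel])^2))
  Tw <- diff(range(tr$t[sel]))
  L <- sim$motion$standard_length * 1e-3
  Vmean <- d / Tw
  tibble::tibble(
    E_J = E,
    mean_power_W = E / Tw,
    d_total_m = d,
    mean_velocity_m_s = Vmean,
    CoT_J_m = cost_of_transport(E, d),
    Re = reynolds(sim$params, Vmean, L),
    duration_s = Tw,
    mu_Pa_s = sim$params$mu
  )
}
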