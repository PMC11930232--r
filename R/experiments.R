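# In-silico experiment orchestration: viscosity sweeps, frequency
# rescaling, and the linear regressions summarizing them.

#' Ordinary least-squares regression with Pearson correlation
#'
#' @param x,y numeric vectors, `length >= 3`, `x` not constant.
#' @return one-row tibble (class `zf_regression`): slope, intercept,
#'   `r_squared`, `pearson_r`, `p_value` (two-sided t test), `n`.
#' @export
regress_linear <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("`x` is constant", call. = FALSE)
  fit <- lm(y ~ x)
  ct <- suppressWarnings(cor.test(x, y))
  out <- tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    pearson_r = unname(ct$estimate),
    p_value = ct$p.value,
    n = length(x)
  )
  class(out) <- c("zf_regression", class(out))
  out
}

#' @export
tidy.zf_regression <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "x"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.zf_regression <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, pearson_r = x$pearson_r,
                 p.value = x$p_value, nobs = x$n)
}

# run one simulation + summary at a given viscosity
run_one <- function(motion, mu_mPas, cfg) {
  params <- fluid_params(rho = cfg$rho %||% 1000, mu = mu_mPas * 1e-3)
  sim <- simulate_escape(motion, params,
                         grid = cfg$grid %||% list(nx = 128, lx = 0.012),
                         lambda = cfg$lambda %||% 1e8,
                         save_every = cfg$save_every %||% 0)
  es <- energetics_summary(sim, depth_mm = cfg$depth_mm %||% 0.6)
  hta <- sim$motion$head_tail_angle
  pk <- curvature_peaks(hta, sim$motion$dt)
  kin <- tibble::tibble(
    max_head_tail_angle_deg = max(abs(hta)),
    fast_swim_beat_amplitude_deg = if (length(pk) >= 6)
      mean(abs(hta[pk[3:6]])) else NA_real_
  )
  list(summary = dplyr::bind_cols(tibble::tibble(mu_mPas = mu_mPas), es, kin),
       sim = sim)
}

sweep_regressions <- function(tbl) {
  if (nrow(tbl) < 3) return(tibble::tibble())
  vars <- c(mean_power_W = "mean_power_W", E_J = "E_J", CoT_J_m = "CoT_J_m")
  dplyr::bind_rows(lapply(names(vars), function(v) {
    r <- regress_linear(tbl$mu_mPas, tbl[[vars[[v]]]])
    dplyr::bind_cols(tibble::tibble(response = v), r)
  }))
}

#' Virtual-viscosity sweep with fixed kinematics
#'
#' Simulates one body-movement sequence (typically recorded/generated in
#' water) at each requested viscosity and regresses mean power, total
#' energy and cost of transport on viscosity.
#'
#' @param motion a `body_motion_2d`.
#' @param viscosities viscosities in mPa s (the study set is
#'   0.83, 1.1, 2.3, 5, 10, 15).
#' @param cfg list: `grid`, `lambda`, `rho`, `depth_mm`, `keep_sims`.
#' @return object of class `sweep_result`: `table` (one row per run) and
#'   `regressions`.
#' @export
run_virtual_sweep <- function(motion,
                              viscosities = c(0.83, 1.1, 2.3, 5, 10, 15),
                              cfg = list()) {
  if (length(viscosities) < 3)
    warning("fewer than 3 viscosities: regression skipped")
  runs <- lapply(viscosities, function(mu) run_one(motion, mu, cfg))
  tbl <- dplyr::bind_rows(lapply(runs, `[[`, "summary"))
  structure(list(
    table = tbl,
    regressions = sweep_regressions(tbl),
    kind = "virtual",
    sims = if (isTRUE(cfg$keep_sims)) lapply(runs, `[[`, "sim") else NULL
  ), class = "sweep_result")
}

#' Realistic viscosity sweep with viscosity-matched kinematics
#'
#' Each body-movement sequence is simulated at the viscosity it was
#' recorded (or generated) in, emulating the experimental sweep in which
#' the animal adapts its kinematics to the medium.
#'
#' @param motions named list of `body_motion_2d`, names = viscosity in
#'   mPa s (or a list with a `mu_mPas` attribute per element).
#' @param cfg as in [run_virtual_sweep()].
#' @return a `sweep_result`.
#' @export
run_realistic_sweep <- function(motions, cfg = list()) {
  mus <- suppressWarnings(as.numeric(names(motions)))
  if (length(mus) != length(motions) || !length(motions) || any(is.na(mus)))
    stop("each motion must be labeled with its viscosity (mPa s)", call. = FALSE)
  runs <- Map(function(m, mu) run_one(m, mu, cfg), motions, mus)
  tbl <- dplyr::bind_rows(lapply(runs, `[[`, "summary"))
  structure(list(
    table = tbl,
    regressions = if (nrow(tbl) >= 3) sweep_regressions(tbl) else tibble::tibble(),
    kind = "realistic",
    sims = if (isTRUE(cfg$keep_sims)) lapply(runs, `[[`, "sim") else NULL
  ), class = "sweep_result")
}

#' @export
tidy.sweep_result <- function(x, ...) x$table

#' @export
glance.sweep_result <- function(x, ...) {
  if (!nrow(x$regressions)) return(tibble::tibble(kind = x$kind, nobs = nrow(x$table)))
  wide <- stats::setNames(x$regressions$r_squared, x$regressions$response)
  tibble::tibble(kind = x$kind, nobs = nrow(x$table),
                 r2_mean_power = wide[["mean_power_W"]],
                 r2_E = wide[["E_J"]],
                 r2_CoT = wide[["CoT_J_m"]])
}

#' Rescale the tail-beat frequency of a body motion
#'
#' Dilates the time axis by `1/factor` and resamples to the original
#' frame interval: per-frame body shapes (hence curvature amplitudes) are
#' unchanged while every rate, including the deformation velocity, scales
#' by `factor`.
#'
#' @param motion a `body_motion_2d`.
#' @param factor frequency multiplier in `(0, 1]` (0.7 applies a 30%
#'   decrease).
#' @return a `body_motion_2d`.
#' @export
rescale_frequency <- function(motion, factor) {
  stopifnot(inherits(motion, "body_motion_2d"))
  if (factor <= 0) stop("`factor` must be > 0", call. = FALSE)
  if (factor == 1) return(motion)
  t_old <- motion$times
  T_new <- max(t_old) / factor
  t_new <- seq(0, T_new, by = motion$dt)
  np <- nrow(motion$midlines[[1]])
  old <- array(unlist(motion$midlines), c(np, 2, length(t_old)))
  mls <- lapply(t_new, function(tn) {
    to <- tn * factor
    k <- min(max(findInterval(to, t_old), 1), length(t_old) - 1)
    f <- (to - t_old[k]) / (t_old[k + 1] - t_old[k])
    (1 - f) * old[, , k] + f * old[, , k + 1]
  })
  hta <- approx(t_old / factor, motion$head_tail_angle, xout = t_new,
                rule = 2)$y
  motion_2d(mls, dt = motion$dt, half_width = motion$half_width,
            head_tail_angle = hta,
            standard_length = motion$standard_length)
}
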