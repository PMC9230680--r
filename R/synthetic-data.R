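# Synthetic rod-force / osteotomy-tension time series.
#
# Emulates the bench measurement of a 10-period distraction: per-period
# correction ramps (rise, slight overshoot, settle) followed by flat stay
# stages; passive support forces below the adjustable forces with the
# opposite intra-correction trend; a transmitted-tension deficit in the
# first periods while the frame pre-tightens. Period-end adjustable-force
# anchors default to the measured bench table, so a zero-noise series
# reproduces it exactly at the period ends.

#' Generator configuration for synthetic force series
#'
#' @param schedule a [correction_schedule()].
#' @param geometry a [fixator_geometry()] (initial varus angle drives the
#'   hinge-angle trajectory).
#' @param anchors_F1,anchors_F2 period-end adjustable-rod forces, N; length
#'   `n_periods`. Defaults are the packaged bench table ([load_table3()]).
#' @param kappa support fraction: `F3 = kappa * F1`, `F4 = kappa * F2`.
#' @param eta_target steady-state transfer efficiency built into the
#'   generated tension.
#' @param pretension_deficit tension lost to frame pre-tightening in the
#'   first periods, N; decays linearly to zero over `n_deficit` periods.
#' @param n_deficit number of early periods affected by the deficit.
#' @param noise_sd additive Gaussian measurement noise on every force
#'   channel, N (>= 0).
#' @param sample_rate sampling rate, Hz.
#' @param seed integer seed; identical seeds give identical series.
#' @return an object of class `"generator_config"`.
#' @export
generator_config <- function(schedule = correction_schedule(),
                             geometry = fixator_geometry(),
                             anchors_F1 = NULL, anchors_F2 = NULL,
                             kappa = 0.4, eta_target = 0.5,
                             pretension_deficit = 5, n_deficit = 2,
                             noise_sd = 1, sample_rate = 10, seed = 1) {
  stopifnot(inherits(schedule, "correction_schedule"),
            inherits(geometry, "fixator_geometry"))
  if (is.null(anchors_F1) || is.null(anchors_F2)) {
    t3 <- load_table3()
    if (is.null(anchors_F1)) anchors_F1 <- t3$F1
    if (is.null(anchors_F2)) anchors_F2 <- t3$F2
  }
  n <- schedule$n_periods
  if (length(anchors_F1) != n || length(anchors_F2) != n)
    stop("anchor vectors must have length n_periods = ", n)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (sample_rate <= 0) stop("'sample_rate' must be > 0")
  if (kappa < 0) stop("'kappa' must be >= 0")
  if (eta_target <= 0 || eta_target > 1)
    stop("'eta_target' must be in (0, 1]")
  structure(list(schedule = schedule, geometry = geometry,
                 anchors_F1 = as.numeric(anchors_F1),
                 anchors_F2 = as.numeric(anchors_F2),
                 kappa = kappa, eta_target = eta_target,
                 pretension_deficit = pretension_deficit,
                 n_deficit = as.integer(n_deficit),
                 noise_sd = noise_sd, sample_rate = sample_rate,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# piecewise-linear correction ramp: previous anchor -> 10% overshoot at
# mid-stage -> anchor; `frac` is position within the correction stage in [0,1]
ramp_overshoot <- function(frac, from, to, overshoot = 0.1) {
  peak <- to + overshoot * (to - from)
  ifelse(frac <= 0.5,
         from + (peak - from) * frac / 0.5,
         peak + (to - peak) * (frac - 0.5) / 0.5)
}

# support-rod intra-correction trend is opposite: dip below the starting
# level at mid-stage, then rise to the new anchor
ramp_dip <- function(frac, from, to, dip = 0.1) {
  low <- from - dip * (to - from)
  ifelse(frac <= 0.5,
         from + (low - from) * frac / 0.5,
         low + (to - low) * (frac - 0.5) / 0.5)
}

#' Generate a synthetic force series
#'
#' Produces the full multichannel time series for one bench run under the
#' configured schedule: adjustable forces `F1`, `F2` (correction-ramp /
#' stay-plateau shape through the period-end anchors), support forces
#' `F3 = kappa * F1`, `F4 = kappa * F2` with the opposite intra-correction
#' trend, hinge angle decreasing linearly across correction stages, and the
#' measured axial tension
#' `Fz2m = eta_target * (F1+F2+F3+F4) * cos(theta) - deficit(period)`
#' (floored at zero), plus small zero-mean transverse tensions `Fx2m`,
#' `Fy2m`. Gaussian noise of sd `noise_sd` is added to every force channel.
#' The generator leaves the caller's RNG state untouched.
#'
#' @param config a [generator_config()].
#' @return an object of class `"force_series"`: a data frame with columns
#'   `time_s`, `F1`..`F4`, `Fx2m`, `Fy2m`, `Fz2m`, `period`, `stage`, with
#'   the configuration in `attr(, "config")`.
#' @examples
#' s <- generate_force_series(generator_config(noise_sd = 0))
#' head(s)
#' @export
generate_force_series <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  sch <- config$schedule
  n <- sch$n_periods
  P <- sch$correction_duration + sch$stay_duration
  # integer sample indices keep period/stage assignment exact
  spp <- round(P * config$sample_rate)           # samples per period
  spc <- round(sch$correction_duration * config$sample_rate)
  if (spp < 2 || spc < 1 || spc >= spp)
    stop("sample_rate too low to resolve the correction/stay stages")
  idx <- seq_len(n * spp)
  t <- idx / config$sample_rate
  period <- (idx - 1) %/% spp + 1L
  within <- (idx - 1) %% spp + 1L
  in_corr <- within <= spc
  stage <- ifelse(in_corr, "correction", "stay")
  frac <- pmin(within / spc, 1)

  a1 <- c(0, config$anchors_F1)  # anchor before period 1 is the unloaded frame
  a2 <- c(0, config$anchors_F2)
  from1 <- a1[period]; to1 <- a1[period + 1]
  from2 <- a2[period]; to2 <- a2[period + 1]
  F1 <- ifelse(in_corr, ramp_overshoot(frac, from1, to1), to1)
  F2 <- ifelse(in_corr, ramp_overshoot(frac, from2, to2), to2)
  k <- config$kappa
  F3 <- ifelse(in_corr, ramp_dip(frac, k * from1, k * to1), k * to1)
  F4 <- ifelse(in_corr, ramp_dip(frac, k * from2, k * to2), k * to2)

  th0 <- config$geometry$initial_varus_angle
  th_deg <- ifelse(in_corr,
                   th0 * (1 - (period - 1 + frac) / n),
                   th0 * (1 - period / n))
  deficit <- ifelse(period <= config$n_deficit,
                    config$pretension_deficit *
                      (config$n_deficit - period + 1) / config$n_deficit,
                    0)
  Fz2m <- pmax(0, config$eta_target * (F1 + F2 + F3 + F4) *
                 cos(deg2rad(th_deg)) - deficit)

  # seeded noise in a private RNG scope
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  m <- length(t)
  sd <- config$noise_sd
  noise <- function() if (sd > 0) stats::rnorm(m, 0, sd) else numeric(m)
  Fx2m <- noise(); Fy2m <- noise()
  out <- data.frame(time_s = t,
                    F1 = F1 + noise(), F2 = F2 + noise(),
                    F3 = F3 + noise(), F4 = F4 + noise(),
                    Fx2m = Fx2m, Fy2m = Fy2m,
                    Fz2m = Fz2m + noise(),
                    period = period, stage = stage)
  structure(out, config = config,
            class = c("force_series", "data.frame"))
}

#' Period-end anchor rows of a force series
#'
#' Reduces a sampled series to one row per period (the last sample of the
#' stay stage), the form consumed by [analyze_series()].
#'
#' @param series a `force_series` from [generate_force_series()] or
#'   [read_force_series()].
#' @return a data frame with columns `period`, `F1`..`F4`, `Fx2m`, `Fy2m`,
#'   `Fz2m`.
#' @export
period_anchors <- function(series) {
  stopifnot(inherits(series, "force_series") || is.data.frame(series))
  need <- c("time_s", "F1", "F2", "Fz2m", "period")
  for (col in need)
    if (!col %in% names(series)) stop("missing required column '", col, "'")
  idx <- vapply(split(seq_len(nrow(series)), series$period),
                function(i) i[which.max(series$time_s[i])], integer(1))
  cols <- intersect(c("period", "F1", "F2", "F3", "F4",
                      "Fx2m", "Fy2m", "Fz2m"), names(series))
  out <- as.data.frame(series)[idx, cols, drop = FALSE]
  out <- out[order(out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Packaged bench tables
#'
#' `load_table3()` returns the measured per-period forces of the sheep-tibia
#' bench run: adjustable-rod forces `F1`, `F2` and measured axial tension
#' `Fz2m` for each of the 10 treatment periods. `load_table4()` returns the
#' finite-element simulated bone-surface tensions `Fz2s` for the same
#' periods.
#'
#' @return a data frame with 10 rows; columns `period`, `F1`, `F2`, `Fz2m`
#'   (`load_table3`) or `period`, `Fz2s` (`load_table4`).
#' @examples
#' load_table3()
#' @export
load_table3 <- function() {
  path <- system.file("extdata", "bench_period_forces.csv",
                      package = "ilizarov", mustWork = TRUE)
  utils::read.csv(path)
}

#' @rdname load_table3
#' @export
load_table4 <- function() {
  path <- system.file("extdata", "bench_simulated_tensions.csv",
                      package = "ilizarov", mustWork = TRUE)
  utils::read.csv(path)
}
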