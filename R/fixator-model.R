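# Fixator model: rod forces + correction schedule -> theoretical bone-end
# tension and per-period transfer efficiency.

#' Fixator geometry
#'
#' Geometric parameters of the two-ring fixator. Lengths in mm, the initial
#' varus angle in degrees. The hinge offsets `a` and `b` locate the bone-end
#' frame relative to the hinge centre; they are carried for the frame
#' surrogate and do not enter the tension model (the hinge transform is a
#' pure rotation). Defaults follow the sheep-tibia bench configuration
#' (190 mm rings, 2.5 mm wires, 6.85 deg initial varus, 10 mm osteotomy gap);
#' `rod_length`, `a` and `b` are bench conventions, not measured values.
#'
#' @param ring_diameter ring diameter, mm.
#' @param rod_length rod length `l`, mm.
#' @param a,b hinge-to-bone-end offsets, mm.
#' @param initial_varus_angle initial frontal-plane deformity, degrees
#'   (0 <= angle < 90).
#' @param bone_gap osteotomy gap, mm.
#' @param wire_diameter Kirschner-wire diameter, mm.
#' @return an object of class `"fixator_geometry"`.
#' @export
fixator_geometry <- function(ring_diameter = 190, rod_length = 150,
                             a = 20, b = 30,
                             initial_varus_angle = 6.85,
                             bone_gap = 10, wire_diameter = 2.5) {
  lens <- c(ring_diameter = ring_diameter, rod_length = rod_length,
            a = a, b = b, bone_gap = bone_gap, wire_diameter = wire_diameter)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all fixator lengths must be positive and finite")
  if (!is.finite(initial_varus_angle) ||
      initial_varus_angle < 0 || initial_varus_angle >= 90)
    stop("'initial_varus_angle' must be in [0, 90) degrees")
  structure(list(ring_diameter = ring_diameter, rod_length = rod_length,
                 a = a, b = b, initial_varus_angle = initial_varus_angle,
                 bone_gap = bone_gap, wire_diameter = wire_diameter),
            class = "fixator_geometry")
}

#' Correction schedule
#'
#' The distraction protocol: `n_periods` treatment periods, each consisting
#' of a correction stage (rod lengthening) followed by a stay stage (rest).
#' Clinically one period is a day at 1 mm/day; on the bench each period is
#' compressed to 24 s.
#'
#' @param n_periods number of periods (>= 1).
#' @param lengthening_per_period rod lengthening per period, mm (> 0).
#' @param correction_duration,stay_duration stage durations, s.
#' @return an object of class `"correction_schedule"`.
#' @export
correction_schedule <- function(n_periods = 10, lengthening_per_period = 1,
                                correction_duration = 12,
                                stay_duration = 12) {
  if (!is.numeric(n_periods) || n_periods < 1 || n_periods != round(n_periods))
    stop("'n_periods' must be an integer >= 1")
  if (lengthening_per_period <= 0)
    stop("'lengthening_per_period' must be > 0")
  if (correction_duration <= 0 || stay_duration < 0)
    stop("stage durations must be positive")
  structure(list(n_periods = as.integer(n_periods),
                 lengthening_per_period = lengthening_per_period,
                 correction_duration = correction_duration,
                 stay_duration = stay_duration),
            class = "correction_schedule")
}

#' Hinge angle at a correction period
#'
#' The residual deformity after `k` of `n` correction periods, interpolated
#' linearly from the initial varus angle at `k = 0` to zero at
#' `k = n_periods`: `theta(k) = theta0 * (1 - k / n_periods)`.
#'
#' @param k period index (0 to `n_periods`), may be a vector.
#' @param schedule a [correction_schedule()].
#' @param geometry a [fixator_geometry()] (supplies the initial angle).
#' @return angle(s) in degrees.
#' @examples
#' theta_at_period(0:10, correction_schedule(), fixator_geometry())
#' @export
theta_at_period <- function(k, schedule = correction_schedule(),
                            geometry = fixator_geometry()) {
  stopifnot(inherits(schedule, "correction_schedule"),
            inherits(geometry, "fixator_geometry"))
  if (any(k < 0 | k > schedule$n_periods))
    stop("period index out of range [0, ", schedule$n_periods, "]")
  geometry$initial_varus_angle * (1 - k / schedule$n_periods)
}

#' Model the passive support-rod forces
#'
#' The support rods are passive load-sharing members; their forces are never
#' measured directly, only known to track the adjustable forces from below.
#' They are modelled as a fixed fraction `kappa` of the corresponding
#' adjustable force: `F3 = kappa * F1`, `F4 = kappa * F2`. The default
#' `kappa = 0.4` reproduces the observed ~300 N total rod load at the final
#' period.
#'
#' @param F1,F2 adjustable-rod forces, N (vectors allowed).
#' @param kappa support fraction (>= 0).
#' @return a list with components `F3` and `F4`, N.
#' @export
support_forces <- function(F1, F2, kappa = 0.4) {
  if (!is.numeric(kappa) || length(kappa) != 1 || !is.finite(kappa) ||
      kappa < 0)
    stop("'kappa' must be a single nonnegative number")
  list(F3 = kappa * F1, F4 = kappa * F2)
}

#' Theoretical bone-end tension from rod forces
#'
#' Each rod's axial force is a wrench along the rod axis (z of the rod
#' frame); rotating it through the hinge angle into the bone-end frame via
#' [rotate_wrench()] and summing the axial components gives
#' `Fz2t = (F1 + F2 + F3 + F4) * cos(theta)`.
#'
#' @param F1,F2 adjustable-rod forces, N.
#' @param F3,F4 support-rod forces, N; if `NULL`, generated by
#'   [support_forces()] at `kappa`.
#' @param theta_deg hinge angle, degrees.
#' @param kappa support fraction used when `F3`/`F4` are absent.
#' @return theoretical axial tension at the osteotomy, N.
#' @examples
#' theoretical_tension(99.62, 117.54, theta_deg = 0)   # period-10 bench row
#' @export
theoretical_tension <- function(F1, F2, F3 = NULL, F4 = NULL,
                                theta_deg = 0, kappa = 0.4) {
  if (is.null(F3) || is.null(F4)) {
    s <- support_forces(F1, F2, kappa)
    if (is.null(F3)) F3 <- s$F3
    if (is.null(F4)) F4 <- s$F4
  }
  forces <- cbind(F1, F2, F3, F4)
  if (any(!is.finite(forces))) stop("rod forces must be finite")
  th <- rep_len(deg2rad(theta_deg), nrow(forces))
  out <- numeric(nrow(forces))
  for (i in seq_len(nrow(forces))) {
    fz <- 0
    for (Fi in forces[i, ]) {
      w <- rotate_wrench(wrench(c(0, 0, Fi)), th[i])
      fz <- fz + w$f[3]
    }
    out[i] <- fz
  }
  out
}

#' Axial force-transfer efficiency
#'
#' The fraction of the theoretically available axial force that appears as
#' measured tension at the bone end: `eta_z = Fz2m / Fz2t`. (Written as a
#' theoretical-to-measured ratio in some sources; this package uses the
#' measured/theoretical orientation so that an ideal, lossless frame gives
#' `eta_z = 1` and the reported plateau is ~0.5.)
#'
#' @param Fz2m measured axial tension, N.
#' @param Fz2t theoretical axial tension, N (> 0).
#' @return dimensionless efficiency.
#' @export
transfer_efficiency <- function(Fz2m, Fz2t) {
  if (any(!is.finite(Fz2t)) || any(Fz2t <= 0))
    stop("'Fz2t' must be positive and finite")
  Fz2m / Fz2t
}

#' Per-period transfer-efficiency analysis
#'
#' Runs the screw-model pipeline over a per-period force table (or a full
#' force time series, from which period-end values are taken): computes the
#' hinge angle, the theoretical tension and the efficiency for every period,
#' and summarises the post-pre-tightening plateau.
#'
#' The first few periods are spent pre-tightening the frame (taking up play
#' in hinges and rods), so their efficiency sits well below the steady-state
#' plateau; `plateau_start` sets the first period counted in the plateau
#' mean (default 4).
#'
#' @param x a data frame with columns `period`, `F1`, `F2`, `Fz2m` and
#'   optionally `F3`, `F4`, `Fx2m`, `Fy2m`; or a `force_series` object from
#'   [generate_force_series()].
#' @param geometry a [fixator_geometry()].
#' @param schedule a [correction_schedule()].
#' @param kappa support fraction used when `F3`/`F4` are absent.
#' @param plateau_start first period of the plateau window (default 4).
#' @return an object of class `"efficiency_report"`: a data frame with
#'   columns `period`, `theta_deg`, `Fz2t`, `eta`, and attributes
#'   `plateau_mean_eta`, `plateau_periods`, `total_load_final_period`.
#' @examples
#' rep <- analyze_series(load_table3())
#' attr(rep, "plateau_mean_eta")
#' @export
analyze_series <- function(x, geometry = fixator_geometry(),
                           schedule = correction_schedule(),
                           kappa = 0.4, plateau_start = 4) {
  stopifnot(inherits(geometry, "fixator_geometry"),
            inherits(schedule, "correction_schedule"))
  if (inherits(x, "force_series")) x <- period_anchors(x)
  if (!is.data.frame(x)) stop("'x' must be a data frame or a force_series")
  if (nrow(x) == 0) stop("empty force table: nothing to analyze")
  for (col in c("period", "F1", "F2", "Fz2m"))
    if (!col %in% names(x)) stop("missing required column '", col, "'")
  if (any(!is.finite(as.matrix(x[c("F1", "F2", "Fz2m")]))))
    stop("force columns must be finite")
  n <- schedule$n_periods
  if (any(x$period < 1 | x$period > n))
    stop("'period' values must lie in 1..", n)

  if (!all(c("F3", "F4") %in% names(x))) {
    s <- support_forces(x$F1, x$F2, kappa)
    x$F3 <- s$F3
    x$F4 <- s$F4
  }
  theta <- theta_at_period(x$period, schedule, geometry)
  Fz2t <- theoretical_tension(x$F1, x$F2, x$F3, x$F4, theta_deg = theta)
  eta <- transfer_efficiency(x$Fz2m, Fz2t)
  if (any(eta >= 1.2))
    stop("efficiency >= 1.2: measured tension exceeds the theoretical ",
         "bound by more than the sanity margin; check kappa and units")
  if (any(eta > 1))
    warning("efficiency above 1 for period(s) ",
            paste(x$period[eta > 1], collapse = ", "))

  in_plateau <- x$period >= plateau_start
  if (!any(in_plateau))
    stop("'plateau_start' leaves no periods in the plateau window")
  report <- data.frame(period = x$period, theta_deg = theta,
                       Fz2t = Fz2t, eta = eta)
  final <- which.max(x$period)
  structure(report,
            plateau_mean_eta = mean(eta[in_plateau]),
            plateau_periods = range(x$period[in_plateau]),
            total_load_final_period =
              x$F1[final] + x$F2[final] + x$F3[final] + x$F4[final],
            kappa = kappa,
            class = c("efficiency_report", "data.frame"))
}

#' @export
print.efficiency_report <- function(x, digits = 4, ...) {
  cat("Transfer-efficiency report (", nrow(x), " periods)\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  pl <- attr(x, "plateau_periods")
  cat(sprintf("plateau mean eta (periods %d-%d): %.4f\n",
              pl[1], pl[2], attr(x, "plateau_mean_eta")))
  cat(sprintf("total rod load, final period: %.2f N\n",
              attr(x, "total_load_final_period")))
  invisible(x)
}
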