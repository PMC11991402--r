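# Joint kinematic wear index: an RC-circuit-like accumulator of postural
# hazard per joint motion.
#
# While a motion's LUBA score exceeds its minimum (1), the index charges
# towards 1:   V(t) = 1 - (1 - V(t0)) * exp(-Int S dt / C)
# and while at the minimum it discharges towards 0:
#              V(t) = V(t0) * exp(-r t / C)
# C (endurance capacity, score*seconds) and r (recovery rate, score units)
# are calibrated so that, under the mid-scale score, the index climbs from 0
# to v_max in exactly t_max seconds, and discharges from v_max to 1 - v_max
# over the same t_max. Because the score is constant within a sample, the
# per-sample exponential update reproduces the continuous integral exactly —
# there is no Euler discretisation error.

#' Calibrate the wear parameters of a joint motion
#'
#' The motion's average score `s_avg` is the midpoint of its LUBA scale,
#' `(1 + max score) / 2`. The endurance capacity is
#' `C = -s_avg * t_max / log(1 - v_max)` and the recovery rate
#' `r = -(C / t_max) * log((1 - v_max) / v_max)`, so that charging under
#' `s_avg` from 0 reaches `v_max` at `t_max` and discharging from `v_max`
#' reaches `1 - v_max` at `t_max`.
#'
#' @param motion a LUBA joint-motion identifier (wear is defined for the nine
#'   LUBA motions only).
#' @param v_max calibration asymptote in (0, 1), default 0.993 (five RC time
#'   constants).
#' @param t_max calibration time in seconds, default 240 (static discomfort
#'   onset under low force).
#' @return A list of class `wear_params`: `motion`, `s_avg`, `capacity_c`,
#'   `recovery_r`, `v_max`, `t_max`.
#' @examples
#' p <- wear_calibrate("back_flexion_extension")
#' p$capacity_c   # ~386.9 score-seconds
#' @export
wear_calibrate <- function(motion, v_max = 0.993, t_max = 240) {
  if (!motion %in% LUBA_MOTIONS) {
    stop("kinematic wear is defined only for the nine LUBA motions, not ",
         motion, call. = FALSE)
  }
  if (!(is.numeric(v_max) && v_max > 0 && v_max < 1)) {
    stop("v_max must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!(is.numeric(t_max) && t_max > 0)) {
    stop("t_max must be positive", call. = FALSE)
  }
  s_avg <- (1 + max(luba_score_scale(motion))) / 2
  capacity_c <- -s_avg * t_max / log(1 - v_max)
  recovery_r <- -capacity_c / t_max * log((1 - v_max) / v_max)
  structure(list(motion = motion, s_avg = s_avg, capacity_c = capacity_c,
                 recovery_r = recovery_r, v_max = v_max, t_max = t_max),
            class = "wear_params")
}

#' One wear/recovery update of the kinematic wear index
#'
#' Applies the exact exponential update for a sample of duration `dt` during
#' which the motion's score is constant: wear (score > 1) moves the index
#' towards 1, recovery (score = 1) towards 0. Both 0 (under recovery) and 1
#' (under wear) are fixed points, so the index never leaves \[0, 1\].
#'
#' @param v current wear index in \[0, 1\] (vectorised).
#' @param score the motion's LUBA score over the sample (vectorised).
#' @param dt sample duration, seconds.
#' @param params a [wear_calibrate()] result.
#' @return Updated wear index, same length as `v`/`score`.
#' @export
wear_step <- function(v, score, dt, params) {
  stopifnot(inherits(params, "wear_params"), dt > 0)
  if (any(v < 0 | v > 1)) stop("wear index must lie in [0, 1]", call. = FALSE)
  wearing <- score > 1
  out <- ifelse(wearing,
                1 - (1 - v) * exp(-score * dt / params$capacity_c),
                v * exp(-params$recovery_r * dt / params$capacity_c))
  pmin(pmax(out, 0), 1)
}

#' Kinematic wear trajectory of one joint motion
#'
#' Runs the recursive wear/recovery update over a per-sample score sequence.
#' Each sample is annotated with its phase: `"wear"` when the score exceeds
#' the minimum, `"recovery"` otherwise. The value reported at sample k is the
#' index *after* k updates from the initial condition, i.e. at time `k * dt`.
#'
#' @param scores integer vector of per-sample LUBA scores for the motion.
#' @param params a [wear_calibrate()] result.
#' @param initial initial wear index in \[0, 1\] (default 0: a rested joint).
#' @param dt sample duration, seconds (1 / sample_rate).
#' @return A data.frame of class `wear_trajectory` with columns `t`, `score`,
#'   `phase`, `value`, plus attributes `motion` and `params`.
#' @export
wear_trajectory <- function(scores, params, initial = 0, dt = 1 / 20) {
  stopifnot(inherits(params, "wear_params"))
  if (!(initial >= 0 && initial <= 1)) {
    stop("initial wear must lie in [0, 1]", call. = FALSE)
  }
  n <- length(scores)
  phase <- ifelse(scores > 1, "wear", "recovery")
  value <- numeric(n)
  # cumulative closed form per phase run: within one phase the update is a
  # single exponential with additive exponents, so process runs at once
  v <- initial
  if (n > 0L) {
    run_id <- cumsum(c(1L, as.integer(phase[-1L] != phase[-n])))
    for (r in seq_len(max(run_id))) {
      idx <- which(run_id == r)
      s <- scores[idx]
      if (phase[idx[1L]] == "wear") {
        expo <- cumsum(s) * dt / params$capacity_c
        value[idx] <- 1 - (1 - v) * exp(-expo)
      } else {
        expo <- params$recovery_r * seq_along(idx) * dt / params$capacity_c
        value[idx] <- v * exp(-expo)
      }
      v <- value[idx[length(idx)]]
    }
  }
  value <- pmin(pmax(value, 0), 1)
  structure(
    data.frame(t = seq_len(n) * dt, score = as.integer(scores),
               phase = phase, value = value, stringsAsFactors = FALSE),
    motion = params$motion, params = params, initial = initial,
    class = c("wear_trajectory", "data.frame"))
}

#' Threshold-breach statistics of a wear trajectory
#'
#' Counts samples strictly above the threshold; no interpolation between
#' samples.
#'
#' @param traj a [wear_trajectory()].
#' @param threshold wear threshold in (0, 1), default 0.7.
#' @return List: `seconds_above`, `fraction_above`, `first_crossing` (time in
#'   seconds of the first sample above the threshold, or `NA` if never).
#' @export
wear_threshold_stats <- function(traj, threshold = 0.7) {
  stopifnot(inherits(traj, "wear_trajectory"))
  if (!(threshold > 0 && threshold < 1)) {
    stop("threshold must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- nrow(traj)
  if (n == 0L) stop("threshold statistics are undefined on an empty trajectory",
                    call. = FALSE)
  dt <- traj$t[1L]
  above <- traj$value > threshold
  list(seconds_above = sum(above) * dt,
       fraction_above = mean(above),
       first_crossing = if (any(above)) traj$t[which(above)[1L]] else NA_real_)
}

#' Kinematic wear for every LUBA motion of a scored series
#'
#' Convenience wrapper: one [wear_trajectory()] per LUBA motion from a
#' [luba_score_series()] result.
#'
#' @param luba_scores data.frame from [luba_score_series()].
#' @param config a [run_config()] supplying `v_max`, `t_max`, `initial_wear`,
#'   `sample_rate`, and `recovery_trigger`.
#' @return Named list of `wear_trajectory` objects, one per LUBA motion.
#' @export
wear_series <- function(luba_scores, config = run_config("luba")) {
  dt <- 1 / config$sample_rate
  out <- lapply(LUBA_MOTIONS, function(m) {
    params <- wear_calibrate(m, v_max = config$v_max, t_max = config$t_max)
    s <- luba_scores[[m]]
    if (identical(config$recovery_trigger, "global")) {
      # experimental alternative: a motion at its own minimum recovers only
      # when the whole-body score is minimal too; otherwise it holds.
      hold <- luba_scores$g > 0L & s == 1L
      v <- config$initial_wear
      value <- numeric(length(s))
      for (k in seq_along(s)) {
        v <- if (hold[k]) v else wear_step(v, s[k], dt, params)
        value[k] <- v
      }
      traj <- wear_trajectory(s, params, initial = config$initial_wear, dt = dt)
      traj$value <- value
      return(traj)
    }
    wear_trajectory(s, params, initial = config$initial_wear, dt = dt)
  })
  names(out) <- LUBA_MOTIONS
  out
}
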