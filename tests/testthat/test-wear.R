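# Kinematic wear index: calibration closed forms, fixed points, trajectory
# dynamics, agreement with an independent high-resolution ODE integrator,
# and threshold-breach statistics.

test_that("calibration evaluates the closed forms at the defaults", {
  p <- wear_calibrate("back_flexion_extension")
  expect_equal(p$s_avg, 8)                      # scale 1..15
  expect_equal(p$capacity_c, -8 * 240 / log(1 - 0.993))
  expect_equal(p$capacity_c, 386.95, tolerance = 1e-4)
  expect_equal(p$recovery_r, p$capacity_c / 240 * log(0.993 / 0.007))
  expect_equal(p$recovery_r, 7.9887, tolerance = 1e-4)

  # capacity is linear in the scale midpoint: elbow (scale 1..5, s_avg 3)
  pe <- wear_calibrate("elbow_left_flexion_extension")
  expect_equal(pe$s_avg, 3)
  expect_equal(pe$capacity_c, (3 / 8) * p$capacity_c)

  expect_error(wear_calibrate("knee_left_flexion_extension"), "nine")
  expect_error(wear_calibrate("back_flexion_extension", v_max = 1), "v_max")
})

test_that("wear and recovery fixed points hold", {
  p <- wear_calibrate("back_flexion_extension")
  expect_equal(wear_step(1, 15, 0.05, p), 1)
  expect_equal(wear_step(0, 1, 0.05, p), 0)
  expect_error(wear_step(1.2, 3, 0.05, p), "\\[0, 1\\]")
})

test_that("calibration self-consistency: v_max at t_max, and back down", {
  for (motion in c("back_flexion_extension", "shoulder_right_abduction_adduction",
                   "elbow_left_flexion_extension")) {
    p <- wear_calibrate(motion)
    n <- 240 * 20
    # charge from 0 under the constant mid-scale score
    traj <- wear_trajectory(rep(p$s_avg, n), p, initial = 0, dt = 1 / 20)
    expect_equal(traj$value[n], 0.993, tolerance = 1e-9, info = motion)
    expect_true(all(traj$phase == "wear"))
    # inverse timing: first sample at/above v_max sits at 240 s
    hit <- which(traj$value >= p$v_max - 1e-12)[1]
    expect_equal(traj$t[hit], 240, tolerance = 0.05 + 1e-9, info = motion)
    # discharge from v_max to 1 - v_max over another t_max
    rec <- wear_trajectory(rep(1L, n), p, initial = p$v_max, dt = 1 / 20)
    expect_equal(rec$value[n], 1 - 0.993, tolerance = 1e-9, info = motion)
    expect_true(all(rec$phase == "recovery"))
  }
})

test_that("trajectories are bounded, phase-monotone, and score-monotone", {
  p <- wear_calibrate("back_flexion_extension")
  scale <- luba_score_scale("back_flexion_extension")
  for (seed in 1:5) {
    scores <- withr::with_seed(seed, sample(scale, 400, replace = TRUE))
    traj <- wear_trajectory(scores, p, initial = 0.3, dt = 1 / 20)
    expect_true(all(traj$value >= 0 & traj$value <= 1))
    dv <- diff(c(0.3, traj$value))
    expect_true(all(dv[traj$phase == "wear"] >= 0))
    expect_true(all(dv[traj$phase == "recovery"] <= 0))
  }
  # higher constant score dominates pointwise
  lo <- wear_trajectory(rep(3L, 200), p, dt = 1 / 20)
  hi <- wear_trajectory(rep(12L, 200), p, dt = 1 / 20)
  expect_true(all(hi$value >= lo$value))
  # per-step increment grows with the score at equal v
  incr <- vapply(scale[scale > 1],
                 function(s) wear_step(0.4, s, 0.05, p) - 0.4, numeric(1))
  expect_true(all(diff(incr) > 0))
  # recovery decrement magnitude grows with accumulated wear
  dec <- vapply(c(0.2, 0.5, 0.8),
                function(v) v - wear_step(v, 1L, 0.05, p), numeric(1))
  expect_true(all(diff(dec) > 0))
})

test_that("closed-form segments match and exponents add across samples", {
  p <- wear_calibrate("shoulder_left_flexion_extension")
  dt <- 1 / 20
  # piecewise-constant schedule: wear at 6, recover, wear at 11
  scores <- c(rep(6L, 120), rep(1L, 80), rep(11L, 100))
  traj <- wear_trajectory(scores, p, initial = 0.1, dt = dt)
  # analytic values at the three segment ends
  v1 <- 1 - (1 - 0.1) * exp(-6 * 120 * dt / p$capacity_c)
  v2 <- v1 * exp(-p$recovery_r * 80 * dt / p$capacity_c)
  v3 <- 1 - (1 - v2) * exp(-11 * 100 * dt / p$capacity_c)
  expect_equal(traj$value[120], v1, tolerance = 1e-12)
  expect_equal(traj$value[200], v2, tolerance = 1e-12)
  expect_equal(traj$value[300], v3, tolerance = 1e-12)
  # whole trajectory against the independent fine-step ODE integrator
  oracle <- wear_ode_oracle(scores, p, initial = 0.1, dt = dt)
  expect_equal(traj$value, oracle, tolerance = 1e-4)
})

test_that("randomised schedules agree with the independent integrator", {
  p <- wear_calibrate("back_lateral_bending")
  scale <- luba_score_scale("back_lateral_bending")
  scores <- withr::with_seed(21, sample(scale, 150, replace = TRUE))
  traj <- wear_trajectory(scores, p, initial = 0, dt = 1 / 20)
  oracle <- wear_ode_oracle(scores, p, initial = 0, dt = 1 / 20)
  expect_equal(traj$value, oracle, tolerance = 1e-4)
})

test_that("threshold statistics count samples exactly, including the crossing", {
  p <- wear_calibrate("back_flexion_extension")
  dt <- 1 / 20
  flat <- wear_trajectory(rep(1L, 100), p, initial = 0, dt = dt)
  st <- wear_threshold_stats(flat, 0.7)
  expect_equal(st$fraction_above, 0)
  expect_equal(st$seconds_above, 0)
  expect_true(is.na(st$first_crossing))

  # constant wear at score 12 from 0: analytic crossing of 0.7 at
  # t* = -(C/12) log(0.3); first sample above is ceil(t*/dt) * dt
  n <- 4000L
  traj <- wear_trajectory(rep(12L, n), p, initial = 0, dt = dt)
  t_star <- -(p$capacity_c / 12) * log(1 - 0.7)
  st <- wear_threshold_stats(traj, 0.7)
  expect_equal(st$first_crossing, ceiling(t_star / dt) * dt, tolerance = 1e-9)
  expect_equal(st$seconds_above, (n - ceiling(t_star / dt) + 1) * dt)
  # saturating run: fraction approaches 1
  expect_gt(wear_threshold_stats(
    wear_trajectory(rep(12L, 40000L), p, dt = dt), 0.7)$fraction_above, 0.98)

  expect_error(wear_threshold_stats(wear_trajectory(integer(0), p, dt = dt)),
               "empty")
  expect_error(wear_threshold_stats(flat, 0), "threshold")
})

test_that("wear_series runs one trajectory per LUBA motion; knees excluded", {
  tr <- generate_trial(bricklaying_script("stooping", seed = 2))
  cfg <- run_config("luba")
  sc <- luba_score_series(tr$angles, cfg)
  w <- wear_series(sc, cfg)
  expect_named(w, joint_motions("luba"))
  for (m in names(w)) {
    expect_equal(w[[m]]$value,
                 wear_trajectory(sc[[m]], wear_calibrate(m),
                                 initial = 0, dt = 1 / 20)$value)
    expect_equal(w[[m]]$phase == "wear", sc[[m]] > 1L)
  }
})

test_that("experimental global recovery trigger holds instead of recovering", {
  cfg <- run_config("luba", recovery_trigger = "global")
  # back bent (wear for back), shoulders neutral -> shoulders hold, not recover
  df <- as.data.frame(constant_series(100))
  df$back_flexion_extension <- 70
  df$shoulder_left_flexion_extension[1:50] <- 100  # charge the shoulder first
  sc <- luba_score_series(angle_series(df), cfg)
  w <- wear_series(sc, cfg)
  sh <- w$shoulder_left_flexion_extension$value
  expect_true(all(diff(sh[51:100]) == 0))  # held while g > 0
  cfg0 <- run_config("luba")
  sh0 <- wear_series(sc, cfg0)$shoulder_left_flexion_extension$value
  expect_true(all(diff(sh0[51:100]) < 0))  # default: per-motion recovery
})
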