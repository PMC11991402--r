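# LUBA finite-state scoring: published lookup rows, partition properties,
# global score with arm selection, categories, per-sample series.

test_that("published score rows reproduce", {
  expect_equal(luba_score_motion("back_flexion_extension", -35), 15L)
  expect_equal(luba_score_motion("back_flexion_extension", 0), 1L)
  expect_equal(luba_score_motion("back_flexion_extension", 70), 6L)
  expect_equal(luba_score_motion("back_flexion_extension", 95), 12L)
  expect_equal(luba_score_motion("shoulder_left_abduction_adduction", 0), 1L)
  expect_equal(luba_score_motion("elbow_right_flexion_extension", 130), 5L)
  # magnitude motions score the absolute angle symmetrically
  expect_equal(luba_score_motion("back_lateral_bending", -25), 9L)
  expect_equal(luba_score_motion("back_lateral_bending", 25), 9L)
  expect_equal(luba_score_motion("back_axial_rotation", -70), 10L)
})

test_that("upper bounds are inclusive as printed", {
  expect_equal(luba_score_motion("back_flexion_extension", 30), 1L)
  expect_equal(luba_score_motion("back_flexion_extension", 30.0001), 3L)
  expect_equal(luba_score_motion("back_flexion_extension", -30), 15L)
  expect_equal(luba_score_motion("shoulder_left_flexion_extension", 45), 1L)
  expect_equal(luba_score_motion("elbow_left_flexion_extension", 120), 3L)
})

test_that("every LUBA partition tiles the angle axis with a unique score", {
  grid <- c(seq(-180, 180, by = 0.25),
            # hit every boundary and its neighbourhood exactly
            outer(c(-30, -20, -10, 10, 20, 30, 45, 60, 90, 120, 150,
                    -45, -60), c(-1e-9, 0, 1e-9), `+`),
            withr::with_seed(99, runif(500, -360, 360)))
  for (m in joint_motions("luba")) {
    expect_equal(luba_score_motion(m, grid), luba_oracle_score(m, grid),
                 info = m)
    expect_true(min(luba_score_motion(m, grid)) >= 1L, info = m)
  }
})

test_that("knee motions are rejected", {
  expect_error(luba_score_motion("knee_left_flexion_extension", 10), "knee")
})

test_that("global score sums only scores above the minimum over back + one arm", {
  neutral <- setNames(rep(1L, 9), LUBA_M)
  gs <- luba_global_score(neutral)
  expect_equal(gs$g, 0L)
  expect_equal(as.character(gs$category), "I")

  one <- neutral; one["back_flexion_extension"] <- 6L
  gs <- luba_global_score(one)
  expect_equal(gs$g, 6L)
  expect_equal(as.character(gs$category), "II")

  # every motion at its maximum on the right arm: 15+13+10+11+8+5 = 62
  maxed <- neutral
  for (m in LUBA_M) maxed[m] <- max(luba_score_scale(m))
  gs <- luba_global_score(maxed)
  expect_equal(gs$g, 62L)
  expect_equal(as.character(gs$category), "IV")

  expect_error(luba_global_score(neutral[-1]), "incomplete")
})

test_that("arm selection picks the higher shoulder+elbow sum, ties to the right", {
  sc <- setNames(rep(1L, 9), LUBA_M)
  sc["shoulder_right_flexion_extension"] <- 6L
  sc["shoulder_right_abduction_adduction"] <- 3L
  sc["elbow_right_flexion_extension"] <- 3L
  expect_equal(luba_global_score(sc)$selected_arm, "right")
  expect_equal(luba_global_score(sc)$g, 12L)

  sc2 <- setNames(rep(1L, 9), LUBA_M)
  sc2["shoulder_left_flexion_extension"] <- 10L
  expect_equal(luba_global_score(sc2)$selected_arm, "left")

  # identical arms: g independent of policy
  sym <- setNames(rep(1L, 9), LUBA_M)
  sym[c("elbow_left_flexion_extension", "elbow_right_flexion_extension")] <- 5L
  gs <- vapply(c("worst_sum", "left", "right"),
               function(p) luba_global_score(sym, p)$g, integer(1))
  expect_true(all(gs == gs[1]))
  expect_equal(luba_global_score(sym)$selected_arm, "right")  # tie-break
})

test_that("categorisation uses the published cut points and is monotone", {
  expect_equal(as.character(luba_categorize(c(0, 5, 6, 10, 12, 15, 16, 62))),
               c("I", "I", "II", "II", "III", "III", "IV", "IV"))
  expect_error(luba_categorize(-1), "non-negative")
  lv <- as.integer(luba_categorize(0:62))
  expect_true(all(diff(lv) >= 0))
  expect_equal(sort(unique(as.character(luba_categorize(0:62)))),
               sort(c("I", "II", "III", "IV")))
})

test_that("series scoring equals frame-by-frame recomputation and stays in [0, 62]", {
  s <- random_series(200, seed = 7)
  cfg <- run_config("luba")
  out <- luba_score_series(s, cfg)
  expect_equal(nrow(out), 200L)
  for (k in c(1L, 57L, 200L)) {
    per <- vapply(LUBA_M, function(m) luba_score_motion(m, s[[m]][k]),
                  integer(1))
    gs <- luba_global_score(per, cfg$arm_selection)
    expect_equal(out$g[k], gs$g)
    expect_equal(out$selected_arm[k], gs$selected_arm)
    expect_equal(as.character(out$category[k]), as.character(gs$category))
  }
  expect_true(all(out$g >= 0 & out$g <= 62))
  # g = 0 iff every contributing score is 1
  contributing <- cbind(
    out[, c("back_flexion_extension", "back_lateral_bending",
            "back_axial_rotation")],
    vapply(c("shoulder_%s_flexion_extension", "shoulder_%s_abduction_adduction",
             "elbow_%s_flexion_extension"),
           function(p) ifelse(out$selected_arm == "left",
                              out[[sprintf(p, "left")]],
                              out[[sprintf(p, "right")]]),
           numeric(nrow(out))))
  expect_equal(out$g == 0L, apply(contributing == 1L, 1L, all))
})

test_that("neutral series scores zero; a single bent frame scores alone", {
  cfg <- run_config("luba")
  out <- luba_score_series(constant_series(100, method = "luba"), cfg)
  expect_true(all(out$g == 0L))

  df <- as.data.frame(constant_series(50))
  df$back_flexion_extension[20] <- 70
  out <- luba_score_series(angle_series(df), cfg)
  expect_equal(which(out$g > 0L), 20L)
  expect_equal(out$g[20], 6L)
})
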