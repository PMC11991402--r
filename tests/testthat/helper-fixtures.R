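# Shared fixtures: all generated in code, nothing on disk.

ALL_M <- joint_motions("awba")
LUBA_M <- joint_motions("luba")

# series of n identical frames with the given named angles (others 0)
constant_series <- function(n, angles = c(), sample_rate = 20,
                            method = "awba") {
  df <- as.data.frame(matrix(0, nrow = n, ncol = length(ALL_M),
                             dimnames = list(NULL, ALL_M)))
  for (m in names(angles)) df[[m]] <- angles[[m]]
  angle_series(df, sample_rate = sample_rate, method = method)
}

random_series <- function(n, sample_rate = 20, seed = 42, range = 170) {
  set.seed(seed)
  df <- as.data.frame(matrix(stats::runif(n * length(ALL_M), -range, range),
                             nrow = n, dimnames = list(NULL, ALL_M)))
  angle_series(df, sample_rate = sample_rate)
}

neutral_labels <- function(n, class = "standing", sample_rate = 20) {
  posture_label_series(rep(class, n), sample_rate = sample_rate,
                       provenance = "synthetic_truth")
}

# Independent transcription of the LUBA angle partitions as predicate lists,
# used as the oracle for totality/uniqueness and lookup agreement. Kept
# deliberately separate from the package's break-vector encoding.
luba_oracle_rows <- list(
  back_flexion_extension = list(
    list(function(a) a <= -30, 15L),
    list(function(a) a > -30 & a <= -20, 8L),
    list(function(a) a > -20 & a <= -10, 4L),
    list(function(a) a > -10 & a <= 30, 1L),
    list(function(a) a > 30 & a <= 60, 3L),
    list(function(a) a > 60 & a <= 90, 6L),
    list(function(a) a > 90, 12L)),
  back_lateral_bending = list(
    list(function(a) abs(a) <= 10, 1L),
    list(function(a) abs(a) > 10 & abs(a) <= 20, 4L),
    list(function(a) abs(a) > 20 & abs(a) <= 30, 9L),
    list(function(a) abs(a) > 30, 13L)),
  back_axial_rotation = list(
    list(function(a) abs(a) <= 20, 1L),
    list(function(a) abs(a) > 20 & abs(a) <= 60, 3L),
    list(function(a) abs(a) > 60, 10L)),
  shoulder_flexion_extension = list(
    list(function(a) a <= -60, 10L),
    list(function(a) a > -60 & a <= -45, 6L),
    list(function(a) a > -45 & a <= -20, 3L),
    list(function(a) a > -20 & a <= 45, 1L),
    list(function(a) a > 45 & a <= 90, 3L),
    list(function(a) a > 90 & a <= 150, 6L),
    list(function(a) a > 150, 11L)),
  shoulder_abduction_adduction = list(
    list(function(a) a <= -30, 8L),
    list(function(a) a > -30 & a <= -10, 2L),
    list(function(a) a > -10 & a <= 30, 1L),
    list(function(a) a > 30 & a <= 90, 3L),
    list(function(a) a > 90, 7L)),
  elbow_flexion_extension = list(
    list(function(a) a <= 45, 1L),
    list(function(a) a > 45 & a <= 120, 3L),
    list(function(a) a > 120, 5L)))

luba_oracle_key <- function(motion) {
  sub("^(shoulder|elbow|knee)_(left|right)_", "\\1_", motion)
}

# score by the predicate transcription; errors unless exactly one row matches
luba_oracle_score <- function(motion, angle) {
  rows <- luba_oracle_rows[[luba_oracle_key(motion)]]
  vapply(angle, function(a) {
    hits <- which(vapply(rows, function(r) r[[1]](a), logical(1)))
    stopifnot(length(hits) == 1L)
    rows[[hits]][[2]]
  }, integer(1))
}

# brute-force high-resolution numeric integrator for the wear ODEs:
# dV/dt = s (1 - V) / C during wear, dV/dt = -r V / C during recovery.
wear_ode_oracle <- function(scores, params, initial, dt, substeps = 200L) {
  v <- initial
  h <- dt / substeps
  out <- numeric(length(scores))
  for (k in seq_along(scores)) {
    s <- scores[k]
    for (j in seq_len(substeps)) {
      dv <- if (s > 1) s * (1 - v) / params$capacity_c else
        -params$recovery_r * v / params$capacity_c
      v <- v + h * dv
    }
    out[k] <- v
  }
  out
}
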