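# Synthetic labelled work trials: sequences of posture segments with
# characteristic joint-angle profiles, smooth transitions, Gaussian jitter,
# and ground-truth labels. The templates are package-defined constants chosen
# so each posture lands in known scoring bands (they are not measurements):
# e.g. the stooping template's 95 deg back flexion sits in the top LUBA band
# (score 12), the standing template is fully neutral (all scores 1).

# mean angles (degrees) per posture; unlisted motions default to 0
POSTURE_TEMPLATES <- list(
  standing = list(),
  reaching = list(back_flexion_extension = 10,
                  shoulder_left_flexion_extension = 100,
                  shoulder_right_flexion_extension = 100,
                  shoulder_left_abduction_adduction = 15,
                  shoulder_right_abduction_adduction = 15,
                  elbow_left_flexion_extension = 30,
                  elbow_right_flexion_extension = 30,
                  knee_left_flexion_extension = 5,
                  knee_right_flexion_extension = 5),
  stooping = list(back_flexion_extension = 95,
                  shoulder_left_flexion_extension = 95,
                  shoulder_right_flexion_extension = 95,
                  elbow_left_flexion_extension = 20,
                  elbow_right_flexion_extension = 20,
                  knee_left_flexion_extension = 10,
                  knee_right_flexion_extension = 10),
  squatting = list(back_flexion_extension = 20,
                   shoulder_left_flexion_extension = 40,
                   shoulder_right_flexion_extension = 40,
                   elbow_left_flexion_extension = 60,
                   elbow_right_flexion_extension = 60,
                   knee_left_flexion_extension = 100,
                   knee_right_flexion_extension = 100),
  kneeling = list(back_flexion_extension = 45,
                  shoulder_left_flexion_extension = 50,
                  shoulder_right_flexion_extension = 50,
                  elbow_left_flexion_extension = 50,
                  elbow_right_flexion_extension = 50,
                  knee_left_flexion_extension = 90,
                  knee_right_flexion_extension = 90),
  lifting_lowering = list(back_flexion_extension = 50,
                          shoulder_left_flexion_extension = 55,
                          shoulder_right_flexion_extension = 55,
                          elbow_left_flexion_extension = 70,
                          elbow_right_flexion_extension = 70,
                          knee_left_flexion_extension = 50,
                          knee_right_flexion_extension = 50),
  carrying = list(back_flexion_extension = 5,
                  shoulder_left_flexion_extension = 10,
                  shoulder_right_flexion_extension = 10,
                  elbow_left_flexion_extension = 90,
                  elbow_right_flexion_extension = 90,
                  knee_left_flexion_extension = 25,
                  knee_right_flexion_extension = 25),
  others = list(back_flexion_extension = 20,
                back_axial_rotation = 30,
                back_lateral_bending = 15,
                shoulder_left_flexion_extension = 20,
                shoulder_right_flexion_extension = 20,
                knee_left_flexion_extension = 20,
                knee_right_flexion_extension = 20)
)

# cyclic knee motion while walking with a load (amplitude deg, frequency Hz)
POSTURE_OSCILLATIONS <- list(
  carrying = list(motions = KNEE_MOTIONS, amplitude = 25, frequency = 1)
)

#' Posture template mean angles
#'
#' @param posture a posture class.
#' @return Named numeric vector over all 11 motions (degrees).
#' @export
posture_template <- function(posture) {
  assert_posture(posture, "posture template")
  tmpl <- POSTURE_TEMPLATES[[posture]]
  ang <- stats::setNames(numeric(length(ALL_MOTIONS)), ALL_MOTIONS)
  ang[names(tmpl)] <- unlist(tmpl)
  ang
}

#' Build a trial script
#'
#' A trial script is a sequence of (posture, duration) segments with a
#' transition time over which angles interpolate linearly between the
#' adjacent templates.
#'
#' @param postures character vector of posture classes, one per segment.
#' @param durations numeric vector of segment durations, seconds (> 0).
#' @param transition_s seconds of linear interpolation entering each segment
#'   (default 0.5).
#' @param jitter_sd Gaussian angle jitter standard deviation, degrees
#'   (default 3).
#' @param seed integer seed making the generated trial reproducible.
#' @return A list of class `trial_script`.
#' @export
trial_script <- function(postures, durations, transition_s = 0.5,
                         jitter_sd = 3, seed = 1L) {
  assert_posture(postures, "script posture")
  stopifnot(length(postures) == length(durations), all(durations > 0),
            sum(durations) >= 1, transition_s >= 0, jitter_sd >= 0)
  structure(list(postures = as.character(postures),
                 durations = as.numeric(durations),
                 transition_s = transition_s, jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "trial_script")
}

#' Generate a labelled synthetic trial
#'
#' Angles are the segment template mean, linearly interpolated from the
#' previous template over the first `transition_s` seconds of each segment,
#' plus i.i.d. Gaussian jitter and, for cyclic postures (carrying), a
#' sinusoidal knee component. Labels are the ground-truth segment postures;
#' samples inside a transition are labelled by the incoming segment.
#'
#' @param script a [trial_script()].
#' @param sample_rate Hz (default 20).
#' @return List with `angles` (an [angle_series()]) and `labels` (a
#'   [posture_label_series()] with provenance `"synthetic_truth"`).
#' @export
generate_trial <- function(script, sample_rate = 20) {
  stopifnot(inherits(script, "trial_script"))
  set.seed(script$seed)
  dt <- 1 / sample_rate
  n_seg <- vapply(script$durations, function(d) as.integer(round(d * sample_rate)),
                  integer(1))
  n <- sum(n_seg)
  t <- (seq_len(n) - 1L) * dt
  ang <- matrix(0, nrow = n, ncol = length(ALL_MOTIONS),
                dimnames = list(NULL, ALL_MOTIONS))
  labels <- character(n)
  prev_mean <- posture_template(script$postures[1L])  # no ramp into segment 1
  offset <- 0L
  for (k in seq_along(script$postures)) {
    idx <- offset + seq_len(n_seg[k])
    mean_k <- posture_template(script$postures[k])
    seg_t <- (seq_len(n_seg[k]) - 1L) * dt
    w <- if (script$transition_s > 0) pmin(seg_t / script$transition_s, 1) else
      rep(1, n_seg[k])
    ang[idx, ] <- outer(1 - w, prev_mean) + outer(w, mean_k)
    osc <- POSTURE_OSCILLATIONS[[script$postures[k]]]
    if (!is.null(osc)) {
      wave <- osc$amplitude * sin(2 * pi * osc$frequency * seg_t)
      for (mo in osc$motions) ang[idx, mo] <- ang[idx, mo] + w * wave
    }
    labels[idx] <- script$postures[k]
    prev_mean <- mean_k
    offset <- offset + n_seg[k]
  }
  if (script$jitter_sd > 0) {
    ang <- ang + matrix(stats::rnorm(n * ncol(ang), sd = script$jitter_sd),
                        nrow = n)
  }
  df <- as.data.frame(ang)
  df$t <- t
  list(angles = angle_series(df, sample_rate = sample_rate, method = "awba"),
       labels = posture_label_series(labels, sample_rate = sample_rate,
                                     provenance = "synthetic_truth"))
}

#' Script emulating a bricklaying work circuit
#'
#' Roughly two minutes: an initial ~20 s carrying segment (bringing the
#' bucket to the bench), then repeated cycles of lifting/lowering, the
#' bricklaying posture itself (stooping, squatting or kneeling, the variant),
#' and a brief standing recovery. The stooping variant holds the back in the
#' top LUBA band long enough for its flexion/extension wear to cross the 0.7
#' threshold within the trial; the kneeling variant alternates wear and
#' recovery without saturating.
#'
#' @param variant `"stooping"`, `"squatting"` or `"kneeling"`.
#' @param seed integer seed.
#' @return A [trial_script()].
#' @export
bricklaying_script <- function(variant = c("stooping", "squatting", "kneeling"),
                               seed = 1L) {
  variant <- match.arg(variant)
  postures <- c("carrying",
                rep(c("lifting_lowering", variant, "standing"), 4L))
  durations <- c(20, rep(c(5, 15, 5), 4L))  # 20 + 4 * 25 = 120 s
  trial_script(postures, durations, seed = seed)
}

#' Script emulating a crop-harvesting circuit
#'
#' Alternates reaching into the canopy, lowering the crop into a bucket, and
#' carrying the bucket between harvest sites.
#'
#' @param seed integer seed.
#' @return A [trial_script()].
#' @export
harvesting_script <- function(seed = 1L) {
  cycle <- c("reaching", "lifting_lowering", "stooping", "standing")
  trial_script(
    c(rep(c(cycle, "carrying"), 3L)),
    rep(c(8, 4, 6, 3, 8), 3L),  # 3 sites x 29 s
    seed = seed)
}
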