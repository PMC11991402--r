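# LUBA (Postural Loading on the Upper Body Assessment) finite-state scoring.
#
# Each joint motion has a fixed partition of the angle axis into half-open
# intervals (lower bound exclusive, upper bound inclusive) carrying integer
# discomfort scores; 1 is always the neutral minimum. Lateral bending and
# axial rotation are scored on |angle|. The global score G sums, over the back
# and one arm, every per-motion score strictly above 1, and is categorised
# I-IV for corrective-action urgency.

# breaks are interval upper bounds; scores has length(breaks) + 1.
# intervals are (break[k-1], break[k]], the first being (-Inf, break[1]].
LUBA_FSM <- list(
  flexion_extension = list(
    back     = list(breaks = c(-30, -20, -10, 30, 60, 90),
                    scores = c(15, 8, 4, 1, 3, 6, 12)),
    shoulder = list(breaks = c(-60, -45, -20, 45, 90, 150),
                    scores = c(10, 6, 3, 1, 3, 6, 11)),
    elbow    = list(breaks = c(45, 120),
                    scores = c(1, 3, 5))
  ),
  lateral_bending = list(
    back = list(breaks = c(10, 20, 30), scores = c(1, 4, 9, 13), magnitude = TRUE)
  ),
  axial_rotation = list(
    back = list(breaks = c(20, 60), scores = c(1, 3, 10), magnitude = TRUE)
  ),
  abduction_adduction = list(
    shoulder = list(breaks = c(-30, -10, 30, 90), scores = c(8, 2, 1, 3, 7))
  )
)

luba_fsm_for <- function(motion) {
  plane <- motion_plane(motion)
  joint <- sub("_(left|right)$", "", motion_joint(motion))
  fsm <- LUBA_FSM[[plane]][[joint]]
  if (is.null(fsm)) {
    stop(sprintf("motion '%s' is not assessed by LUBA", motion), call. = FALSE)
  }
  fsm
}

#' Score a joint-motion angle with the LUBA state machine
#'
#' Looks up the integer LUBA discomfort score for one joint motion at one or
#' more angles. The angle intervals partition the real line, with upper bounds
#' inclusive: a back flexion of exactly 30 deg still scores 1, while
#' 30.0001 deg scores 3. Lateral bending and axial rotation are scored on the
#' magnitude of the signed angle.
#'
#' @param motion a LUBA joint-motion identifier (see
#'   `joint_motions("luba")`); knees are not assessed by LUBA.
#' @param angle numeric vector of angles in degrees (signed: flexion/abduction
#'   positive, extension/adduction negative).
#' @return Integer vector of scores, same length as `angle`.
#' @examples
#' luba_score_motion("back_flexion_extension", c(-35, 0, 70, 95))  # 15 1 6 12
#' luba_score_motion("elbow_left_flexion_extension", 130)          # 5
#' @export
luba_score_motion <- function(motion, angle) {
  if (motion %in% KNEE_MOTIONS) {
    stop("LUBA does not assess knee motions (", motion, ")", call. = FALSE)
  }
  fsm <- luba_fsm_for(motion)
  if (!is.numeric(angle) || any(!is.finite(angle))) {
    stop("angle must be finite numeric (degrees)", call. = FALSE)
  }
  x <- if (isTRUE(fsm$magnitude)) abs(angle) else angle
  idx <- findInterval(x, fsm$breaks, left.open = TRUE) + 1L
  as.integer(fsm$scores[idx])
}

#' Score range of a LUBA joint motion
#'
#' @param motion a LUBA joint-motion identifier.
#' @return Sorted integer vector of the scores the motion's state machine can
#'   emit (its scale; minimum is always 1).
#' @export
luba_score_scale <- function(motion) {
  sort(unique(as.integer(luba_fsm_for(motion)$scores)))
}

arm_motions <- function(side) {
  c(sprintf("shoulder_%s_flexion_extension", side),
    sprintf("shoulder_%s_abduction_adduction", side),
    sprintf("elbow_%s_flexion_extension", side))
}

#' Global LUBA score over the back and one arm
#'
#' Sums every per-motion score strictly greater than 1 (the neutral minimum)
#' over the three back motions and the motions of a single arm. Under the
#' default `"worst_sum"` policy the arm with the higher shoulder+elbow score
#' sum is selected at each evaluation; ties go to the right arm. The result
#' lies between 0 (fully neutral) and 62 (every motion at its scale maximum).
#'
#' @param scores named numeric vector or list mapping all nine LUBA motion
#'   identifiers to their per-motion scores.
#' @param arm_selection `"worst_sum"`, `"left"` or `"right"`.
#' @return A list with integer `g`, `selected_arm` (`"left"`/`"right"`), and
#'   `category` (`"I"`..`"IV"`, see [luba_categorize()]).
#' @export
luba_global_score <- function(scores,
                              arm_selection = c("worst_sum", "left", "right")) {
  arm_selection <- match.arg(arm_selection)
  scores <- unlist(scores)
  missing <- setdiff(LUBA_MOTIONS, names(scores))
  if (length(missing) > 0L) {
    stop("incomplete frame: missing LUBA score(s) for ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  arm <- switch(arm_selection,
    left = "left",
    right = "right",
    worst_sum = {
      left_sum <- sum(scores[arm_motions("left")])
      right_sum <- sum(scores[arm_motions("right")])
      if (left_sum > right_sum) "left" else "right"
    })
  contributing <- scores[c("back_flexion_extension", "back_lateral_bending",
                           "back_axial_rotation", arm_motions(arm))]
  g <- as.integer(sum(contributing[contributing > 1]))
  list(g = g, selected_arm = arm, category = luba_categorize(g))
}

#' Corrective-action category from a global LUBA score
#'
#' Four categories express the urgency of workplace intervention: I (G <= 5,
#' none needed), II (5 < G <= 10, address at the next regular check),
#' III (10 < G <= 15, redesign soon), IV (G > 15, immediate action).
#'
#' @param g integer global score(s), >= 0.
#' @return Factor with levels `I`, `II`, `III`, `IV`.
#' @export
luba_categorize <- function(g) {
  if (any(g < 0)) stop("global score must be non-negative", call. = FALSE)
  cut(g, breaks = c(-Inf, 5, 10, 15, Inf), labels = c("I", "II", "III", "IV"),
      right = TRUE)
}

#' Colour convention for LUBA categories and AWBA levels
#'
#' Green, yellow, orange, red in ascending risk order, used by the report
#' renderers.
#'
#' @param x factor/character of categories (`I`..`IV`) or integer levels 1-4.
#' @return Character vector of colour names.
#' @export
risk_colours <- function(x) {
  pal <- c("green", "yellow", "orange", "red")
  if (is.numeric(x)) pal[x] else pal[match(as.character(x), c("I", "II", "III", "IV"))]
}

#' Per-sample LUBA assessment of an angle series
#'
#' Applies the per-motion state machines and the global score to every sample.
#'
#' @param series an [angle_series()] containing the nine LUBA motions.
#' @param config a [run_config()]; only `arm_selection` is used here.
#' @return A data.frame with one row per sample: `t`, one integer score column
#'   per LUBA motion, `g`, `selected_arm`, `category`.
#' @export
luba_score_series <- function(series, config = run_config("luba")) {
  stopifnot(inherits(series, "angle_series"))
  missing <- setdiff(LUBA_MOTIONS, names(series))
  if (length(missing) > 0L) {
    stop("series lacks LUBA motion(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(series)
  out <- data.frame(t = series$t)
  for (m in LUBA_MOTIONS) out[[m]] <- luba_score_motion(m, series[[m]])
  if (n == 0L) {
    out$g <- integer(0); out$selected_arm <- character(0)
    out$category <- factor(character(0), levels = c("I", "II", "III", "IV"))
    return(out)
  }
  arm <- switch(config$arm_selection,
    left = rep("left", n),
    right = rep("right", n),
    worst_sum = {
      ls <- rowSums(out[, arm_motions("left")])
      rs <- rowSums(out[, arm_motions("right")])
      ifelse(ls > rs, "left", "right")
    })
  g <- integer(n)
  for (m in c("back_flexion_extension", "back_lateral_bending",
              "back_axial_rotation")) {
    g <- g + ifelse(out[[m]] > 1L, out[[m]], 0L)
  }
  for (part in c("shoulder_%s_flexion_extension",
                 "shoulder_%s_abduction_adduction",
                 "elbow_%s_flexion_extension")) {
    s <- ifelse(arm == "left", out[[sprintf(part, "left")]],
                out[[sprintf(part, "right")]])
    g <- g + ifelse(s > 1L, s, 0L)
  }
  out$g <- as.integer(g)
  out$selected_arm <- arm
  out$category <- luba_categorize(out$g)
  out
}
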