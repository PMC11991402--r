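# Joint-motion vocabulary shared by every scoring and wear routine.
# Only anatomically monitored combinations are constructible: the back moves in
# three planes, each shoulder in two, each elbow and knee in one.

#' Joint motions assessed by the package
#'
#' The package scores a fixed set of joint motions. LUBA covers the upper body
#' only: three back motions (flexion/extension, lateral bending, axial
#' rotation), two motions per shoulder (flexion/extension,
#' abduction/adduction) and one per elbow, nine motions in total. The
#' whole-body AWBA method adds one flexion/extension motion per knee, for
#' eleven scored motions overall.
#'
#' Motion identifiers are strings of the form `<joint>_<motion>`, e.g.
#' `"back_flexion_extension"` or `"shoulder_left_abduction_adduction"`; the
#' same identifiers name the columns of an angle CSV.
#'
#' @param method `"luba"` for the nine upper-body motions, `"awba"` for all
#'   eleven (knees included).
#' @return Character vector of motion identifiers.
#' @examples
#' joint_motions("luba")   # 9 motions
#' joint_motions("awba")   # 11 motions
#' @export
joint_motions <- function(method = c("awba", "luba")) {
  method <- match.arg(method)
  if (method == "luba") LUBA_MOTIONS else ALL_MOTIONS
}

LUBA_MOTIONS <- c(
  "back_flexion_extension",
  "back_lateral_bending",
  "back_axial_rotation",
  "shoulder_left_flexion_extension",
  "shoulder_left_abduction_adduction",
  "shoulder_right_flexion_extension",
  "shoulder_right_abduction_adduction",
  "elbow_left_flexion_extension",
  "elbow_right_flexion_extension"
)

KNEE_MOTIONS <- c("knee_left_flexion_extension", "knee_right_flexion_extension")

ALL_MOTIONS <- c(LUBA_MOTIONS, KNEE_MOTIONS)

#' The eight recognised posture classes
#'
#' Posture recognition partitions each 1-s window of a work trial into one of
#' eight classes common to agricultural and construction work. `"sitting"` is
#' deliberately absent: the lower-limb assessment reserves its lowest risk
#' level for sitting, which is out of scope here.
#'
#' @return Character vector of the eight class names.
#' @export
posture_classes <- function() {
  c("standing", "reaching", "stooping", "squatting", "kneeling",
    "lifting_lowering", "carrying", "others")
}

# strict membership check used by label readers and the synthetic generator
assert_posture <- function(x, what = "posture label") {
  bad <- setdiff(unique(as.character(x)), posture_classes())
  if (length(bad) > 0L) {
    stop(sprintf("unknown %s: %s (must be one of: %s)", what,
                 paste(sQuote(bad), collapse = ", "),
                 paste(posture_classes(), collapse = ", ")),
         call. = FALSE)
  }
  invisible(as.character(x))
}

# joint/motion split helpers (identifiers are <joint>_<motion> with joint
# possibly containing a side suffix)
motion_joint <- function(motion) {
  sub("_(flexion_extension|lateral_bending|axial_rotation|abduction_adduction)$",
      "", motion)
}

motion_plane <- function(motion) {
  m <- regmatches(motion, regexpr(
    "(flexion_extension|lateral_bending|axial_rotation|abduction_adduction)$",
    motion))
  if (length(m) == 0L) stop("not a joint motion identifier: ", motion)
  m
}

# motions scored on the magnitude of a signed angle
MAGNITUDE_MOTIONS <- c("back_lateral_bending", "back_axial_rotation")
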