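# AWBA (Agricultural Whole-Body Assessment): AULA for the upper body, ALLA
# for the lower limbs, combined through a fixed 4x4 rule grid. All angles are
# sagittal-plane flexion/extension. Risk levels run 1 (green) to 4 (red).

#' Upper-body (AULA) risk level
#'
#' Finite-state lookup over back, shoulder and elbow flexion/extension angles.
#' The branches, in order: with the back near neutral (<= 22.5 deg) the level
#' follows the shoulder alone (1 up to 22.5, 2 up to 72.5, 3 up to 105, 4
#' beyond); with moderate back flexion (22.5-72.5 deg) a bent elbow
#' (> 22.5 deg) or raised shoulder (> 72.5 deg) raises level 2 to 3; back
#' flexion beyond 72.5 deg is level 2 regardless of the arms, as the source
#' method prescribes.
#'
#' @param back_fe,shoulder_fe,elbow_fe flexion/extension angles in degrees
#'   (vectors recycle to a common length).
#' @return Integer risk level(s) 1-4.
#' @examples
#' aula_level(10, 10, 0)    # 1
#' aula_level(10, 110, 0)   # 4
#' aula_level(50, 50, 30)   # 3
#' aula_level(80, 0, 0)     # 2
#' @export
aula_level <- function(back_fe, shoulder_fe, elbow_fe) {
  n <- max(length(back_fe), length(shoulder_fe), length(elbow_fe))
  a <- rep_len(back_fe, n); b <- rep_len(shoulder_fe, n)
  g <- rep_len(elbow_fe, n)
  if (any(!is.finite(c(a, b, g)))) {
    stop("AULA angles must be finite (degrees)", call. = FALSE)
  }
  lvl <- integer(n)
  low <- a <= 22.5
  lvl[low] <- cut(b[low], c(-Inf, 22.5, 72.5, 105, Inf), labels = FALSE)
  mid <- a > 22.5 & a <= 72.5
  lvl[mid] <- ifelse(b[mid] > 72.5, 3L, ifelse(g[mid] > 22.5, 3L, 2L))
  lvl[a > 72.5] <- 2L
  as.integer(lvl)
}

#' Lower-limb (ALLA) risk level
#'
#' Kneeling is its own state and is pinned at level 3 irrespective of the knee
#' angle. Every other posture routes through the knee flexion angle:
#' level 2 up to 15 deg, 3 up to 45 deg, 4 up to 135 deg, and back to 3 beyond
#' 135 deg. Level 1 is reserved for sitting, which is out of scope, so it is
#' unreachable here.
#'
#' @param knee_fe knee flexion/extension angle(s), degrees. May be `NA` where
#'   `posture == "kneeling"`.
#' @param posture posture class label(s), see [posture_classes()].
#' @return Integer risk level(s) 2-4.
#' @examples
#' alla_level(10, "standing")    # 2
#' alla_level(90, "squatting")   # 4
#' alla_level(0, "kneeling")     # 3 (angle ignored)
#' @export
alla_level <- function(knee_fe, posture) {
  n <- max(length(knee_fe), length(posture))
  d <- rep_len(knee_fe, n)
  p <- assert_posture(rep_len(as.character(posture), n))
  kneel <- p == "kneeling"
  if (any(!is.finite(d[!kneel]))) {
    stop("knee angle must be finite except under kneeling", call. = FALSE)
  }
  lvl <- integer(n)
  lvl[kneel] <- 3L
  dk <- d[!kneel]
  lvl[!kneel] <- c(2L, 3L, 4L, 3L)[findInterval(dk, c(15, 45, 135),
                                                left.open = TRUE) + 1L]
  lvl
}

# rule grid: rows = ALLA level 1..4, cols = AULA level 1..4
AWBA_GRID <- matrix(
  c(1L, 2L, 3L, 3L,
    2L, 2L, 3L, 4L,
    3L, 3L, 3L, 4L,
    3L, 4L, 4L, 4L),
  nrow = 4, byrow = TRUE,
  dimnames = list(alla = 1:4, aula = 1:4))

#' Combine AULA and ALLA levels into the whole-body (AWBA) level
#'
#' Direct lookup in the published 4x4 rule grid.
#'
#' @param aula integer upper-body level(s) 1-4.
#' @param alla integer lower-limb level(s) 1-4.
#' @return Integer whole-body risk level(s) 1-4.
#' @export
awba_level <- function(aula, alla) {
  n <- max(length(aula), length(alla))
  aula <- rep_len(as.integer(aula), n); alla <- rep_len(as.integer(alla), n)
  if (any(aula < 1L | aula > 4L | alla < 1L | alla > 4L)) {
    stop("risk levels must lie in 1..4", call. = FALSE)
  }
  AWBA_GRID[cbind(alla, aula)]
}

#' Per-sample AWBA assessment of an angle series
#'
#' For each sample, AULA is evaluated on both arms and the worse (higher)
#' level is kept; ALLA uses the more flexed knee, plus the sample's posture
#' label (kneeling overrides the angle). The two are combined by
#' [awba_level()].
#'
#' @param series an [angle_series()] containing all 11 motions.
#' @param labels a [posture_label_series()] of the same length, required
#'   because kneeling changes the lower-limb rule.
#' @param config a [run_config()]; unused fields ignored.
#' @return data.frame with per-sample `t`, `aula`, `alla`, `awba`, `posture`.
#' @export
awba_series <- function(series, labels, config = run_config("awba")) {
  stopifnot(inherits(series, "angle_series"))
  missing <- setdiff(ALL_MOTIONS, names(series))
  if (length(missing) > 0L) {
    stop("series lacks motion(s) required by AWBA: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  labels <- as_posture_labels(labels)
  if (length(labels$posture) != nrow(series)) {
    stop(sprintf("posture labels (%d) do not cover the angle series (%d samples)",
                 length(labels$posture), nrow(series)), call. = FALSE)
  }
  aula <- pmax(
    aula_level(series$back_flexion_extension,
               series$shoulder_left_flexion_extension,
               series$elbow_left_flexion_extension),
    aula_level(series$back_flexion_extension,
               series$shoulder_right_flexion_extension,
               series$elbow_right_flexion_extension))
  knee <- pmax(series$knee_left_flexion_extension,
               series$knee_right_flexion_extension)
  alla <- alla_level(knee, labels$posture)
  data.frame(t = series$t, aula = aula, alla = alla,
             awba = awba_level(aula, alla),
             posture = labels$posture, stringsAsFactors = FALSE)
}
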