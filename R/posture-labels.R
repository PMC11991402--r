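# Posture labels: 1-s window labels from file or a classifier, broadcast to
# the per-sample cadence of the angle series.

#' Per-sample posture label series
#'
#' @param posture character vector of per-sample posture classes.
#' @param sample_rate Hz.
#' @param provenance where the labels came from: `"file"` (1-s window file,
#'   broadcast), `"classifier"`, or `"synthetic_truth"` (ground truth from the
#'   trial generator).
#' @param partial logical vector marking samples past the last full labelled
#'   window (these are labelled `"others"` and excluded from per-posture
#'   aggregates).
#' @return A list of class `posture_label_series`.
#' @export
posture_label_series <- function(posture, sample_rate = 20,
                                 provenance = c("file", "classifier",
                                                "synthetic_truth"),
                                 partial = rep(FALSE, length(posture))) {
  provenance <- match.arg(provenance)
  posture <- assert_posture(posture)
  stopifnot(length(partial) == length(posture), is.logical(partial))
  structure(list(posture = posture, sample_rate = sample_rate,
                 provenance = provenance, partial = partial),
            class = "posture_label_series")
}

as_posture_labels <- function(x) {
  if (inherits(x, "posture_label_series")) return(x)
  if (is.character(x) || is.factor(x)) {
    return(posture_label_series(as.character(x), provenance = "classifier"))
  }
  stop("cannot interpret object as posture labels", call. = FALSE)
}

#' @export
print.posture_label_series <- function(x, ...) {
  cat(sprintf("<posture_label_series> %d samples at %g Hz (%s)\n",
              length(x$posture), x$sample_rate, x$provenance))
  print(table(x$posture))
  invisible(x)
}

#' Read posture labels from CSV
#'
#' The file has a mandatory header and a `posture` column of class names; the
#' granularity (1-s windows vs per-sample) is declared by the caller through
#' `granularity`, or auto-detected against `n_samples` when given.
#'
#' @param path CSV path.
#' @param granularity `"window"` (one row per 1-s window, the native cadence
#'   of posture recognition) or `"sample"`.
#' @return Character vector of validated class labels (one per row).
#' @export
read_labels <- function(path, granularity = c("window", "sample")) {
  granularity <- match.arg(granularity)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"posture" %in% names(df)) {
    stop("label CSV must have a 'posture' column", call. = FALSE)
  }
  assert_posture(df$posture)
}

#' Write posture labels to CSV
#'
#' @param labels character vector of posture classes (window or sample
#'   granularity) or a [posture_label_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  if (inherits(labels, "posture_label_series")) labels <- labels$posture
  utils::write.csv(
    data.frame(window = seq_along(labels) - 1L, posture = labels),
    path, row.names = FALSE)
  invisible(path)
}

#' Broadcast 1-s window labels to per-sample resolution
#'
#' Posture recognition emits one label per non-overlapping 1-s window, while
#' ergonomic scores are computed per sample; each window label is therefore
#' repeated `sample_rate` times. Trailing samples beyond the last labelled
#' full window (at most one window's worth) are labelled `"others"` and
#' flagged `partial`, so they never enter per-posture aggregates.
#'
#' @param window_labels character vector, one class per 1-s window.
#' @param sample_rate Hz (samples per window).
#' @param n_samples length of the companion angle series.
#' @return A [posture_label_series()] of length `n_samples`.
#' @export
broadcast_windows <- function(window_labels, sample_rate = 20, n_samples) {
  window_labels <- assert_posture(window_labels)
  rate <- as.integer(round(sample_rate))
  covered <- length(window_labels) * rate
  if (n_samples - covered >= rate) {
    stop(sprintf(
      "label coverage error: %d windows cover %d samples but %d are required",
      length(window_labels), covered, n_samples), call. = FALSE)
  }
  full <- rep(window_labels, each = rate)[seq_len(min(covered, n_samples))]
  n_trail <- n_samples - length(full)
  posture_label_series(
    c(full, rep("others", n_trail)),
    sample_rate = sample_rate, provenance = "file",
    partial = c(rep(FALSE, length(full)), rep(TRUE, n_trail)))
}

#' Collapse per-sample labels back to window labels by majority vote
#'
#' Inverse of [broadcast_windows()] over full windows; useful for comparing a
#' per-sample classifier to window-level ground truth.
#'
#' @param labels a [posture_label_series()] or character vector.
#' @param sample_rate Hz.
#' @return Character vector, one label per full window.
#' @export
collapse_windows <- function(labels, sample_rate = 20) {
  if (inherits(labels, "posture_label_series")) labels <- labels$posture
  rate <- as.integer(round(sample_rate))
  n_win <- length(labels) %/% rate
  vapply(seq_len(n_win), function(w) {
    block <- labels[((w - 1L) * rate + 1L):(w * rate)]
    tab <- table(block)
    names(tab)[which.max(tab)]
  }, character(1))
}

# --- classifier plug-in registry -------------------------------------------
# A classifier is any function(window_angles) -> single posture class, where
# window_angles is the angle_series slice of one 1-s window. The deep-learning
# recogniser the framework was designed around is one such plug-in; it is not
# shipped here (its weights depend on a proprietary dataset), but the contract
# lets it drop in.

.classifiers <- new.env(parent = emptyenv())

#' Register or fetch a posture classifier plug-in
#'
#' @param name classifier name.
#' @param fn function taking a one-window `angle_series` slice (data.frame of
#'   angle columns) and returning one posture class string. Omit to fetch.
#' @return The classifier function, invisibly on registration.
#' @export
posture_classifier <- function(name, fn = NULL) {
  if (is.null(fn)) {
    f <- get0(name, envir = .classifiers)
    if (is.null(f)) stop("no classifier registered under ", sQuote(name),
                         call. = FALSE)
    return(f)
  }
  stopifnot(is.function(fn))
  assign(name, fn, envir = .classifiers)
  invisible(fn)
}

#' Classify every 1-s window of a series with a registered classifier
#'
#' @param series an [angle_series()].
#' @param name registered classifier name (default the built-in heuristic).
#' @return A [posture_label_series()] (per-sample, after broadcasting).
#' @export
classify_series <- function(series, name = "heuristic") {
  fn <- posture_classifier(name)
  rate <- as.integer(round(attr(series, "sample_rate")))
  n <- nrow(series)
  n_win <- n %/% rate
  wins <- vapply(seq_len(n_win), function(w) {
    slice <- as.data.frame(series)[((w - 1L) * rate + 1L):(w * rate), ,
                                   drop = FALSE]
    fn(slice)
  }, character(1))
  out <- broadcast_windows(wins, sample_rate = rate, n_samples = n)
  out$provenance <- "classifier"
  out
}

#' Heuristic angle-threshold posture classifier
#'
#' A deterministic rule set over window-mean back, knee and shoulder angles
#' and the within-window knee variability. It exists so synthetic pipelines
#' run end-to-end without a trained recogniser, and its thresholds sit halfway
#' between the synthetic posture templates; it makes no claim of validity on
#' real recordings.
#'
#' Rules, in order: deep back flexion with straight knees is stooping; deep
#' knee flexion splits into squatting (upright back) and kneeling (bent
#' back); a raised shoulder with an upright back is reaching; moderate back
#' and knee flexion together is lifting/lowering; an oscillating knee under a
#' near-neutral back is carrying (gait); everything near neutral with low
#' variability is standing; anything else is others.
#'
#' @param window data.frame slice of one 1-s window with the 11 motion columns.
#' @return One posture class string.
#' @export
heuristic_classify <- function(window) {
  m <- function(col) mean(window[[col]])
  back <- m("back_flexion_extension")
  knee <- max(m("knee_left_flexion_extension"), m("knee_right_flexion_extension"))
  shoulder <- max(m("shoulder_left_flexion_extension"),
                  m("shoulder_right_flexion_extension"))
  knee_sd <- max(stats::sd(window$knee_left_flexion_extension),
                 stats::sd(window$knee_right_flexion_extension))
  other_planes <- max(abs(m("back_lateral_bending")), abs(m("back_axial_rotation")))
  if (back > 70 && knee < 35) return("stooping")
  if (knee > 65 && back <= 30) return("squatting")
  if (knee > 65 && back > 30) return("kneeling")
  if (shoulder > 75 && back < 30) return("reaching")
  if (back > 30 && back <= 70 && knee > 30) return("lifting_lowering")
  if (knee_sd > 8 && back < 20) return("carrying")
  if (abs(back) < 15 && knee < 15 && shoulder < 25 && other_planes < 15 &&
      knee_sd <= 8) return("standing")
  "others"
}

# built-in registration at load time
.onLoad <- function(libname, pkgname) {
  posture_classifier("heuristic", heuristic_classify)
}
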