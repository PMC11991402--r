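# Work-shift report: associates per-sample ergonomic risk with posture
# classes, summarises wear threshold breaches, and serialises to JSON/HTML/PNG.

REPORT_SCHEMA_VERSION <- "1.0"

#' Build a work-shift report
#'
#' Aggregates per-sample risk by posture class: for each class the fraction
#' of labelled time spent in it and the arithmetic mean of the per-sample
#' risk measure (global LUBA score, or AWBA level) over its samples. Samples
#' flagged `partial` (past the last full labelled window) are excluded from
#' per-posture aggregates. Wear trajectories are summarised by their time
#' above the configured threshold, and the up-to-three longest-breaching
#' motions are listed.
#'
#' @param scores per-sample assessment: a [luba_score_series()] result
#'   (method `"luba"`) or an [awba_series()] result (method `"awba"`).
#' @param labels a [posture_label_series()] covering the samples.
#' @param wear optional named list of [wear_trajectory()] objects (LUBA only).
#' @param config a [run_config()].
#' @return A list of class `shift_report` with fields `schema_version`,
#'   `method`, `scope`, `n_trials`, `n_samples`, `per_posture`,
#'   `sequence_track`, `wear_summary`, `top_breaching_motions`.
#' @export
build_report <- function(scores, labels, wear = NULL,
                         config = run_config()) {
  labels <- as_posture_labels(labels)
  n <- nrow(scores)
  if (length(labels$posture) != n) {
    stop(sprintf("alignment error: %d score samples vs %d labels",
                 n, length(labels$posture)), call. = FALSE)
  }
  risk <- if (config$method == "luba") scores$g else scores$awba
  if (is.null(risk)) {
    stop("scores do not match method ", sQuote(config$method), call. = FALSE)
  }
  keep <- !labels$partial
  per_posture <- data.frame(posture = posture_classes(),
                            time_fraction = 0, mean_score = NA_real_,
                            stringsAsFactors = FALSE)
  n_lab <- sum(keep)
  for (i in seq_len(nrow(per_posture))) {
    sel <- keep & labels$posture == per_posture$posture[i]
    if (any(sel)) {
      per_posture$time_fraction[i] <- sum(sel) / n_lab
      per_posture$mean_score[i] <- mean(risk[sel])
    }
  }
  colour <- if (config$method == "luba") risk_colours(scores$category) else
    risk_colours(scores$awba)
  sequence_track <- data.frame(
    t = scores$t, risk = risk, posture = labels$posture,
    band = if (config$method == "luba") as.character(scores$category) else
      as.character(scores$awba),
    colour = colour, stringsAsFactors = FALSE)
  wear_summary <- NULL
  top <- character(0)
  if (!is.null(wear) && length(wear) > 0L) {
    stats_list <- lapply(wear, wear_threshold_stats,
                         threshold = config$wear_threshold)
    wear_summary <- data.frame(
      motion = names(wear),
      seconds_above = vapply(stats_list, `[[`, numeric(1), "seconds_above"),
      fraction_above = vapply(stats_list, `[[`, numeric(1), "fraction_above"),
      stringsAsFactors = FALSE, row.names = NULL)
    breaching <- wear_summary[wear_summary$seconds_above > 0, ]
    breaching <- breaching[order(-breaching$seconds_above, breaching$motion), ]
    top <- utils::head(breaching$motion, 3L)
  }
  structure(list(schema_version = REPORT_SCHEMA_VERSION,
                 method = config$method, scope = "single_trial",
                 n_trials = 1L, n_samples = as.integer(n),
                 wear_threshold = config$wear_threshold,
                 per_posture = per_posture,
                 sequence_track = sequence_track,
                 wear_summary = wear_summary,
                 top_breaching_motions = top),
            class = "shift_report")
}

#' Merge several shift reports
#'
#' Per-posture fields are unweighted means of the per-trial values: a trial
#' that never shows a posture contributes 0 to that posture's time fraction,
#' so merged fractions need not sum to 1. Mean scores average over the trials
#' in which the posture occurs. Wear summaries average per motion; the
#' per-sample sequence track is dropped (it has no cross-trial meaning).
#'
#' @param reports list of `shift_report`s with the same method.
#' @param scope label for the merged scope (default `"all_subjects"`).
#' @return A merged `shift_report`.
#' @export
merge_reports <- function(reports, scope = c("all_subjects", "per_subject")) {
  scope <- match.arg(scope)
  stopifnot(length(reports) >= 1L,
            all(vapply(reports, inherits, logical(1), "shift_report")))
  methods <- unique(vapply(reports, `[[`, character(1), "method"))
  if (length(methods) != 1L) {
    stop("cannot merge reports with mixed methods: ",
         paste(methods, collapse = ", "), call. = FALSE)
  }
  classes <- posture_classes()
  frac <- rowMeans(vapply(reports,
                          function(r) r$per_posture$time_fraction,
                          numeric(length(classes))))
  mean_mat <- vapply(reports, function(r) r$per_posture$mean_score,
                     numeric(length(classes)))
  mean_mat <- matrix(mean_mat, nrow = length(classes))
  ms <- apply(mean_mat, 1L, function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  })
  per_posture <- data.frame(posture = classes, time_fraction = frac,
                            mean_score = ms, stringsAsFactors = FALSE)
  wear_summary <- NULL
  top <- character(0)
  have_wear <- !vapply(reports, function(r) is.null(r$wear_summary), logical(1))
  if (all(have_wear)) {
    motions <- reports[[1L]]$wear_summary$motion
    sec <- rowMeans(vapply(reports, function(r) r$wear_summary$seconds_above,
                           numeric(length(motions))))
    fr <- rowMeans(vapply(reports, function(r) r$wear_summary$fraction_above,
                          numeric(length(motions))))
    wear_summary <- data.frame(motion = motions, seconds_above = sec,
                               fraction_above = fr, stringsAsFactors = FALSE)
    breaching <- wear_summary[wear_summary$seconds_above > 0, ]
    breaching <- breaching[order(-breaching$seconds_above, breaching$motion), ]
    top <- utils::head(breaching$motion, 3L)
  }
  structure(list(schema_version = REPORT_SCHEMA_VERSION,
                 method = methods, scope = scope,
                 n_trials = sum(vapply(reports, `[[`, integer(1), "n_trials")),
                 n_samples = sum(vapply(reports, `[[`, integer(1), "n_samples")),
                 wear_threshold = reports[[1L]]$wear_threshold,
                 per_posture = per_posture,
                 sequence_track = NULL,
                 wear_summary = wear_summary,
                 top_breaching_motions = top),
            class = "shift_report")
}

#' @export
print.shift_report <- function(x, ...) {
  cat(sprintf("<shift_report> method=%s scope=%s trials=%d samples=%d\n",
              x$method, x$scope, x$n_trials, x$n_samples))
  pp <- x$per_posture[x$per_posture$time_fraction > 0 |
                        !is.na(x$per_posture$mean_score), ]
  if (nrow(pp) > 0) {
    cat("time and mean risk per posture:\n")
    print(pp, row.names = FALSE, digits = 3)
  }
  if (length(x$top_breaching_motions) > 0) {
    cat("motions longest above the wear threshold:",
        paste(x$top_breaching_motions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a shift report to JSON
#'
#' Versioned schema; [read_report_json()] reconstructs an equal report.
#'
#' @param report a `shift_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "shift_report"))
  ok <- tryCatch({
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write report: ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}

#' Read a shift report from JSON
#'
#' @param path path to a JSON report written by [write_report_json()].
#' @return A `shift_report`.
#' @export
read_report_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$schema_version)) {
    stop("not a shift report: missing schema_version", call. = FALSE)
  }
  raw$n_trials <- as.integer(raw$n_trials)
  raw$n_samples <- as.integer(raw$n_samples)
  if (!is.null(raw$per_posture)) {
    raw$per_posture <- as.data.frame(raw$per_posture)
    if (!"mean_score" %in% names(raw$per_posture)) {
      raw$per_posture$mean_score <- NA_real_
    }
    raw$per_posture$mean_score <- as.numeric(raw$per_posture$mean_score)
  }
  if (!is.null(raw$sequence_track)) {
    raw$sequence_track <- as.data.frame(raw$sequence_track)
  }
  if (!is.null(raw$wear_summary)) raw$wear_summary <- as.data.frame(raw$wear_summary)
  if (is.null(raw$top_breaching_motions)) {
    raw$top_breaching_motions <- character(0)
  } else {
    raw$top_breaching_motions <- as.character(unlist(raw$top_breaching_motions))
  }
  structure(raw, class = "shift_report")
}
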