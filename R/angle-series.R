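# Angle time series container and CSV I/O.
#
# An angle_series is a plain data.frame (column `t` in seconds plus one column
# per joint motion, in degrees) with a `sample_rate` attribute. Signs follow
# the anatomical convention: flexion and abduction positive, extension and
# adduction negative; lateral bending and axial rotation are stored signed and
# scored on magnitude.

#' Construct an angle time series
#'
#' @param angles data.frame (or coercible) with one numeric column per joint
#'   motion, named as in [joint_motions()], and an optional `t` column in
#'   seconds. When `t` is absent it is reconstructed as `(0:(n-1))/sample_rate`.
#' @param sample_rate sampling frequency in Hz (default 20, the cadence of the
#'   wearable inertial capture this package targets).
#' @param method which motion set must be present: `"awba"` requires all 11
#'   motions, `"luba"` only the 9 upper-body ones (knees optional).
#' @return An object of class `angle_series`: a data.frame with `t` first,
#'   then the motion columns, and attribute `sample_rate`.
#' @export
angle_series <- function(angles, sample_rate = 20, method = c("awba", "luba")) {
  method <- match.arg(method)
  angles <- as.data.frame(angles)
  required <- joint_motions(method)
  missing <- setdiff(required, names(angles))
  if (length(missing) > 0L) {
    stop("angle series is missing required joint-motion column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("sample_rate must be a positive scalar (Hz)", call. = FALSE)
  }
  n <- nrow(angles)
  if (is.null(angles$t)) {
    angles$t <- if (n == 0L) numeric(0) else (seq_len(n) - 1L) / sample_rate
  }
  keep <- c("t", intersect(ALL_MOTIONS, names(angles)))
  angles <- angles[, keep, drop = FALSE]
  for (col in keep) {
    v <- angles[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))) & !is.na(v))
      stop(sprintf("non-numeric value in column '%s' (row %s)", col,
                   if (length(bad)) bad[1L] else "?"), call. = FALSE)
    }
    if (anyNA(v) || any(!is.finite(v))) {
      stop(sprintf("non-finite value in column '%s' (row %d)", col,
                   which(!is.finite(v))[1L]), call. = FALSE)
    }
  }
  ang_cols <- setdiff(keep, "t")
  over <- vapply(ang_cols, function(col) any(abs(angles[[col]]) > 360), logical(1))
  if (any(over)) {
    stop("implausible joint angle (|angle| > 360 deg) in column(s): ",
         paste(ang_cols[over], collapse = ", "), call. = FALSE)
  }
  if (n > 1L) {
    dt <- diff(angles$t)
    if (any(dt <= 0)) stop("time stamps must be strictly increasing", call. = FALSE)
    if (any(abs(dt - 1 / sample_rate) > 1e-6)) {
      stop(sprintf("non-uniform sampling: expected dt = %g s, found dt = %g s",
                   1 / sample_rate, dt[which.max(abs(dt - 1 / sample_rate))]),
           call. = FALSE)
    }
  }
  structure(angles, sample_rate = sample_rate,
            class = c("angle_series", "data.frame"))
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series> %d samples at %g Hz (%.2f s), %d joint motions\n",
              nrow(x), attr(x, "sample_rate"),
              if (nrow(x) > 0) nrow(x) / attr(x, "sample_rate") else 0,
              ncol(x) - 1L))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 4L))
  invisible(x)
}

#' Read an angle time series from CSV
#'
#' Expects a header row with one column per joint motion (named as in
#' [joint_motions()]) and an optional `t` column. Angles are degrees.
#'
#' @inheritParams angle_series
#' @param path path to a CSV file.
#' @return An [angle_series()].
#' @export
read_angle_series <- function(path, sample_rate = 20, method = c("awba", "luba")) {
  method <- match.arg(method)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in intersect(c("t", ALL_MOTIONS), names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric cell in column '%s' at data row %d of %s",
                     col, bad[1L], path), call. = FALSE)
      }
      df[[col]] <- num
    }
  }
  angle_series(df, sample_rate = sample_rate, method = method)
}

#' Write an angle time series to CSV
#'
#' @param series an [angle_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_angle_series <- function(series, path) {
  stopifnot(inherits(series, "angle_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}
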