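# Static report rendering: JSON, a templated HTML summary page, and PNG
# plots (wear-over-time with red/green phase bands, risk+posture sequence
# track, per-posture summary bars and time pie).

#' Render a shift report to files
#'
#' @param report a `shift_report`.
#' @param format `"json"`, `"html"` or `"png_plots"`.
#' @param dir output directory (created if needed).
#' @param wear optional named list of [wear_trajectory()] objects, used by
#'   `"png_plots"` for the wear-over-time figure.
#' @return Character vector of the files written.
#' @export
render_report <- function(report, format = c("json", "html", "png_plots"),
                          dir = ".", wear = NULL) {
  stopifnot(inherits(report, "shift_report"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  switch(format,
    json = {
      path <- file.path(dir, "report.json")
      write_report_json(report, path)
      path
    },
    html = render_html(report, file.path(dir, "report.html")),
    png_plots = render_plots(report, dir, wear))
}

render_html <- function(report, path) {
  pp <- report$per_posture
  shown <- pp[pp$time_fraction > 0 | !is.na(pp$mean_score), , drop = FALSE]
  rows <- if (nrow(shown) == 0) "" else paste(sprintf(
    "<tr><td>%s</td><td>%.1f%%</td><td>%s</td></tr>",
    shown$posture, 100 * shown$time_fraction,
    ifelse(is.na(shown$mean_score), "&mdash;",
           sprintf("%.2f", shown$mean_score))), collapse = "\n")
  wear_rows <- ""
  if (!is.null(report$wear_summary)) {
    ws <- report$wear_summary
    wear_rows <- paste(sprintf(
      "<tr><td>%s</td><td>%.1f s</td><td>%.1f%%</td></tr>",
      ws$motion, ws$seconds_above, 100 * ws$fraction_above), collapse = "\n")
  }
  html <- sprintf(
    "<!DOCTYPE html>\n<html><head><meta charset='utf-8'>\n<title>Work-shift ergonomic report</title>\n<style>body{font-family:sans-serif;margin:2em}table{border-collapse:collapse}td,th{border:1px solid #999;padding:4px 10px}</style>\n</head><body>\n<h1>Work-shift ergonomic report</h1>\n<p>Method: <b>%s</b> &middot; scope: %s &middot; trials: %d &middot; samples: %d &middot; schema v%s</p>\n<h2>Time and mean risk per posture</h2>\n<table><tr><th>Posture</th><th>Time</th><th>Mean risk</th></tr>\n%s\n</table>\n<h2>Kinematic wear above threshold (%.2f)</h2>\n%s\n<p>Longest-breaching motions: %s</p>\n</body></html>\n",
    report$method, report$scope, report$n_trials, report$n_samples,
    report$schema_version, rows, report$wear_threshold,
    if (nzchar(wear_rows))
      sprintf("<table><tr><th>Joint motion</th><th>Time above</th><th>%% of trial</th></tr>\n%s\n</table>", wear_rows)
    else "<p>No wear data.</p>",
    if (length(report$top_breaching_motions))
      paste(report$top_breaching_motions, collapse = ", ") else "none")
  writeLines(html, path)
  path
}

render_plots <- function(report, dir, wear = NULL) {
  files <- character(0)
  # per-posture summary: time pie + mean-risk bars, empty classes omitted
  pp <- report$per_posture[report$per_posture$time_fraction > 0, , drop = FALSE]
  if (nrow(pp) > 0) {
    f <- file.path(dir, "summary.png")
    grDevices::png(f, width = 900, height = 450)
    op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 3, 1))
    graphics::pie(pp$time_fraction, labels = pp$posture,
                  main = "Time per posture")
    graphics::barplot(pp$mean_score, names.arg = pp$posture, las = 2,
                      main = sprintf("Mean %s risk per posture",
                                     toupper(report$method)),
                      ylab = "mean risk")
    graphics::par(op)
    grDevices::dev.off()
    files <- c(files, f)
  }
  if (!is.null(report$sequence_track) && nrow(report$sequence_track) > 0) {
    st <- report$sequence_track
    f <- file.path(dir, "sequence.png")
    grDevices::png(f, width = 900, height = 420)
    graphics::plot(st$t, st$risk, type = "n", xlab = "time [s]",
                   ylab = if (report$method == "luba") "global LUBA score" else
                     "AWBA level",
                   main = "Risk and posture sequence")
    graphics::points(st$t, st$risk, col = st$colour, pch = 16, cex = 0.4)
    change <- c(TRUE, st$posture[-1] != st$posture[-nrow(st)])
    graphics::abline(v = st$t[change], col = "grey80", lty = 3)
    graphics::text(st$t[change], max(st$risk) * 0.98, st$posture[change],
                   srt = 90, adj = c(1, 0.5), cex = 0.6, col = "grey30")
    grDevices::dev.off()
    files <- c(files, f)
  }
  if (!is.null(wear) && length(wear) > 0) {
    f <- file.path(dir, "wear.png")
    grDevices::png(f, width = 900, height = 300 * length(wear))
    op <- graphics::par(mfrow = c(length(wear), 1), mar = c(4, 4, 2, 1))
    for (m in names(wear)) plot(wear[[m]], threshold = report$wear_threshold,
                                main = m)
    graphics::par(op)
    grDevices::dev.off()
    files <- c(files, f)
  }
  files
}

#' Plot a wear trajectory
#'
#' Wear samples are banded red, recovery samples green, with a dashed line at
#' the threshold and the driving score overlaid on a secondary scale.
#'
#' @param x a [wear_trajectory()].
#' @param threshold dashed threshold line (default 0.7).
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @export
plot.wear_trajectory <- function(x, threshold = 0.7,
                                 main = attr(x, "motion"), ...) {
  graphics::plot(x$t, x$value, type = "n", ylim = c(0, 1),
                 xlab = "time [s]", ylab = "kinematic wear", main = main, ...)
  runs <- rle(x$phase)
  ends <- cumsum(runs$lengths); starts <- c(1L, utils::head(ends, -1L) + 1L)
  for (k in seq_along(runs$values)) {
    graphics::rect(x$t[starts[k]], 0, x$t[ends[k]], 1, border = NA,
                   col = if (runs$values[k] == "wear")
                     grDevices::adjustcolor("red", 0.12) else
                       grDevices::adjustcolor("green", 0.12))
  }
  graphics::lines(x$t, x$value, lwd = 2)
  graphics::lines(x$t, (x$score - 1) / max(c(x$score - 1, 1)), col = "grey50",
                  lty = 1)
  graphics::abline(h = threshold, lty = 2, col = "red3")
  invisible(x)
}
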