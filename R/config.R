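# Run configuration: method selection plus the wear-model constants.

#' Run configuration for an assessment
#'
#' Bundles the method choice and the kinematic wear constants. Defaults follow
#' the calibration used throughout the package: the wear index saturates at
#' `v_max = 0.993` (five RC time constants, the point at which a capacitor is
#' conventionally considered fully charged) after `t_max = 240` s of sustained
#' mid-scale discomfort, the time after which a static low-force posture
#' becomes uncomfortable.
#'
#' @param method `"luba"` or `"awba"`.
#' @param sample_rate sampling frequency, Hz.
#' @param v_max asymptotic wear target in (0, 1) used for calibration.
#' @param t_max calibration time in seconds to reach `v_max` under the
#'   mid-scale score, and to recover back down from it.
#' @param wear_threshold wear level in (0, 1) above which accumulated postural
#'   hazard is flagged (default 0.7).
#' @param initial_wear wear index at trial start in \[0, 1\] (default 0;
#'   set > 0 to resume a shift).
#' @param arm_selection how the global LUBA score picks an arm:
#'   `"worst_sum"` (higher shoulder+elbow score sum, ties to the right),
#'   `"left"`, or `"right"`.
#' @param recovery_trigger `"motion"` (default: each motion recovers whenever
#'   its own score is minimal) or `"global"` (experimental: recovery only when
#'   the global score is minimal).
#' @param seed optional integer seed for stochastic components.
#' @return A list of class `run_config`.
#' @export
run_config <- function(method = c("luba", "awba"), sample_rate = 20,
                       v_max = 0.993, t_max = 240, wear_threshold = 0.7,
                       initial_wear = 0,
                       arm_selection = c("worst_sum", "left", "right"),
                       recovery_trigger = c("motion", "global"),
                       seed = NULL) {
  method <- match.arg(method)
  arm_selection <- match.arg(arm_selection)
  recovery_trigger <- match.arg(recovery_trigger)
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  chk(is.numeric(v_max) && length(v_max) == 1 && v_max > 0 && v_max < 1,
      "v_max must lie strictly between 0 and 1")
  chk(is.numeric(t_max) && length(t_max) == 1 && t_max > 0,
      "t_max must be positive (seconds)")
  chk(is.numeric(wear_threshold) && length(wear_threshold) == 1 &&
        wear_threshold > 0 && wear_threshold < 1,
      "wear_threshold must lie strictly between 0 and 1")
  chk(is.numeric(initial_wear) && length(initial_wear) == 1 &&
        initial_wear >= 0 && initial_wear <= 1,
      "initial_wear must lie in [0, 1]")
  chk(is.numeric(sample_rate) && length(sample_rate) == 1 && sample_rate > 0,
      "sample_rate must be positive (Hz)")
  if (!is.null(seed)) {
    chk(is.numeric(seed) && length(seed) == 1 && seed == as.integer(seed),
        "seed must be a single integer")
    seed <- as.integer(seed)
  }
  structure(list(method = method, sample_rate = sample_rate, v_max = v_max,
                 t_max = t_max, wear_threshold = wear_threshold,
                 initial_wear = initial_wear, arm_selection = arm_selection,
                 recovery_trigger = recovery_trigger, seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The file may define any subset of the [run_config()] fields; omitted fields
#' take their defaults. Unknown keys are an error, to catch typos.
#'
#' @param path path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, raw)
}

#' Write a run configuration to YAML
#'
#' @param config a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) cat(sprintf("  %-16s %s\n", k, format(x[[k]])))
  invisible(x)
}
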