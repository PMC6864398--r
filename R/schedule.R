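#' Pulse schedules: piecewise-constant growth-factor inputs
#'
#' A `pulse_schedule` describes the ligand concentration u(t) delivered to the
#' cells over an experiment: a baseline (pre-stimulation) interval followed by
#' an ordered set of non-overlapping dose episodes. Episodes are half-open
#' intervals `[onset, onset + duration)`, so washout is instantaneous, matching
#' step-like delivery by a flow chamber. Time is in minutes, dose in ng/ml.
#'
#' @param episodes data.frame with columns `onset`, `duration`, `dose`
#'   (minutes, minutes, ng/ml). May have zero rows (no stimulation).
#' @param baseline_min minutes of pre-stimulation recording (>= 0).
#' @param total_min total duration in minutes.
#' @param grid_step_min output sampling interval in minutes (default 2,
#'   the acquisition interval of the FRET time-lapse data this emulates).
#' @return An object of class `pulse_schedule`.
#' @export
pulse_schedule <- function(episodes, baseline_min, total_min,
                           grid_step_min = 2) {
  stopifnot(is.data.frame(episodes),
            all(c("onset", "duration", "dose") %in% names(episodes)))
  episodes <- episodes[, c("onset", "duration", "dose"), drop = FALSE]
  if (baseline_min < 0) stop("baseline_min must be >= 0")
  if (grid_step_min <= 0) stop("grid_step_min must be > 0")
  if (nrow(episodes) > 0) {
    if (any(episodes$duration <= 0)) stop("episode durations must be > 0")
    if (any(episodes$dose < 0)) stop("doses must be >= 0")
    if (is.unsorted(episodes$onset, strictly = TRUE))
      stop("episode onsets must be strictly increasing")
    ends <- episodes$onset + episodes$duration
    if (nrow(episodes) > 1 &&
        any(episodes$onset[-1] < ends[-nrow(episodes)] - 1e-9))
      stop("episodes must not overlap")
    if (episodes$onset[1] < baseline_min)
      stop("first onset must be >= baseline_min")
    if (total_min < max(ends))
      stop("schedule exceeds total_min")
  }
  structure(list(episodes = episodes, baseline_min = baseline_min,
                 total_min = total_min, grid_step_min = grid_step_min),
            class = "pulse_schedule")
}

#' Construct a named stimulation pattern
#'
#' Builds the stimulation patterns used throughout: `sustained` (one episode
#' from `baseline_min` to `total_min`), `single_pulse` (one episode of
#' `width_min`), `multi_pulse` (`n_pulses` episodes of `width_min` separated by
#' `pause_min`), and `mixed_pulse` (the fixed 3'/30'/20'/60'/5'
#' pulse/pause/pulse/pause/pulse sequence; `width_min`, `pause_min` and
#' `n_pulses` are ignored).
#'
#' @param kind one of `"sustained"`, `"single_pulse"`, `"multi_pulse"`,
#'   `"mixed_pulse"`.
#' @param dose dose in ng/ml (>= 0).
#' @param width_min pulse width in minutes (single/multi pulse).
#' @param pause_min pause between pulses in minutes (multi pulse).
#' @param n_pulses number of pulses (multi pulse).
#' @param baseline_min minutes before the first onset; default 40, the
#'   pre-stimulation normalization window.
#' @param total_min total duration; required for `sustained`, otherwise
#'   defaults to the last episode end plus a 20-minute tail, rounded up to the
#'   grid.
#' @param grid_step_min sampling interval (default 2).
#' @return A `pulse_schedule`.
#' @examples
#' sched <- make_schedule("multi_pulse", dose = 250, width_min = 3,
#'                        pause_min = 20, n_pulses = 3)
#' sched$episodes$onset  # 40, 63, 86
#' @export
make_schedule <- function(kind, dose, width_min = NULL, pause_min = NULL,
                          n_pulses = NULL, baseline_min = 40,
                          total_min = NULL, grid_step_min = 2) {
  kind <- match.arg(kind,
                    c("sustained", "single_pulse", "multi_pulse", "mixed_pulse"))
  if (dose < 0) stop("dose must be >= 0")
  if (baseline_min < 0) stop("baseline_min must be >= 0")
  eps <- switch(kind,
    sustained = {
      if (is.null(total_min)) stop("sustained schedule needs total_min")
      data.frame(onset = baseline_min,
                 duration = total_min - baseline_min, dose = dose)
    },
    single_pulse = {
      if (is.null(width_min) || width_min <= 0) stop("width_min must be > 0")
      data.frame(onset = baseline_min, duration = width_min, dose = dose)
    },
    multi_pulse = {
      if (is.null(width_min) || width_min <= 0) stop("width_min must be > 0")
      if (is.null(pause_min) || pause_min <= 0) stop("pause_min must be > 0")
      if (is.null(n_pulses) || n_pulses < 1) stop("n_pulses must be >= 1")
      onsets <- baseline_min + (seq_len(n_pulses) - 1) * (width_min + pause_min)
      data.frame(onset = onsets, duration = width_min, dose = dose)
    },
    mixed_pulse = {
      widths <- c(3, 20, 5)
      pauses <- c(30, 60)
      onsets <- baseline_min + cumsum(c(0, widths[1] + pauses[1],
                                        widths[2] + pauses[2]))
      data.frame(onset = onsets, duration = widths, dose = dose)
    })
  if (is.null(total_min)) {
    last_end <- max(eps$onset + eps$duration)
    total_min <- ceiling((last_end + 20) / grid_step_min) * grid_step_min
  }
  pulse_schedule(eps, baseline_min, total_min, grid_step_min)
}

#' Evaluate the input dose at a time point
#'
#' Piecewise-constant: returns the episode dose inside each half-open episode
#' interval `[onset, onset + duration)` and 0 elsewhere.
#'
#' @param schedule a `pulse_schedule`.
#' @param t time(s) in minutes, each within `[0, total_min]`.
#' @return Dose(s) in ng/ml, same length as `t`.
#' @export
schedule_dose <- function(schedule, t) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  if (any(t < 0 | t > schedule$total_min))
    stop("t outside [0, total_min]")
  out <- numeric(length(t))
  eps <- schedule$episodes
  for (i in seq_len(nrow(eps))) {
    inside <- t >= eps$onset[i] & t < eps$onset[i] + eps$duration[i]
    out[inside] <- eps$dose[i]
  }
  out
}

#' Sample a schedule on its regular output grid
#'
#' @param schedule a `pulse_schedule`.
#' @return data.frame with columns `time_min` (0, step, 2*step, ...,
#'   `total_min`) and `dose_ng_ml`.
#' @export
sample_grid <- function(schedule) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  tt <- seq(0, schedule$total_min, by = schedule$grid_step_min)
  data.frame(time_min = tt, dose_ng_ml = schedule_dose(schedule, tt))
}

#' @export
print.pulse_schedule <- function(x, ...) {
  cat("pulse_schedule: baseline", x$baseline_min, "min, total", x$total_min,
      "min, grid", x$grid_step_min, "min,", nrow(x$episodes), "episode(s)\n")
  if (nrow(x$episodes)) print(x$episodes, row.names = FALSE)
  invisible(x)
}

# episodes as the (onset, end, dose) matrix the compiled integrator expects
schedule_matrix <- function(schedule) {
  eps <- schedule$episodes
  cbind(onset = eps$onset, end = eps$onset + eps$duration, dose = eps$dose)
}

#' Serialize / deserialize a schedule
#'
#' `schedule_to_list()` gives a plain list suitable for JSON; `parse_schedule()`
#' accepts either a JSON config file with those keys, an inline
#' `"kind:dose:width:pause:n"` string, or a list.
#'
#' @param schedule a `pulse_schedule`.
#' @export
schedule_to_list <- function(schedule) {
  list(baseline_min = schedule$baseline_min, total_min = schedule$total_min,
       grid_step_min = schedule$grid_step_min,
       episodes = schedule$episodes)
}

#' @rdname schedule_to_list
#' @param x file path, inline string, or list.
#' @export
parse_schedule <- function(x) {
  if (inherits(x, "pulse_schedule")) return(x)
  if (is.character(x) && length(x) == 1 && file.exists(x))
    x <- jsonlite::read_json(x, simplifyVector = TRUE)
  if (is.character(x) && length(x) == 1) {
    parts <- strsplit(x, ":", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("inline schedule must be kind:dose[:width:pause:n]")
    num <- function(i) if (length(parts) >= i && nzchar(parts[i]))
      as.numeric(parts[i]) else NULL
    return(make_schedule(parts[1], dose = as.numeric(parts[2]),
                         width_min = num(3), pause_min = num(4),
                         n_pulses = num(5)))
  }
  if (is.list(x)) {
    if (!is.null(x$kind))
      return(make_schedule(x$kind, dose = x$dose_ng_ml,
                           width_min = x$width_min, pause_min = x$pause_min,
                           n_pulses = x$n_pulses,
                           baseline_min = x$baseline_min %||% 40,
                           total_min = x$total_min,
                           grid_step_min = x$grid_step_min %||% 2))
    return(pulse_schedule(as.data.frame(x$episodes), x$baseline_min,
                          x$total_min, x$grid_step_min %||% 2))
  }
  stop("cannot interpret schedule specification")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
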