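#' Moving-bar stimulus protocol
#'
#' Describes the direction set and trial timing of a moving-bar experiment.
#' Frame windows are half-open, 0-based intervals `[from, to)`, matching the
#' convention used throughout the package: `baseline_window` frames are the
#' pre-stimulus baseline, `stim_on_window` frames cover bar motion, and
#' `post_off_window` frames follow stimulus offset (where OFF-type cells
#' respond). Peak responses are extracted from the union of the stimulus-on
#' and post-offset windows.
#'
#' @param direction_angles_deg distinct motion directions in degrees,
#'   `[0, 360)`. Every direction must have its 180-degree opposite present
#'   (orientation averaging pairs opposite directions).
#' @param n_reps number of repetitions R of each direction.
#' @param frames_per_trial frames T recorded per trial.
#' @param frame_rate_hz acquisition rate in Hz.
#' @param baseline_window,stim_on_window,post_off_window integer frame
#'   intervals `c(from, to)`, half-open, 0-based, within `[0, T]`.
#' @return object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(direction_angles_deg = seq(0, 315, by = 45),
                              n_reps = 5L,
                              frames_per_trial = 48L,
                              frame_rate_hz = 10,
                              baseline_window = c(0L, 8L),
                              stim_on_window = c(8L, 28L),
                              post_off_window = c(28L, 40L)) {
  ang <- norm_dir_deg(as.numeric(direction_angles_deg))
  if (anyDuplicated(ang)) stop("stimulus directions must be distinct")
  if (length(ang) %% 2L != 0L) stop("n_directions must be even")
  opp <- norm_dir_deg(ang + 180)
  if (!all(vapply(opp, function(a) any(abs(a - ang) < 1e-9), logical(1))))
    stop("every direction needs its 180-degree opposite in the protocol")
  T <- as.integer(frames_per_trial)
  chk_win <- function(w, nm) {
    if (length(w) != 2L || w[1] < 0L || w[2] > T || w[1] >= w[2])
      stop("invalid ", nm, ": must be half-open [from, to) within [0, ", T, "]")
    as.integer(w)
  }
  out <- list(
    direction_angles_deg = ang,
    n_reps = as.integer(n_reps),
    frames_per_trial = T,
    frame_rate_hz = frame_rate_hz,
    baseline_window = chk_win(baseline_window, "baseline_window"),
    stim_on_window = chk_win(stim_on_window, "stim_on_window"),
    post_off_window = chk_win(post_off_window, "post_off_window")
  )
  class(out) <- "stimulus_protocol"
  out
}

## 1-based frame indices of a half-open 0-based window
window_frames <- function(w) (w[1] + 1L):w[2]

## 1-based frames of the response window (stim-on union post-off)
response_frames <- function(proto) {
  sort(unique(c(window_frames(proto$stim_on_window),
                window_frames(proto$post_off_window))))
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("Moving-bar stimulus protocol\n")
  cat("  directions:", paste(x$direction_angles_deg, collapse = ", "), "deg\n")
  cat("  reps:", x$n_reps, " frames/trial:", x$frames_per_trial,
      " rate:", x$frame_rate_hz, "Hz\n")
  cat("  stim-on frames [", x$stim_on_window[1], ",", x$stim_on_window[2],
      ")  post-off [", x$post_off_window[1], ",", x$post_off_window[2], ")\n")
  invisible(x)
}
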