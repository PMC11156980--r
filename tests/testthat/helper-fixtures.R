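## Shared fixtures: tiny protocols and hand-built response sets.

proto8 <- stimulus_protocol()   # 8 directions x 5 reps, 48 frames @ 10 Hz

## A response set whose every trial is `trace` scaled by the per-direction
## gain; no noise.
build_responses <- function(gains, trace, proto = proto8) {
  stopifnot(length(gains) == length(proto$direction_angles_deg),
            length(trace) == proto$frames_per_trial)
  rm <- lapply(gains, function(g)
    matrix(g * trace, proto$frames_per_trial, proto$n_reps))
  names(rm) <- as.character(proto$direction_angles_deg)
  rm
}

## Pulse trace: zero everywhere except the stimulus-on window.
pulse_trace <- function(proto = proto8, amp = 1) {
  tr <- numeric(proto$frames_per_trial)
  tr[(proto$stim_on_window[1] + 1):proto$stim_on_window[2]] <- amp
  tr
}

small_retina_config <- function(...) {
  args <- list(...)
  if (!"seed" %in% names(args)) args$seed <- 99L
  do.call(retina_config, c(list(n_fovs = 4L, cells_per_fov_mean = 40,
                                cells_per_fov_sd = 0), args))
}
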