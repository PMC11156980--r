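#' Baseline-normalize fluorescence to dF/F
#'
#' Computes (F - F0) / F0 where F0 is the mean of the non-stimulus
#' (baseline) frames, the standard normalization for slow calcium
#' indicators: frames during which the light stimulus occurred are excluded
#' so that F0 reflects resting fluorescence only.
#'
#' @param x raw fluorescence: a numeric vector (one ROI trace, time along
#'   the vector) or a 3-D array (x, y, time) movie.
#' @param stimulus_frames which frames are stimulus frames: a logical vector
#'   of length T, or integer frame indices (1-based). These are removed from
#'   the baseline.
#' @return dF/F with the same shape as `x`.
#' @export
compute_dfof <- function(x, stimulus_frames) {
  nt <- if (is.array(x) && length(dim(x)) == 3L) dim(x)[3] else length(x)
  if (is.logical(stimulus_frames)) {
    if (length(stimulus_frames) != nt)
      stop("logical stimulus_frames must have length T = ", nt)
    stim <- which(stimulus_frames)
  } else {
    stim <- as.integer(stimulus_frames)
    if (length(stim) && (min(stim) < 1L || max(stim) > nt))
      stop("stimulus frame indices out of range")
  }
  base <- setdiff(seq_len(nt), stim)
  if (length(base) == 0L)
    stop("no baseline frames: all frames are marked as stimulus")
  if (is.array(x) && length(dim(x)) == 3L) {
    f0 <- apply(x[, , base, drop = FALSE], c(1, 2), mean)
    if (any(f0 == 0)) stop("degenerate baseline: F0 = 0 for some pixels")
    sweep(sweep(x, c(1, 2), f0, "-"), c(1, 2), f0, "/")
  } else {
    f0 <- mean(x[base])
    if (f0 == 0) stop("degenerate baseline: F0 = 0")
    (x - f0) / f0
  }
}

#' Average peak dF/F response per stimulus direction
#'
#' For each direction, takes each repetition's maximum dF/F inside the
#' response window (stimulus-on union post-offset) and averages those maxima
#' across repetitions. Averaging outside the maximum is robust to trial-to-
#' trial timing jitter.
#'
#' @param rm named list of T x R dF/F matrices, one per direction; names are
#'   the direction angles in degrees.
#' @param proto a [stimulus_protocol()].
#' @return named numeric vector of peak responses, one per direction, in
#'   protocol direction order.
#' @export
peak_responses <- function(rm, proto) {
  fr <- response_frames(proto)
  if (length(fr) == 0L) stop("empty response window")
  key <- as.character(proto$direction_angles_deg)
  if (!all(key %in% names(rm)))
    stop("response matrices missing for directions: ",
         paste(setdiff(key, names(rm)), collapse = ", "))
  peaks <- vapply(key, function(k) {
    C <- rm[[k]]
    if (max(fr) > nrow(C)) stop("response window exceeds trial length")
    mean(apply(C[fr, , drop = FALSE], 2, max))
  }, numeric(1))
  names(peaks) <- key
  peaks
}

#' Response quality index
#'
#' Trial-to-trial reliability of a cell's response: the variance over time
#' of the across-repetition mean trace, divided by the across-repetition
#' mean of each repetition's variance over time,
#' \deqn{QI = Var_t[\langle C \rangle_r] / \langle Var_t[C] \rangle_r.}
#' QI equals 1 when all repetitions are identical (the mean trace carries
#' all the variance) and approaches 1/R for pure i.i.d. noise.
#'
#' @param x a T x R response matrix, or a list of such matrices (e.g. one
#'   per direction) which are concatenated along time so the index reflects
#'   the full stimulus sequence.
#' @return scalar QI in `(0, 1]`. If all traces are constant in time the
#'   denominator vanishes; QI is then defined as 0 and carries attribute
#'   `degenerate = TRUE` so batch pipelines can proceed.
#' @export
quality_index <- function(x) {
  C <- if (is.list(x)) do.call(rbind, x) else x
  stopifnot(is.matrix(C), nrow(C) >= 2L, ncol(C) >= 1L)
  num <- stats::var(rowMeans(C))
  den <- mean(apply(C, 2, stats::var))
  if (den == 0) {
    return(structure(0, degenerate = TRUE))
  }
  num / den
}

#' Direction tuning from peak responses
#'
#' Vector-sum direction tuning: \eqn{L_{dir} = |\sum_k R(\theta_k)
#' e^{i\theta_k}| / \sum_k R(\theta_k)}, with the preferred direction given
#' by the phase of the complex sum. The direction selectivity index
#' DSI = (pref - null)/(pref + null) contrasts the sampled direction nearest
#' the vector-sum direction ("pref") with its 180-degree opposite ("null").
#'
#' @param peaks nonnegative peak responses per direction (not all zero).
#' @param angles_deg matching direction angles in degrees.
#' @return list with `l_dir`, `dsi`, `pref_direction_deg` (vector-sum phase,
#'   `[0, 360)`) and `pref_direction_sampled_deg` (nearest sampled
#'   direction, used for the DSI contrast). Because "pref" is tied to the
#'   vector sum rather than the largest peak, DSI can be slightly negative
#'   for weakly tuned cells.
#' @export
direction_selectivity <- function(peaks, angles_deg) {
  peaks <- as.numeric(peaks)
  stopifnot(length(peaks) == length(angles_deg))
  if (any(peaks < 0)) stop("peaks must be nonnegative")
  tot <- sum(peaks)
  if (tot == 0) stop("undefined tuning: all peak responses are zero")
  z <- sum(peaks * exp(1i * deg2rad(angles_deg)))
  l_dir <- Mod(z) / tot
  pref <- norm_dir_deg(rad2deg(Arg(z)))
  dd <- abs(((angles_deg - pref) + 180) %% 360 - 180)
  ipref <- which.min(dd)
  inull <- which.min(abs(((angles_deg - (angles_deg[ipref] + 180)) + 180) %% 360 - 180))
  rp <- peaks[ipref]; rn <- peaks[inull]
  dsi <- if (rp + rn == 0) 0 else (rp - rn) / (rp + rn)
  list(l_dir = l_dir, dsi = dsi,
       pref_direction_deg = pref,
       pref_direction_sampled_deg = norm_dir_deg(angles_deg[ipref]))
}

#' Orientation tuning from peak responses
#'
#' Vector-sum tuning in double-angle (orientation) space:
#' \eqn{L_{ori} = |\sum_k R(\theta_k) e^{2i\theta_k}| / \sum_k R(\theta_k)};
#' half the phase of the complex sum is the preferred orientation, folded
#' into `[0, 180)`. The orientation selectivity index is computed on the
#' four orientation-averaged responses (opposite directions averaged):
#' OSI = (pref - orthogonal)/(pref + orthogonal), where "pref" is the
#' sampled orientation with the largest averaged response — which can differ
#' from the vector-sum phase; both are returned.
#'
#' @inheritParams direction_selectivity
#' @return list with `l_ori`, `osi`, `pref_orientation_deg` (vector-sum
#'   phase / 2), `pref_orientation_sampled_deg` (argmax of the
#'   orientation-averaged responses) and `orientation_peaks` (the averaged
#'   responses, named by orientation angle).
#' @export
orientation_selectivity <- function(peaks, angles_deg) {
  peaks <- as.numeric(peaks)
  stopifnot(length(peaks) == length(angles_deg))
  if (any(peaks < 0)) stop("peaks must be nonnegative")
  tot <- sum(peaks)
  if (tot == 0) stop("undefined tuning: all peak responses are zero")
  z <- sum(peaks * exp(2i * deg2rad(angles_deg)))
  l_ori <- Mod(z) / tot
  pref_vec <- norm_axis_deg(rad2deg(Arg(z)) / 2)
  ## average responses of opposite-direction pairs -> orientations
  ori <- norm_axis_deg(angles_deg)
  uori <- sort(unique(round(ori, 9)))
  opeaks <- vapply(uori, function(o) mean(peaks[abs(ori - o) < 1e-9]), numeric(1))
  names(opeaks) <- format(uori, trim = TRUE)
  ipref <- which.max(opeaks)
  iorth <- which.min(axis_diff_deg(uori, uori[ipref] + 90))
  rp <- opeaks[ipref]; ro <- opeaks[iorth]
  osi <- if (rp + ro == 0) 0 else (rp - ro) / (rp + ro)
  list(l_ori = l_ori, osi = unname(osi),
       pref_orientation_deg = pref_vec,
       pref_orientation_sampled_deg = uori[ipref],
       orientation_peaks = opeaks)
}

#' Per-cell tuning summary
#'
#' Runs the full per-cell response characterization — quality index, peak
#' extraction and the four selectivity statistics with preferred angles —
#' and returns one row per cell.
#'
#' @param responses named list (by cell id) of per-cell response sets, each
#'   a named list of T x R dF/F matrices keyed by direction angle.
#' @param proto a [stimulus_protocol()].
#' @return data.frame with columns `cell_id`, `qi`, `qi_degenerate`,
#'   `l_dir`, `dsi`, `pref_direction_deg`, `l_ori`, `osi`,
#'   `pref_orientation_deg`, `pref_orientation_sampled_deg` and one
#'   `peak_<angle>` column per direction.
#' @export
summarize_tuning <- function(responses, proto) {
  rows <- lapply(names(responses), function(id) {
    rm <- responses[[id]]
    qi <- quality_index(rm)
    peaks <- peak_responses(rm, proto)
    ds <- direction_selectivity(peaks, proto$direction_angles_deg)
    os <- orientation_selectivity(peaks, proto$direction_angles_deg)
    pk <- as.list(peaks)
    names(pk) <- paste0("peak_", names(peaks))
    c(list(cell_id = id,
           qi = as.numeric(qi),
           qi_degenerate = isTRUE(attr(qi, "degenerate")),
           l_dir = ds$l_dir, dsi = ds$dsi,
           pref_direction_deg = ds$pref_direction_deg,
           l_ori = os$l_ori, osi = os$osi,
           pref_orientation_deg = os$pref_orientation_deg,
           pref_orientation_sampled_deg = os$pref_orientation_sampled_deg),
      pk)
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
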