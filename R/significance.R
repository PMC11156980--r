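#' Filter cells by response quality
#'
#' Retains cells whose quality index strictly exceeds the threshold
#' (QI > 0.6 by default); a cell at exactly the threshold is dropped.
#'
#' @param summaries data.frame with a `qi` column (e.g. from
#'   [summarize_tuning()]).
#' @param threshold QI threshold.
#' @return the retained rows, with attributes `n_retained` and `n_dropped`.
#' @export
quality_filter <- function(summaries, threshold = 0.6) {
  stopifnot("qi" %in% names(summaries))
  keep <- summaries$qi > threshold
  out <- summaries[keep, , drop = FALSE]
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

## deterministic per-cell RNG substream seed from (global seed, cell index)
cell_substream_seed <- function(seed, cell_index) {
  (as.integer(seed) + 7919L * (as.integer(cell_index) %% 100003L)) %% 2147483647L
}

#' Block-shuffled permutation test of tuning significance
#'
#' Tests whether a cell's L_dir or L_ori exceeds chance by block-shuffling
#' the direction labels: a block is one whole trial (all frames of one bar
#' presentation), so within-trial autocorrelation is preserved while the
#' trial-to-direction assignment is permuted. For each of `n_perms`
#' permutations the peak responses and the statistic are recomputed; the
#' cell is significant iff its observed statistic is strictly greater than
#' more than 95% of the permuted statistics (ties count against
#' significance, which is conservative for degenerate cells).
#'
#' Because the per-trial maxima inside the response window do not change
#' under relabeling, they are computed once and only re-aggregated per
#' permutation.
#'
#' @param rm per-cell response set (named list of T x R matrices by
#'   direction).
#' @param proto a [stimulus_protocol()].
#' @param stat_kind `"l_ori"` or `"l_dir"`.
#' @param n_perms number of permutations (1000 in the standard procedure).
#' @param rng_seed integer seed for the permutation stream, so results are
#'   reproducible regardless of evaluation order.
#' @param rank_threshold required exceedance fraction (0.95).
#' @return object of class `permutation_result`: `observed_stat`,
#'   `perm_stats`, `rank_fraction` (fraction of permuted stats strictly
#'   below observed), `significant`, `stat_kind`, `n_perms`.
#' @export
permutation_test <- function(rm, proto, stat_kind = c("l_ori", "l_dir"),
                             n_perms = 1000L, rng_seed = 1L,
                             rank_threshold = 0.95) {
  stat_kind <- match.arg(stat_kind)
  stopifnot(n_perms >= 1L)
  angles <- proto$direction_angles_deg
  k <- length(angles)
  R <- proto$n_reps
  fr <- response_frames(proto)
  key <- as.character(angles)
  if (!all(key %in% names(rm))) stop("response matrices missing for some directions")
  ## per-trial maxima, ordered direction-major (R trials per direction)
  m <- unlist(lapply(key, function(kk) {
    C <- rm[[kk]]
    if (ncol(C) != R) stop("inconsistent repetition count")
    apply(C[fr, , drop = FALSE], 2, max)
  }), use.names = FALSE)
  n_trials <- k * R
  if (n_trials < k) stop("fewer trials than directions")

  mult <- if (stat_kind == "l_ori") 2 else 1
  z <- exp(mult * 1i * deg2rad(angles))
  peaks_obs <- colMeans(matrix(m, nrow = R))
  tot <- sum(peaks_obs)
  observed <- if (tot == 0) 0 else Mod(sum(peaks_obs * z)) / tot

  set.seed(rng_seed)
  perm_idx <- vapply(seq_len(n_perms), function(i) sample.int(n_trials),
                     integer(n_trials))
  M <- matrix(m[perm_idx], nrow = n_trials)
  dim(M) <- c(R, k, n_perms)
  peaks_perm <- colMeans(M)                        # k x n_perms
  tots <- colSums(peaks_perm)
  num <- Mod(colSums(peaks_perm * z))
  perm_stats <- ifelse(tots == 0, 0, num / tots)

  rank_fraction <- mean(perm_stats < observed)
  structure(list(observed_stat = observed,
                 n_perms = as.integer(n_perms),
                 perm_stats = perm_stats,
                 rank_fraction = rank_fraction,
                 significant = rank_fraction > rank_threshold,
                 stat_kind = stat_kind),
            class = "permutation_result")
}

#' Classify cells from their pair of significance flags
#'
#' @param sig_ori,sig_dir logical vectors: per-cell significance of L_ori
#'   and L_dir.
#' @return character vector with levels `OS`, `DS`, `both`, `none`. Both
#'   flags should be kept alongside: downstream OS analyses include cells
#'   flagged `both` (the overlap is <1% of neurons).
#' @export
classify_cells <- function(sig_ori, sig_dir) {
  stopifnot(length(sig_ori) == length(sig_dir))
  ifelse(sig_ori & sig_dir, "both",
         ifelse(sig_ori, "OS", ifelse(sig_dir, "DS", "none")))
}

#' Run both permutation tests for every cell
#'
#' Convenience batch driver: runs the L_ori and L_dir permutation tests per
#' cell with a per-cell RNG substream derived from `(seed, cell index)`, so
#' parallel or reordered evaluation cannot change results, and appends
#' significance columns and the selectivity class.
#'
#' @param responses named list of per-cell response sets.
#' @param summaries tuning summary data.frame with a `cell_id` column; one
#'   row per entry of `responses`.
#' @param proto a [stimulus_protocol()].
#' @param n_perms,rank_threshold see [permutation_test()].
#' @param seed global seed for the per-cell substreams.
#' @return `summaries` with added columns `sig_ori`, `sig_dir`,
#'   `rank_ori`, `rank_dir`, `selectivity_class`.
#' @export
test_selectivity <- function(responses, summaries, proto,
                             n_perms = 1000L, rank_threshold = 0.95,
                             seed = 1L) {
  stopifnot(all(summaries$cell_id %in% names(responses)))
  n <- nrow(summaries)
  sig_ori <- logical(n); sig_dir <- logical(n)
  rank_ori <- numeric(n); rank_dir <- numeric(n)
  for (i in seq_len(n)) {
    rm <- responses[[summaries$cell_id[i]]]
    po <- permutation_test(rm, proto, "l_ori", n_perms,
                           cell_substream_seed(seed, i), rank_threshold)
    pd <- permutation_test(rm, proto, "l_dir", n_perms,
                           cell_substream_seed(seed, i) + 1L, rank_threshold)
    sig_ori[i] <- po$significant; rank_ori[i] <- po$rank_fraction
    sig_dir[i] <- pd$significant; rank_dir[i] <- pd$rank_fraction
  }
  summaries$sig_ori <- sig_ori
  summaries$sig_dir <- sig_dir
  summaries$rank_ori <- rank_ori
  summaries$rank_dir <- rank_dir
  summaries$selectivity_class <- classify_cells(sig_ori, sig_dir)
  summaries
}
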