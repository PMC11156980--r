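#' Histogram of preferred orientations
#'
#' Bins axis angles over `[0, 180)`. For polar display each axis is
#' duplicated at `phi` and `phi + 180` (an axis has no arrowhead); the
#' returned counts are over `[0, 180)` and conserve the sample size.
#'
#' @param axis_deg axis angles in degrees, `[0, 180)`.
#' @param bin_deg bin width in degrees (must divide 180).
#' @return data.frame `(bin_lo_deg, bin_mid_deg, count)`; zero rows of
#'   counts for an empty input, not an error.
#' @export
orientation_histogram <- function(axis_deg, bin_deg = 10) {
  if (180 %% bin_deg != 0) stop("bin_deg must divide 180")
  breaks <- seq(0, 180, by = bin_deg)
  mids <- breaks[-length(breaks)] + bin_deg / 2
  if (length(axis_deg) == 0)
    return(data.frame(bin_lo_deg = breaks[-length(breaks)],
                      bin_mid_deg = mids,
                      count = rep(0L, length(mids))))
  a <- norm_axis_deg(axis_deg)
  cnt <- as.integer(table(cut(a, breaks = breaks, right = FALSE,
                              include.lowest = TRUE)))
  data.frame(bin_lo_deg = breaks[-length(breaks)], bin_mid_deg = mids,
             count = cnt)
}

#' Signed deviation of an axis from the ventral cardinal axis
#'
#' The ventral cardinal axis is the vertical (90-270 degree) axis. The
#' deviation is the smallest signed rotation taking the ventral axis to the
#' given axis, `dev = 90 - axis`, in `(-90, 90]`: negative in ventronasal-
#' leaning axes, positive in ventrotemporal-leaning ones (so concentric
#' circles at the optic nerve give -45 on the VN axis and +45 on the VT
#' axis), and the horizontal axis maps to +90 by convention. The inverse is
#' `axis = 90 - dev` (mod 180).
#'
#' @param axis_deg axis angles in degrees, `[0, 180)`.
#' @return signed deviations in degrees, `(-90, 90]`.
#' @export
deviation_from_ventral <- function(axis_deg) {
  if (any(axis_deg < 0 | axis_deg >= 180))
    stop("axis angles must lie in [0, 180)")
  90 - axis_deg
}

#' Per-FOV deviation from ventral versus distance from the optic nerve
#'
#' For every field of view, takes the double-angle circular mean of its
#' cells' preferred orientations, converts to signed deviation from the
#' ventral axis, and pairs it with the FOV center's distance from the optic
#' nerve. FOVs with no cells are skipped with a message.
#'
#' @param samples data.frame with `fov_id` and `pref_orientation_deg`
#'   (typically the overrepresented OS cells).
#' @param fovs data.frame with `fov_id`, `distance_um` and `quadrant`.
#' @return list with `fov_curve` (`fov_id`, `quadrant`, `distance_um`, `n`,
#'   `mean_axis_deg`, `deviation_deg`, sorted by distance) and `cells`
#'   (per-cell scatter: `fov_id`, `distance_um`, `deviation_deg`).
#' @export
deviation_vs_distance <- function(samples, fovs) {
  stopifnot(all(c("fov_id", "pref_orientation_deg") %in% names(samples)))
  rows <- lapply(seq_len(nrow(fovs)), function(i) {
    id <- fovs$fov_id[i]
    a <- samples$pref_orientation_deg[samples$fov_id == id]
    if (length(a) == 0) {
      message("deviation_vs_distance: FOV ", id, " has no cells; skipped")
      return(NULL)
    }
    cm <- circular_mean_axis(a)
    data.frame(fov_id = id, quadrant = fovs$quadrant[i],
               distance_um = fovs$distance_um[i],
               center_x_um = fovs$center_x_um[i],
               center_y_um = fovs$center_y_um[i],
               n = length(a),
               mean_axis_deg = cm$mean_axis_deg,
               deviation_deg = deviation_from_ventral(cm$mean_axis_deg),
               stringsAsFactors = FALSE)
  })
  curve <- do.call(rbind, rows)
  if (!is.null(curve)) curve <- curve[order(curve$distance_um), , drop = FALSE]
  m <- match(samples$fov_id, fovs$fov_id)
  cells <- data.frame(fov_id = samples$fov_id,
                      distance_um = fovs$distance_um[m],
                      deviation_deg = deviation_from_ventral(
                        norm_axis_deg(samples$pref_orientation_deg)),
                      stringsAsFactors = FALSE)
  list(fov_curve = curve, cells = cells)
}

#' Vector flow field of preferred orientations
#'
#' Grids the retina and reports per bin the double-angle circular mean axis
#' of the cells inside, the resultant length (coherence, 1 = all axes
#' aligned) and the cell count. Bins with fewer than `min_n` cells are
#' dropped; bins whose resultant falls below `resultant_min` (near-complete
#' cancellation, e.g. an orthogonal 50/50 mixture) keep their count but
#' report an undefined (`NA`) mean axis.
#'
#' @param samples data.frame with `x_um`, `y_um`, `pref_orientation_deg`.
#' @param grid_um grid spacing in um.
#' @param min_n minimum cells per reported bin.
#' @param resultant_min coherence below which the mean axis is undefined.
#' @return data.frame `(bin_x_um, bin_y_um, n, mean_axis_deg, resultant)`.
#' @export
flow_field <- function(samples, grid_um = 100, min_n = 5, resultant_min = 0.1) {
  stopifnot(all(c("x_um", "y_um", "pref_orientation_deg") %in% names(samples)))
  bx <- floor(samples$x_um / grid_um)
  by <- floor(samples$y_um / grid_um)
  key <- paste(bx, by, sep = ":")
  rows <- lapply(split(seq_len(nrow(samples)), key), function(ii) {
    if (length(ii) < min_n) return(NULL)
    cm <- circular_mean_axis(samples$pref_orientation_deg[ii],
                             resultant_min = resultant_min)
    data.frame(bin_x_um = (bx[ii[1]] + 0.5) * grid_um,
               bin_y_um = (by[ii[1]] + 0.5) * grid_um,
               n = length(ii),
               mean_axis_deg = cm$mean_axis_deg,
               resultant = cm$resultant)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(bin_x_um = numeric(0), bin_y_um = numeric(0),
                      n = integer(0), mean_axis_deg = numeric(0),
                      resultant = numeric(0))
  rownames(out) <- NULL
  out[order(out$bin_x_um, out$bin_y_um), , drop = FALSE]
}

## two-sample KS statistic without p-value machinery (used in permutations)
ks_stat <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  ord <- order(pooled)
  w <- c(rep(1 / na, na), rep(-1 / nb, nb))[ord]
  max(abs(cumsum(w)))
}

#' Compare deviation distributions between two retinal regions
#'
#' Two-sample Kolmogorov-Smirnov test plus a label-permutation test using
#' the KS D statistic, applied to per-cell deviation (or orientation)
#' values split into two groups (e.g. more-ventral vs less-ventral FOVs).
#'
#' @param values numeric per-cell values (e.g. deviation from ventral in
#'   degrees).
#' @param group logical or two-level vector splitting the cells; both
#'   groups must be nonempty.
#' @param split_rule character description of the split, echoed in errors
#'   and the result.
#' @param n_perm number of label permutations.
#' @param seed permutation RNG seed.
#' @return object of class `distribution_comparison`: `ks_statistic`,
#'   `ks_p` (asymptotic), `perm_p` (permutation), `n_a`, `n_b`,
#'   `split_rule`.
#' @export
compare_regions <- function(values, group, split_rule = "user split",
                            n_perm = 10000L, seed = 1L) {
  g <- as.factor(group)
  if (nlevels(g) != 2L)
    stop("split '", split_rule, "' must produce exactly 2 groups")
  a <- values[g == levels(g)[1]]
  b <- values[g == levels(g)[2]]
  if (length(a) == 0 || length(b) == 0)
    stop("split '", split_rule, "' leaves an empty group")
  ks <- suppressWarnings(stats::ks.test(a, b))
  D <- unname(ks$statistic)
  set.seed(seed)
  n <- length(values)
  na <- length(a)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n, na)
    if (ks_stat(values[idx], values[-idx]) >= D) exceed <- exceed + 1L
  }
  structure(list(ks_statistic = D,
                 ks_p = unname(ks$p.value),
                 perm_p = (exceed + 1) / (n_perm + 1),
                 n_a = length(a), n_b = length(b),
                 split_rule = split_rule),
            class = "distribution_comparison")
}

#' @export
print.distribution_comparison <- function(x, ...) {
  cat("Region comparison (", x$split_rule, ")\n", sep = "")
  cat(sprintf("  n = %d vs %d;  KS D = %.4f (p = %.3g);  permutation p = %.3g\n",
              x$n_a, x$n_b, x$ks_statistic, x$ks_p, x$perm_p))
  invisible(x)
}
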