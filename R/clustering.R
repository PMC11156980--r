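#' ON-OFF response feature vector of a cell
#'
#' Averages the cell's dF/F traces over repetitions and directions, crops
#' to the stimulus-on and post-offset windows (where ON and OFF responses
#' live), resamples to a fixed length by linear interpolation, and
#' peak-normalizes, yielding a shape-only descriptor of the cell's
#' onset/offset response.
#'
#' @param rm per-cell response set (named list of T x R matrices).
#' @param proto a [stimulus_protocol()].
#' @param out_len length of the resampled feature vector.
#' @return numeric feature vector of length `out_len`; attribute
#'   `degenerate = TRUE` flags a zero-peak (flat) trace, returned
#'   un-normalized.
#' @export
extract_onoff_features <- function(rm, proto, out_len = 40L) {
  avg <- Reduce(`+`, lapply(rm, rowMeans)) / length(rm)
  fr <- c(window_frames(proto$stim_on_window),
          window_frames(proto$post_off_window))
  v <- avg[fr]
  v <- stats::approx(seq_along(v), v, n = out_len)$y
  pk <- max(abs(v))
  if (pk == 0) return(structure(v, degenerate = TRUE))
  v / pk
}

#' Silhouette values of a clustering
#'
#' Per-point clustering fitness `SV(i) = (b(i) - a(i)) / max(a(i), b(i))`,
#' where cohesion `a(i)` is the average Euclidean distance from point i to
#' the other members of its cluster and separation `b(i)` is the smallest
#' average distance from i to the points of any other cluster. SV near 1
#' means well clustered, near 0 ambiguous. Points in singleton clusters get
#' SV = 0 (the standard convention).
#'
#' @param points numeric matrix (rows = points) or vector (1-D points).
#' @param labels cluster labels, one per point; at least 2 distinct
#'   clusters, all nonempty.
#' @return list with `sv` (per point) and `mean_sv`.
#' @export
silhouette_values <- function(points, labels) {
  if (is.vector(points)) points <- matrix(points, ncol = 1)
  labels <- as.vector(labels)
  stopifnot(nrow(points) == length(labels))
  ulab <- unique(labels)
  if (length(ulab) < 2L) stop("silhouette requires k >= 2 clusters")
  D <- as.matrix(stats::dist(points))
  n <- nrow(points)
  sv <- numeric(n)
  idx <- split(seq_len(n), labels)
  for (i in seq_len(n)) {
    own <- idx[[as.character(labels[i])]]
    if (length(own) == 1L) { sv[i] <- 0; next }
    a <- sum(D[i, own]) / (length(own) - 1L)
    b <- min(vapply(idx[names(idx) != as.character(labels[i])],
                    function(j) mean(D[i, j]), numeric(1)))
    sv[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  list(sv = sv, mean_sv = mean(sv))
}

#' Cluster features and choose k by silhouette analysis
#'
#' Iterates k-means over a range of cluster numbers (best of `restarts`
#' starts by within-cluster sum of squares), scores each k by the mean
#' silhouette value, and picks the k with the largest mean SV. A
#' permuted-data control — features shuffled across cells independently per
#' dimension, destroying joint structure while keeping marginals — reports
#' the null mean-SV curve for comparison.
#'
#' @param features numeric matrix, rows = cells.
#' @param k_range candidate cluster counts (2..10 in the standard
#'   procedure); needs `nrow(features) > max(k_range)`.
#' @param restarts k-means restarts per k.
#' @param seed integer seed (k-means initialization and the permuted
#'   control).
#' @param n_null number of permuted-control replicates averaged into the
#'   null curve.
#' @return object of class `cluster_solution`: `k_range`, `mean_sv`,
#'   `permuted_mean_sv`, `chosen_k`, `labels`, `sv_per_cell`, `centers`,
#'   and `solutions` (labels for every k).
#' @export
cluster_and_select_k <- function(features, k_range = 2:10, restarts = 10L,
                                 seed = 1L, n_null = 3L) {
  if (is.vector(features)) features <- matrix(features, ncol = 1)
  n <- nrow(features)
  if (n <= max(k_range)) stop("need more points than the largest k")
  if (all(apply(features, 2, function(c) length(unique(c)) == 1L)))
    stop("degenerate features: all cells identical")
  set.seed(seed)
  run_curve <- function(X) {
    labs <- vector("list", length(k_range))
    msv <- numeric(length(k_range))
    for (j in seq_along(k_range)) {
      km <- stats::kmeans(X, centers = k_range[j], nstart = restarts,
                          iter.max = 100)
      labs[[j]] <- km$cluster
      msv[j] <- silhouette_values(X, km$cluster)$mean_sv
    }
    list(labels = labs, mean_sv = msv)
  }
  obs <- run_curve(features)
  null_curves <- replicate(n_null, {
    perm <- apply(features, 2, sample)
    run_curve(perm)$mean_sv
  })
  null_msv <- rowMeans(matrix(null_curves, nrow = length(k_range)))
  j_best <- which.max(obs$mean_sv)
  labels <- obs$labels[[j_best]]
  svb <- silhouette_values(features, labels)
  centers <- do.call(rbind, lapply(sort(unique(labels)), function(l)
    colMeans(features[labels == l, , drop = FALSE])))
  structure(list(k_range = k_range,
                 mean_sv = obs$mean_sv,
                 permuted_mean_sv = null_msv,
                 chosen_k = k_range[j_best],
                 labels = labels,
                 sv_per_cell = svb$sv,
                 centers = centers,
                 solutions = obs$labels),
            class = "cluster_solution")
}

#' Name ON-OFF clusters as functional subtypes
#'
#' Assigns each cluster of ON-OFF features to ONs, ONt or OFF by template
#' matching on the cluster centroid: a centroid whose peak lies in the
#' post-offset segment of the feature is OFF; otherwise the sustainedness
#' of the onset response (mean of the late stimulus-on segment relative to
#' the peak) separates ONs (sustained, >= `sustain_threshold`) from ONt
#' (transient). A centroid with no positive peak is labeled `unassigned`
#' rather than silently misnamed.
#'
#' @param solution a [cluster_and_select_k()] result on ON-OFF features.
#' @param proto the [stimulus_protocol()] the features were built from
#'   (fixes where the onset/offset segments fall in the feature vector).
#' @param out_len feature length used in [extract_onoff_features()].
#' @param sustain_threshold late-onset mean / peak ratio above which an ON
#'   centroid counts as sustained.
#' @return list with `cluster_subtype` (named by cluster label) and
#'   `subtype` (per cell).
#' @export
label_subtypes <- function(solution, proto, out_len = 40L,
                           sustain_threshold = 0.5) {
  n_on <- length(window_frames(proto$stim_on_window))
  n_off <- length(window_frames(proto$post_off_window))
  split_at <- round(out_len * n_on / (n_on + n_off))
  on_seg <- seq_len(split_at)
  off_seg <- (split_at + 1L):out_len
  late_on <- on_seg[on_seg > split_at * 2 / 3]
  labs <- sort(unique(solution$labels))
  sub <- vapply(seq_along(labs), function(j) {
    ctr <- solution$centers[j, ]
    if (max(ctr) <= 0) return("unassigned")
    if (which.max(ctr) %in% off_seg) return("OFF")
    sustain <- mean(ctr[late_on]) / max(ctr[on_seg])
    if (!is.finite(sustain)) return("unassigned")
    if (sustain >= sustain_threshold) "ONs" else "ONt"
  }, character(1))
  names(sub) <- as.character(labs)
  list(cluster_subtype = sub,
       subtype = unname(sub[as.character(solution$labels)]))
}

#' Double-angle feature vectors of preferred orientations
#'
#' Embeds orientation axes as unit vectors `(cos 2phi, sin 2phi)` so that 0
#' and 180 degrees coincide and Euclidean clustering respects axial
#' geometry.
#'
#' @param pref_orientation_deg axis angles in degrees.
#' @return n x 2 numeric matrix.
#' @export
orientation_features <- function(pref_orientation_deg) {
  a <- 2 * deg2rad(pref_orientation_deg)
  cbind(cos2phi = cos(a), sin2phi = sin(a))
}

#' Name orientation clusters as over/underrepresented groups
#'
#' The larger cluster is the locally dominant (overrepresented) orientation
#' group, the smaller the orthogonal underrepresented group. Each cluster's
#' mean axis is the double-angle circular mean of its members.
#'
#' Grouping is only meaningful where the map is locally constant (one FOV
#' or a small region): pooled across much of the retina the dominant
#' orientations form an arc that k-means fragments. Use
#' [assign_orientation_groups()] for whole-dataset labeling.
#'
#' @param solution a [cluster_and_select_k()] result on
#'   [orientation_features()] (meaningful for `chosen_k = 2`).
#' @param pref_orientation_deg the clustered axes.
#' @return list with `orientation_group` per cell, `cluster_axis_deg`
#'   (mean axis per cluster) and `axis_separation_deg` (axis angle between
#'   the two largest clusters' means).
#' @export
label_orientation_groups <- function(solution, pref_orientation_deg) {
  labs <- solution$labels
  sizes <- sort(table(labs), decreasing = TRUE)
  ord <- as.integer(names(sizes))
  axes <- vapply(ord, function(l)
    circular_mean_axis(pref_orientation_deg[labs == l])$mean_axis_deg,
    numeric(1))
  names(axes) <- as.character(ord)
  group <- ifelse(labs == ord[1], "overrepresented", "underrepresented")
  sep <- if (length(ord) >= 2) axis_diff_deg(axes[1], axes[2]) else NA_real_
  list(orientation_group = group,
       cluster_axis_deg = axes,
       axis_separation_deg = unname(sep))
}

#' Assign orientation groups FOV by FOV
#'
#' Labels each OS cell overrepresented or underrepresented within its own
#' field of view, where the orientation map is locally constant: FOVs with
#' enough cells are clustered in double-angle space
#' ([cluster_and_select_k()] + [label_orientation_groups()]); smaller FOVs
#' fall back to comparing each axis with the FOV's dominant axis (within
#' 45 degrees = overrepresented).
#'
#' @param pref_orientation_deg per-cell preferred axes.
#' @param fov_id matching FOV identifiers.
#' @param k_range candidate cluster counts for the per-FOV clustering.
#' @param restarts,seed passed to [cluster_and_select_k()].
#' @param min_cluster_n minimum cells in a FOV for the clustering route.
#' @return character vector of group labels, one per cell.
#' @export
assign_orientation_groups <- function(pref_orientation_deg, fov_id,
                                      k_range = 2:4, restarts = 10L,
                                      seed = 1L, min_cluster_n = 12L) {
  out <- character(length(pref_orientation_deg))
  for (f in unique(fov_id)) {
    ii <- which(fov_id == f)
    a <- pref_orientation_deg[ii]
    grp <- NULL
    if (length(a) >= max(min_cluster_n, max(k_range) + 1L) &&
        length(unique(round(a, 6))) > 1L) {
      sol <- try(cluster_and_select_k(orientation_features(a), k_range,
                                      restarts, seed = seed), silent = TRUE)
      if (!inherits(sol, "try-error")) {
        lab <- label_orientation_groups(sol, a)
        ## trust the clustering only when it found the orthogonal-group
        ## structure; otherwise (e.g. no minority group in this FOV,
        ## k-means halves the dominant cluster) fall back
        if (!is.na(lab$axis_separation_deg) && lab$axis_separation_deg > 60)
          grp <- lab$orientation_group
      }
    }
    if (is.null(grp)) {
      dom <- circular_mean_axis(a)$mean_axis_deg
      grp <- ifelse(is.na(dom) | axis_diff_deg(a, dom) < 45,
                    "overrepresented", "underrepresented")
    }
    out[ii] <- grp
  }
  out
}
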