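#' Ellipse specification for the concentric map model
#'
#' An axis-aligned ellipse (circle when the radii are equal) anchored at a
#' retinal point; the concentric map model is the family of such ellipses
#' of growing size sharing one anchor and aspect ratio.
#'
#' @param x_center,y_center anchor coordinates in um (optic-nerve origin).
#' @param x_radius,y_radius horizontal and vertical radii in um, positive.
#' @return object of class `ellipse_spec` with the aspect ratio
#'   (`x_radius / y_radius`) precomputed.
#' @export
ellipse_spec <- function(x_center, y_center, x_radius, y_radius) {
  if (!(x_radius > 0 && y_radius > 0)) stop("ellipse radii must be positive")
  structure(list(x_center = x_center, y_center = y_center,
                 x_radius = x_radius, y_radius = y_radius,
                 aspect = x_radius / y_radius),
            class = "ellipse_spec")
}

#' Sampling axis through the optic nerve
#'
#' A ray from an origin (the optic nerve by default) along a fixed
#' direction. The two standard sampling axes are ventronasal
#' (VN, 225 degrees: ventral rotated 45 toward nasal) and ventrotemporal
#' (VT, 315 degrees), with +x temporal, +y dorsal, ventral = 270.
#'
#' @param angle_deg direction of the ray in degrees `[0, 360)`, or one of
#'   the named axes `"VN"`, `"VT"`, `"V"`, `"T"`.
#' @param origin length-2 numeric, ray origin in um.
#' @return object of class `axis_line`.
#' @export
axis_line <- function(angle_deg, origin = c(0, 0)) {
  if (is.character(angle_deg)) {
    if (!angle_deg %in% names(sector_center_deg))
      stop("unknown named axis: ", angle_deg)
    angle_deg <- sector_center_deg[[angle_deg]]
  }
  structure(list(angle_deg = norm_dir_deg(angle_deg),
                 origin = as.numeric(origin)),
            class = "axis_line")
}

#' Intersection of a line with a circle or ellipse
#'
#' Solves the quadratic obtained by substituting the parametric line
#' `origin + t * (cos a, sin a)` into the ellipse equation. Both roots are
#' returned; `t` is the signed distance from the line's origin, so `t > 0`
#' selects the forward ray.
#'
#' @param line an [axis_line()].
#' @param conic an [ellipse_spec()].
#' @return data.frame with columns `t`, `x`, `y` (0, 1 or 2 rows, ordered
#'   by increasing `t`); zero rows when the line misses the conic.
#' @export
line_conic_intersection <- function(line, conic) {
  u <- c(cos(deg2rad(line$angle_deg)), sin(deg2rad(line$angle_deg)))
  o <- line$origin
  A <- conic$x_radius; B <- conic$y_radius
  dx <- o[1] - conic$x_center; dy <- o[2] - conic$y_center
  a <- (u[1] / A)^2 + (u[2] / B)^2
  b <- 2 * (dx * u[1] / A^2 + dy * u[2] / B^2)
  cc <- (dx / A)^2 + (dy / B)^2 - 1
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(data.frame(t = numeric(0), x = numeric(0), y = numeric(0)))
  t <- sort(c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a)))
  if (disc == 0) t <- t[1]
  data.frame(t = t, x = o[1] + t * u[1], y = o[2] + t * u[2])
}

#' Tangent axis of an ellipse at a point on it
#'
#' The tangent direction at a boundary point is orthogonal to the gradient
#' of the implicit ellipse equation; it is computed from the un-normalized
#' direction vector `(-x_radius^2 (y - y_center), y_radius^2 (x - x_center))`
#' via the two-argument arctangent and folded to `[0, 180)`, so vertical
#' tangents (where the slope form `-y_r^2 (x - xc) / (x_r^2 (y - yc))`
#' blows up) are handled exactly. For circles this reduces to the axis
#' perpendicular to the radius through the point.
#'
#' @param conic an [ellipse_spec()].
#' @param point length-2 numeric `c(x, y)`; must lie on the conic within
#'   `tol` (relative to the radii).
#' @param tol relative tolerance of the on-conic check.
#' @return tangent axis angle in degrees, `[0, 180)`.
#' @export
tangent_axis_at_point <- function(conic, point, tol = 1e-6) {
  dx <- point[1] - conic$x_center; dy <- point[2] - conic$y_center
  if (dx == 0 && dy == 0) stop("point is at the ellipse center")
  resid <- (dx / conic$x_radius)^2 + (dy / conic$y_radius)^2 - 1
  if (abs(resid) > tol * 10)
    stop("point does not lie on the ellipse (residual ", signif(resid, 3), ")")
  vx <- -conic$x_radius^2 * dy
  vy <- conic$y_radius^2 * dx
  norm_axis_deg(rad2deg(atan2(vy, vx)))
}

## Tangent axis of the concentric family (anchor + aspect) at arbitrary
## points: the family member through (x, y) shares the tangent direction
## (-aspect^2 (y - yc), (x - xc)) up to scale. Vectorized over x, y.
map_tangent_axis <- function(anchor_xy, aspect, x, y) {
  dx <- x - anchor_xy[1]; dy <- y - anchor_xy[2]
  if (any(dx == 0 & dy == 0)) stop("point at the map anchor has no tangent")
  norm_axis_deg(rad2deg(atan2(dx, -aspect^2 * dy)))
}

#' Model-predicted orientation along a sampling axis
#'
#' Sweeps the concentric family over the given radii, intersects each
#' ellipse with the sampling axis, and at every forward-ray intersection
#' (t > 0; there can be two when the anchor lies off the axis) computes the
#' tangent axis and its signed deviation from the ventral cardinal axis.
#' Distances are straight-line distances along the axis from its origin
#' (the optic nerve).
#'
#' @param anchor_xy length-2 anchor of the concentric family, um.
#' @param aspect horizontal/vertical radius ratio (1 = circles).
#' @param axis an [axis_line()] (or name accepted by [axis_line()]).
#' @param radii vertical radii (um) to sweep; the horizontal radius of each
#'   family member is `aspect * radius`.
#' @return data.frame `(radius, distance_um, x, y, axis_deg,
#'   deviation_deg)`, sorted by distance; radii that miss the axis are
#'   skipped.
#' @export
predicted_angle_curve <- function(anchor_xy, aspect, axis,
                                  radii = seq(100, 2000, by = 25)) {
  if (length(radii) == 0) stop("empty radius sweep")
  if (is.character(axis)) axis <- axis_line(axis)
  u <- c(cos(deg2rad(axis$angle_deg)), sin(deg2rad(axis$angle_deg)))
  o <- axis$origin
  dx <- o[1] - anchor_xy[1]; dy <- o[2] - anchor_xy[2]
  ## quadratic in t per radius r (A = aspect*r, B = r):
  ## ((dx + t ux)/A)^2 + ((dy + t uy)/B)^2 = 1
  a <- (u[1] / aspect)^2 + u[2]^2
  b <- 2 * (dx * u[1] / aspect^2 + dy * u[2])
  cc <- (dx / aspect)^2 + dy^2 - radii^2
  disc <- b^2 - 4 * a * cc
  keep <- disc >= 0
  r2 <- rep(radii[keep], each = 2)
  sq <- sqrt(disc[keep])
  t <- as.vector(rbind((-b - sq) / (2 * a), (-b + sq) / (2 * a)))
  fwd <- t > 1e-9
  r2 <- r2[fwd]; t <- t[fwd]
  if (length(t) == 0)
    return(data.frame(radius = numeric(0), distance_um = numeric(0),
                      x = numeric(0), y = numeric(0),
                      axis_deg = numeric(0), deviation_deg = numeric(0)))
  px <- o[1] + t * u[1]; py <- o[2] + t * u[2]
  ax <- map_tangent_axis(anchor_xy, aspect, px, py)
  out <- data.frame(radius = r2, distance_um = t, x = px, y = py,
                    axis_deg = ax, deviation_deg = deviation_from_ventral(ax))
  out[order(out$distance_um), , drop = FALSE]
}

#' Least-squares quadratic fit of deviation versus distance
#'
#' @param distance_um,deviation_deg numeric vectors of equal length; at
#'   least 3 distinct distances are required.
#' @return object of class `quadratic_fit`: coefficients `c0 + c1 d +
#'   c2 d^2` and the fitted distance range.
#' @export
fit_quadratic <- function(distance_um, deviation_deg) {
  stopifnot(length(distance_um) == length(deviation_deg))
  if (length(unique(distance_um)) < 3L)
    stop("rank-deficient input: need >= 3 distinct distances")
  X <- cbind(1, distance_um, distance_um^2)
  fit <- stats::lm.fit(X, deviation_deg)
  structure(list(coef = unname(fit$coefficients),
                 range = range(distance_um)),
            class = "quadratic_fit")
}

#' Evaluate a quadratic fit
#' @param fit a [fit_quadratic()] result.
#' @param d distances (um).
#' @return fitted deviations (degrees).
#' @export
predict_quadratic <- function(fit, d) {
  fit$coef[1] + fit$coef[2] * d + fit$coef[3] * d^2
}

#' Area between two quadratic fits
#'
#' Integrates the absolute difference of the two fitted curves over a
#' distance range by the trapezoid rule on a 1-um grid; the model-
#' comparison score (degrees x um). Symmetric in its arguments and zero iff
#' the fits coincide on the range.
#'
#' @param fit_a,fit_b [fit_quadratic()] results.
#' @param d_range length-2 range of distances (um); defaults to the
#'   intersection of the two fitted ranges.
#' @param step grid step in um.
#' @return nonnegative area in degrees x um.
#' @export
area_between_fits <- function(fit_a, fit_b, d_range = NULL, step = 1) {
  if (is.null(d_range))
    d_range <- c(max(fit_a$range[1], fit_b$range[1]),
                 min(fit_a$range[2], fit_b$range[2]))
  if (d_range[2] <= d_range[1])
    stop("empty overlap between fitted distance ranges")
  d <- seq(d_range[1], d_range[2], by = step)
  if (d[length(d)] < d_range[2]) d <- c(d, d_range[2])
  y <- abs(predict_quadratic(fit_a, d) - predict_quadratic(fit_b, d))
  sum((y[-1] + y[-length(y)]) / 2 * diff(d))
}

#' Model-predicted deviation at given distances along an axis
#'
#' Every point of a sampling axis lies on exactly one member of the
#' concentric family, so the model's prediction can be evaluated directly
#' at any distance: the tangent axis of the family member through the
#' point, as a deviation from ventral. Equivalent to the radius sweep of
#' [predicted_angle_curve()] but sampled uniformly in distance, which is
#' what curve fitting wants.
#'
#' @inheritParams predicted_angle_curve
#' @param distance_um distances along the forward ray (um, positive).
#' @return deviations from ventral (degrees) at each distance.
#' @export
predicted_deviation_at <- function(anchor_xy, aspect, axis, distance_um) {
  if (is.character(axis)) axis <- axis_line(axis)
  u <- c(cos(deg2rad(axis$angle_deg)), sin(deg2rad(axis$angle_deg)))
  px <- axis$origin[1] + distance_um * u[1]
  py <- axis$origin[2] + distance_um * u[2]
  deviation_from_ventral(map_tangent_axis(anchor_xy, aspect, px, py))
}

#' Fit the map anchor and aspect ratio by grid search
#'
#' Deterministic grid search for the concentric-ellipse map that best
#' explains measured deviation-versus-distance curves along the VN and VT
#' axes: for every candidate (anchor, aspect), the model curve along each
#' axis is evaluated at a uniform distance grid spanning the measured
#' range ([predicted_deviation_at()]), both model and data curves are
#' reduced to quadratic fits, and the candidate's score is the summed
#' [area_between_fits()] over the axes on the measured distance range.
#'
#' @param curves named list of measured curves, e.g. `list(VN = df, VT =
#'   df)`, each a data.frame with `distance_um` and `deviation_deg`
#'   (typically per-FOV circular-mean deviations from
#'   [deviation_vs_distance()]); names must be axis names accepted by
#'   [axis_line()]. If a curve also carries the sample locations
#'   (`center_x_um`, `center_y_um`), the model is evaluated at those
#'   retinal locations instead of idealized on-axis points, so measured
#'   and modeled curves share the same sampling geometry and off-axis
#'   field-of-view scatter does not bias the comparison.
#' @param anchor_x,anchor_y numeric grids of candidate anchor coordinates
#'   (um). Defaults bracket the ventral retina around the optic nerve.
#' @param aspects numeric grid of candidate aspect ratios.
#' @param d_step spacing (um) of the model evaluation grid.
#' @return list with `anchor` (best `c(x, y)`), `aspect`, `score`
#'   (degrees x um), `surface` (data.frame of all scored candidates) and
#'   `data_fits` (the per-axis quadratic fits of the data).
#' @export
fit_anchor_and_aspect <- function(curves,
                                  anchor_x = seq(-400, 400, by = 100),
                                  anchor_y = seq(-650, -50, by = 50),
                                  aspects = seq(1.00, 1.20, by = 0.01),
                                  d_step = 25) {
  if (length(anchor_x) == 0 || length(anchor_y) == 0 || length(aspects) == 0)
    stop("empty search grid")
  stopifnot(length(curves) >= 1, !is.null(names(curves)))
  axes <- lapply(names(curves), axis_line)
  dfits <- lapply(curves, function(cv) fit_quadratic(cv$distance_um, cv$deviation_deg))
  has_xy <- vapply(curves, function(cv)
    all(c("center_x_um", "center_y_um") %in% names(cv)), logical(1))
  dgrids <- lapply(curves, function(cv) {
    rng <- range(cv$distance_um)
    seq(rng[1], rng[2], by = d_step)
  })

  grid <- expand.grid(anchor_x = anchor_x, anchor_y = anchor_y,
                      aspect = aspects, KEEP.OUT.ATTRS = FALSE)
  score <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    anc <- c(grid$anchor_x[g], grid$anchor_y[g])
    s <- 0
    for (j in seq_along(curves)) {
      cv <- curves[[j]]
      if (has_xy[j]) {
        mdev <- deviation_from_ventral(
          map_tangent_axis(anc, grid$aspect[g], cv$center_x_um, cv$center_y_um))
        mfit <- fit_quadratic(cv$distance_um, mdev)
      } else {
        dg <- dgrids[[j]]
        mdev <- predicted_deviation_at(anc, grid$aspect[g], axes[[j]], dg)
        mfit <- fit_quadratic(dg, mdev)
      }
      s <- s + area_between_fits(dfits[[j]], mfit, d_range = range(dgrids[[j]]))
    }
    score[g] <- s
  }
  grid$score <- score
  best <- which.min(score)
  list(anchor = c(grid$anchor_x[best], grid$anchor_y[best]),
       aspect = grid$aspect[best],
       score = score[best],
       surface = grid,
       data_fits = dfits)
}
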