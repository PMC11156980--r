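#' Polar histogram of preferred orientations
#'
#' Displays an orientation histogram on the circle; each axis bin is drawn
#' at both `phi` and `phi + 180` degrees, the standard symmetric display
#' for axial data.
#'
#' @param hist a data.frame from [orientation_histogram()].
#' @param main plot title.
#' @export
plot_orientation_histogram <- function(hist, main = "Preferred orientations") {
  r <- c(hist$count, hist$count)
  a <- deg2rad(c(hist$bin_mid_deg, hist$bin_mid_deg + 180))
  rmax <- max(r, 1)
  graphics::plot(NA, xlim = c(-rmax, rmax), ylim = c(-rmax, rmax),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::symbols(0, 0, circles = rmax, inches = FALSE, add = TRUE,
                    fg = "grey80")
  graphics::segments(0, 0, r * cos(a), r * sin(a), lwd = 3, col = "magenta4")
}

#' Quiver-style plot of an orientation flow field
#'
#' Draws each occupied grid bin's mean axis as a headless segment scaled by
#' its coherence (resultant length); bins with undefined mean axis are
#' drawn as points.
#'
#' @param ff a data.frame from [flow_field()].
#' @param scale_um segment half-length (um) at coherence 1.
#' @param main plot title.
#' @export
plot_flow_field <- function(ff, scale_um = 40, main = "Orientation flow field") {
  graphics::plot(ff$bin_x_um, ff$bin_y_um, pch = 16, cex = 0.4,
                 col = "grey70", asp = 1, xlab = "x (um, temporal +)",
                 ylab = "y (um, dorsal +)", main = main)
  ok <- !is.na(ff$mean_axis_deg)
  a <- deg2rad(ff$mean_axis_deg[ok])
  L <- scale_um * ff$resultant[ok]
  graphics::segments(ff$bin_x_um[ok] - L * cos(a), ff$bin_y_um[ok] - L * sin(a),
                     ff$bin_x_um[ok] + L * cos(a), ff$bin_y_um[ok] + L * sin(a),
                     lwd = 2, col = "magenta4")
}

#' Plot measured versus model-predicted deviation curves
#'
#' Scatter of per-FOV deviations against distance from the optic nerve with
#' the quadratic fit to the data and the concentric-model prediction
#' overlaid; the area between the two fits is the model score.
#'
#' @param curve data.frame with `distance_um` and `deviation_deg` (measured).
#' @param model_curve data.frame from [predicted_angle_curve()].
#' @param main plot title.
#' @export
plot_deviation_curves <- function(curve, model_curve,
                                  main = "Deviation from ventral vs distance") {
  graphics::plot(curve$distance_um, curve$deviation_deg, pch = 16,
                 xlab = "distance from optic nerve (um)",
                 ylab = "deviation from ventral (deg)", main = main,
                 ylim = range(c(curve$deviation_deg, model_curve$deviation_deg)))
  dfit <- fit_quadratic(curve$distance_um, curve$deviation_deg)
  d <- seq(min(curve$distance_um), max(curve$distance_um), length.out = 200)
  graphics::lines(d, predict_quadratic(dfit, d), lwd = 2)
  graphics::lines(model_curve$distance_um, model_curve$deviation_deg,
                  col = "red", lwd = 2)
  graphics::legend("topleft", c("data fit", "model"), lwd = 2,
                   col = c("black", "red"), bty = "n")
}
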