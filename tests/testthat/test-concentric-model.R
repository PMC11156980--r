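test_that("line-conic intersections solve the quadratic exactly", {
  circ <- ellipse_spec(0, 0, 1, 1)
  hor <- axis_line(0, c(-2, 0))
  pts <- line_conic_intersection(hor, circ)
  expect_equal(pts$x, c(-1, 1))
  expect_equal(pts$y, c(0, 0))
  # line y = 2 misses the unit circle
  expect_equal(nrow(line_conic_intersection(axis_line(0, c(0, 2)), circ)), 0L)
  # ellipse 2:1, line y = x: x^2/4 + x^2 = 1 -> x = +/- sqrt(4/5)
  ell <- ellipse_spec(0, 0, 2, 1)
  diag <- axis_line(45, c(-3, -3))
  pd <- line_conic_intersection(diag, ell)
  expect_equal(sort(pd$x), c(-sqrt(4 / 5), sqrt(4 / 5)), tolerance = 1e-12)
  expect_equal(pd$x, pd$y, tolerance = 1e-12)
})

test_that("tangent axes at canonical points match geometry", {
  circ <- ellipse_spec(0, 0, 500, 500)
  # ventral pole: horizontal tangent (the model's central-ventral prediction)
  expect_equal(tangent_axis_at_point(circ, c(0, -500)), 0)
  # temporal pole: vertical tangent; slope-formula singularity handled
  expect_equal(tangent_axis_at_point(circ, c(500, 0)), 90)
  # 2:1 ellipse at its top: horizontal
  expect_equal(tangent_axis_at_point(ellipse_spec(0, 0, 2, 1), c(0, 1)), 0)
  expect_error(tangent_axis_at_point(circ, c(0, 0)), "center")
  expect_error(tangent_axis_at_point(circ, c(0, -490)), "does not lie")
})

test_that("circle tangents are orthogonal to the radius for random anchors and radii", {
  set.seed(14)
  for (i in 1:50) {
    ctr <- runif(2, -1000, 1000)
    r <- runif(1, 50, 2000)
    phi <- runif(1, 0, 2 * pi)
    p <- ctr + r * c(cos(phi), sin(phi))
    tang <- tangent_axis_at_point(ellipse_spec(ctr[1], ctr[2], r, r), p)
    radial <- norm_axis_deg(phi * 180 / pi)
    d <- abs(tang - norm_axis_deg(radial + 90)) %% 180
    expect_lt(min(d, 180 - d), 1e-9)
  }
})

test_that("vector-form tangent equals the analytic slope formula wherever finite", {
  # slope = -(y_r^2 (x - xc)) / (x_r^2 (y - yc)), the ellipse implicit
  # derivative; compare over random ellipses and boundary points
  set.seed(15)
  n <- 10000
  xc <- runif(n, -500, 500); yc <- runif(n, -500, 500)
  xr <- runif(n, 10, 1000); yr <- runif(n, 10, 1000)
  phi <- runif(n, 0, 2 * pi)
  x <- xc + xr * cos(phi); y <- yc + yr * sin(phi)
  ok <- abs(y - yc) > 1e-6 * yr
  slope <- -(yr^2 * (x - xc)) / (xr^2 * (y - yc))
  ref_axis <- norm_axis_deg(atan(slope) * 180 / pi)
  for (i in which(ok)[1:2000]) {
    tang <- tangent_axis_at_point(ellipse_spec(xc[i], yc[i], xr[i], yr[i]),
                                  c(x[i], y[i]))
    d <- abs(tang - ref_axis[i]) %% 180
    expect_lt(min(d, 180 - d), 1e-8)
  }
})

test_that("optic-nerve circles predict constant +/-45 deviation along VN and VT", {
  vn <- predicted_angle_curve(c(0, 0), 1, "VN", seq(100, 2000, 25))
  vt <- predicted_angle_curve(c(0, 0), 1, "VT", seq(100, 2000, 25))
  expect_equal(nrow(vn), 77L)  # one forward intersection per radius
  expect_equal(vn$deviation_deg, rep(-45, 77), tolerance = 1e-9)
  expect_equal(vt$deviation_deg, rep(45, 77), tolerance = 1e-9)
  expect_equal(vn$distance_um, seq(100, 2000, 25), tolerance = 1e-9)
})

test_that("an anchor on the axis line predicts orthogonal axes everywhere", {
  # anchor on the VN line itself: tangent always perpendicular to the axis
  anc <- 1800 * c(cos(225 * pi / 180), sin(225 * pi / 180))
  pc <- predicted_angle_curve(anc, 1, "VN", seq(100, 1500, 50))
  expect_true(all(abs(pc$axis_deg - 135) < 1e-9 | abs(pc$axis_deg - 45) < 1e-9))
  expect_error(predicted_angle_curve(c(0, 0), 1, "VN", numeric(0)), "empty")
})

test_that("direct per-distance model evaluation agrees with the radius sweep", {
  anc <- c(-150, -350)
  pc <- predicted_angle_curve(anc, 1.1, "VT", seq(50, 2000, 5))
  dev <- predicted_deviation_at(anc, 1.1, "VT", pc$distance_um)
  expect_equal(pc$deviation_deg, dev, tolerance = 1e-9)
})

test_that("quadratic fits recover exact coefficients and degenerate cases error", {
  d <- seq(100, 1000, by = 50)
  y <- 3 - 0.02 * d + 1e-5 * d^2
  f <- fit_quadratic(d, y)
  expect_equal(f$coef, c(3, -0.02, 1e-5), tolerance = 1e-9)
  fc <- fit_quadratic(d, rep(4, length(d)))
  expect_equal(fc$coef[2:3], c(0, 0), tolerance = 1e-12)
  expect_error(fit_quadratic(c(1, 1, 2), c(1, 2, 3)), "rank-deficient")
  # Monte-Carlo: coefficient error shrinks with n roughly as 1/sqrt(n)
  set.seed(16)
  err <- sapply(c(100, 1600), function(n) {
    mean(replicate(40, {
      dd <- seq(0, 1, length.out = n)
      ff <- fit_quadratic(dd, 1 + dd - 2 * dd^2 + rnorm(n, 0, 0.3))
      abs(ff$coef[3] + 2)
    }))
  })
  expect_gt(err[1] / err[2], 2.5)   # 4x n -> ~4x shrinkage of c2 error
})

test_that("area between fits is symmetric, zero iff equal, and matches closed forms", {
  d <- 0:10
  fa <- fit_quadratic(d, 2 + 0 * d)
  fb <- fit_quadratic(d, 5 + 0 * d)
  expect_equal(area_between_fits(fa, fa), 0)
  # constant offset 3 over length 10 -> 30
  expect_equal(area_between_fits(fa, fb), 30, tolerance = 1e-9)
  expect_equal(area_between_fits(fa, fb), area_between_fits(fb, fa))
  # difference x^2 on [0, 1] -> 1/3 (trapezoid tolerance)
  dd <- seq(0, 1, 0.1)
  ga <- fit_quadratic(dd, dd^2)
  gb <- fit_quadratic(dd, 0 * dd)
  expect_equal(area_between_fits(ga, gb, c(0, 1), step = 0.001), 1 / 3,
               tolerance = 1e-5)
  expect_error(area_between_fits(fit_quadratic(0:5, 0:5),
                                 fit_quadratic(10:15, 10:15)), "empty overlap")
})

test_that("anchor and aspect are recovered from noiseless model-generated curves", {
  true_anchor <- c(-100, -250); true_aspect <- 1.09
  d <- seq(400, 1400, by = 50)
  curves <- list(
    VN = data.frame(distance_um = d,
                    deviation_deg = predicted_deviation_at(true_anchor, true_aspect, "VN", d)),
    VT = data.frame(distance_um = d,
                    deviation_deg = predicted_deviation_at(true_anchor, true_aspect, "VT", d)))
  fit <- fit_anchor_and_aspect(curves,
                               anchor_x = seq(-300, 100, 100),
                               anchor_y = seq(-450, -150, 50),
                               aspects = seq(1.0, 1.2, 0.01))
  expect_equal(fit$anchor, true_anchor)
  expect_equal(fit$aspect, true_aspect)
  ## residual score is only the quadratic-approximation mismatch between
  ## the two sampling grids: well under a degree on average
  expect_lt(fit$score / 1000, 1)
  # circles anchored at the optic nerve recovered as aspect ~ 1, anchor ~ origin
  curves0 <- list(
    VN = data.frame(distance_um = d,
                    deviation_deg = predicted_deviation_at(c(0, -1), 1, "VN", d)),
    VT = data.frame(distance_um = d,
                    deviation_deg = predicted_deviation_at(c(0, -1), 1, "VT", d)))
  fit0 <- fit_anchor_and_aspect(curves0,
                                anchor_x = seq(-200, 200, 100),
                                anchor_y = seq(-300, 0, 100),
                                aspects = seq(1.0, 1.1, 0.01))
  expect_equal(fit0$aspect, 1)
  expect_equal(fit0$anchor, c(0, 0))
  expect_error(fit_anchor_and_aspect(curves, anchor_x = numeric(0)), "empty")
})
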