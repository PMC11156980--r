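test_that("orientation histograms conserve counts and bin correctly", {
  h <- orientation_histogram(rep(45, 12), bin_deg = 10)
  expect_equal(sum(h$count), 12L)
  expect_equal(h$count[h$bin_lo_deg == 40], 12L)
  expect_equal(sum(h$count > 0), 1L)
  # empty input: empty histogram, not an error
  h0 <- orientation_histogram(numeric(0))
  expect_equal(sum(h0$count), 0L)
  expect_equal(nrow(h0), 18L)
  # uniform angles: occupancy within multinomial bounds
  set.seed(11)
  hu <- orientation_histogram(runif(18000, 0, 180), bin_deg = 10)
  expect_equal(sum(hu$count), 18000L)
  expect_true(all(abs(hu$count - 1000) < qnorm(0.9995) * sqrt(1000 * 17 / 18)))
  expect_error(orientation_histogram(1, bin_deg = 7), "divide 180")
})

test_that("deviation from ventral follows the fixed sign convention", {
  expect_equal(deviation_from_ventral(90), 0)
  expect_equal(deviation_from_ventral(0), 90)    # boundary by convention
  expect_equal(deviation_from_ventral(45), 45)   # VT-leaning axis positive
  expect_equal(deviation_from_ventral(135), -45) # VN-leaning axis negative
  expect_error(deviation_from_ventral(180), "0, 180")
  # inverse consistency: rotating back recovers the axis (mod 180)
  set.seed(12)
  ax <- runif(100, 0, 180 - 1e-9)
  dev <- deviation_from_ventral(ax)
  expect_true(all(dev > -90 & dev <= 90))
  expect_equal(norm_axis_deg(90 - dev), ax, tolerance = 1e-12)
})

test_that("per-FOV deviation curves use double-angle circular means", {
  fovs <- data.frame(fov_id = c("f1", "f2"), center_x_um = c(-500, -900),
                     center_y_um = c(-500, -900), quadrant = "VN",
                     distance_um = c(707, 1273))
  samples <- data.frame(fov_id = c("f1", "f1", "f2"),
                        pref_orientation_deg = c(10, 170, 60))
  out <- deviation_vs_distance(samples, fovs)
  # 10 and 170 average to axis 0 in double-angle space -> deviation 90
  expect_equal(out$fov_curve$deviation_deg[out$fov_curve$fov_id == "f1"], 90)
  expect_equal(out$fov_curve$deviation_deg[out$fov_curve$fov_id == "f2"], 30)
  expect_equal(nrow(out$cells), 3L)
  # FOV with no cells is skipped with a message, not an error
  fovs2 <- rbind(fovs, data.frame(fov_id = "f3", center_x_um = 0,
                                  center_y_um = -100, quadrant = "V",
                                  distance_um = 100))
  expect_message(out2 <- deviation_vs_distance(samples, fovs2), "f3")
  expect_equal(nrow(out2$fov_curve), 2L)
})

test_that("flow field averages axes per bin and masks sparse or cancelling bins", {
  s <- data.frame(x_um = rep(50, 10), y_um = rep(50, 10),
                  pref_orientation_deg = rep(30, 10))
  ff <- flow_field(s, grid_um = 100, min_n = 5)
  expect_equal(nrow(ff), 1L)
  expect_equal(ff$mean_axis_deg, 30)
  expect_equal(ff$resultant, 1)
  # angles 10 and 170 in one bin -> mean axis 0
  s2 <- data.frame(x_um = rep(10, 6), y_um = rep(10, 6),
                   pref_orientation_deg = rep(c(10, 170), 3))
  expect_equal(flow_field(s2, min_n = 5)$mean_axis_deg, 0, tolerance = 1e-9)
  # orthogonal 50/50 mixture cancels: resultant ~ 0, angle undefined
  s3 <- data.frame(x_um = rep(10, 6), y_um = rep(10, 6),
                   pref_orientation_deg = rep(c(20, 110), 3))
  ff3 <- flow_field(s3, min_n = 5)
  expect_lt(ff3$resultant, 1e-9)
  expect_true(is.na(ff3$mean_axis_deg))
  # sparse bins masked
  expect_equal(nrow(flow_field(s[1:3, ], min_n = 5)), 0L)
})

test_that("flow field mean is invariant to 0/180 relabeling of any subset", {
  set.seed(13)
  s <- data.frame(x_um = runif(40, 0, 90), y_um = runif(40, 0, 90),
                  pref_orientation_deg = runif(40, 0, 180))
  flip <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  s2 <- s
  ## represent flipped axes by the equivalent angle before re-normalization
  s2$pref_orientation_deg <- norm_axis_deg(s$pref_orientation_deg + 180 * flip)
  expect_equal(flow_field(s, min_n = 1)$mean_axis_deg,
               flow_field(s2, min_n = 1)$mean_axis_deg, tolerance = 1e-9)
})

test_that("region comparison: identical groups D = 0, disjoint supports D = 1", {
  v <- rep(c(1, 2, 3, 4, 5), 4)
  g <- rep(c("a", "b"), 10)
  cmp <- compare_regions(v, g, "identical halves", n_perm = 200, seed = 1)
  expect_equal(cmp$ks_statistic, 0)
  expect_gt(cmp$perm_p, 0.9)
  cmp2 <- compare_regions(c(1:10, 101:110), rep(c("lo", "hi"), each = 10),
                          "disjoint", n_perm = 200, seed = 1)
  expect_equal(cmp2$ks_statistic, 1)
  expect_lt(cmp2$perm_p, 0.05)
  expect_error(compare_regions(1:5, rep("a", 5), "degenerate split"),
               "degenerate split")
})

test_that("ventral-anchored synthetic map separates more- and less-ventral FOVs as predicted", {
  cfg <- retina_config(n_fovs = 16L, cells_per_fov_mean = 80,
                       cells_per_fov_sd = 0, frac_os = 1, frac_ds = 0,
                       frac_both = 0, underrep_frac = 0, seed = 17L)
  ret <- generate_retina(cfg)
  cells <- ret$cells
  m <- match(cells$fov_id, ret$fovs$fov_id)
  dev <- deviation_from_ventral(norm_axis_deg(cells$true_pref_orientation_deg))
  more_ventral <- ret$fovs$center_y_um[m] < median(ret$fovs$center_y_um)
  cmp <- compare_regions(abs(dev), more_ventral, "ventral split",
                         n_perm = 500, seed = 2)
  expect_lt(cmp$perm_p, 0.05)
  expect_lt(cmp$ks_p, 0.05)
  ## direction of the effect: FOVs nearer the ventral anchor deviate more
  expect_gt(mean(abs(dev[more_ventral])), mean(abs(dev[!more_ventral])))
})

test_that("VN and VT modal axes are mirror-symmetric about the ventral axis", {
  cfg <- retina_config(n_fovs = 10L, cells_per_fov_mean = 200,
                       cells_per_fov_sd = 0, frac_os = 1, frac_ds = 0,
                       frac_both = 0, underrep_frac = 0, seed = 19L)
  ret <- generate_retina(cfg)
  cells <- ret$cells
  q <- ret$fovs$quadrant[match(cells$fov_id, ret$fovs$fov_id)]
  dev_vn <- circular_mean_axis(cells$true_pref_orientation_deg[q == "VN"])
  dev_vt <- circular_mean_axis(cells$true_pref_orientation_deg[q == "VT"])
  ## mirror symmetry: deviations of equal magnitude, opposite sign
  expect_equal(deviation_from_ventral(dev_vn$mean_axis_deg),
               -deviation_from_ventral(dev_vt$mean_axis_deg), tolerance = 6)
  expect_lt(deviation_from_ventral(dev_vn$mean_axis_deg), 0)
})
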