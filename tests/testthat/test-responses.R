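test_that("dF/F normalization matches direct arithmetic and flags degenerate baselines", {
  # constant trace: dF/F identically zero
  expect_equal(compute_dfof(rep(2, 10), rep(FALSE, 10)), rep(0, 10))
  # baseline 1.0, stimulus frames at 2.0
  tr <- c(1, 1, 2, 2, 1)
  expect_equal(compute_dfof(tr, c(3, 4)), c(0, 0, 1, 1, 0))
  # baseline frames {1, 3} -> F0 = 2; stimulus value 5 -> dF/F = 1.5
  tr2 <- c(1, 5, 3)
  expect_equal(compute_dfof(tr2, 2)[2], 1.5)
  # errors
  expect_error(compute_dfof(tr, rep(TRUE, 5)), "no baseline")
  expect_error(compute_dfof(c(0, 0, 1), 3), "degenerate baseline")
  # 3-D movie: per-pixel normalization
  mov <- array(1, dim = c(2, 2, 4)); mov[1, 1, 3] <- 3
  out <- compute_dfof(mov, 3)
  expect_equal(out[1, 1, 3], 2)
  expect_equal(out[2, 2, ], rep(0, 4))
})

test_that("peak responses average per-repetition maxima inside the response window", {
  rm <- build_responses(rep(1, 8), pulse_trace(amp = 2))
  expect_equal(unname(peak_responses(rm, proto8)), rep(2, 8))
  # two reps with maxima 1 and 3 -> 2
  p2 <- stimulus_protocol(n_reps = 2L)
  rm2 <- build_responses(rep(1, 8), pulse_trace(p2), p2)
  rm2[["0"]][, 2] <- 3 * rm2[["0"]][, 2]
  expect_equal(unname(peak_responses(rm2, p2)["0"]), 2)
  # peaks occurring after stimulus offset are captured (post-off window)
  tr <- numeric(proto8$frames_per_trial)
  tr[proto8$post_off_window[1] + 2] <- 1.7
  expect_equal(unname(peak_responses(build_responses(rep(1, 8), tr), proto8)),
               rep(1.7, 8))
})

test_that("quality index is 1 for identical repeats and for a single repeat", {
  tr <- sin(seq_len(48) / 5)
  expect_equal(quality_index(matrix(rep(tr, 5), 48, 5)), 1)
  expect_equal(quality_index(matrix(tr, 48, 1)), 1)
  # list input concatenates directions
  rm <- build_responses(c(2, 1, 1, 1, 1, 1, 1, 1), pulse_trace())
  expect_equal(quality_index(rm), 1)
})

test_that("quality index approaches 1/R for pure i.i.d. noise and 0 for flat traces", {
  set.seed(1)
  R <- 5
  qis <- replicate(20, quality_index(matrix(rnorm(4000 * R), 4000, R)))
  expect_equal(mean(qis), 1 / R, tolerance = 0.05)
  flat <- quality_index(matrix(3, 10, 4))
  expect_equal(as.numeric(flat), 0)
  expect_true(attr(flat, "degenerate"))
})

test_that("direction tuning matches brute-force complex arithmetic", {
  a <- seq(0, 315, by = 45)
  # single responsive direction: perfect tuning
  d <- direction_selectivity(c(1, 0, 0, 0, 0, 0, 0, 0), a)
  expect_equal(d$l_dir, 1)
  expect_equal(d$pref_direction_deg, 0)
  expect_equal(d$dsi, 1)
  # equal peaks: symmetric cancellation
  expect_equal(direction_selectivity(rep(1, 8), a)$l_dir, 0, tolerance = 1e-12)
  # worked example: unit vectors cancel, leaving 1/9
  expect_equal(direction_selectivity(c(2, rep(1, 7)), a)$l_dir, 1 / 9,
               tolerance = 1e-12)
  # brute-force oracle on random nonnegative peaks
  set.seed(42)
  for (i in 1:25) {
    p <- runif(8)
    ref <- abs(sum(complex(modulus = p, argument = a * pi / 180))) / sum(p)
    expect_equal(direction_selectivity(p, a)$l_dir, ref, tolerance = 1e-12)
  }
  expect_error(direction_selectivity(rep(0, 8), a), "undefined tuning")
})

test_that("orientation tuning separates axis preference from direction preference", {
  a <- seq(0, 315, by = 45)
  expect_equal(orientation_selectivity(rep(1, 8), a)$l_ori, 0, tolerance = 1e-12)
  # responses at 0 and 180 only: opposite directions cancel in direction
  # space but add in double-angle space
  p <- c(1, 0, 0, 0, 1, 0, 0, 0)
  expect_equal(orientation_selectivity(p, a)$l_ori, 1, tolerance = 1e-12)
  expect_equal(direction_selectivity(p, a)$l_dir, 0, tolerance = 1e-12)
  expect_equal(orientation_selectivity(p, a)$pref_orientation_deg, 0)
  # OSI from orientation-averaged peaks: pref 3 vs orthogonal 1 -> 0.5
  p2 <- c(3, 0, 1, 0, 3, 0, 1, 0)
  os <- orientation_selectivity(p2, a)
  expect_equal(os$osi, 0.5)
  expect_equal(os$pref_orientation_sampled_deg, 0)
  # brute-force double-angle oracle
  set.seed(43)
  for (i in 1:25) {
    p <- runif(8)
    ref <- abs(sum(p * exp(2i * a * pi / 180))) / sum(p)
    expect_equal(orientation_selectivity(p, a)$l_ori, ref, tolerance = 1e-12)
  }
})

test_that("tuning statistics are rotation-equivariant and bounded", {
  set.seed(7)
  a <- seq(0, 315, by = 45)
  for (i in 1:20) {
    p <- runif(8, 0.01, 1)
    delta <- runif(1, 0, 360)
    d0 <- direction_selectivity(p, a); d1 <- direction_selectivity(p, a + delta)
    o0 <- orientation_selectivity(p, a); o1 <- orientation_selectivity(p, a + delta)
    expect_equal(d1$l_dir, d0$l_dir, tolerance = 1e-10)
    expect_equal(o1$l_ori, o0$l_ori, tolerance = 1e-10)
    expect_equal(norm_dir_deg(d1$pref_direction_deg - delta),
                 d0$pref_direction_deg, tolerance = 1e-8)
    dd <- abs(o1$pref_orientation_deg - norm_axis_deg(o0$pref_orientation_deg + delta)) %% 180
    expect_lt(min(dd, 180 - dd), 1e-8)
    ## resultant lengths and OSI are bounded in [0, 1]; DSI lives in
    ## [-1, 1] (its "pref" comes from the vector sum, not the argmax, so
    ## it can dip below zero for weakly tuned cells)
    expect_true(all(c(d0$l_dir, o0$l_ori, o0$osi) >= 0))
    expect_true(all(c(d0$l_dir, d0$dsi, o0$l_ori, o0$osi) <= 1))
    expect_gte(d0$dsi, -1)
  }
})

test_that("a cell responding to exactly one direction maxes out both indices", {
  # the documented degeneracy that motivates joint OS/DS significance testing
  a <- seq(0, 315, by = 45)
  p <- c(0, 0, 1, 0, 0, 0, 0, 0)
  expect_equal(direction_selectivity(p, a)$l_dir, 1, tolerance = 1e-12)
  expect_equal(orientation_selectivity(p, a)$l_ori, 1, tolerance = 1e-12)
})

test_that("summarize_tuning produces one validated row per cell", {
  rs <- list(cellA = build_responses(c(2, rep(1, 7)), pulse_trace()),
             cellB = build_responses(rep(1, 8), pulse_trace()))
  ts <- summarize_tuning(rs, proto8)
  expect_equal(nrow(ts), 2)
  expect_equal(ts$cell_id, c("cellA", "cellB"))
  expect_equal(ts$qi, c(1, 1))
  expect_equal(ts$l_dir, c(1 / 9, 0), tolerance = 1e-12)
  expect_true(all(ts$pref_orientation_deg >= 0 & ts$pref_orientation_deg < 180))
})
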