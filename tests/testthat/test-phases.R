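test_that("velocity of a linear trace is its slope, of a stationary trace zero", {
  t <- (0:60) / 3
  lin <- data.frame(t_s = t, x_nm = 100 + 46 * t)
  v <- instantaneous_velocity(lin, window = 5)
  expect_true(all(abs(v$v_nm_s - 46) < 1e-9))

  still <- data.frame(t_s = t, x_nm = rep(2500, length(t)))
  v0 <- instantaneous_velocity(still, window = 5)
  expect_true(all(v0$v_nm_s == 0))
})

test_that("time reversal negates velocities", {
  set.seed(1)
  t <- (0:80) / 3
  x <- cumsum(rnorm(length(t), 10, 3))
  v_fwd <- instantaneous_velocity(data.frame(t_s = t, x_nm = x))$v_nm_s
  v_rev <- instantaneous_velocity(data.frame(t_s = t, x_nm = rev(x)))$v_nm_s
  expect_equal(v_rev, -rev(v_fwd), tolerance = 1e-12)
})

test_that("velocity preconditions are enforced", {
  t <- (0:10) / 3
  e <- data.frame(t_s = t, x_nm = t)
  expect_error(instantaneous_velocity(e, window = 4), "odd")
  expect_error(instantaneous_velocity(e, window = 15), "shorter")
  expect_error(instantaneous_velocity(e[1, ]), "two tracked")
})

test_that("three-phase segmentation recovers constructed changepoints", {
  set.seed(42)
  t <- seq(0, 150, by = 1 / 3)
  vtrue <- ifelse(t <= 60, 46, ifelse(t <= 90, 46 * (90 - t) / 30, 0))
  hits12 <- hits23 <- 0
  for (rep in 1:5) {
    v <- vtrue + rnorm(length(t), 0, 5)
    vt <- structure(data.frame(t_s = t, v_nm_s = v),
                    class = c("velocity_trace", "data.frame"), window = 1L)
    seg <- segment_phases(vt)
    expect_equal(seg$model, "three_phase")
    hits12 <- hits12 + (abs(seg$t12 - 60) <= 3)
    hits23 <- hits23 + (abs(seg$t23 - 90) <= 3)
    expect_equal(seg$v_phase1, 46, tolerance = 0.05)
  }
  expect_gte(hits12, 4)
  expect_gte(hits23, 4)
})

test_that("degenerate traces give degenerate segmentations", {
  t <- seq(0, 50, by = 1 / 3)
  const <- structure(data.frame(t_s = t, v_nm_s = rep(30, length(t))),
                     class = c("velocity_trace", "data.frame"), window = 1L)
  seg_c <- segment_phases(const)
  expect_equal(seg_c$model, "constant")
  expect_equal(seg_c$t12, max(t))
  expect_equal(seg_c$v_phase1, 30)

  zero <- structure(data.frame(t_s = t, v_nm_s = rep(0, length(t))),
                    class = c("velocity_trace", "data.frame"), window = 1L)
  seg_z <- segment_phases(zero)
  expect_equal(seg_z$model, "stalled")
  expect_equal(seg_z$t12, 0)
  expect_error(segment_phases(data.frame(t_s = t, v_nm_s = NA_real_)), "NA")
})

test_that("v_phase1 of a pure phase-1 trace equals its arithmetic mean", {
  set.seed(3)
  t <- seq(0, 30, by = 1 / 3)
  v <- 25 + rnorm(length(t), 0, 2)
  vt <- structure(data.frame(t_s = t, v_nm_s = v),
                  class = c("velocity_trace", "data.frame"), window = 1L)
  seg <- segment_phases(vt)
  expect_equal(seg$model, "constant")
  expect_equal(seg$v_phase1, mean(v), tolerance = 1e-12)
})

test_that("segmentation recovers simulated changepoints across SNR levels", {
  # one simulated stalling event per SNR; errors within a few frames
  p <- simulation_params(ML1 = 9000, ML2 = 9000, s0 = 500,
                         endtag_fraction = 0.35, endtag_growth_rate = Inf,
                         duration = 260)
  tr <- simulate_pair(p)
  truth12 <- max(tr$frames$t_s[tr$frames$phase == 1])
  truth23 <- max(tr$frames$t_s[tr$frames$phase == 2])
  for (snr in c(3, 5, 10)) {
    k <- render_kymograph(tr, optics_at_snr(optics_params(seed = snr), snr))
    ev <- track_event(k)
    seg <- segment_phases(ev$velocity)
    expect_lt(abs(seg$t12 - truth12), 6)   # seconds
    expect_lt(abs(seg$t23 - truth23), 6)
    expect_equal(seg$v_phase1, tr$v_phase1_true, tolerance = 0.1)
  }
})

test_that("the overlap density at slowdown onset approaches the end-tag density", {
  ens <- noisy_ensemble()
  ratios <- vapply(ens$events[1:3], function(e) {
    ev <- track_event(e$kymo)
    seg <- segment_phases(ev$velocity)
    transition_density_check(ev, seg)
  }, numeric(1))
  expect_true(all(is.finite(ratios)))
  expect_gt(mean(ratios), 0.7)
  expect_true(all(ratios <= 1.2))
})
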