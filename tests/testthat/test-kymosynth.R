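test_that("roadblock stalling makes the final overlap the sum of the end-tag lengths", {
  p <- simulation_params(ML1 = 8000, ML2 = 6000, s0 = 3000,
                         endtag_fraction = 0.15, endtag_growth_rate = Inf,
                         duration = 300)
  tr1 <- simulate_pair(p)   # saturated end-tags: 1200 nm and 900 nm
  f <- tr1$frames
  expect_true(any(f$phase == 3))
  expect_equal(tr1$L_FO_true, 1200 + 900)
  expect_equal(tr1$L_FO_true,
               f$LET1_nm[nrow(f)] + f$LET2_nm[nrow(f)])
})

test_that("zero sliding efficiency freezes the pair", {
  tr <- simulate_pair(simulation_params(S = 0, duration = 60))
  expect_true(all(tr$frames$v_nm_per_s == 0))
  expect_equal(diff(range(tr$frames$L_overlap_nm)), 0)
})

test_that("phase-1 velocity is constant while the overlap shrinks", {
  p <- simulation_params(ML1 = 12000, ML2 = 12000, s0 = 2000,
                         slowdown_width = 1e-6, endtag_fraction = 0.1,
                         endtag_growth_rate = Inf, duration = 60)
  tr <- simulate_pair(p)
  f <- tr$frames
  ph1 <- f$phase == 1
  expect_gt(sum(ph1), 100)
  expect_lt(diff(range(f$v_nm_per_s[ph1])), 1e-9)
  expect_lt(f$L_overlap_nm[sum(ph1)], f$L_overlap_nm[1])  # overlap shrank
})

test_that("phase labels are non-decreasing and velocity non-increasing", {
  for (seed in 1:3) {
    ens <- simulate_ensemble(2, simulation_params(endtag_fraction = 0.4,
                                                  endtag_growth_rate = Inf,
                                                  duration = 300),
                             seed = seed)
    for (e in ens$events) {
      f <- e$truth$frames
      expect_true(all(diff(f$phase) >= 0))
      expect_true(all(diff(f$v_nm_per_s) <= 1e-9))
      on <- which(f$v_nm_per_s > 0)[1]
      expect_true(all(diff(f$L_overlap_nm[on:nrow(f)]) <= 1e-9))
    }
  }
})

test_that("phase-1 velocity depends on the initial untagged overlap only", {
  base <- simulation_params(endtag_growth_rate = Inf, endtag_fraction = 0,
                            duration = 30)
  # same initial overlap (3000 nm), very different filament lengths
  a <- base; a$ML1 <- 6000; a$ML2 <- 9000; a$s0 <- 3000
  b <- base; b$ML1 <- 12000; b$ML2 <- 4000; b$s0 <- 9000
  va <- simulate_pair(a)$v_phase1_true
  vb <- simulate_pair(b)$v_phase1_true
  expect_equal(va, vb, tolerance = 1e-12)

  # monotonicity in S and a
  s_hi <- base; s_hi$ML1 <- 6000; s_hi$ML2 <- 9000; s_hi$s0 <- 3000
  s_hi$S <- base$S + 0.2
  expect_gt(simulate_pair(s_hi)$v_phase1_true, va)
  a_hi <- a; a_hi$a <- a$a * 2
  expect_gt(simulate_pair(a_hi)$v_phase1_true, va)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(simulation_params(s0 = 20000), "overlap")
  expect_error(simulation_params(duration = 0.1, dt = 0.5), "dt")
  expect_error(simulation_params(S = 1.5))
  expect_error(simulation_params(endtag_fraction = 0.6))
})

test_that("noiseless unblurred rendering conserves flux times length", {
  p <- simulation_params(duration = 5, endtag_growth_rate = Inf,
                         endtag_fraction = 0.2)
  tr <- simulate_pair(p)
  o <- optics_params(psf_sigma = 0, background = 0)
  k <- render_kymograph(tr, o, noise = FALSE)
  f <- tr$frames[1, ]
  # MT channel: total = mt_flux * (ML1 + ML2)
  expect_equal(sum(k$mt[1, ]), o$mt_flux * (p$ML1 + p$ML2),
               tolerance = 1e-10)
  # GFP channel decomposes into the three region classes (end-tags lie
  # inside the overlap in this geometry)
  tag_len <- f$L_overlap_nm - f$L_untagged_nm
  single <- (p$ML1 + p$ML2) - 2 * f$L_overlap_nm
  expected <- o$rho_endtag * tag_len +
    o$rho_untagged * f$L_untagged_nm + o$rho_single * single
  expect_equal(sum(k$gfp[1, ]), expected, tolerance = 1e-6)
})

test_that("zero fluxes and zero background give an all-zero image", {
  p <- simulation_params(duration = 3)
  tr <- simulate_pair(p)
  o <- optics_params(background = 0)
  o$rho_single <- o$rho_untagged <- o$rho_endtag <- o$mt_flux <- 0
  k <- render_kymograph(tr, o, noise = TRUE)
  expect_true(all(k$mt == 0) && all(k$gfp == 0))
})

test_that("rendering is deterministic given the seed and Poisson about the noiseless mean", {
  p <- simulation_params(duration = 3)
  tr <- simulate_pair(p)
  o <- optics_params(seed = 11)
  k1 <- render_kymograph(tr, o)
  k2 <- render_kymograph(tr, o)
  expect_identical(k1$gfp, k2$gfp)
  k0 <- render_kymograph(tr, o, noise = FALSE)
  acc <- 0
  for (s in 1:120) {
    o$seed <- s
    acc <- acc + render_kymograph(tr, o)$gfp
  }
  m <- acc / 120
  # mean over seeds approaches the Poisson mean; relative error at bright px
  bright <- k0$gfp > 500
  expect_lt(max(abs(m[bright] - k0$gfp[bright]) / k0$gfp[bright]), 0.05)
})

test_that("ensembles are reproducible and length-scaled end-tags set the final overlap slope", {
  p <- simulation_params(endtag_fraction = 0.4, endtag_growth_rate = Inf,
                         duration = 300)
  e1 <- simulate_ensemble(12, p, seed = 5)
  e2 <- simulate_ensemble(12, p, seed = 5)
  expect_identical(e1$truth_table, e2$truth_table)
  tt <- e1$truth_table[e1$truth_table$stalled, ]
  fit <- linear_fit(tt$ML1_nm + tt$ML2_nm, tt$L_FO_nm)
  expect_equal(fit$slope, 0.4, tolerance = 0.05)

  # longer initial overlaps slide faster (qualitative)
  expect_gt(cor(e1$truth_table$L0_nm, e1$truth_table$v_phase1_nm_s), 0.3)
})
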