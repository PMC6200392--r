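test_that("edges of a noiseless render are localized within half a pixel", {
  fx <- noiseless_event()
  k <- fx$kymo
  st <- detect_edges(k, "mt", 1)
  expect_equal(nrow(st), 1)  # one contiguous filament union
  expect_lt(abs(st$start_nm - 0), k$pixel_size / 2)
  expect_lt(abs(st$end_nm - (fx$params$s0 + fx$params$ML2)),
            k$pixel_size / 2)

  ob <- overlap_bounds(k, 1)
  expect_true(ob$ok)
  expect_lt(abs(ob$o1 - fx$params$s0), k$pixel_size / 2)
  expect_lt(abs(ob$o2 - fx$params$ML1), k$pixel_size / 2)
})

test_that("uniform images contain no structure", {
  m <- matrix(100, 40, 120)
  k <- kymograph(m, m, pixel_size = 100, frame_interval = 1 / 3)
  st <- detect_edges(k, "gfp", 5)
  expect_equal(nrow(st), 0)
  ob <- overlap_bounds(k, 5)
  expect_false(ob$ok)
})

test_that("edge localization stays within a pixel down to SNR 3", {
  p <- simulation_params(ML1 = 8000, ML2 = 8000, s0 = 500,
                         endtag_fraction = 0.4, endtag_growth_rate = Inf,
                         duration = 10)
  tr <- simulate_pair(p)
  for (snr in c(3, 5, 10)) {
    o <- optics_at_snr(optics_params(seed = 100 + snr), snr)
    k <- render_kymograph(tr, o)
    errs <- vapply(seq_len(nrow(k$mt)), function(fr) {
      ob <- overlap_bounds(k, fr)
      if (!isTRUE(ob$ok)) return(NA_real_)
      ob$o1 - tr$frames$s_nm[fr]
    }, numeric(1))
    expect_lt(sqrt(mean(errs^2, na.rm = TRUE)), k$pixel_size)
  }
})

test_that("end-tag segmentation recovers constructed plateaus", {
  prof <- profile_fixture(bg = 20, untagged = 500, endtag = 1200,
                          tag1_px = 10, tag2_px = 10, overlap = c(11, 50))
  et <- segment_end_tags(prof, c(11, 50), bg = 20, noise_sd = 5,
                         px = 100, origin = 0)
  expect_true(et$present)
  expect_true(et$resolved)
  expect_equal(et$LET1, 1000, tolerance = 0.1)  # 10 px at 100 nm
  expect_equal(et$LET2, 1000, tolerance = 0.1)
})

test_that("flat profiles yield no end-tags and merged tags are unresolved", {
  flat <- rep(520, 40)
  et <- segment_end_tags(flat, c(5, 36), bg = 20, noise_sd = 5,
                         px = 100, origin = 0)
  expect_false(et$present)

  # end-tags merged to within one pixel: present but not resolvable
  merged <- profile_fixture(tag1_px = 19, tag2_px = 20, overlap = c(11, 50))
  et2 <- segment_end_tags(merged, c(11, 50), bg = 20, noise_sd = 5,
                          px = 100, origin = 0)
  expect_true(et2$present)
  expect_false(et2$resolved)
})

test_that("the overlap intensity partitions into untagged plus end-tag parts", {
  fx <- noiseless_event()
  for (fr in c(1, 50, 100)) {
    m <- measure_frame(fx$kymo, fr)
    if (!m$ok || !m$endtags_present) next
    expect_equal(m$I_overlap, m$I_untagged + m$IET1 + m$IET2,
                 tolerance = 0.01)
  }
})

test_that("intensity measurements recover the rendered fluxes", {
  # wide untagged region, tags at the ends, moderate noise
  p <- simulation_params(ML1 = 12000, ML2 = 12000, s0 = 1000,
                         endtag_fraction = 0.1, endtag_growth_rate = Inf,
                         duration = 5)
  tr <- simulate_pair(p)
  o <- optics_params(seed = 3)
  k <- render_kymograph(tr, o)
  m <- measure_frame(k, 1)
  expect_true(m$ok && m$endtags_resolved)
  # untagged intensity within a few percent of flux * length
  expect_equal(m$I_untagged, o$rho_untagged * m$L_untagged_nm,
               tolerance = 0.05)
  expect_equal(m$rho_untagged, 3.5, tolerance = 0.1)
})

test_that("measurements are invariant to a global GFP intensity scale", {
  fx <- noiseless_event()
  k <- fx$kymo
  k2 <- k
  k2$gfp <- k$gfp * 3
  m1 <- measure_frame(k, 30)
  m2 <- measure_frame(k2, 30)
  expect_equal(m2$L_overlap_nm, m1$L_overlap_nm)
  expect_equal(m2$LET1_nm, m1$LET1_nm, tolerance = 1e-6)
  expect_equal(m2$LET2_nm, m1$LET2_nm, tolerance = 1e-6)
  # A.U. quantities scale linearly
  expect_equal(m2$I_untagged, 3 * m1$I_untagged, tolerance = 1e-6)
  expect_equal(m2$rho_untagged, 3 * m1$rho_untagged, tolerance = 1e-6)
})

test_that("a full noiseless event round-trips within one pixel", {
  fx <- noiseless_event()
  ev <- track_event(fx$kymo)
  px <- fx$kymo$pixel_size
  truth <- fx$truth$frames
  expect_true(ev$trackable)
  expect_lt(abs(ev$L0_nm - truth$L_overlap_nm[1]), px)
  expect_lt(abs(ev$ML1_nm - fx$params$ML1), px)
  expect_lt(abs(ev$ML2_nm - fx$params$ML2), px)
  expect_false(is.na(ev$L_FO_nm))
  expect_lt(abs(ev$L_FO_nm - fx$truth$L_FO_true), px)
  expect_lt(abs(ev$LET1_nm - 0.4 * fx$params$ML1), px)
  expect_lt(abs(ev$LET2_nm - 0.4 * fx$params$ML2), px)
})

test_that("events without a stall are flagged as such", {
  p <- simulation_params(ML1 = 12000, ML2 = 12000, s0 = 1000,
                         endtag_fraction = 0.1, endtag_growth_rate = Inf,
                         duration = 40)
  tr <- simulate_pair(p)
  expect_true(is.na(tr$L_FO_true))
  k <- render_kymograph(tr, optics_params(seed = 5))
  ev <- track_event(k)
  expect_true(is.na(ev$L_FO_nm))
  expect_true(is.na(ev$stall_frame))
})
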