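make_records <- function(n = 6) {
  data.frame(
    id = seq_len(n), condition = "A",
    ML1_nm = 8000, ML2_nm = 6000, L0_nm = 3000,
    v_phase1_nm_s = 40, L_FO_nm = 2000, LET1_nm = 1200, LET2_nm = 800,
    rho_untagged_initial = 3.5,
    n_microtubules = 2L, encountered_bundle = FALSE,
    proximal_plus_ends_at_start = FALSE,
    overlap_edge_distinguishable = TRUE,
    mt_edges_distinguishable = TRUE)
}

test_that("event exclusion applies the screening criteria in order", {
  r <- make_records(5)
  r$n_microtubules[1] <- 3L
  r$encountered_bundle[2] <- TRUE
  r$L0_nm[3] <- 6000
  r$overlap_edge_distinguishable[4] <- FALSE

  out <- filter_events(r, "velocity_vs_overlap")
  expect_equal(nrow(out$included), 1)
  expect_equal(out$excluded$reason,
               c("multiple_mts", "bundle_encounter",
                 "overlap_gt_5um", "overlap_edge_indistinct"))

  # the >5 um rule applies only to the velocity analysis
  out_len <- filter_events(r, "length_vs_final_overlap")
  expect_true(3 %in% out_len$included$id)

  # partition-complete and idempotent
  expect_equal(nrow(out$included) + nrow(out$excluded), nrow(r))
  again <- filter_events(out$included, "velocity_vs_overlap")
  expect_equal(nrow(again$excluded), 0)
  expect_error(filter_events(r, "unknown_analysis"))
})

test_that("a clean record survives every analysis filter", {
  r <- make_records(1)
  for (a in c("general", "velocity_vs_overlap", "length_vs_final_overlap"))
    expect_equal(nrow(filter_events(r, a)$included), 1)
})

test_that("gaussian histogram fits recover the sampling distribution", {
  set.seed(101)
  x <- rnorm(10000, 3.5, 1.7)
  fit <- gaussian_fit(x, bin_width = 0.5)
  expect_equal(fit$mu, 3.5, tolerance = 0.05 / 3.5)
  expect_equal(fit$sigma, 1.7, tolerance = 0.05)
  # mu is within sd/sqrt(n) of the sample mean
  expect_lt(abs(fit$mu - mean(x)), 1.7 / sqrt(length(x)) * 3)
})

test_that("gaussian fit of symmetric data centres at the midpoint", {
  x <- rep(c(2, 4), each = 30) + rep(c(-0.01, 0.01), 30)
  fit <- gaussian_fit(x, bin_width = 0.25)
  expect_equal(fit$mu, 3, tolerance = 0.15)
  expect_error(gaussian_fit(rep(1, 50)), "identical")
  expect_error(gaussian_fit(rnorm(5)), "20 values")
})

test_that("pearson handles exact and degenerate relationships", {
  x <- 1:20
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  expect_warning(r0 <- pearson(x, rep(3, 20)), "zero variance")
  expect_true(is.na(r0))
  expect_error(pearson(1:2, 1:2), "3 finite")
  # affine invariance
  set.seed(2); a <- rnorm(30); b <- a + rnorm(30)
  expect_equal(pearson(a, b), pearson(10 * a - 3, 0.5 * b + 7))
})

test_that("linear_fit is exact on exact lines and transforms predictably", {
  x <- seq(0, 10, 0.5)
  f <- linear_fit(x, 0.8 * x + 2)
  expect_equal(f$slope, 0.8)
  expect_equal(f$intercept, 2)
  expect_equal(f$r, 1)
  f2 <- linear_fit(2 * x, 0.8 * x + 2)  # x rescaled: slope halves
  expect_equal(f2$slope, 0.4)
  expect_error(linear_fit(rep(1, 5), 1:5), "zero variance")
})

test_that("binned means cover the range and drop empty bins", {
  x <- c(0.1, 0.2, 1.1, 1.2, 5.1)
  y <- c(1, 3, 10, 12, 7)
  b <- binned_means(x, y, 1)
  expect_equal(nrow(b), 3)        # bins [0,1), [1,2), [5,6) only
  expect_equal(b$mean, c(2, 11, 7))
  expect_equal(b$n, c(2, 2, 1))
  # constant y: every bin mean equals that constant
  b2 <- binned_means(runif(50, 0, 5), rep(4.2, 50), 0.5)
  expect_true(all(b2$mean == 4.2))
  # y = x on a grid with bin width = step: means equal bin centres
  g <- seq(0.25, 4.75, by = 0.5)
  b3 <- binned_means(g, g, 0.5)
  expect_equal(b3$mean, b3$center)
})

test_that("molecule densities follow the single-molecule calibration", {
  expect_equal(molecules_per_micron(1000, 2000, 50), 10)
  expect_equal(molecules_per_micron(0, 2000, 50), 0)
  expect_error(molecules_per_micron(100, 2000, 0), "positive")
  expect_error(molecules_per_micron(100, 0, 50), "positive")
})

test_that("measured untagged densities calibrate to ~10 molecules per micron", {
  # one rendered frame at the flagship condition: with the single-molecule
  # unit intensity set to rho_untagged * 100 nm (one molecule per ~100 nm,
  # i.e. ~10 per um), the measured density converts back to ~10/um
  p <- simulation_params(ML1 = 12000, ML2 = 12000, s0 = 1000,
                         endtag_fraction = 0.1, endtag_growth_rate = Inf,
                         duration = 5)
  k <- render_kymograph(simulate_pair(p), optics_params(seed = 8))
  m <- measure_frame(k, 1)
  unit_intensity <- 3.5 * 100   # A.U. per molecule
  dens <- molecules_per_micron(m$I_untagged, m$L_untagged_nm, unit_intensity)
  expect_equal(dens, 10, tolerance = 0.08)
})
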