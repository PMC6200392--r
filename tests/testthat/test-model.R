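test_that("the saturating velocity-overlap relation evaluates correctly", {
  expect_equal(mm_velocity(2000, v0 = 100, KL = 2000), 50)  # half-max at KL
  expect_equal(mm_velocity(0, v0 = 80, KL = 1500), 0)
  expect_equal(mm_velocity(6000, v0 = 100, KL = 2000), 75)
  expect_error(mm_velocity(-5, v0 = 10, KL = 10), "non-negative")
})

test_that("fit_mm is a fixed point on noiseless model data", {
  L <- seq(500, 5000, length.out = 25)
  v <- mm_velocity(L, v0 = 80, KL = 1500)
  fit <- fit_mm(L, v)
  expect_equal(unname(coef(fit)), c(80, 1500), tolerance = 1e-6)
  expect_equal(unname(predict(fit, data.frame(L = 1500))), 40,
               tolerance = 1e-6)
})

test_that("fit_mm enforces its preconditions", {
  expect_error(fit_mm(c(1000, 2000), c(10, 20)), "4 points")
  expect_error(fit_mm(c(1000, 1100, 1200, 1300), c(1, 2, 3, 4)),
               "2-fold")
})

test_that("fit_mm recovers parameters from noisy ensembles", {
  # KL is weakly identified when the data stop near the bend (its
  # Cramer-Rao bound here is ~20% relative sd), so the assertion for KL is
  # looser than for v0
  set.seed(2024)
  errs <- replicate(60, {
    L <- runif(60, 500, 5000)
    v <- mm_velocity(L, 80, 1500) + rnorm(60, 0, 10)
    cf <- coef(fit_mm(L, v))
    abs(cf / c(80, 1500) - 1)
  })
  expect_lt(median(errs[1, ]), 0.15)  # v0
  expect_lt(median(errs[2, ]), 0.30)  # KL
})

test_that("the motor-ensemble velocity law behaves at its anchors", {
  expect_equal(ensemble_velocity(100, 0.5, 0), 0)
  expect_equal(ensemble_velocity(100, 1, 1), 100)
  expect_equal(ensemble_velocity(100, 0.5, 1), 50)
  # strictly increasing in each argument
  expect_gt(ensemble_velocity(100, 0.5, 2), ensemble_velocity(100, 0.5, 1))
  expect_gt(ensemble_velocity(100, 0.6, 1), ensemble_velocity(100, 0.5, 1))
  expect_gt(ensemble_velocity(110, 0.5, 1), ensemble_velocity(100, 0.5, 1))
})

test_that("molecule counts follow occupancy times binding sites", {
  expect_equal(n_from_overlap(0.01, 8000, 8), 10)
  expect_equal(n_from_overlap(1, 8, 8), 1)
  expect_equal(n_from_overlap(0.1, 1600, 8), 20)
  expect_error(n_from_overlap(0, 100, 8))
})

test_that("sliding efficiency solves the half-maximum condition", {
  expect_equal(efficiency(KL = 800, a = 0.01, delta = 8), 0.5)  # N = 1
  expect_equal(efficiency(KL = 1600, a = 0.01, delta = 8),
               1 - 2^(-1 / 2), tolerance = 1e-12)              # N = 2
  # strictly decreasing in a * KL
  S <- efficiency(KL = 1600, a = seq(0.01, 0.1, 0.01))
  expect_true(all(diff(S) < 0))
})

test_that("efficiency and the ensemble law close on the half-max point", {
  # brute-force oracle: solve v(L) = v0/2 with N(L) = a L / delta, then
  # efficiency(KL) must return the S we started from
  for (S in c(0.03, 0.1, 0.3, 0.6)) {
    for (a in c(0.01, 0.05, 0.1)) {
      f <- function(L) ensemble_velocity(1, S, n_from_overlap(a, L, 8)) - 0.5
      KL <- uniroot(f, c(1e-9, 1e9), tol = 1e-14)$root
      expect_equal(efficiency(KL, a, 8), S, tolerance = 1e-9)
    }
  }
})

test_that("the roadblock prediction is the scaled end-tag sum", {
  expect_equal(predict_final_overlap(1200, 800), 2000)
  expect_equal(predict_final_overlap(1200, 800, 0.8), 1600)
  expect_error(predict_final_overlap(1200, 800, 1.3), "occupancy_factor")
  expect_error(predict_final_overlap(-1, 800))
})
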