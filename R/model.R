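#' Saturating velocity-overlap relation
#'
#' Evaluates \eqn{v = v_0 L / (L + K_L)}: sliding velocity rises with
#' overlap length and saturates at \eqn{v_0}, with \eqn{K_L} the overlap
#' length at half-maximal velocity.
#'
#' @param L overlap length(s), nm; must be non-negative.
#' @param v0 maximal velocity (nm/s).
#' @param KL half-saturation overlap length (nm).
#' @return Velocity in nm/s.
#' @examples
#' mm_velocity(2000, v0 = 100, KL = 2000)  # 50
#' @export
mm_velocity <- function(L, v0, KL) {
  if (inherits(v0, "mm_fit")) {
    fit <- coef(v0); KL <- fit[["KL"]]; v0 <- fit[["v0"]]
  }
  stopifnot(v0 > 0, KL > 0)
  if (any(L < 0)) stop("overlap length must be non-negative")
  v0 * L / (L + KL)
}

#' Fit the velocity-overlap relation
#'
#' Nonlinear least squares of \eqn{v = v_0 L/(L+K_L)} on per-event points
#' (initial overlap length, phase-1 velocity). Initialization uses
#' \eqn{v_0 = \max(v)}, \eqn{K_L = \mathrm{median}(L)}; parameters are
#' bounded away from zero and above by ten times the data range for
#' numerical stability on sparse data. A binned mode (mean velocity per
#' overlap-length bin) is available for comparison with binned plots.
#'
#' @param L initial overlap lengths (nm).
#' @param v phase-1 velocities (nm/s).
#' @param binned if \code{TRUE}, fit bin means instead of raw points.
#' @param bin_width bin width (nm) for the binned mode.
#' @return An object of class \code{"mm_fit"} wrapping the
#'   \code{\link[minpack.lm]{nlsLM}} fit, with \code{coef}, \code{vcov},
#'   \code{predict}, \code{print} and \code{plot} methods.
#' @export
fit_mm <- function(L, v, binned = FALSE, bin_width = 500) {
  keep <- is.finite(L) & is.finite(v)
  L <- L[keep]; v <- v[keep]
  if (length(L) < 4)
    stop("need at least 4 points to fit the velocity-overlap relation")
  if (max(L) < 2 * min(L))
    stop("overlap lengths must span at least a 2-fold range")
  if (binned) {
    b <- binned_means(L, v, bin_width)
    L <- b$center; v <- b$mean
  }
  d <- data.frame(L = L, v = v)
  upper <- c(v0 = 10 * max(v), KL = 10 * max(L))
  starts <- list(
    list(v0 = max(v), KL = stats::median(L)),
    list(v0 = 1.3 * max(v), KL = unname(stats::quantile(L, 0.25))),
    list(v0 = 1.1 * max(v), KL = unname(stats::quantile(L, 0.75))))
  fit <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ v0 * L / (L + KL), data = d, start = s,
        lower = c(v0 = 1e-8, KL = 1e-8), upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(err) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    fit <- stats::nls(v ~ v0 * L / (L + KL), data = d,
                      start = starts[[1]], algorithm = "port",
                      lower = c(v0 = 1e-8, KL = 1e-8), upper = upper)
  cf <- stats::coef(fit)
  if (cf[["KL"]] > 0.999 * upper[["KL"]] || cf[["v0"]] > 0.999 * upper[["v0"]])
    stop("velocity-overlap fit ran into its parameter bounds ",
         "(v0 = ", signif(cf[["v0"]], 4), ", KL = ", signif(cf[["KL"]], 4),
         "); the data do not constrain the saturation")
  structure(list(fit = fit, v0 = cf[["v0"]], KL = cf[["KL"]],
                 n_points = nrow(d), binned = binned, data = d),
            class = "mm_fit")
}

#' @export
coef.mm_fit <- function(object, ...) c(v0 = object$v0, KL = object$KL)

#' @export
vcov.mm_fit <- function(object, ...) stats::vcov(object$fit)

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  L <- if (is.null(newdata)) object$data$L else newdata$L
  mm_velocity(L, object$v0, object$KL)
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Velocity-overlap fit: v = v0 * L / (L + KL)\n")
  cat(sprintf("  v0 = %.2f nm/s, KL = %.0f nm (n = %d%s)\n",
              x$v0, x$KL, x$n_points, if (x$binned) ", binned" else ""))
  invisible(x)
}

#' @export
summary.mm_fit <- function(object, ...) summary(object$fit, ...)

#' @export
plot.mm_fit <- function(x, ...) {
  graphics::plot(x$data$L / 1000, x$data$v, xlab = "initial overlap (um)",
                 ylab = "phase-1 velocity (nm/s)", ...)
  Lg <- seq(0, max(x$data$L), length.out = 200)
  graphics::lines(Lg / 1000, mm_velocity(Lg, x$v0, x$KL), col = "red", lwd = 2)
  invisible(x)
}

#' Motor-ensemble sliding velocity
#'
#' Probability that at least one of \eqn{N} independent complexes, each in
#' its sliding-competent configuration a fraction \eqn{S} of the time, is
#' engaged: \eqn{v = v_0 (1 - (1 - S)^N)}. \eqn{N} may be non-integer
#' (continuous extension, as it is estimated from lengths).
#'
#' @param v0 maximal velocity (nm/s).
#' @param S sliding efficiency in [0, 1].
#' @param N number of sliding-competent complexes, >= 0.
#' @return Velocity in nm/s.
#' @export
ensemble_velocity <- function(v0, S, N) {
  stopifnot(all(S >= 0), all(S <= 1), all(N >= 0), all(v0 >= 0))
  v0 * (1 - (1 - S)^N)
}

#' Number of sliding-competent complexes in an overlap
#'
#' \eqn{N = a L / \delta}: occupancy times the number of binding sites in
#' a length-\eqn{L} overlap, with \eqn{\delta} the binding-site length
#' (8 nm per tubulin dimer).
#'
#' @param a fractional occupancy of sliding-competent complexes (> 0).
#' @param L overlap length (nm, > 0).
#' @param delta binding-site length (nm, default 8).
#' @return N (dimensionless, possibly non-integer).
#' @export
n_from_overlap <- function(a, L, delta = 8) {
  stopifnot(all(a > 0), all(L > 0), delta > 0)
  a * L / delta
}

#' Sliding efficiency from the half-saturation overlap length
#'
#' At \eqn{L = K_L} the ensemble velocity is half-maximal, so
#' \eqn{(1 - S)^{N(K_L)} = 1/2} with \eqn{N(K_L) = a K_L / \delta}, giving
#' \eqn{S = 1 - 2^{-1/N}}. The efficiency is the per-complex analogue of a
#' motor duty ratio: the fraction of time a complex is dual-bound and
#' competent to slide.
#'
#' @param KL half-saturation overlap length (nm).
#' @param a fractional occupancy (may be a vector, e.g. 0.01-0.10).
#' @param delta binding-site length (nm).
#' @return S, same length as \code{a}.
#' @examples
#' efficiency(KL = 1600, a = c(0.01, 0.1))  # ~0.29 down to ~0.034
#' @export
efficiency <- function(KL, a, delta = 8) {
  stopifnot(KL > 0, delta > 0, all(a > 0))
  N <- n_from_overlap(a, KL, delta)
  if (any(N <= 0)) stop("N must be positive")
  1 - 0.5^(1 / N)
}

#' Sliding-efficiency table over an occupancy grid
#'
#' @param KL half-saturation overlap length (nm).
#' @param a occupancy grid (default 1-10\%).
#' @param delta binding-site length (nm).
#' @return data frame with columns \code{a}, \code{N}, \code{S}.
#' @export
efficiency_table <- function(KL, a = seq(0.01, 0.10, by = 0.01), delta = 8) {
  data.frame(a = a, N = n_from_overlap(a, KL, delta),
             S = efficiency(KL, a, delta))
}

#' Roadblock prediction for the final overlap length
#'
#' Under the roadblock mechanism sliding stalls when the two end-tags
#' collide, so the stable final overlap is the sum of the end-tag lengths,
#' scaled by the fraction of that sum retained at stall
#' (\code{occupancy_factor} 1 for saturated end-tags, < 1 for
#' sub-saturated conditions).
#'
#' @param LET1,LET2 end-tag lengths (nm, >= 0).
#' @param occupancy_factor fraction in (0, 1].
#' @return Predicted final overlap length (nm).
#' @examples
#' predict_final_overlap(1200, 800)  # 2000
#' @export
predict_final_overlap <- function(LET1, LET2, occupancy_factor = 1) {
  stopifnot(all(LET1 >= 0), all(LET2 >= 0))
  if (any(occupancy_factor <= 0) || any(occupancy_factor > 1))
    stop("occupancy_factor must lie in (0, 1]")
  occupancy_factor * (LET1 + LET2)
}
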