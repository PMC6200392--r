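#' Instantaneous sliding velocity from an edge trace
#'
#' Smooths the edge position with a centred moving average and
#' differentiates it: central differences in the interior, one-sided
#' differences at the end points. Frames where the edge was not tracked
#' propagate as \code{NA}; gaps are never interpolated silently.
#'
#' @param edge a data frame with columns \code{t_s} (strictly increasing)
#'   and \code{x_nm}, e.g. the \code{edge} element of [track_event()].
#' @param window odd moving-average window (frames), at least 3; 1 disables
#'   smoothing.
#' @return An object of class \code{"velocity_trace"}: data frame with
#'   columns \code{t_s} and \code{v_nm_s} on the same grid as the input,
#'   with the window stored as an attribute.
#' @examples
#' e <- data.frame(t_s = 0:20 / 3, x_nm = 46 * (0:20) / 3)
#' instantaneous_velocity(e)$v_nm_s  # constant 46 nm/s
#' @export
instantaneous_velocity <- function(edge, window = 5) {
  stopifnot(is.data.frame(edge), all(c("t_s", "x_nm") %in% names(edge)))
  n <- nrow(edge)
  if (sum(!is.na(edge$x_nm)) < 2)
    stop("need at least two tracked frames to differentiate")
  if (window > 1 && window %% 2 == 0)
    stop("smoothing window must be odd")
  if (window >= n)
    stop("smoothing window must be shorter than the trace")
  if (any(diff(edge$t_s) <= 0))
    stop("frame times must be strictly increasing")
  x_src <- edge$x_nm
  x <- edge$x_nm
  t <- edge$t_s
  tc <- t
  if (window > 1) {
    half <- (window - 1) / 2
    sm <- vapply(seq_len(n), function(i) {
      j <- max(1, i - half):min(n, i + half)
      c(mean(x[j]), mean(t[j]))       # NA if any gap inside the window
    }, numeric(2))
    xs <- sm[1, ]
    tc <- sm[2, ]   # effective sample time of each (partial) window
  } else xs <- x
  v <- rep(NA_real_, n)
  if (n >= 3)
    v[2:(n - 1)] <- (xs[3:n] - xs[1:(n - 2)]) / (tc[3:n] - tc[1:(n - 2)])
  v[1] <- (xs[2] - xs[1]) / (tc[2] - tc[1])
  v[n] <- (xs[n] - xs[n - 1]) / (tc[n] - tc[n - 1])
  structure(data.frame(t_s = t, v_nm_s = v),
            class = c("velocity_trace", "data.frame"), window = window,
            edge = data.frame(t_s = t, x_nm = x_src))
}

#' Segment the three kinetic phases of a sliding velocity trace
#'
#' Fits the trace with a continuous piecewise model: constant velocity
#' \eqn{v_1} up to \eqn{t_{12}} (phase 1), linear decay to zero on
#' \eqn{[t_{12}, t_{23}]} (phase 2), and zero afterwards (phase 3), by
#' least squares over an exhaustive changepoint grid. Nested degenerate
#' models (a single constant phase, or an immediate stall) are compared by
#' BIC and returned when they describe the trace better. Ties in the sum of
#' squares are broken toward the earliest \eqn{t_{12}} (conservative
#' phase-1 duration). In the position-domain path the reported phase-1
#' velocity is the fitted phase-1 slope, which is robust to changepoint
#' error; in the velocity-domain path it is the arithmetic mean of the
#' observed velocities over \eqn{[0, t_{12}]}.
#'
#' @param vt a [instantaneous_velocity()] result (or any data frame with
#'   \code{t_s}, \code{v_nm_s}).
#' @param min_frames minimum trace length.
#' @param grid_max maximum number of candidate changepoints per axis; longer
#'   traces are scanned on a coarse grid and refined locally.
#' @return An object of class \code{"phase_fit"}: list with \code{t12},
#'   \code{t23} (s), \code{v_phase1} (nm/s), \code{model} (one of
#'   \code{"three_phase"}, \code{"constant"}, \code{"stalled"}),
#'   \code{sse}, \code{bic}, \code{n}, and \code{phase} (per-frame labels
#'   on the input grid).
#' @export
segment_phases <- function(vt, min_frames = 20, grid_max = 300) {
  stopifnot(all(c("t_s", "v_nm_s") %in% names(vt)))
  keep <- !is.na(vt$v_nm_s)
  if (!any(keep)) stop("velocity trace is all NA")
  t <- vt$t_s[keep]
  v <- vt$v_nm_s[keep]
  n <- length(v)
  if (n < min_frames)
    stop("trace spans fewer than ", min_frames, " usable frames")

  # When the source edge trace is attached, fit the integrated model to the
  # raw positions instead: x(t) is piecewise linear / quadratic / constant
  # with iid localization noise, which localizes the changepoints with less
  # bias than least squares on the smoothed, differentiated trace.
  edge <- attr(vt, "edge")
  if (!is.null(edge) && sum(is.finite(edge$x_nm)) >= min_frames)
    return(segment_phases_position(vt, edge, grid_max))

  # prefix sums give the profiled SSE of the piecewise model in O(1) per
  # changepoint pair: phase-1 basis 1 on [1, i], linear decay on (i, j],
  # zero after; v1 enters linearly so it is profiled out analytically
  Sv <- cumsum(v); Svt <- cumsum(v * t)
  St <- cumsum(t); St2 <- cumsum(t^2)
  Sv2n <- sum(v^2)
  scan_pairs <- function(ci, best) {
    for (i in ci$i) {
      js <- ci$j[ci$j >= i]
      if (!length(js)) next
      tj1 <- t[pmin(js + 1L, n)]
      D <- tj1 - t[i]
      mid <- js > i & D > 0
      A <- tj1 * (Sv[js] - Sv[i]) - (Svt[js] - Svt[i])
      B <- tj1^2 * (js - i) - 2 * tj1 * (St[js] - St[i]) + (St2[js] - St2[i])
      svb <- Sv[i] + ifelse(mid, A / D, 0)
      sb2 <- i + ifelse(mid, B / D^2, 0)
      v1 <- svb / sb2
      sse <- Sv2n - v1^2 * sb2
      k <- which.min(sse)
      if (sse[k] < best$sse - 1e-12)
        best <- list(sse = sse[k], i = i, j = js[k])
    }
    best
  }
  step <- max(1L, ceiling(n / grid_max))
  cand <- unique(c(seq(1L, n - 1L, by = step), n - 1L))
  best <- scan_pairs(list(i = cand, j = cand), list(sse = Inf, i = 1L, j = 1L))
  if (step > 1L)  # local refinement around the coarse optimum
    best <- scan_pairs(list(
      i = max(1L, best$i - step):min(n - 1L, best$i + step),
      j = max(1L, best$j - step):min(n - 1L, best$j + step)), best)

  # Exact local refinement with the measurement kernel: a velocity trace
  # derived from a smoothed position by central differences is the true
  # velocity convolved with boxcar(window) * boxcar(2); fitting the raw
  # kinked model to that rounded corner biases short phases. Convolving the
  # model basis with the same kernel removes the bias.
  win <- attr(vt, "window")
  if (is.null(win) || !is.finite(win)) win <- 1L
  smooth_basis <- function(b) {
    if (win > 1) {
      half <- (win - 1) / 2
      cs <- cumsum(b)
      lo <- pmax(0L, seq_len(n) - half - 1L)
      hi <- pmin(n, seq_len(n) + half)
      b <- (cs[hi] - ifelse(lo == 0L, 0, cs[pmax(lo, 1L)])) / (hi - lo)
    }
    b2 <- b
    if (n >= 3) b2[2:(n - 1)] <- (b[1:(n - 2)] + b[3:n]) / 2
    b2
  }
  sse_exact <- function(i, j) {
    b <- numeric(n)
    if (i >= 1) b[1:i] <- 1
    if (j > i) b[(i + 1):j] <- (t[j + 1] - t[(i + 1):j]) / (t[j + 1] - t[i])
    bs <- smooth_basis(b)
    sb2 <- sum(bs^2)
    if (sb2 == 0) return(sum(v^2))
    sum(v^2) - (sum(v * bs))^2 / sb2
  }
  wloc <- step + 8L
  best_e <- list(sse = Inf, i = best$i, j = best$j)
  for (i in max(1L, best$i - wloc):min(n - 1L, best$i + wloc)) {
    for (j in max(i, best$j - wloc):min(n - 1L, best$j + wloc)) {
      s <- sse_exact(i, j)
      if (s < best_e$sse - 1e-12) best_e <- list(sse = s, i = i, j = j)
    }
  }
  best <- best_e

  sse3 <- best$sse
  sse_const <- sum((v - mean(v))^2)
  sse_zero <- sum(v^2)
  bic <- function(sse, k) n * log(max(sse, 1e-12) / n) + k * log(n)
  bics <- c(three_phase = bic(sse3, 3), constant = bic(sse_const, 1),
            stalled = bic(sse_zero, 0))
  model <- names(bics)[which.min(bics)]

  if (model == "constant") {
    t12 <- t23 <- t[n]; i <- n
  } else if (model == "stalled") {
    t12 <- t23 <- t[1]; i <- 0L
  } else {
    i <- best$i
    t12 <- (t[i] + t[min(i + 1L, n)]) / 2
    t23 <- (t[best$j] + t[min(best$j + 1L, n)]) / 2
  }
  v_phase1 <- if (i >= 1) mean(v[t <= t12]) else 0
  phase <- rep(NA_integer_, nrow(vt))
  phase[keep] <- ifelse(t <= t12, 1L, ifelse(t <= t23, 2L, 3L))
  structure(list(t12 = t12, t23 = t23, v_phase1 = v_phase1, model = model,
                 sse = switch(model, three_phase = sse3,
                              constant = sse_const, stalled = sse_zero),
                 bic = bics, n = n, phase = phase,
                 t = vt$t_s, v = vt$v_nm_s),
            class = "phase_fit")
}

# Position-domain fit of the three-phase model: x(t) = x0 + v1 * g(t) with
# g the integral of the unit velocity shape (1 on [0,t12], linear decay on
# (t12,t23], 0 after). For fixed changepoints the model is linear in
# (x0, v1), so the profiled SSE comes from a two-column regression.
segment_phases_position <- function(vt, edge, grid_max) {
  keep <- is.finite(edge$x_nm) & is.finite(edge$t_s)
  t <- edge$t_s[keep]
  x <- edge$x_nm[keep]
  n <- length(x)

  g_basis <- function(i, j) {
    ti <- t[i]; tj <- t[min(j + 1L, n)]
    if (tj <= ti) {
      ifelse(t <= ti, t, ti)
    } else {
      ifelse(t <= ti, t,
             ifelse(t <= tj,
                    ti + (tj * (t - ti) - (t^2 - ti^2) / 2) / (tj - ti),
                    ti + (tj - ti) / 2))
    }
  }
  sse_at <- function(i, j) {
    fit <- stats::.lm.fit(cbind(1, g_basis(i, j)), x)
    sum(fit$residuals^2)
  }
  scan <- function(is, js, best) {
    for (i in is) {
      for (j in js[js >= i]) {
        s <- sse_at(i, j)
        if (s < best$sse - 1e-9) best <- list(sse = s, i = i, j = j)
      }
    }
    best
  }
  step <- max(1L, ceiling(n / 80))
  cand <- unique(c(seq(1L, n - 1L, by = step), n - 1L))
  best <- scan(cand, cand, list(sse = Inf, i = 1L, j = 1L))
  while (step > 1L) {
    step2 <- max(1L, step %/% 4)
    best <- scan(unique(seq(max(1L, best$i - step), min(n - 1L, best$i + step), by = step2)),
                 unique(seq(max(1L, best$j - step), min(n - 1L, best$j + step), by = step2)),
                 best)
    step <- step2
  }

  sse3 <- best$sse
  lin <- stats::.lm.fit(cbind(1, t), x)       # constant velocity, no stall
  sse_lin <- sum(lin$residuals^2)
  sse_flat <- sum((x - mean(x))^2)            # stalled throughout
  bic <- function(sse, k) n * log(max(sse, 1e-12) / n) + k * log(n)
  bics <- c(three_phase = bic(sse3, 4), constant = bic(sse_lin, 2),
            stalled = bic(sse_flat, 1))
  model <- names(bics)[which.min(bics)]

  if (model == "constant") {
    t12 <- t23 <- t[n]
    v_phase1 <- lin$coefficients[2]
  } else if (model == "stalled") {
    t12 <- t23 <- t[1]
    v_phase1 <- 0
  } else {
    t12 <- (t[best$i] + t[min(best$i + 1L, n)]) / 2
    t23 <- (t[best$j] + t[min(best$j + 1L, n)]) / 2
    # phase-1 velocity: slope of the raw positions over phase 1, keeping a
    # margin before the estimated changepoint so that changepoint error
    # cannot mix slowdown frames into the estimate; the joint regression
    # slope is the fallback for very short phases
    ph1 <- t <= t12 - 3
    if (sum(ph1) >= 10) {
      sfit <- stats::.lm.fit(cbind(1, t[ph1]), x[ph1])
      v_phase1 <- sfit$coefficients[2]
    } else {
      refit <- stats::.lm.fit(cbind(1, g_basis(best$i, best$j)), x)
      v_phase1 <- refit$coefficients[2]
    }
  }
  v_phase1 <- unname(v_phase1)
  vkeep <- !is.na(vt$v_nm_s)
  tv <- vt$t_s[vkeep]
  phase <- rep(NA_integer_, nrow(vt))
  phase[vkeep] <- ifelse(tv <= t12, 1L, ifelse(tv <= t23, 2L, 3L))
  structure(list(t12 = t12, t23 = t23, v_phase1 = v_phase1, model = model,
                 sse = switch(model, three_phase = sse3,
                              constant = sse_lin, stalled = sse_flat),
                 bic = bics, n = n, phase = phase,
                 t = vt$t_s, v = vt$v_nm_s, domain = "position"),
            class = "phase_fit")
}

#' @export
print.phase_fit <- function(x, ...) {
  cat("Three-phase velocity segmentation (", x$model, " model)\n", sep = "")
  cat(sprintf("  t12 = %.2f s, t23 = %.2f s, v_phase1 = %.2f nm/s (n = %d)\n",
              x$t12, x$t23, x$v_phase1, x$n))
  invisible(x)
}

#' @export
coef.phase_fit <- function(object, ...) {
  c(t12 = object$t12, t23 = object$t23, v_phase1 = object$v_phase1)
}

#' @export
fitted.phase_fit <- function(object, ...) {
  t <- object$t
  ifelse(t <= object$t12, object$v_phase1,
         ifelse(t <= object$t23,
                object$v_phase1 * (object$t23 - t) /
                  max(object$t23 - object$t12, .Machine$double.eps), 0))
}

#' @export
plot.phase_fit <- function(x, ...) {
  graphics::plot(x$t, x$v, type = "l", col = "grey40",
                 xlab = "time (s)", ylab = "velocity (nm/s)", ...)
  graphics::lines(x$t, fitted(x), col = "red", lwd = 2)
  graphics::abline(v = c(x$t12, x$t23), lty = 2)
  invisible(x)
}

#' GFP density at the slowdown transition relative to the end-tag density
#'
#' Computes the ratio of the mean GFP density in the overlap at the
#' phase-1/phase-2 transition to the mean end-tag density over the frames
#' where the end-tags were resolved. Slowdown setting in when the overlap
#' density reaches a large fraction (around 70\%) of the end-tag density is
#' the signature of the steric roadblock mechanism.
#'
#' @param event an [track_event()] result.
#' @param seg a [segment_phases()] result for the same event.
#' @return The density ratio (dimensionless), or \code{NA} with a warning
#'   if the end-tags were never resolved.
#' @export
transition_density_check <- function(event, seg) {
  stopifnot(inherits(event, "event_trace"), inherits(seg, "phase_fit"))
  f <- event$frames
  res <- f$endtags_resolved & f$ok
  if (!any(res)) {
    warning("end-tags never resolved; transition density undefined")
    return(NA_real_)
  }
  rho_et <- mean((f$IET1[res] + f$IET2[res]) /
                   (f$LET1_nm[res] + f$LET2_nm[res]), na.rm = TRUE)
  k <- which.min(abs(f$t_s - seg$t12))
  rho_ov <- f$I_overlap[k] / f$L_overlap_nm[k]
  rho_ov / rho_et
}
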