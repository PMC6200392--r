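#' Simulate sliding and stalling of one crosslinked microtubule pair
#'
#' Integrates the 1-D mechanistic model of antiparallel sliding driven by
#' PRC1-Kif4A complexes. The number of sliding-competent complexes is set by
#' the untagged overlap at the start of the record, \eqn{N = a L_{untagged}(0)
#' / \delta}, and held fixed thereafter: the total amount of motor in the
#' overlap is conserved while the overlap shrinks, which is what makes the
#' phase-1 velocity constant. The unattenuated velocity follows the
#' motor-ensemble law \eqn{v = v_0 (1 - (1-S)^N)}.
#'
#' End-tags grow at each plus-end at \code{endtag_growth_rate} until reaching
#' their length-scaled plateau \code{endtag_fraction * ML_i}. Once the gap
#' between the two inner end-tag boundaries falls below
#' \code{slowdown_width} the velocity is attenuated by
#' \eqn{\sqrt{gap / w}} (phase 2) -- the square-root ramp makes the
#' velocity decay linearly in time and the end-tags collide in finite time
#' \eqn{2 w / v} -- and sliding halts
#' permanently when the boundaries meet (phase 3): the moving filament is
#' snapped to contact, so the final overlap equals \code{LET1 + LET2}
#' exactly, and end-tag lengths are frozen from the moment of collision.
#'
#' @param params a [simulation_params()] object.
#' @return An object of class \code{"sliding_truth"}: a list with
#'   \describe{
#'     \item{frames}{data frame with columns \code{t_s}, \code{s_nm},
#'       \code{L_overlap_nm}, \code{L_untagged_nm}, \code{LET1_nm},
#'       \code{LET2_nm}, \code{v_nm_per_s}, \code{phase} (1 constant,
#'       2 slowdown, 3 stall).}
#'     \item{L_FO_true}{final overlap length (nm), \code{NA} if no stall
#'       within the record.}
#'     \item{v_phase1_true}{the constant phase-1 velocity (nm/s).}
#'     \item{t12_true, t23_true}{continuous-time phase boundaries: when the
#'       inner end-tag gap first falls below \code{slowdown_width}, and the
#'       collision time (\code{NA} when not reached).}
#'     \item{N_true}{number of sliding-competent complexes.}
#'     \item{params}{the input parameters.}
#'   }
#' @examples
#' tr <- simulate_pair(simulation_params(duration = 120))
#' tail(tr$frames)
#' @export
simulate_pair <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  validate_simulation_params(params)
  p <- params
  n <- floor(p$duration / p$dt) + 1L
  t <- (seq_len(n) - 1L) * p$dt

  let_len <- function(tt, ML) {
    plateau <- p$endtag_fraction * ML
    if (is.finite(p$endtag_growth_rate))
      pmin(p$endtag_growth_rate * tt, plateau)
    else rep(plateau, length(tt))
  }
  LET1 <- let_len(t, p$ML1)
  LET2 <- let_len(t, p$ML2)

  s <- numeric(n)
  v <- numeric(n)
  phase <- integer(n)
  s[1] <- p$s0

  # complexes recruited to the initial untagged overlap, then conserved
  Lu0 <- untagged_length(s[1], LET1[1], LET2[1], p)
  N <- p$a * Lu0 / p$delta
  v_max <- p$v0 * (1 - (1 - p$S)^N)

  stalled <- FALSE
  t23_true <- NA_real_
  for (k in seq_len(n)) {
    gap <- (p$ML1 - LET1[k]) - (s[k] + LET2[k])
    vk <- 0
    if (!stalled) {
      att <- if (p$slowdown_width > 0) sqrt(max(0, min(1, gap / p$slowdown_width))) else 1
      vk <- v_max * att
      # contact within this step (or already overlapping, e.g. through
      # end-tag growth): snap to contact and stall permanently
      if (gap <= 0 || vk * p$dt >= gap) {
        if (is.na(t23_true))
          t23_true <- if (vk > 0 && gap > 0) t[k] + gap / vk else t[k]
        stalled <- TRUE
        s[k] <- p$ML1 - LET1[k] - LET2[k]
        if (k < n) {                   # end-tags frozen at collision
          LET1[(k + 1):n] <- LET1[k]
          LET2[(k + 1):n] <- LET2[k]
        }
      }
    }
    if (stalled) {
      v[k] <- 0
      phase[k] <- 3L
      if (k < n) s[k + 1] <- s[k]
    } else {
      v[k] <- vk
      phase[k] <- if (gap >= p$slowdown_width) 1L else 2L
      if (k < n) s[k + 1] <- s[k] + v[k] * p$dt
    }
  }

  # continuous phase-1 -> 2 boundary: linear interpolation of the gap
  # across the step in which it first drops below slowdown_width
  gaps <- (p$ML1 - LET1) - (s + LET2)
  t12_true <- NA_real_
  k2 <- which(phase == 2L)[1]
  if (!is.na(k2)) {
    if (k2 == 1L) t12_true <- 0
    else {
      drop <- gaps[k2 - 1L] - gaps[k2]
      t12_true <- if (drop > 0)
        t[k2 - 1L] + (gaps[k2 - 1L] - p$slowdown_width) / drop * p$dt
      else t[k2 - 1L]
    }
  } else if (any(phase == 3L)) t12_true <- t23_true

  L_ov <- pmax(0, pmin(p$ML1, s + p$ML2) - pmax(0, s))
  L_un <- mapply(untagged_length, s, LET1, LET2, MoreArgs = list(p = p))

  frames <- data.frame(t_s = t, s_nm = s, L_overlap_nm = L_ov,
                       L_untagged_nm = L_un, LET1_nm = LET1, LET2_nm = LET2,
                       v_nm_per_s = v, phase = phase)
  structure(list(frames = frames,
                 L_FO_true = if (any(phase == 3L))
                   L_ov[match(3L, phase)] else NA_real_,
                 v_phase1_true = v_max, N_true = N,
                 t12_true = t12_true, t23_true = t23_true, params = p),
            class = "sliding_truth")
}

# length of the untagged part of the overlap for one configuration
untagged_length <- function(s, LET1, LET2, p) {
  lo <- max(s + LET2, max(0, s))
  hi <- min(p$ML1 - LET1, min(p$ML1, s + p$ML2))
  max(0, hi - lo)
}

#' @export
print.sliding_truth <- function(x, ...) {
  f <- x$frames
  cat("Ground-truth sliding trajectory\n")
  cat(sprintf("  %d frames over %.1f s; N = %.2f complexes, phase-1 v = %.1f nm/s\n",
              nrow(f), max(f$t_s), x$N_true, x$v_phase1_true))
  cat(sprintf("  overlap %.0f -> %.0f nm; phases reached: %s\n",
              f$L_overlap_nm[1], f$L_overlap_nm[nrow(f)],
              paste(sort(unique(f$phase)), collapse = ",")))
  if (!is.na(x$L_FO_true))
    cat(sprintf("  stalled; final overlap L_FO = %.1f nm (= LET1+LET2)\n",
                x$L_FO_true))
  else cat("  no stall within the record\n")
  invisible(x)
}

#' @export
plot.sliding_truth <- function(x, ...) {
  f <- x$frames
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(f$t_s, f$v_nm_per_s, type = "l", xlab = "time (s)",
                 ylab = "velocity (nm/s)", ...)
  graphics::plot(f$t_s, f$L_overlap_nm / 1000, type = "l", xlab = "time (s)",
                 ylab = "overlap (um)", ...)
  invisible(x)
}

#' Simulate an ensemble of sliding events
#'
#' Draws microtubule lengths uniformly from \code{ml_range}, samples a
#' starting position \code{s0} compatible with roadblock stalling (both
#' plus-ends inside the partner filament, and an initial clearance of at
#' least \code{slowdown_width} + 500 nm between the saturated inner end-tag
#' boundaries, the configuration the sliding assay selects for), simulates
#' each pair, and optionally renders kymographs.
#'
#' Geometrically incompatible length pairs are resampled up to
#' \code{max_tries} times per event before the call errors out.
#'
#' @param n number of events.
#' @param params a [simulation_params()] template; \code{ML1}, \code{ML2}
#'   and \code{s0} are resampled per event.
#' @param optics an [optics_params()] object, or \code{NULL} to skip
#'   rendering.
#' @param ml_range length range (nm) for both microtubules.
#' @param L0_range if given, the initial overlap length is drawn uniformly
#'   from this range (nm) and \code{s0 = ML1 - L0}; used for
#'   velocity-versus-overlap ensembles where end-tags grow from zero. When
#'   \code{NULL} (default), \code{s0} is drawn to leave at least
#'   \code{slowdown_width} + 500 nm of clearance between the saturated
#'   inner end-tag boundaries.
#' @param seed integer seed; the whole ensemble is reproducible given it.
#' @param max_tries resampling cap for incompatible geometries.
#' @return An object of class \code{"sliding_ensemble"}: list with
#'   \code{events} (each a list of \code{truth} and optional \code{kymo}),
#'   and \code{truth_table}, a per-event data frame of ground-truth summaries
#'   (\code{ML1_nm}, \code{ML2_nm}, \code{s0_nm}, \code{L0_nm},
#'   \code{v_phase1_nm_s}, \code{L_FO_nm}, \code{LET1_nm}, \code{LET2_nm},
#'   \code{stalled}).
#' @export
simulate_ensemble <- function(n, params = simulation_params(),
                              optics = NULL,
                              ml_range = c(4000, 10000),
                              L0_range = NULL,
                              seed = 1L, max_tries = 100L) {
  stopifnot(n >= 1, inherits(params, "simulation_params"),
            length(ml_range) == 2, ml_range[1] > 0,
            ml_range[2] >= ml_range[1])
  set.seed(as.integer(seed))
  event_seeds <- sample.int(.Machine$integer.max - 1L, n)
  events <- vector("list", n)
  for (i in seq_len(n)) {
    geom <- NULL
    for (try in seq_len(max_tries)) {
      ML1 <- stats::runif(1, ml_range[1], ml_range[2])
      ML2 <- stats::runif(1, ml_range[1], ml_range[2])
      if (is.null(L0_range)) {
        # leave clearance between the saturated inner end-tag boundaries
        let_sum <- params$endtag_fraction * (ML1 + ML2)
        s0_min <- max(0, ML1 - ML2)
        s0_max <- ML1 - let_sum - params$slowdown_width - 500
        if (s0_max > s0_min) {
          geom <- list(ML1 = ML1, ML2 = ML2,
                       s0 = stats::runif(1, s0_min, s0_max))
          break
        }
      } else {
        # prescribe the initial overlap; both plus-ends must lie inside the
        # partner filament (s0 >= 0 and s0 + ML2 >= ML1)
        L0 <- stats::runif(1, L0_range[1], L0_range[2])
        if (L0 <= min(ML1, ML2)) {
          geom <- list(ML1 = ML1, ML2 = ML2, s0 = ML1 - L0)
          break
        }
      }
    }
    if (is.null(geom))
      stop("could not sample a stall-compatible geometry in ", max_tries,
           " tries; widen ml_range or reduce endtag_fraction")
    p <- params
    p$ML1 <- geom$ML1; p$ML2 <- geom$ML2; p$s0 <- geom$s0
    truth <- simulate_pair(p)
    kymo <- NULL
    if (!is.null(optics)) {
      o <- optics
      o$seed <- event_seeds[i]
      kymo <- render_kymograph(truth, o)
    }
    events[[i]] <- list(truth = truth, kymo = kymo, id = i)
  }
  tt <- do.call(rbind, lapply(events, function(e) {
    f <- e$truth$frames
    last <- nrow(f)
    data.frame(id = e$id,
               ML1_nm = e$truth$params$ML1, ML2_nm = e$truth$params$ML2,
               s0_nm = e$truth$params$s0, L0_nm = f$L_overlap_nm[1],
               v_phase1_nm_s = e$truth$v_phase1_true,
               L_FO_nm = e$truth$L_FO_true,
               LET1_nm = f$LET1_nm[last], LET2_nm = f$LET2_nm[last],
               stalled = any(f$phase == 3L))
  }))
  structure(list(events = events, truth_table = tt, seed = seed),
            class = "sliding_ensemble")
}

#' @export
print.sliding_ensemble <- function(x, ...) {
  tt <- x$truth_table
  cat(sprintf("Simulated sliding ensemble: %d events (seed %s)\n",
              nrow(tt), format(x$seed)))
  cat(sprintf("  stalled: %d/%d; phase-1 velocity %.1f +/- %.1f nm/s\n",
              sum(tt$stalled), nrow(tt),
              mean(tt$v_phase1_nm_s), stats::sd(tt$v_phase1_nm_s)))
  invisible(x)
}
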