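#' Simulation parameters for a sliding microtubule pair
#'
#' Bundles the mechanical parameters of the sliding model: geometry of the
#' two filaments, the motor-ensemble velocity law, end-tag growth, and the
#' time grid. All lengths are in nanometres, times in seconds.
#'
#' The immobilized microtubule spans \code{[0, ML1]} with its plus-end at
#' \code{ML1}; the moving microtubule spans \code{[s, s + ML2]} with its
#' plus-end at \code{s}. Plus-end-directed stepping of Kif4A on the
#' immobilized lattice transports the moving filament toward the immobilized
#' plus-end, i.e. sliding increases \code{s}.
#'
#' @param ML1 immobilized microtubule length (nm).
#' @param ML2 moving microtubule length (nm).
#' @param s0 initial position of the moving microtubule plus-end (nm).
#' @param v0 maximal sliding velocity (nm/s).
#' @param S sliding efficiency: fraction of time a PRC1-Kif4A complex is in
#'   the dual-bound, sliding-competent configuration (0-1).
#' @param a fractional occupancy of sliding-competent complexes (0-1).
#' @param delta binding-site length on the microtubule lattice (nm).
#' @param endtag_fraction end-tag length per unit microtubule length; one
#'   end-tag forms at each plus-end with saturated length
#'   \code{endtag_fraction * ML_i}. Must be < 0.5.
#' @param endtag_growth_rate end-tag elongation rate until the length-scaled
#'   plateau is reached (nm/s); \code{Inf} means end-tags start saturated.
#' @param slowdown_width spatial scale (nm) over which the velocity ramps
#'   from full speed to zero as the inner end-tag boundaries approach.
#' @param duration total simulated time (s).
#' @param dt time step (s); defaults to the 3 frames/s acquisition interval.
#' @return An object of class \code{"simulation_params"}.
#' @seealso [simulate_pair()], [sliding_conditions()]
#' @export
simulation_params <- function(ML1 = 8000, ML2 = 6000, s0 = 3000,
                              v0 = 55, S = 0.4, a = 0.01,
                              delta = 8,
                              endtag_fraction = 0.3,
                              endtag_growth_rate = 20,
                              slowdown_width = 500,
                              duration = 240, dt = 1 / 3) {
  p <- list(ML1 = ML1, ML2 = ML2, s0 = s0, v0 = v0, S = S, a = a,
            delta = delta, endtag_fraction = endtag_fraction,
            endtag_growth_rate = endtag_growth_rate,
            slowdown_width = slowdown_width,
            duration = duration, dt = dt)
  validate_simulation_params(p)
  structure(p, class = "simulation_params")
}

validate_simulation_params <- function(p) {
  stopifnot(
    p$ML1 > 0, p$ML2 > 0, p$v0 > 0, p$duration > 0, p$dt > 0,
    p$S >= 0, p$S <= 1, p$a > 0, p$a <= 1, p$delta > 0,
    p$endtag_fraction >= 0, p$endtag_fraction < 0.5,
    p$endtag_growth_rate > 0, p$slowdown_width >= 0
  )
  if (p$dt >= p$duration)
    stop("time step dt must be smaller than the simulated duration")
  L0 <- min(p$ML1, p$s0 + p$ML2) - max(0, p$s0)
  if (L0 <= 0)
    stop("parameters give no initial overlap between the two microtubules")
  invisible(p)
}

#' @export
print.simulation_params <- function(x, ...) {
  cat("Sliding simulation parameters\n")
  cat(sprintf("  filaments: ML1 = %.0f nm, ML2 = %.0f nm, s0 = %.0f nm\n",
              x$ML1, x$ML2, x$s0))
  cat(sprintf("  motility:  v0 = %.1f nm/s, S = %.3f, a = %.3f, delta = %g nm\n",
              x$v0, x$S, x$a, x$delta))
  cat(sprintf("  end-tags:  fraction = %.2f, growth = %s nm/s, slowdown width = %g nm\n",
              x$endtag_fraction,
              if (is.finite(x$endtag_growth_rate)) format(x$endtag_growth_rate)
              else "saturated", x$slowdown_width))
  cat(sprintf("  time:      %.0f s at dt = %.3f s\n", x$duration, x$dt))
  invisible(x)
}

#' Optics and camera parameters for kymograph rendering
#'
#' Describes how a ground-truth trajectory is turned into a noisy two-channel
#' kymograph: physical pixel size, line (frame) interval, point-spread
#' function width, the mean GFP photon flux per nanometre in each region
#' class, the rhodamine flux per filament, and the camera background.
#'
#' The GFP flux ordering \code{rho_single < rho_untagged < rho_endtag}
#' mirrors the three intensity plateaus of the assay: lowest on single
#' microtubules, intermediate in the untagged overlap, highest in end-tags.
#'
#' @param pixel_size nm per pixel.
#' @param frame_interval s per kymograph line (default 1/3 s, i.e. 3 frames/s).
#' @param psf_sigma Gaussian PSF sigma (nm); 0 disables blur.
#' @param rho_single,rho_untagged,rho_endtag mean GFP photon flux per nm in
#'   single-microtubule, untagged-overlap and end-tag regions (A.U./nm).
#' @param mt_flux rhodamine photon flux per nm per microtubule (A.U./nm).
#' @param background mean background counts per pixel.
#' @param seed RNG seed used for the Poisson shot noise.
#' @return An object of class \code{"optics_params"}.
#' @seealso [render_kymograph()], [optics_at_snr()]
#' @export
optics_params <- function(pixel_size = 100, frame_interval = 1 / 3,
                          psf_sigma = 150,
                          rho_single = 0.8, rho_untagged = 3.5,
                          rho_endtag = 12, mt_flux = 5,
                          background = 100, seed = 1L) {
  stopifnot(pixel_size > 0, frame_interval > 0, psf_sigma >= 0,
            rho_single >= 0, rho_untagged >= 0, rho_endtag >= 0,
            mt_flux >= 0, background >= 0)
  if (!(rho_single < rho_untagged && rho_untagged < rho_endtag))
    stop("GFP fluxes must satisfy rho_single < rho_untagged < rho_endtag")
  structure(list(pixel_size = pixel_size, frame_interval = frame_interval,
                 psf_sigma = psf_sigma, rho_single = rho_single,
                 rho_untagged = rho_untagged, rho_endtag = rho_endtag,
                 mt_flux = mt_flux, background = background,
                 seed = as.integer(seed)),
            class = "optics_params")
}

#' @export
print.optics_params <- function(x, ...) {
  cat("Kymograph optics\n")
  cat(sprintf("  pixel %g nm, frame interval %.3f s, PSF sigma %g nm\n",
              x$pixel_size, x$frame_interval, x$psf_sigma))
  cat(sprintf("  GFP flux (A.U./nm): single %.2f, untagged %.2f, end-tag %.2f\n",
              x$rho_single, x$rho_untagged, x$rho_endtag))
  cat(sprintf("  MT flux %.2f A.U./nm per filament, background %g counts/px, seed %d\n",
              x$mt_flux, x$background, x$seed))
  invisible(x)
}

#' Set the background so the untagged overlap is rendered at a target SNR
#'
#' Signal-to-noise for a Poisson camera is
#' \eqn{SNR = s / \sqrt{s + b}} where \eqn{s} is the per-pixel signal above
#' background (here \code{rho_untagged * pixel_size}) and \eqn{b} the mean
#' background. This helper solves for the background that yields the
#' requested SNR at the untagged-overlap plateau, leaving the fluxes (and
#' hence the A.U. calibration of all intensity measurements) untouched.
#'
#' @param optics an [optics_params()] object.
#' @param snr target signal-to-noise ratio at the untagged-overlap plateau.
#' @return The optics object with its \code{background} replaced.
#' @export
optics_at_snr <- function(optics, snr) {
  stopifnot(inherits(optics, "optics_params"), snr > 0)
  s <- optics$rho_untagged * optics$pixel_size
  b <- max(0, (s / snr)^2 - s)
  if (b == 0 && s / sqrt(s) < snr)
    warning("requested SNR exceeds the shot-noise limit of the untagged plateau")
  optics$background <- b
  optics
}

#' Condition presets emulating the sliding assays
#'
#' Named parameter sets for the two flagship assay conditions. The
#' 0.2 nM PRC1 + 6 nM Kif4A-GFP condition is calibrated so that the
#' motor-ensemble law over the experimental range of initial overlaps
#' (1.5-5 um) reproduces the reported velocity-overlap relation: mean
#' phase-1 velocity around 46 nm/s, and a saturating-fit half-maximal
#' overlap length K_L around 1.5 um, which with occupancy a = 1-10\%
#' yields sliding-efficiency estimates spanning about 0.3 down to 0.03.
#' The 1 nM PRC1 condition has a denser, slower overlap (untagged GFP
#' density 6.5 A.U./nm, phase-1 velocities around 11 nm/s) and longer
#' end-tags.
#'
#' @return A named list with elements \code{params} (a
#'   [simulation_params()] template) and \code{optics} per condition.
#' @export
sliding_conditions <- function() {
  list(
    "0.2nM_PRC1_6nM_Kif4A" = list(
      params = simulation_params(v0 = 55, S = 0.4, a = 0.01,
                                 endtag_fraction = 0.3),
      optics = optics_params(rho_untagged = 3.5, rho_endtag = 12)
    ),
    "1nM_PRC1_6nM_Kif4A" = list(
      params = simulation_params(v0 = 11.5, S = 0.4, a = 0.02,
                                 endtag_fraction = 0.45),
      optics = optics_params(rho_untagged = 6.5, rho_endtag = 16)
    )
  )
}
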