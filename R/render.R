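#' Render a ground-truth trajectory as a noisy two-channel kymograph
#'
#' Builds, for every frame, the ideal photon-flux profile of the rhodamine
#' (microtubule) and GFP channels, convolves it with a Gaussian PSF, and
#' draws Poisson counts per pixel on top of a constant camera background.
#'
#' The microtubule channel is the sum of two box profiles (one per
#' filament). The GFP channel is piecewise: \code{rho_single} on
#' non-overlap microtubule regions, \code{rho_untagged} on the untagged
#' overlap, \code{rho_endtag} on end-tags. A box of flux \eqn{\rho} on
#' \eqn{[a,b]} convolved with a Gaussian of width \eqn{\sigma} evaluates in
#' closed form to \eqn{\rho[\Phi((b-x)/\sigma) - \Phi((a-x)/\sigma)]}; pixel
#' values are this profile at the pixel centre times the pixel size. With
#' \code{psf_sigma = 0} the exact pixel-box overlap is used instead, so
#' pixel sums equal flux times length exactly.
#'
#' One image row is produced per \code{frame_interval}; the trajectory is
#' sampled at the nearest simulated time point. The field of view covers
#' both filaments at all times with a margin. Rendering is deterministic
#' given \code{optics$seed}.
#'
#' @param truth a [simulate_pair()] result.
#' @param optics an [optics_params()] object.
#' @param margin field-of-view margin beyond the filament extent (nm).
#' @param noise draw Poisson noise? If \code{FALSE} the expected (noiseless)
#'   image is returned, including the background.
#' @return An object of class \code{"kymograph"}: list with matrices
#'   \code{mt} and \code{gfp} (rows = time, columns = space), and
#'   \code{pixel_size}, \code{frame_interval}, \code{origin_nm} (left edge
#'   of the first pixel), \code{optics}, and the embedded ground
#'   \code{truth}.
#' @export
render_kymograph <- function(truth, optics, margin = 2000, noise = TRUE) {
  stopifnot(inherits(truth, "sliding_truth"),
            inherits(optics, "optics_params"))
  p <- truth$params
  f <- truth$frames
  px <- optics$pixel_size

  xmin <- min(0, min(f$s_nm)) - margin
  xmax <- max(p$ML1, max(f$s_nm) + p$ML2) + margin
  ncol <- ceiling((xmax - xmin) / px)
  if (ncol < 8)
    stop("pixel_size is larger than the features to render; ",
         "field of view spans only ", ncol, " pixels")
  centers <- xmin + (seq_len(ncol) - 0.5) * px

  # frame times on the acquisition grid, mapped to nearest simulated step
  t_frames <- seq(0, max(f$t_s), by = optics$frame_interval)
  idx <- pmin(nrow(f), pmax(1L, round(t_frames / p$dt) + 1L))

  mt <- matrix(0, length(idx), ncol)
  gfp <- matrix(0, length(idx), ncol)
  for (r in seq_along(idx)) {
    k <- idx[r]
    segs <- frame_segments(f$s_nm[k], f$LET1_nm[k], f$LET2_nm[k], p, optics)
    mt[r, ] <- profile_from_segments(segs$mt, centers, optics$psf_sigma, px)
    gfp[r, ] <- profile_from_segments(segs$gfp, centers, optics$psf_sigma, px)
  }
  mt <- mt + optics$background
  gfp <- gfp + optics$background
  if (noise) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(optics$seed)
    mt[] <- stats::rpois(length(mt), mt)
    gfp[] <- stats::rpois(length(gfp), gfp)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  structure(list(mt = mt, gfp = gfp, pixel_size = px,
                 frame_interval = optics$frame_interval,
                 origin_nm = xmin, optics = optics, truth = truth),
            class = "kymograph")
}

# Disjoint flux segments for one frame. End-tag regions take priority over
# overlap, overlap over single-filament lattice.
frame_segments <- function(s, LET1, LET2, p, optics) {
  mt1 <- c(0, p$ML1)
  mt2 <- c(s, s + p$ML2)
  tag1 <- c(p$ML1 - LET1, p$ML1)
  tag2 <- c(s, s + LET2)
  brk <- sort(unique(c(mt1, mt2, tag1, tag2)))
  a <- brk[-length(brk)]
  b <- brk[-1]
  mid <- (a + b) / 2
  in1 <- mid > mt1[1] & mid < mt1[2]
  in2 <- mid > mt2[1] & mid < mt2[2]
  intag <- (LET1 > 0 & mid > tag1[1] & mid < tag1[2] & in1) |
           (LET2 > 0 & mid > tag2[1] & mid < tag2[2] & in2)
  gflux <- ifelse(intag, optics$rho_endtag,
           ifelse(in1 & in2, optics$rho_untagged,
           ifelse(in1 | in2, optics$rho_single, 0)))
  mflux <- (in1 + in2) * optics$mt_flux
  keep <- b > a
  list(mt = data.frame(a = a, b = b, flux = mflux)[keep & mflux > 0, ],
       gfp = data.frame(a = a, b = b, flux = gflux)[keep & gflux > 0, ])
}

profile_from_segments <- function(segs, centers, sigma, px) {
  out <- numeric(length(centers))
  if (nrow(segs) == 0) return(out)
  for (i in seq_len(nrow(segs))) {
    if (sigma > 0) {
      out <- out + segs$flux[i] * px *
        (stats::pnorm((segs$b[i] - centers) / sigma) -
         stats::pnorm((segs$a[i] - centers) / sigma))
    } else {
      lo <- pmax(centers - px / 2, segs$a[i])
      hi <- pmin(centers + px / 2, segs$b[i])
      out <- out + segs$flux[i] * pmax(0, hi - lo)
    }
  }
  out
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("Kymograph: %d frames x %d px (%.0f nm/px, %.3f s/frame)\n",
              nrow(x$mt), ncol(x$mt), x$pixel_size, x$frame_interval))
  cat(sprintf("  origin %.0f nm; ground truth %s\n", x$origin_nm,
              if (is.null(x$truth)) "absent" else "embedded"))
  invisible(x)
}

#' @export
plot.kymograph <- function(x, channel = c("gfp", "mt"), ...) {
  channel <- match.arg(channel)
  m <- x[[channel]]
  graphics::image(x = x$origin_nm / 1000 + (seq_len(ncol(m)) - 0.5) *
                    x$pixel_size / 1000,
                  y = (seq_len(nrow(m)) - 1) * x$frame_interval,
                  z = t(m),
                  useRaster = TRUE, xlab = "position (um)", ylab = "time (s)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
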