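#' Detect high-intensity structures and their sub-pixel edges in one frame
#'
#' Works on a single kymograph line: estimates the background as the median
#' of off-structure pixels, segments structures by a noise-scaled threshold
#' on a lightly smoothed profile, and localizes each boundary at the
#' half-maximum crossing of the local plateau with linear sub-pixel
#' interpolation. Structures separated by less than one pixel are merged
#' (duplicate detections from noise collapse into one).
#'
#' Half-maximum localization is unbiased for a step edge blurred by a
#' symmetric PSF: the blurred profile passes through half its plateau
#' exactly at the true edge position.
#'
#' @param kymo a [kymograph] object (see [render_kymograph()] or
#'   [read_kymograph()]).
#' @param channel \code{"gfp"} or \code{"mt"}.
#' @param frame 1-based frame (row) index.
#' @return A data frame with one row per structure: \code{start_nm},
#'   \code{end_nm} (sub-pixel edge positions), \code{start_px},
#'   \code{end_px} (pixel index range), \code{plateau} (median excess over
#'   background). Zero rows if no pixel rises above the noise
#'   (\code{attr(, "background")} and \code{attr(, "noise_sd")} are always
#'   set).
#' @export
detect_edges <- function(kymo, channel = c("gfp", "mt"), frame) {
  channel <- match.arg(channel)
  stopifnot(inherits(kymo, "kymograph"),
            frame >= 1, frame <= nrow(kymo[[channel]]))
  p <- kymo[[channel]][frame, ]
  analyze_profile(p, kymo$pixel_size, kymo$origin_nm)
}

# Core single-line structure finder shared by both channels.
analyze_profile <- function(p, px, origin) {
  sm <- smooth_profile(p)
  low <- p[p <= stats::quantile(p, 0.25)]
  bg0 <- stats::median(low)
  # robust per-pixel noise: adjacent differences cancel structure except at
  # the few step pixels, which the MAD ignores
  sd0 <- max(stats::mad(diff(p)) / sqrt(2), sqrt(max(bg0, 1)) / 2, 1e-9)
  sd_sm <- sd0 / sqrt(3)
  thr <- bg0 + 5 * sd_sm
  runs <- runs_above(sm, thr, min_len = 2L, merge_gap = 1L)
  # refine background from pixels clear of any structure
  out <- rep(TRUE, length(p))
  for (r in runs) out[max(1, r[1] - 3):min(length(p), r[2] + 3)] <- FALSE
  bg <- if (sum(out) >= 5) stats::median(p[out]) else bg0
  res <- data.frame(
    start_nm = vapply(runs, function(r)
      edge_position(sm, r, "left", bg, px, origin), numeric(1)),
    end_nm = vapply(runs, function(r)
      edge_position(sm, r, "right", bg, px, origin), numeric(1)),
    start_px = vapply(runs, `[`, numeric(1), 1),
    end_px = vapply(runs, `[`, numeric(1), 2),
    plateau = vapply(runs, function(r)
      stats::median(sm[r[1]:r[2]]) - bg, numeric(1)))
  attr(res, "background") <- bg
  attr(res, "noise_sd") <- sd0
  res
}

smooth_profile <- function(p) {
  n <- length(p)
  if (n < 3) return(p)
  s <- as.numeric(stats::filter(p, rep(1 / 3, 3), sides = 2))
  s[1] <- mean(p[1:2]); s[n] <- mean(p[(n - 1):n])
  s
}

# contiguous index runs where x > thr; short runs dropped, near runs merged
runs_above <- function(x, thr, min_len = 1L, merge_gap = 0L) {
  above <- !is.na(x) & x > thr
  if (!any(above)) return(list())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- Map(c, starts[r$values], ends[r$values])
  if (merge_gap > 0 && length(runs) > 1) {
    merged <- list(runs[[1]])
    for (k in 2:length(runs)) {
      last <- merged[[length(merged)]]
      if (runs[[k]][1] - last[2] - 1L <= merge_gap)
        merged[[length(merged)]] <- c(last[1], runs[[k]][2])
      else merged <- c(merged, list(runs[[k]]))
    }
    runs <- merged
  }
  Filter(function(r) r[2] - r[1] + 1L >= min_len, runs)
}

# Half-maximum crossing of the local plateau, linearly interpolated.
# Pixel j has centre origin + (j - 0.5) * px.
edge_position <- function(sm, run, side, bg, px, origin,
                          level = NULL) {
  n <- length(sm)
  inner <- if (side == "left")
    seq(min(run[1] + 2L, run[2]), min(run[1] + 6L, run[2]))
  else
    seq(max(run[2] - 6L, run[1]), max(run[2] - 2L, run[1]))
  if (is.null(level))
    level <- bg + 0.5 * (stats::median(sm[inner]) - bg)
  if (side == "left") {
    j <- run[1]
    while (j < run[2] && sm[j] <= level) j <- j + 1L   # enter the plateau
    if (sm[j] <= level) return(origin + (run[1] - 0.5) * px)
    while (j > 1 && sm[j - 1] > level) j <- j - 1L     # walk out to the edge
    if (j == 1) return(origin + 0.5 * px)
    frac <- (sm[j] - level) / (sm[j] - sm[j - 1])
    origin + (j - 0.5 - frac) * px
  } else {
    j <- run[2]
    while (j > run[1] && sm[j] <= level) j <- j - 1L
    if (sm[j] <= level) return(origin + (run[2] - 0.5) * px)
    while (j < n && sm[j + 1] > level) j <- j + 1L
    if (j == n) return(origin + (n - 0.5) * px)
    frac <- (sm[j] - level) / (sm[j] - sm[j + 1])
    origin + (j - 0.5 + frac) * px
  }
}

# Deterministic 1-D 2-means split; returns low/high centres and midpoint.
split2 <- function(v, iter = 30L) {
  c1 <- min(v)
  c2 <- max(v)
  for (i in seq_len(iter)) {
    mid <- (c1 + c2) / 2
    lo <- v <= mid
    if (!any(lo) || all(lo)) break
    n1 <- mean(v[lo]); n2 <- mean(v[!lo])
    if (n1 == c1 && n2 == c2) break
    c1 <- n1; c2 <- n2
  }
  list(low = c1, high = c2, mid = (c1 + c2) / 2)
}

#' Overlap bounds of one frame from the microtubule channel
#'
#' The overlap is the region where the two filament box profiles superpose,
#' i.e. the rhodamine intensity sits on the two-filament plateau. Structure
#' pixels are split into single- and double-filament levels; the overlap is
#' the longest contiguous run above the midpoint between the two levels,
#' localized sub-pixel at that midpoint (unbiased for a blurred step
#' between two plateaus).
#'
#' @param kymo a kymograph.
#' @param frame frame index.
#' @return list with \code{o1}, \code{o2} (overlap bounds, nm), \code{u1},
#'   \code{u2} (union filament extent, nm), \code{ok} (logical: overlap
#'   distinguishable) and \code{reason} when not.
#' @export
overlap_bounds <- function(kymo, frame) {
  st <- detect_edges(kymo, "mt", frame)
  bg <- attr(st, "background")
  sd_sm <- attr(st, "noise_sd") / sqrt(3)
  if (nrow(st) == 0)
    return(list(ok = FALSE, reason = "no_structure"))
  u1 <- min(st$start_nm); u2 <- max(st$end_nm)
  p <- kymo$mt[frame, ]
  sm <- smooth_profile(p)
  jlo <- min(st$start_px); jhi <- max(st$end_px)
  vals <- sm[jlo:jhi]
  cl <- split2(vals)
  if ((cl$high - cl$low) < 4 * sd_sm)
    return(list(ok = FALSE, reason = "overlap_indistinct",
                u1 = u1, u2 = u2))
  runs <- runs_above(sm, cl$mid, min_len = 2L, merge_gap = 1L)
  if (length(runs) == 0)
    return(list(ok = FALSE, reason = "overlap_indistinct",
                u1 = u1, u2 = u2))
  len <- vapply(runs, function(r) r[2] - r[1], numeric(1))
  r <- runs[[which.max(len)]]
  # Refine the single/double threshold from the two-filament plateau alone:
  # the double excess is exactly twice the single excess, so the midpoint
  # between the levels is bg + 0.75 * double-excess. This avoids the bias
  # of a data-driven split when the single-filament stretches are short or
  # ramp-contaminated.
  interior <- if (r[2] - r[1] >= 6) (r[1] + 3):(r[2] - 3) else r[1]:r[2]
  dbl <- stats::median(sm[interior]) - bg
  lvl2 <- bg + 0.75 * dbl
  runs2 <- runs_above(sm, lvl2, min_len = 2L, merge_gap = 1L)
  if (length(runs2)) {
    len2 <- vapply(runs2, function(rr) rr[2] - rr[1], numeric(1))
    r <- runs2[[which.max(len2)]]
  } else lvl2 <- cl$mid
  o1 <- edge_position(sm, r, "left", bg, kymo$pixel_size, kymo$origin_nm,
                      level = lvl2)
  o2 <- edge_position(sm, r, "right", bg, kymo$pixel_size, kymo$origin_nm,
                      level = lvl2)
  list(ok = TRUE, o1 = o1, o2 = o2, u1 = u1, u2 = u2,
       o_px = c(r[1], r[2]), bg = bg)
}

#' Segment end-tags within the overlap of a GFP profile
#'
#' End-tags are the maximal contiguous regions at the two plus-ends of the
#' overlap whose intensity exceeds the midpoint between the untagged-overlap
#' plateau and the end-tag plateau. The two plateaus are estimated by a
#' two-level split of the overlap pixels; if they are not separated beyond
#' the noise (no bimodality), or if the two end-tag segments touch, the
#' end-tags are reported as unresolved.
#'
#' @param gfp GFP intensity profile for one frame (raw counts).
#' @param overlap_px integer range \code{c(first, last)} of overlap pixels.
#' @param bg background level (counts/pixel).
#' @param noise_sd per-pixel noise standard deviation.
#' @param px pixel size (nm); \code{origin} left edge of pixel 1 (nm).
#' @return list with \code{LET1}, \code{LET2} (lengths, nm; ET1 at the
#'   overlap's right/immobilized plus-end, ET2 at the left/moving plus-end),
#'   \code{IET1}, \code{IET2} (background-subtracted summed intensities),
#'   \code{resolved} flag, \code{present} flag (any end-tag signal at all),
#'   \code{tag_px} (logical mask over overlap pixels), and the plateau
#'   estimates \code{rho_untagged_level}, \code{rho_endtag_level}
#'   (counts/pixel above background).
#' @export
segment_end_tags <- function(gfp, overlap_px, bg, noise_sd, px, origin) {
  j1 <- overlap_px[1]; j2 <- overlap_px[2]
  stopifnot(j2 >= j1)
  sm <- smooth_profile(gfp)
  vals <- sm[j1:j2]
  # cluster on the overlap interior so the PSF ramps at the overlap ends
  # cannot fake a second intensity level
  core <- if (j2 - j1 >= 8) sm[(j1 + 2):(j2 - 2)] else vals
  none <- list(LET1 = NA_real_, LET2 = NA_real_, IET1 = NA_real_,
               IET2 = NA_real_, resolved = FALSE, present = FALSE,
               tag_px = rep(FALSE, j2 - j1 + 1),
               rho_untagged_level = stats::median(vals) - bg,
               rho_endtag_level = NA_real_)
  if (length(vals) < 4) return(none)
  cl <- split2(core)
  sd_sm <- noise_sd / sqrt(3)
  # bimodality guard: a uniform noisy plateau yields a split of roughly
  # 2-3 noise sd, so demand clearly more before calling two plateaus
  if ((cl$high - cl$low) < 6 * sd_sm) return(none)   # no plateau separation
  runs <- runs_above(sm[j1:j2], cl$mid, min_len = 1L, merge_gap = 0L)
  if (length(runs) == 0) return(none)
  touch_l <- vapply(runs, function(r) r[1] <= 4L, logical(1))
  touch_r <- vapply(runs, function(r) r[2] >= (j2 - j1 - 2L), logical(1))
  tag_px <- rep(FALSE, j2 - j1 + 1)
  for (r in runs[touch_l | touch_r]) tag_px[r[1]:r[2]] <- TRUE
  present <- any(touch_l | touch_r)
  merged <- any(touch_l & touch_r)
  if (!present) return(none)

  raw_excess <- gfp[j1:j2] - bg
  if (merged) {
    out <- none
    out$present <- TRUE
    out$tag_px <- tag_px
    out$rho_untagged_level <- cl$low - bg
    out$rho_endtag_level <- cl$high - bg
    return(out)
  }

  # Refine the segmentation level: the low cluster mean is contaminated by
  # PSF ramp pixels when the untagged gap is narrow, which would bias the
  # tag edges inward. The dip minimum between the tags tracks the true
  # untagged level much more closely, so re-threshold at the midpoint
  # between dip minimum and tag-plateau interior.
  tag_interior <- which(tag_px)
  tag_interior <- tag_interior[c(-1, -length(tag_interior))]
  c2r <- if (length(tag_interior) >= 3)
    stats::median(sm[j1:j2][tag_interior]) else cl$high
  gap_idx <- which(!tag_px)
  c1r <- if (length(gap_idx)) min(sm[j1:j2][gap_idx]) else cl$low
  lvl <- (c1r + c2r) / 2
  if (lvl > cl$low && lvl < cl$high + (cl$high - cl$low)) {
    runs2 <- runs_above(sm[j1:j2], lvl, min_len = 1L, merge_gap = 0L)
    if (length(runs2)) {
      runs <- runs2
      touch_l <- vapply(runs, function(r) r[1] <= 4L, logical(1))
      touch_r <- vapply(runs, function(r) r[2] >= (j2 - j1 - 2L), logical(1))
      tag_px <- rep(FALSE, j2 - j1 + 1)
      for (r in runs[touch_l | touch_r]) tag_px[r[1]:r[2]] <- TRUE
      cl$mid <- lvl
      cl$high <- c2r
      if (any(touch_l) && any(touch_r)) {
        right_start <- min(vapply(runs[touch_r], `[`, numeric(1), 1))
        left_end <- max(vapply(runs[touch_l], `[`, numeric(1), 2))
        resolved <- (right_start - left_end) > 4
      }
    }
  }
  resolved <- FALSE
  if (any(touch_l) && any(touch_r)) {
    right_start <- min(vapply(runs[touch_r], `[`, numeric(1), 1))
    left_end <- max(vapply(runs[touch_l], `[`, numeric(1), 2))
    resolved <- (right_start - left_end) > 4
  }

  LET1 <- IET1 <- LET2 <- IET2 <- NA_real_
  if (any(touch_r)) {
    r <- runs[touch_r][[which.min(vapply(runs[touch_r], `[`, numeric(1), 1))]]
    inner <- edge_position(sm, c(j1 + r[1] - 1L, j1 + r[2] - 1L), "left",
                           bg, px, origin, level = cl$mid)
    o2_nm <- origin + (j2) * px  # fallback right bound at pixel edge
    LET1 <- o2_nm - inner
    IET1 <- sum(raw_excess[r[1]:r[2]])
  }
  if (any(touch_l)) {
    r <- runs[touch_l][[which.max(vapply(runs[touch_l], `[`, numeric(1), 2))]]
    inner <- edge_position(sm, c(j1 + r[1] - 1L, j1 + r[2] - 1L), "right",
                           bg, px, origin, level = cl$mid)
    o1_nm <- origin + (j1 - 1L) * px
    LET2 <- inner - o1_nm
    IET2 <- sum(raw_excess[r[1]:r[2]])
  }
  list(LET1 = LET1, LET2 = LET2, IET1 = IET1, IET2 = IET2,
       resolved = isTRUE(resolved), present = TRUE, tag_px = tag_px,
       rho_untagged_level = cl$low - bg, rho_endtag_level = cl$high - bg)
}

#' Per-frame geometric and intensity measurements
#'
#' Measures one kymograph frame: overlap bounds from the microtubule
#' channel, end-tag segmentation from the GFP channel, and the
#' background-subtracted intensity partition of the overlap
#' (\eqn{I_{overlap} = I_{untagged} + I_{ET1} + I_{ET2}} holds by
#' construction on the pixel partition).
#'
#' @param kymo a kymograph.
#' @param frame frame index.
#' @return One-row data frame with columns \code{frame}, \code{t_s},
#'   \code{o1_nm}, \code{o2_nm}, \code{u1_nm}, \code{u2_nm},
#'   \code{L_overlap_nm}, \code{L_untagged_nm}, \code{LET1_nm},
#'   \code{LET2_nm}, \code{I_overlap}, \code{I_untagged}, \code{IET1},
#'   \code{IET2}, \code{rho_untagged}, \code{endtags_resolved},
#'   \code{endtags_present}, \code{moving_edge_nm}, \code{ML1_nm},
#'   \code{ML2_nm}, \code{ok}, \code{reason}.
#' @export
measure_frame <- function(kymo, frame) {
  as.data.frame(measure_frame_core(kymo, frame), stringsAsFactors = FALSE)
}

measure_frame_core <- function(kymo, frame) {
  ob <- overlap_bounds(kymo, frame)
  if (!isTRUE(ob$ok)) {
    return(list(
      frame = frame, t_s = (frame - 1) * kymo$frame_interval,
      o1_nm = NA_real_, o2_nm = NA_real_, u1_nm = NA_real_, u2_nm = NA_real_,
      L_overlap_nm = NA_real_, L_untagged_nm = NA_real_,
      LET1_nm = NA_real_, LET2_nm = NA_real_,
      I_overlap = NA_real_, I_untagged = NA_real_,
      IET1 = NA_real_, IET2 = NA_real_, rho_untagged = NA_real_,
      endtags_resolved = FALSE, endtags_present = FALSE,
      moving_edge_nm = NA_real_, ML1_nm = NA_real_, ML2_nm = NA_real_,
      ok = FALSE, reason = ob$reason))
  }
  px <- kymo$pixel_size
  gfp <- kymo$gfp[frame, ]
  gst <- analyze_profile(gfp, px, kymo$origin_nm)
  gbg <- attr(gst, "background")
  gsd <- attr(gst, "noise_sd")

  et <- segment_end_tags(gfp, ob$o_px, gbg, gsd, px, kymo$origin_nm)
  # tighten end-tag outer limits to the sub-pixel overlap bounds
  if (!is.na(et$LET1)) et$LET1 <- et$LET1 - (kymo$origin_nm + ob$o_px[2] * px - ob$o2)
  if (!is.na(et$LET2)) et$LET2 <- et$LET2 - (ob$o1 - (kymo$origin_nm + (ob$o_px[1] - 1) * px))

  jj <- ob$o_px[1]:ob$o_px[2]
  excess <- gfp[jj] - gbg
  I_overlap <- sum(excess)
  I_untagged <- sum(excess[!et$tag_px])
  L_overlap <- ob$o2 - ob$o1
  L_untagged <- if (et$present) {
    if (et$resolved) max(0, L_overlap - et$LET1 - et$LET2) else
      px * sum(!et$tag_px)
  } else L_overlap
  IET1 <- if (et$present && !is.na(et$IET1)) et$IET1 else 0
  IET2 <- if (et$present && !is.na(et$IET2)) et$IET2 else 0

  # Moving edge: the GFP step at the moving filament's plus-end. While the
  # end-tag is absent or narrower than the PSF, its blurred bump rides on
  # the untagged step and drags any GFP crossing inward as it grows, so the
  # microtubule-channel overlap bound is used instead; once the tag has a
  # genuine plateau (>= 7 px), the unbiased GFP crossing is the midpoint of
  # the single-filament level left of the overlap and the local plateau
  # just inside it.
  moving_edge <- ob$o1
  left_tag_wide <- FALSE
  if (et$present && any(et$tag_px)) {
    r <- rle(et$tag_px)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    first_true <- which(r$values & starts <= 5L)
    if (length(first_true))
      left_tag_wide <- r$lengths[first_true[1]] >= 7L
  }
  if (left_tag_wide) {
    sm <- smooth_profile(gfp)
    j1 <- ob$o_px[1]; j2 <- ob$o_px[2]
    left_px <- max(1L, j1 - 8L):max(1L, j1 - 3L)
    left_level <- if (length(left_px) >= 3) stats::median(sm[left_px]) else gbg
    inner_level <- stats::median(sm[min(j1 + 2L, j2):min(j1 + 6L, j2)])
    lvl <- (left_level + inner_level) / 2
    runs_abs <- runs_above(sm, lvl, min_len = 1L, merge_gap = 1L)
    cand <- Filter(function(r) r[2] >= j1 && r[1] <= j2, runs_abs)
    if (length(cand) && inner_level > lvl)
      moving_edge <- edge_position(sm, cand[[1]], "left", gbg, px,
                                   kymo$origin_nm, level = lvl)
  }

  list(
    frame = frame, t_s = (frame - 1) * kymo$frame_interval,
    o1_nm = ob$o1, o2_nm = ob$o2, u1_nm = ob$u1, u2_nm = ob$u2,
    L_overlap_nm = L_overlap,
    L_untagged_nm = L_untagged,
    LET1_nm = if (et$resolved) et$LET1 else NA_real_,
    LET2_nm = if (et$resolved) et$LET2 else NA_real_,
    I_overlap = I_overlap, I_untagged = I_untagged,
    IET1 = IET1, IET2 = IET2,
    rho_untagged = if (sum(!et$tag_px) > 0)
      I_untagged / (px * sum(!et$tag_px)) else NA_real_,
    endtags_resolved = et$resolved, endtags_present = et$present,
    moving_edge_nm = moving_edge,
    ML1_nm = ob$o2 - ob$u1, ML2_nm = ob$u2 - ob$o1,
    ok = TRUE, reason = "")
}

#' Track a full sliding event across a kymograph
#'
#' Runs [measure_frame()] on every frame, links the measurements in time,
#' derives the moving-edge trace and its velocity, detects the stall (the
#' moving edge slower than \code{stall_v} nm/s for at least \code{stall_t}
#' seconds, sustained), and summarizes the event: initial overlap \code{L0}
#' from the first measured frame, final overlap \code{L_FO} from the
#' microtubule channel after the end-tags have collided, filament lengths,
#' and end-tag lengths as the per-tag median over the pre-stall frames in
#' which the two end-tags were resolved (frames at the very edge of
#' resolvability are noise-selected toward wider apparent gaps, so pooling
#' all resolved frames is the less biased summary for plateaued end-tags).
#'
#' @param kymo a kymograph.
#' @param stall_v stall velocity threshold (nm/s).
#' @param stall_t minimum stalled duration (s).
#' @param window smoothing window (frames) for the velocity estimate.
#' @param max_gap maximum run of untracked frames tolerated before the
#'   event is flagged untrackable.
#' @return An object of class \code{"event_trace"}: list with
#'   \code{frames} (per-frame measurements), \code{edge} (data frame
#'   \code{t_s}, \code{x_nm} of the moving edge), \code{L0_nm},
#'   \code{L_FO_nm} (NA when no stall), \code{ML1_nm}, \code{ML2_nm},
#'   \code{LET1_nm}, \code{LET2_nm}, \code{rho_untagged_initial},
#'   \code{stall_frame}, \code{trackable}, and the source kymograph
#'   calibration.
#' @export
track_event <- function(kymo, stall_v = 2, stall_t = 10, window = 5,
                        max_gap = 10L) {
  stopifnot(inherits(kymo, "kymograph"))
  nfr <- nrow(kymo$mt)
  rows <- lapply(seq_len(nfr), function(i) measure_frame_core(kymo, i))
  nm <- names(rows[[1]])
  frames <- as.data.frame(lapply(stats::setNames(nm, nm), function(cn)
    unlist(lapply(rows, `[[`, cn), use.names = FALSE)),
    stringsAsFactors = FALSE)

  okr <- rle(!frames$ok)
  trackable <- !any(okr$values & okr$lengths > max_gap) && any(frames$ok)
  edge <- data.frame(t_s = frames$t_s, x_nm = frames$moving_edge_nm)

  stall_frame <- NA_integer_
  L_FO <- NA_real_
  vtr <- NULL
  if (sum(frames$ok) >= window + 2) {
    vtr <- instantaneous_velocity(edge, window = window)
    # Stall detection uses a long-baseline velocity (displacement over the
    # stall window) so that single-frame localization noise cannot mask a
    # genuine stall at the few-nm/s level.
    half <- max(2L, ceiling(stall_t / (2 * kymo$frame_interval)))
    x <- edge$x_nm
    n <- length(x)
    if (n > 4 * half + 4) {
      xs <- vapply(seq_len(n), function(i) {
        j <- max(1, i - half):min(n, i + half)
        mean(x[j], na.rm = TRUE)
      }, numeric(1))
      vlong <- rep(NA_real_, n)
      i <- (half + 1):(n - half)
      vlong[i] <- (xs[i + half] - xs[i - half]) /
        (edge$t_s[i + half] - edge$t_s[i - half])
      slow <- !is.na(vlong) & abs(vlong) < stall_v
      slow[(n - half + 1):n] <- slow[n - half]   # extend last estimate
      r <- rle(slow)
      ends <- cumsum(r$lengths)
      need <- max(2L, ceiling(stall_t / kymo$frame_interval))
      cand <- which(r$values & r$lengths >= need & ends == length(slow))
      if (length(cand)) {
        stall_frame <- ends[cand[1]] - r$lengths[cand[1]] + 1L
        stalled_rows <- frames$ok & seq_len(nfr) >= stall_frame
        L_FO <- stats::median(frames$L_overlap_nm[stalled_rows], na.rm = TRUE)
      }
    }
  }

  res_idx <- which(frames$endtags_resolved)
  if (!is.na(stall_frame))           # end-tags have merged at the stall;
    res_idx <- res_idx[res_idx < stall_frame]  # only pre-stall frames count
  last_res <- res_idx
  first_ok <- which(frames$ok)[1]
  structure(list(
    frames = frames, edge = edge, velocity = vtr,
    L0_nm = if (length(first_ok)) frames$L_overlap_nm[first_ok] else NA_real_,
    L_FO_nm = L_FO,
    ML1_nm = stats::median(frames$ML1_nm, na.rm = TRUE),
    ML2_nm = stats::median(frames$ML2_nm, na.rm = TRUE),
    LET1_nm = if (length(last_res)) stats::median(frames$LET1_nm[last_res])
      else NA_real_,
    LET2_nm = if (length(last_res)) stats::median(frames$LET2_nm[last_res])
      else NA_real_,
    rho_untagged_initial = stats::median(
      utils::head(frames$rho_untagged[frames$ok], 3L), na.rm = TRUE),
    stall_frame = stall_frame, trackable = trackable,
    pixel_size = kymo$pixel_size, frame_interval = kymo$frame_interval),
    class = "event_trace")
}

#' @export
print.event_trace <- function(x, ...) {
  cat("Sliding event trace\n")
  cat(sprintf("  %d frames (%d measured), trackable: %s\n",
              nrow(x$frames), sum(x$frames$ok), x$trackable))
  cat(sprintf("  L0 = %.0f nm, ML1 = %.0f nm, ML2 = %.0f nm\n",
              x$L0_nm, x$ML1_nm, x$ML2_nm))
  if (!is.na(x$L_FO_nm))
    cat(sprintf("  stalled at frame %d; L_FO = %.0f nm; LET1+LET2 = %.0f nm\n",
                x$stall_frame, x$L_FO_nm, x$LET1_nm + x$LET2_nm))
  else cat("  no stall detected within the record\n")
  invisible(x)
}

#' @export
plot.event_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$edge$t_s, x$edge$x_nm / 1000, type = "l",
                 xlab = "time (s)", ylab = "moving edge (um)", ...)
  graphics::plot(x$frames$t_s, x$frames$L_overlap_nm / 1000, type = "l",
                 xlab = "time (s)", ylab = "overlap (um)", ...)
  invisible(x)
}
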