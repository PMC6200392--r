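#' Apply the event-exclusion criteria
#'
#' Filters an event table the way sliding kymographs are screened before
#' analysis. The criteria are applied in order and the first failure is
#' recorded as the exclusion reason:
#' \enumerate{
#'   \item exactly two microtubules identifiable (\code{multiple_mts});
#'   \item no encounter with another bundle (\code{bundle_encounter});
#'   \item plus-ends not already proximal at the start
#'     (\code{proximal_plus_ends});
#'   \item for the velocity-versus-overlap analysis: the overlap and the
#'     moving end-tag edge distinguishable (\code{overlap_edge_indistinct})
#'     and initial overlap at most 5 um (\code{overlap_gt_5um});
#'   \item for the length-versus-final-overlap analysis: both microtubule
#'     edges distinguishable (\code{mt_edges_indistinct}).
#' }
#'
#' @param records data frame with (at least) the logical quality flags
#'   \code{n_microtubules}, \code{encountered_bundle},
#'   \code{proximal_plus_ends_at_start}, \code{overlap_edge_distinguishable},
#'   \code{mt_edges_distinguishable} and \code{L0_nm}.
#' @param analysis one of \code{"general"}, \code{"velocity_vs_overlap"},
#'   \code{"length_vs_final_overlap"}.
#' @param max_L0 overlap cutoff (nm) for the velocity analysis.
#' @return list with data frames \code{included} and \code{excluded}; the
#'   latter gains a \code{reason} column. Every record lands in exactly one
#'   of the two.
#' @export
filter_events <- function(records,
                          analysis = c("general", "velocity_vs_overlap",
                                       "length_vs_final_overlap"),
                          max_L0 = 5000) {
  analysis <- match.arg(analysis)
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  mark <- function(bad, code) ifelse(is.na(reason) & bad, code, reason)
  reason <- mark(records$n_microtubules != 2L, "multiple_mts")
  reason <- mark(records$encountered_bundle, "bundle_encounter")
  reason <- mark(records$proximal_plus_ends_at_start, "proximal_plus_ends")
  if (analysis == "velocity_vs_overlap") {
    reason <- mark(!records$overlap_edge_distinguishable,
                   "overlap_edge_indistinct")
    reason <- mark(records$L0_nm > max_L0, "overlap_gt_5um")
  }
  if (analysis == "length_vs_final_overlap")
    reason <- mark(!records$mt_edges_distinguishable, "mt_edges_indistinct")
  excluded <- records[!is.na(reason), , drop = FALSE]
  excluded$reason <- reason[!is.na(reason)]
  list(included = records[is.na(reason), , drop = FALSE],
       excluded = excluded)
}

#' Gaussian fit of a histogram
#'
#' Histograms the values with a fixed bin width and fits a Gaussian
#' \eqn{A \exp(-(x-\mu)^2 / 2\sigma^2)} to the bin counts by nonlinear
#' least squares -- the procedure used for distributions of e.g. the
#' untagged-overlap GFP density.
#'
#' @param values numeric vector (at least 20 finite values).
#' @param bin_width histogram bin width in data units.
#' @return An object of class \code{"gaussian_fit"}: list with \code{mu},
#'   \code{sigma}, \code{amplitude}, \code{n}, \code{sse}, and the binned
#'   \code{histogram} (data frame \code{mid}, \code{count}).
#' @export
gaussian_fit <- function(values, bin_width = 0.5) {
  values <- values[is.finite(values)]
  if (length(values) < 20)
    stop("need at least 20 values for a histogram fit")
  if (stats::sd(values) == 0)
    stop("degenerate input: all values identical")
  stopifnot(bin_width > 0)
  breaks <- seq(floor(min(values) / bin_width) * bin_width,
                max(values) + bin_width, by = bin_width)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  d <- data.frame(mid = h$mids, count = h$counts)
  if (sum(d$count > 0) < 4) {
    # too few occupied bins to constrain a 3-parameter curve: fall back to
    # count-weighted moments of the histogram (exact for symmetric data)
    mu <- sum(d$mid * d$count) / sum(d$count)
    sigma <- sqrt(sum(d$count * (d$mid - mu)^2) / sum(d$count))
    return(structure(list(mu = mu, sigma = max(sigma, 1e-8),
                          amplitude = max(d$count), n = length(values),
                          sse = NA_real_, histogram = d),
                     class = "gaussian_fit"))
  }
  fit <- minpack.lm::nlsLM(
    count ~ A * exp(-(mid - mu)^2 / (2 * sigma^2)), data = d,
    start = list(A = max(d$count), mu = mean(values),
                 sigma = stats::sd(values)),
    lower = c(A = 0, mu = min(values), sigma = 1e-8),
    upper = c(A = Inf, mu = max(values),
              sigma = 2 * diff(range(values))),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  structure(list(mu = cf[["mu"]], sigma = abs(cf[["sigma"]]),
                 amplitude = cf[["A"]], n = length(values),
                 sse = sum(stats::resid(fit)^2), histogram = d),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("Gaussian histogram fit: mu = %.3f, sigma = %.3f (n = %d)\n",
              x$mu, x$sigma, x$n))
  invisible(x)
}

#' Pearson correlation with domain checks
#'
#' @param x,y numeric vectors of equal length, n >= 3, finite values only.
#' @return The sample Pearson correlation coefficient; \code{NA} with a
#'   warning if either input has zero variance.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Ordinary least-squares line
#'
#' @param x,y numeric vectors, n >= 3.
#' @return list with \code{slope}, \code{intercept}, \code{r} (Pearson),
#'   and the underlying \code{lm} fit.
#' @export
linear_fit <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 finite pairs")
  if (stats::sd(x) == 0) stop("zero variance in x: line undefined")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = pearson(x, y), fit = fit)
}

#' Binned means of y over x
#'
#' Fixed-width bins covering the data range; empty bins are omitted.
#'
#' @param x,y numeric vectors.
#' @param bin_width bin width in units of \code{x} (> 0).
#' @return data frame with \code{center}, \code{mean}, \code{sd}, \code{n}
#'   per non-empty bin.
#' @export
binned_means <- function(x, y, bin_width) {
  stopifnot(bin_width > 0, length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  lo <- floor(min(x) / bin_width) * bin_width
  idx <- floor((x - lo) / bin_width)
  out <- do.call(rbind, lapply(sort(unique(idx)), function(i) {
    yy <- y[idx == i]
    data.frame(center = lo + (i + 0.5) * bin_width, mean = mean(yy),
               sd = if (length(yy) > 1) stats::sd(yy) else NA_real_,
               n = length(yy))
  }))
  out
}

#' Molecule count density from calibrated fluorescence
#'
#' Converts a background-subtracted summed GFP intensity into molecules per
#' micron using the measured intensity of a single surface-immobilized
#' GFP-labelled molecule.
#'
#' @param I_untagged summed intensity in the untagged overlap (A.U.).
#' @param L_untagged untagged overlap length (nm, > 0).
#' @param unit_intensity intensity of one molecule (A.U., > 0).
#' @return Molecules per micron of overlap.
#' @examples
#' molecules_per_micron(1000, 2000, 50)  # 10 molecules/um
#' @export
molecules_per_micron <- function(I_untagged, L_untagged, unit_intensity) {
  if (any(unit_intensity <= 0)) stop("unit intensity must be positive")
  if (any(L_untagged <= 0)) stop("untagged length must be positive")
  I_untagged / (unit_intensity * L_untagged) * 1000
}
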