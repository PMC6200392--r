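#' Write a kymograph as a two-page TIFF with a JSON sidecar
#'
#' Channel 0 (first page) is the microtubule/rhodamine channel, channel 1
#' the GFP channel; one image row per frame. TIFF samples are stored
#' scaled by a power of two recorded in the sidecar, which also carries the
#' pixel size, frame interval, spatial origin and an event id. Photon-count
#' images (integers) round-trip bit-exactly. If the kymograph embeds
#' ground truth, it is written alongside as \code{<path>_truth.csv}.
#'
#' @param kymo a [kymograph] object.
#' @param path output TIFF path; the sidecar is \code{<path>.json}.
#' @param id optional event identifier stored in the sidecar.
#' @return \code{path}, invisibly.
#' @export
write_kymograph <- function(kymo, path, id = NULL) {
  stopifnot(inherits(kymo, "kymograph"))
  mx <- max(1, kymo$mt, kymo$gfp)
  scale <- 2^ceiling(log2(mx))
  tiff::writeTIFF(list(kymo$mt / scale, kymo$gfp / scale), path,
                  bits.per.sample = 32L, compression = "none")
  integer_counts <- all(kymo$mt == round(kymo$mt)) &&
    all(kymo$gfp == round(kymo$gfp))
  meta <- list(pixel_size_nm = kymo$pixel_size,
               frame_interval_s = kymo$frame_interval,
               origin_nm = kymo$origin_nm,
               intensity_scale = scale,
               integer_counts = integer_counts,
               channels = c("mt", "gfp"),
               id = id)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(kymo$truth)) {
    f <- kymo$truth$frames
    utils::write.csv(
      data.frame(t_s = f$t_s, s_nm = f$s_nm, L_overlap_nm = f$L_overlap_nm,
                 LET1_nm = f$LET1_nm, LET2_nm = f$LET2_nm,
                 v_nm_per_s = f$v_nm_per_s, phase = f$phase),
      paste0(tools::file_path_sans_ext(path), "_truth.csv"),
      row.names = FALSE)
  }
  invisible(path)
}

#' Read a kymograph written by [write_kymograph()]
#'
#' @param path TIFF path; the sidecar \code{<path>.json} must exist and
#'   carry the calibration (pixel size and frame interval), otherwise the
#'   error lists what is missing.
#' @return A [kymograph] object (without embedded ground truth).
#' @export
read_kymograph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing sidecar ", sidecar,
         ": cannot recover pixel size and frame interval")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("pixel_size_nm", "frame_interval_s", "intensity_scale")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("sidecar lacks calibration field(s): ", paste(miss, collapse = ", "))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 2)
    stop("expected a 2-channel (2-page) TIFF, found ", length(pages),
         " page(s)")
  sc <- meta$intensity_scale
  mt <- pages[[1]] * sc
  gfp <- pages[[2]] * sc
  if (isTRUE(meta$integer_counts)) {
    mt <- round(mt); gfp <- round(gfp)
  }
  structure(list(mt = mt, gfp = gfp,
                 pixel_size = meta$pixel_size_nm,
                 frame_interval = meta$frame_interval_s,
                 origin_nm = if (!is.null(meta$origin_nm)) meta$origin_nm else 0,
                 optics = NULL, truth = NULL, id = meta$id),
            class = "kymograph")
}

#' Assemble a kymograph object from raw matrices
#'
#' @param mt,gfp numeric matrices (rows = time, columns = space) with equal
#'   dimensions and non-negative intensities.
#' @param pixel_size nm per pixel.
#' @param frame_interval s per row.
#' @param origin_nm physical position of the left edge of the first pixel.
#' @return A [kymograph] object.
#' @export
kymograph <- function(mt, gfp, pixel_size, frame_interval, origin_nm = 0) {
  stopifnot(is.matrix(mt), is.matrix(gfp), all(dim(mt) == dim(gfp)),
            pixel_size > 0, frame_interval > 0,
            all(mt >= 0), all(gfp >= 0))
  structure(list(mt = mt, gfp = gfp, pixel_size = pixel_size,
                 frame_interval = frame_interval, origin_nm = origin_nm,
                 optics = NULL, truth = NULL),
            class = "kymograph")
}
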