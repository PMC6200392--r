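#' Pipeline configuration
#'
#' Strictly validated configuration for [run_pipeline()]: unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param n_events number of simulated events.
#' @param params a [simulation_params()] template.
#' @param optics an [optics_params()] object.
#' @param ml_range microtubule length range (nm).
#' @param L0_range optional initial-overlap range (nm) passed to
#'   [simulate_ensemble()].
#' @param snr if not \code{NULL}, the optics background is set so the
#'   untagged overlap renders at this SNR (see [optics_at_snr()]).
#' @param seed integer seed for the whole run.
#' @param stall_v,stall_t stall detection threshold (nm/s) and minimum
#'   stalled duration (s).
#' @param smoothing_window velocity smoothing window (frames).
#' @param bin_width_density histogram bin width for GFP densities
#'   (A.U./nm).
#' @param occupancy_grid occupancy values for the efficiency table.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return An object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(n_events = 20,
                            params = simulation_params(),
                            optics = optics_params(),
                            ml_range = c(4000, 10000),
                            L0_range = NULL,
                            snr = NULL,
                            seed = 1L,
                            stall_v = 2, stall_t = 10,
                            smoothing_window = 5,
                            bin_width_density = 0.5,
                            occupancy_grid = seq(0.01, 0.10, by = 0.01),
                            out_dir = NULL) {
  cfg <- list(n_events = n_events, params = params, optics = optics,
              ml_range = ml_range, L0_range = L0_range, snr = snr, seed = seed,
              stall_v = stall_v, stall_t = stall_t,
              smoothing_window = smoothing_window,
              bin_width_density = bin_width_density,
              occupancy_grid = occupancy_grid, out_dir = out_dir)
  stopifnot(cfg$n_events >= 1, inherits(cfg$params, "simulation_params"),
            inherits(cfg$optics, "optics_params"),
            cfg$stall_v > 0, cfg$stall_t > 0, cfg$smoothing_window >= 1,
            cfg$bin_width_density > 0, all(cfg$occupancy_grid > 0))
  structure(cfg, class = "pipeline_config")
}

#' Run the full simulate-analyze-fit pipeline
#'
#' Simulates an ensemble of sliding events, renders kymographs, tracks and
#' measures every event, segments the velocity phases, assembles the event
#' table, applies the exclusion filters, and fits the velocity-overlap
#' relation plus the sliding-efficiency table. Deterministic given the
#' configured seed.
#'
#' @param config a [pipeline_config()] object.
#' @param progress print per-stage progress?
#' @return An object of class \code{"pipeline_result"}: list with
#'   \code{events} (per-event [track_event()] + [segment_phases()]
#'   results), \code{event_table} (one row per event), \code{filters}
#'   (inclusion/exclusion for the velocity and length analyses),
#'   \code{mm_fit}, \code{efficiency} (S over the occupancy grid),
#'   \code{stats} (summary statistics: mean phase-1 velocity, GFP density
#'   fit, final-overlap ratio, length regression), and \code{config}.
#' @export
run_pipeline <- function(config = pipeline_config(), progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  optics <- config$optics
  if (!is.null(config$snr)) optics <- optics_at_snr(optics, config$snr)

  say <- function(...) if (progress) message(...)
  say("simulating ", config$n_events, " events")
  ens <- simulate_ensemble(config$n_events, config$params, optics,
                           ml_range = config$ml_range,
                           L0_range = config$L0_range, seed = config$seed)

  say("tracking and segmenting")
  events <- lapply(ens$events, function(e) {
    tr <- track_event(e$kymo, stall_v = config$stall_v,
                      stall_t = config$stall_t,
                      window = config$smoothing_window)
    seg <- tryCatch(segment_phases(tr$velocity), error = function(err) NULL)
    list(id = e$id, trace = tr, phases = seg, truth = e$truth)
  })

  event_table <- do.call(rbind, lapply(events, function(e) {
    tr <- e$trace
    data.frame(
      id = e$id,
      ML1_nm = tr$ML1_nm, ML2_nm = tr$ML2_nm, L0_nm = tr$L0_nm,
      v_phase1_nm_s = if (!is.null(e$phases)) e$phases$v_phase1 else NA_real_,
      t12_s = if (!is.null(e$phases)) e$phases$t12 else NA_real_,
      t23_s = if (!is.null(e$phases)) e$phases$t23 else NA_real_,
      L_FO_nm = tr$L_FO_nm, LET1_nm = tr$LET1_nm, LET2_nm = tr$LET2_nm,
      rho_untagged_initial = tr$rho_untagged_initial,
      n_microtubules = 2L, encountered_bundle = FALSE,
      proximal_plus_ends_at_start = FALSE,
      overlap_edge_distinguishable = tr$trackable &&
        sum(tr$frames$ok) > 0.8 * nrow(tr$frames),
      mt_edges_distinguishable = is.finite(tr$ML1_nm) && is.finite(tr$ML2_nm))
  }))

  say("filtering and fitting")
  fv <- filter_events(event_table, "velocity_vs_overlap")
  fl <- filter_events(event_table, "length_vs_final_overlap")

  mm <- tryCatch(
    fit_mm(fv$included$L0_nm, fv$included$v_phase1_nm_s),
    error = function(err) structure(list(error = conditionMessage(err)),
                                    class = "mm_fit_failure"))
  eff <- if (inherits(mm, "mm_fit"))
    efficiency_table(mm$KL, config$occupancy_grid, config$params$delta)
  else NULL

  li <- fl$included
  stalled <- li[is.finite(li$L_FO_nm), , drop = FALSE]
  ratio <- stalled$L_FO_nm / (stalled$LET1_nm + stalled$LET2_nm)
  length_reg <- if (nrow(stalled) >= 3)
    linear_fit(stalled$ML1_nm + stalled$ML2_nm, stalled$L_FO_nm) else NULL
  rho_fit <- tryCatch(
    gaussian_fit(event_table$rho_untagged_initial,
                 config$bin_width_density),
    error = function(err) NULL)

  stats <- list(
    v_phase1_mean = mean(fv$included$v_phase1_nm_s, na.rm = TRUE),
    v_phase1_sd = stats::sd(fv$included$v_phase1_nm_s, na.rm = TRUE),
    pearson_v_L0 = tryCatch(pearson(fv$included$L0_nm,
                                    fv$included$v_phase1_nm_s),
                            error = function(err) NA_real_),
    rho_untagged_fit = rho_fit,
    final_overlap_ratio_mean = mean(ratio, na.rm = TRUE),
    final_overlap_ratio_sd = stats::sd(ratio, na.rm = TRUE),
    n_stalled = nrow(stalled),
    length_regression = length_reg)

  res <- structure(list(events = events, event_table = event_table,
                        filters = list(velocity = fv, length = fl),
                        mm_fit = mm, efficiency = eff, stats = stats,
                        config = config, truth_table = ens$truth_table),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$event_table, file.path(out_dir, "events.csv"),
                   row.names = FALSE)
  ph <- res$event_table[, c("id", "t12_s", "t23_s", "v_phase1_nm_s")]
  utils::write.csv(ph, file.path(out_dir, "phases.csv"), row.names = FALSE)
  model <- list(
    mm = if (inherits(res$mm_fit, "mm_fit")) as.list(coef(res$mm_fit))
         else list(error = res$mm_fit$error),
    efficiency = res$efficiency,
    final_overlap_ratio_mean = res$stats$final_overlap_ratio_mean)
  jsonlite::write_json(model, file.path(out_dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$stats
  cat("Sliding-analysis pipeline result\n")
  cat(sprintf("  events: %d (velocity analysis kept %d, length analysis kept %d)\n",
              nrow(x$event_table), nrow(x$filters$velocity$included),
              nrow(x$filters$length$included)))
  cat(sprintf("  phase-1 velocity: %.1f +/- %.1f nm/s; r(v, L0) = %.2f\n",
              s$v_phase1_mean, s$v_phase1_sd, s$pearson_v_L0))
  if (inherits(x$mm_fit, "mm_fit"))
    cat(sprintf("  velocity-overlap fit: v0 = %.1f nm/s, KL = %.0f nm\n",
                x$mm_fit$v0, x$mm_fit$KL))
  if (!is.null(s$final_overlap_ratio_mean) && is.finite(s$final_overlap_ratio_mean))
    cat(sprintf("  final overlap ratio L_FO/(LET1+LET2): %.3f +/- %.3f (n = %d stalled)\n",
                s$final_overlap_ratio_mean, s$final_overlap_ratio_sd,
                s$n_stalled))
  invisible(x)
}
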