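# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_cache)) assign(name, build(), .fixture_cache)
  get(name, .fixture_cache)
}

# One saturated-end-tag event rendered without noise: the round-trip oracle.
noiseless_event <- function() {
  fixture("noiseless_event", function() {
    p <- simulation_params(ML1 = 8000, ML2 = 8000, s0 = 500,
                           endtag_fraction = 0.4, endtag_growth_rate = Inf,
                           duration = 200)
    truth <- simulate_pair(p)
    kymo <- render_kymograph(truth, optics_params(), noise = FALSE)
    list(truth = truth, kymo = kymo, params = p)
  })
}

# A small noisy ensemble at SNR 5 with saturated, length-scaled end-tags.
noisy_ensemble <- function() {
  fixture("noisy_ensemble", function() {
    p <- simulation_params(endtag_fraction = 0.4, endtag_growth_rate = Inf,
                           duration = 300)
    simulate_ensemble(6, p, optics_at_snr(optics_params(), 5), seed = 7)
  })
}

# Synthetic GFP line profile with known plateaus (counts per pixel), used
# to exercise end-tag segmentation without a renderer in the loop.
profile_fixture <- function(n_px = 60, bg = 20, untagged = 500,
                            endtag = 1200, tag1_px = 10, tag2_px = 10,
                            overlap = c(11, 50)) {
  prof <- rep(bg, n_px)
  prof[overlap[1]:overlap[2]] <- bg + untagged
  prof[overlap[1]:(overlap[1] + tag2_px - 1)] <- bg + endtag
  prof[(overlap[2] - tag1_px + 1):overlap[2]] <- bg + endtag
  prof
}

# Full-pipeline recovery table on a saturated roadblock ensemble at SNR 5.
acceptance_roundtrip <- function(n = 50, seed = 1) {
  fixture("acceptance_roundtrip", function() {
    p <- simulation_params(endtag_fraction = 0.4, endtag_growth_rate = Inf,
                           duration = 300)
    ens <- simulate_ensemble(n, p, optics_at_snr(optics_params(), 5),
                             ml_range = c(4000, 10000), seed = seed)
    rows <- lapply(ens$events, function(e) {
      tr <- track_event(e$kymo)
      seg <- tryCatch(segment_phases(tr$velocity), error = function(err) NULL)
      tru <- e$truth
      data.frame(
        id = e$id,
        v1_rel_err = if (!is.null(seg))
          seg$v_phase1 / tru$v_phase1_true - 1 else NA_real_,
        t12_err_s = if (!is.null(seg)) seg$t12 - tru$t12_true else NA_real_,
        t23_err_s = if (!is.null(seg)) seg$t23 - tru$t23_true else NA_real_,
        L0_err_nm = tr$L0_nm - tru$frames$L_overlap_nm[1],
        LFO_err_nm = tr$L_FO_nm - tru$L_FO_true,
        LET1_err_nm = tr$LET1_nm - ens$truth_table$LET1_nm[e$id],
        LET2_err_nm = tr$LET2_nm - ens$truth_table$LET2_nm[e$id],
        ratio = tr$L_FO_nm / (tr$LET1_nm + tr$LET2_nm),
        stalled = !is.na(tr$L_FO_nm))
    })
    do.call(rbind, rows)
  })
}

# Pipeline run on the flagship growing-end-tag condition, for the
# velocity-overlap refit and efficiency calculation.
acceptance_velocity_run <- function(n = 40, seed = 2) {
  fixture("acceptance_velocity_run", function() {
    cfg <- pipeline_config(n_events = n,
                           ml_range = c(5500, 10000),
                           L0_range = c(1500, 5000),
                           snr = 5, seed = seed)
    run_pipeline(cfg)
  })
}
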