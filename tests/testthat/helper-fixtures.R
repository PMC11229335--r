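# Shared fixtures: small, fast parameter sets and hand-built kymographs.

quiet_optics <- function(n_frames = 100, ...) {
  optics_params(n_frames = n_frames, background_sd = 0,
                bleach_rate_per_frame = 0, ...)
}

single_speed_motor <- function(v_bp_s, d_kb = 6, ...) {
  motor_params(mixture_weights = 1, mixture_means_bp_s = v_bp_s,
               mixture_sds_bp_s = 0, track_len_weights = 1,
               track_len_means_kb = d_kb, track_len_sds_kb = 0,
               pause_prob_per_frame = 0, ...)
}

# A noiseless kymograph matrix with one emitter following `px_path`
# (1-based pixel per frame, NA = absent), narrow PSF so the peak stays on
# one pixel.
path_kymograph <- function(px_path, n_px = 49, bg = 10, amp = 1000) {
  m <- matrix(bg, length(px_path), n_px)
  for (f in seq_along(px_path)) {
    if (!is.na(px_path[f])) m[f, px_path[f]] <- bg + amp
  }
  m
}

# One row resembling detect_tracks() output, built by applying the public
# segmentation to a hand-built kymograph.
segment_path <- function(px_path, thresholds = segmentation_thresholds()) {
  detect_tracks(path_kymograph(px_path), thresholds = thresholds)
}

colony_probs_uniformish <- function() {
  tibble::tibble(
    outcome = c("CO", "NCO", "BIR", "chromosome_loss",
                "CO", "NCO", "CO", "NCO", "chromosome_loss"),
    colony_class = c(rep("sectored", 4), rep("solid_red", 2), rep("white", 3)),
    prob = c(0.25, 0.2, 0.1, 0.05, 0.1, 0.1, 0.05, 0.1, 0.05)
  )
}
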