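#' Position-wise binding probability profile along the DNA
#'
#' Normalized histogram of PSC positions at a snapshot time (15 min of
#' observation in the standard assay), binned at one pixel's worth of DNA by
#' default since positions are pixel-resolved.
#'
#' @param final_positions_bp Numeric vector of PSC positions at the snapshot
#'   time, in bp.
#' @param dna_length_bp Length of the DNA substrate.
#' @param bin_bp Bin width in bp.
#' @param target_pos_bp Optional coordinate of the homologous site; recorded
#'   as the target bin.
#' @param observation_time_s Snapshot time, recorded as metadata.
#' @returns A tibble of class `binding_profile` with one row per bin
#'   (`bin`, `start_bp`, `end_bp`, `count`, `prob`), plus attributes
#'   `target_bin`, `n_events`, `dna_length_bp` and `observation_time_s`.
#' @examples
#' binding_profile(c(100, 1500, 1700, 23000), 48502, target_pos_bp = 23000)
#' @export
binding_profile <- function(final_positions_bp, dna_length_bp,
                            bin_bp = 1000, target_pos_bp = NULL,
                            observation_time_s = 900) {
  check_scalar(dna_length_bp, "dna_length_bp", lower = 0, strict_lower = TRUE)
  check_scalar(bin_bp, "bin_bp", lower = 0, strict_lower = TRUE)
  if (length(final_positions_bp) == 0 ||
      any(!is.finite(final_positions_bp))) {
    abort("`final_positions_bp` must be non-empty and finite.",
          class = "curtainr_invalid_input")
  }
  if (any(final_positions_bp < 0 | final_positions_bp > dna_length_bp)) {
    abort("Positions fall outside [0, dna_length_bp].",
          class = "curtainr_invalid_input")
  }
  n_bins <- as.integer(ceiling(dna_length_bp / bin_bp))
  bin <- pmin(floor(final_positions_bp / bin_bp), n_bins - 1L)
  counts <- tabulate(bin + 1L, nbins = n_bins)
  out <- tibble(
    bin = seq_len(n_bins) - 1L,
    start_bp = (seq_len(n_bins) - 1L) * bin_bp,
    end_bp = pmin(seq_len(n_bins) * bin_bp, dna_length_bp),
    count = counts,
    prob = counts / length(final_positions_bp)
  )
  class(out) <- c("binding_profile", class(out))
  attr(out, "target_bin") <- if (is.null(target_pos_bp)) NA_integer_ else {
    check_scalar(target_pos_bp, "target_pos_bp", lower = 0, upper = dna_length_bp)
    as.integer(min(floor(target_pos_bp / bin_bp), n_bins - 1L))
  }
  attr(out, "n_events") <- length(final_positions_bp)
  attr(out, "dna_length_bp") <- dna_length_bp
  attr(out, "observation_time_s") <- observation_time_s
  out
}

#' Fold enrichment between two binding probabilities
#'
#' The arithmetic core of target-site enrichment: the probability of the
#' target bin divided by a reference probability (the mean off-target
#' probability, or the same bin's probability in a reference profile).
#'
#' @param p_target Probability at the site of interest.
#' @param p_reference Reference probability (> 0).
#' @returns The fold value `p_target / p_reference`.
#' @examples
#' fold_enrichment(0.165, 0.022) # 7.5
#' @export
fold_enrichment <- function(p_target, p_reference) {
  if (any(p_reference <= 0)) {
    abort("Reference probability must be positive.",
          class = "curtainr_undefined_enrichment")
  }
  p_target / p_reference
}

#' Enrichment of the homologous site in a binding profile
#'
#' @param profile A [binding_profile()] with a target bin set.
#' @param mode `"vs_mean_offtarget"` divides the target-bin probability by
#'   the mean probability of all non-target bins; `"vs_reference_profile"`
#'   divides it by the probability of the same bin in `reference` (e.g. a
#'   non-homologous DNA control).
#' @param reference A reference [binding_profile()]; required for
#'   `"vs_reference_profile"`.
#' @returns The fold value.
#' @examples
#' pr <- binding_profile(rep(c(500, 23500), c(33, 67)), 48502,
#'                       target_pos_bp = 23500)
#' enrichment_at_target(pr)
#' @export
enrichment_at_target <- function(profile,
                                 mode = c("vs_mean_offtarget", "vs_reference_profile"),
                                 reference = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "binding_profile"))
  tb <- attr(profile, "target_bin")
  if (is.na(tb)) {
    abort("Profile has no target bin.", class = "curtainr_invalid_parameter")
  }
  p_t <- profile$prob[profile$bin == tb]
  p_ref <- switch(mode,
    vs_mean_offtarget = mean(profile$prob[profile$bin != tb]),
    vs_reference_profile = {
      if (is.null(reference) || !inherits(reference, "binding_profile")) {
        abort("`reference` profile required for vs_reference_profile.",
              class = "curtainr_invalid_parameter")
      }
      reference$prob[reference$bin == tb]
    }
  )
  fold_enrichment(p_t, p_ref)
}

#' Classify target-alignment events as 1D or 3D homology search
#'
#' A segmented track that ends within one bin of the homologous coordinate
#' is an alignment event. It is classed as 1D when the translocation
#' distance before stabilization exceeds `min_1d_kb` (long-range sliding
#' along the duplex), otherwise 3D (capture from solution; translocation
#' faster or shorter than the resolution cannot be excluded and is classed
#' 3D by this operational definition). Dwell is measured from stabilization
#' (the stop frame) to the molecule's disappearance or the end of the
#' record; `released` flags molecules that left before the movie ended.
#'
#' @param tracks Segmented tracks ([detect_tracks()] output).
#' @param target_pos_bp Coordinate of the homologous site, bp.
#' @param optics [optics_params()] (pixel size and frame interval).
#' @param min_1d_kb 1D threshold on pre-capture translocation distance (kb).
#' @param bin_bp Tolerance around the target defining "at the target".
#' @returns A tibble with one row per alignment event: `track_id`, `mode`
#'   (`"1D"`/`"3D"`), `pre_capture_kb`, `dwell_s`, `released`. Tracks not at
#'   the target are omitted.
#' @examples
#' op <- optics_params(n_frames = 300)
#' mo <- motor_params(target_pos_bp = 24000)
#' sim <- simulate_curtain(mo, op, n_dna = 4, seed = 1)
#' seg <- dplyr::bind_rows(lapply(sim$kymographs, detect_tracks))
#' classify_search_mode(seg, 24000, op)
#' @export
classify_search_mode <- function(tracks, target_pos_bp, optics,
                                 min_1d_kb = 2, bin_bp = 1000) {
  stopifnot(is.data.frame(tracks), inherits(optics, "optics_params"))
  check_scalar(target_pos_bp, "target_pos_bp", lower = 0)
  check_scalar(min_1d_kb, "min_1d_kb", lower = 0)
  if (nrow(tracks) == 0) {
    return(tibble(track_id = character(), mode = character(),
                  pre_capture_kb = double(), dwell_s = double(),
                  released = logical()))
  }
  dt <- optics$frame_interval_s
  end_bp <- (tracks$stop_px - 0.5) * optics$bp_per_pixel
  at_target <- abs(end_bp - target_pos_bp) <= bin_bp
  trk <- compute_distance(tracks[at_target, , drop = FALSE], optics)
  tibble(
    track_id = trk$track_id,
    mode = ifelse(trk$distance_kb > min_1d_kb, "1D", "3D"),
    pre_capture_kb = trk$distance_kb,
    dwell_s = (trk$last_frame - trk$stop_frame) * dt,
    released = trk$last_frame < trk$movie_frames
  )
}

#' Fraction of target dwellers that were transient
#'
#' Among molecules that aligned with the homologous site for at least
#' `min_dwell_s`, the fraction that subsequently released rather than
#' remaining stably bound. The default dwell threshold is 20 s; 10 s is an
#' alternative convention in use for the same quantity, so the threshold is
#' exposed rather than fixed.
#'
#' @param events Alignment events from [classify_search_mode()].
#' @param min_dwell_s Minimum dwell to count as having aligned.
#' @returns A one-row tibble: `n_transient`, `n_dwellers`, `fraction`.
#' @examples
#' ev <- tibble::tibble(dwell_s = c(25, 30, 40), released = c(TRUE, FALSE, TRUE))
#' transient_fraction(ev)
#' @export
transient_fraction <- function(events, min_dwell_s = 20) {
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0) {
    abort("`events` is empty.", class = "curtainr_invalid_parameter")
  }
  check_scalar(min_dwell_s, "min_dwell_s", lower = 0)
  dwellers <- events$dwell_s >= min_dwell_s
  n_d <- sum(dwellers)
  n_t <- sum(dwellers & events$released)
  tibble(n_transient = n_t, n_dwellers = n_d,
         fraction = if (n_d > 0) n_t / n_d else 0)
}

#' Tally 1D versus 3D alignment events
#'
#' @param events Alignment events from [classify_search_mode()].
#' @returns A tibble with one row per mode: counts and shares.
#' @examples
#' ev <- tibble::tibble(mode = c("1D", "1D", "3D"))
#' search_mode_tally(ev)
#' @export
search_mode_tally <- function(events) {
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0) {
    abort("`events` is empty.", class = "curtainr_invalid_parameter")
  }
  events |>
    count(.data$mode, name = "n") |>
    mutate(share = .data$n / sum(.data$n))
}
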