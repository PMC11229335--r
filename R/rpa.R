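#' Detect RPA episodes colocalized with segmented PSC tracks
#'
#' An RPA event is called on a track when the magenta channel shows a peak
#' within `tolerance_px` of the track position for at least two consecutive
#' frames (single-frame coincidences are treated as noise). The association
#' frame is the first such frame and the dissociation frame the last; events
#' still colocalized in the movie's final frame are censored. The event
#' intensity is the background-subtracted intensity integrated over a window
#' of `2 * integration_halfwidth_px + 1` pixels around the track, summarised
#' as the median of the first five colocalized frames (before appreciable
#' photobleaching); the global background is the median intensity of the
#' magenta channel, whose pixels are overwhelmingly track-free.
#'
#' @param tracks Segmented tracks from [detect_tracks()] (green or blue
#'   channel).
#' @param kymo The [render_kymograph()] object (its `magenta` channel is
#'   used), or a bare numeric matrix of the same shape as the segmented
#'   channel.
#' @param tolerance_px Maximum distance in pixels between the RPA peak and
#'   the track position.
#' @param thresholds [segmentation_thresholds()] supplying the peak
#'   detection SNR.
#' @param integration_halfwidth_px Half-width of the intensity integration
#'   window.
#' @param frame_interval_s Seconds per frame; taken from the kymograph's
#'   optics when omitted (required for bare matrices).
#' @param psf_sigma_px PSF width used for the aperture correction of the
#'   integration window; taken from the kymograph's optics when omitted.
#' @returns A tibble with one row per event: `track_id`, `bind_frame` (first
#'   detection of the owning track), `assoc_frame`, `assoc_delay_s`,
#'   `dissoc_frame` (`NA` when censored), `censored`, `lifetime_s` (`NA`
#'   when censored), `peak_intensity` (integrated, background-subtracted
#'   window intensity) and `background_estimate` (per-pixel global
#'   background).
#' @examples
#' op <- optics_params(n_frames = 200)
#' sim <- simulate_curtain(motor_params(), op, rpa = rpa_gen_params(),
#'                         n_dna = 1, seed = 1)
#' seg <- detect_tracks(sim$kymographs[[1]])
#' detect_colocalization(seg, sim$kymographs[[1]], frame_interval_s = 0.4)
#' @export
detect_colocalization <- function(tracks, kymo, tolerance_px = 2,
                                  thresholds = segmentation_thresholds(),
                                  integration_halfwidth_px = 3L,
                                  frame_interval_s = NULL,
                                  psf_sigma_px = NULL) {
  stopifnot(is.data.frame(tracks))
  check_scalar(tolerance_px, "tolerance_px", lower = 0)
  if (inherits(kymo, "kymograph")) {
    m <- kymo$magenta
    dt <- frame_interval_s %||% kymo$optics$frame_interval_s
    psf_sigma_px <- psf_sigma_px %||% kymo$optics$psf_sigma_px
  } else if (is.matrix(kymo) && is.numeric(kymo)) {
    m <- kymo
    dt <- frame_interval_s %||%
      abort("`frame_interval_s` is required with a bare matrix.",
            class = "curtainr_invalid_parameter")
    psf_sigma_px <- psf_sigma_px %||% 1
  } else {
    abort("`kymo` must be a kymograph object or numeric matrix.",
          class = "curtainr_invalid_input")
  }
  if (nrow(tracks) > 0 && any(tracks$movie_frames != nrow(m))) {
    abort("Channel shape does not match the segmented tracks.",
          class = "curtainr_invalid_input")
  }
  if (nrow(tracks) == 0) return(empty_rpa_event_tbl())

  bg <- median(m)
  peaks <- find_peaks(m, thresholds$detection_snr)
  n_frames <- nrow(m)
  n_px <- ncol(m)
  hw <- as.integer(integration_halfwidth_px)
  peaks_by_frame <- split(peaks$subpx, peaks$frame)

  rows <- list()
  for (i in seq_len(nrow(tracks))) {
    frames <- tracks$frames[[i]]
    pos <- tracks$subpx[[i]]
    coloc <- map_lgl(seq_along(frames), function(j) {
      p <- peaks_by_frame[[as.character(frames[j])]]
      !is.null(p) && any(abs(p - pos[j]) <= tolerance_px)
    })
    runs <- value_runs(coloc)
    ok <- runs$value & runs$length >= 2L
    if (!any(ok)) next
    first_run <- which(ok)[1]
    last_run <- which(ok)[length(which(ok))]
    a_idx <- runs$start[first_run]
    d_idx <- runs$start[last_run] + runs$length[last_run] - 1L
    assoc <- frames[a_idx]
    last_coloc <- frames[d_idx]
    censored <- last_coloc >= n_frames

    ev_idx <- a_idx:d_idx
    ev_idx <- ev_idx[coloc[ev_idx]]
    head_idx <- ev_idx[seq_len(min(5L, length(ev_idx)))]
    # aperture correction: a finite window captures slightly less than the
    # fluorophore's full PSF mass
    capture <- 2 * pnorm((hw + 0.5) / psf_sigma_px) - 1
    ints <- map_dbl(head_idx, function(j) {
      ctr <- tracks$px[[i]][j]
      cols <- max(1L, ctr - hw):min(n_px, ctr + hw)
      (sum(m[frames[j], cols]) - length(cols) * bg) / capture
    })
    rows[[length(rows) + 1L]] <- tibble(
      track_id = tracks$track_id[i],
      bind_frame = tracks$first_frame[i],
      assoc_frame = as.integer(assoc),
      assoc_delay_s = (assoc - tracks$first_frame[i]) * dt,
      dissoc_frame = if (censored) NA_integer_ else as.integer(last_coloc),
      censored = censored,
      lifetime_s = if (censored) NA_real_ else (last_coloc - assoc) * dt,
      peak_intensity = median(ints),
      background_estimate = bg
    )
  }
  if (length(rows) == 0) return(empty_rpa_event_tbl())
  bind_rows(rows)
}

empty_rpa_event_tbl <- function() {
  tibble(track_id = character(), bind_frame = integer(),
         assoc_frame = integer(), assoc_delay_s = double(),
         dissoc_frame = integer(), censored = logical(),
         lifetime_s = double(), peak_intensity = double(),
         background_estimate = double())
}

#' Association delays of RPA events
#'
#' Converts the frame lag between PSC binding and RPA colocalization into
#' seconds and reports the population median (the summary used for
#' comparisons between protein variants, robust to the long delay tail).
#'
#' @param events Output of [detect_colocalization()] (or any tibble with
#'   `assoc_frame` and `bind_frame`).
#' @param frame_interval_s Seconds per frame.
#' @returns A tibble with `track_id` and `assoc_delay_s`, with the median
#'   delay attached as attribute `"median_s"`.
#' @examples
#' ev <- tibble::tibble(track_id = "a", assoc_frame = 22L, bind_frame = 1L)
#' attr(association_times(ev, 0.4), "median_s")
#' @export
association_times <- function(events, frame_interval_s) {
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0) {
    abort("`events` is empty.", class = "curtainr_invalid_parameter")
  }
  check_scalar(frame_interval_s, "frame_interval_s", lower = 0, strict_lower = TRUE)
  if (any(events$assoc_frame < events$bind_frame)) {
    abort("An RPA event precedes its track's binding.",
          class = "curtainr_contract_violation")
  }
  out <- tibble(track_id = events$track_id,
                assoc_delay_s = (events$assoc_frame - events$bind_frame) *
                  frame_interval_s)
  attr(out, "median_s") <- median(out$assoc_delay_s)
  out
}

#' Fraction of RPA events that dissociated within the observation window
#'
#' Because dissociation curves from different variants do not share an end
#' point, the summary used here is the fraction of events whose dissociation
#' was actually observed (uncensored events over all events), not a fitted
#' decay rate.
#'
#' @param events Output of [detect_colocalization()] (needs a `censored`
#'   column).
#' @returns A single fraction in `[0, 1]`.
#' @examples
#' fraction_dissociated(tibble::tibble(censored = c(TRUE, FALSE, FALSE)))
#' @export
fraction_dissociated <- function(events) {
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0) {
    abort("`events` is empty.", class = "curtainr_invalid_parameter")
  }
  mean(!events$censored)
}

#' Intensity-based RPA stoichiometry and underwound-DNA extent
#'
#' Estimates the number of RPA molecules in an event by dividing the
#' background-subtracted event intensity by the calibrated intensity of a
#' single fluorophore, then quantizes the estimate to its bracketing integer
#' counts and converts those to an underwound-DNA extent using the RPA
#' binding footprint on ssDNA.
#'
#' @param peak_intensity Event intensity (same scale as `unit_intensity`);
#'   vectorized.
#' @param background Background intensity to subtract (already-subtracted
#'   inputs can pass 0).
#' @param unit_intensity Calibrated single-fluorophore intensity (> 0).
#' @param footprint_nt Nucleotides of ssDNA occluded per RPA molecule.
#' @returns A tibble with `estimated_molecules` (non-negative real),
#'   `quant_low`/`quant_high` (floor/ceiling integers, equal when the
#'   estimate is exact) and `underwound_low_nt`/`underwound_high_nt`.
#' @examples
#' estimate_stoichiometry(2.5 * 1000, 0, 1000)  # 2-3 molecules, 60-90 nt
#' @export
estimate_stoichiometry <- function(peak_intensity, background = 0,
                                   unit_intensity, footprint_nt = 30) {
  check_scalar(unit_intensity, "unit_intensity", lower = 0, strict_lower = TRUE)
  check_scalar(footprint_nt, "footprint_nt", lower = 0, strict_lower = TRUE)
  est <- pmax((peak_intensity - background) / unit_intensity, 0)
  # quantize with a small tolerance (0.01 molecule) so that a noiselessly
  # rendered integer count, measured through a finite off-centre window,
  # does not straddle the integer boundary
  q <- round(est, 2)
  lo <- floor(q)
  hi <- ceiling(q)
  tibble(
    estimated_molecules = est,
    quant_low = as.integer(lo),
    quant_high = as.integer(hi),
    underwound_low_nt = lo * footprint_nt,
    underwound_high_nt = hi * footprint_nt
  )
}
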