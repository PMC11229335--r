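#' Imaging and camera parameters for kymograph simulation
#'
#' Describes the geometry and noise model of the shuttered three-colour TIRF
#' acquisition that the synthetic kymograph generator emulates: a doubly
#' tethered ~48.5 kb lambda DNA imaged as a 1-pixel-wide line at roughly
#' 1 kb per pixel, with alternating-excitation frames.
#'
#' @param bp_per_pixel Base pairs imaged per pixel along the DNA axis.
#' @param frame_interval_s Seconds between consecutive frames of the same
#'   channel. The default 0.4 s corresponds to a 200 ms integration time plus
#'   a 200 ms shutter delay under alternating illumination.
#' @param n_pixels Pixels along the DNA axis; must cover the DNA length.
#' @param n_frames Frames recorded per channel.
#' @param psf_sigma_px Standard deviation, in pixels, of the 1-D Gaussian
#'   point-spread function used to deposit fluorophore intensity.
#' @param background_mean,background_sd Mean and standard deviation of the
#'   Gaussian camera background (arbitrary camera units).
#' @param unit_intensity Mean integrated intensity contributed by a single
#'   fluorophore (the photobleaching-calibrated single-step intensity).
#' @param bleach_rate_per_frame Per-fluorophore probability of photobleaching
#'   in any one frame (geometric survival).
#' @returns An object of class `optics_params` (a validated list).
#' @examples
#' optics_params(n_frames = 100)
#' @export
optics_params <- function(bp_per_pixel = 1000,
                          frame_interval_s = 0.4,
                          n_pixels = 49,
                          n_frames = 600,
                          psf_sigma_px = 1,
                          background_mean = 100,
                          background_sd = 10,
                          unit_intensity = 1000,
                          bleach_rate_per_frame = 2e-4) {
  check_scalar(bp_per_pixel, "bp_per_pixel", lower = 0, strict_lower = TRUE)
  check_scalar(frame_interval_s, "frame_interval_s", lower = 0, strict_lower = TRUE)
  check_scalar(n_pixels, "n_pixels", lower = 1)
  check_scalar(n_frames, "n_frames", lower = 1)
  check_scalar(psf_sigma_px, "psf_sigma_px", lower = 0, strict_lower = TRUE)
  check_scalar(background_mean, "background_mean", lower = 0)
  check_scalar(background_sd, "background_sd", lower = 0)
  check_scalar(unit_intensity, "unit_intensity", lower = 0, strict_lower = TRUE)
  check_scalar(bleach_rate_per_frame, "bleach_rate_per_frame", lower = 0)
  if (bleach_rate_per_frame >= 1) {
    abort("`bleach_rate_per_frame` must be < 1.", class = "curtainr_invalid_parameter")
  }
  structure(list(
    bp_per_pixel = bp_per_pixel,
    frame_interval_s = frame_interval_s,
    n_pixels = as.integer(n_pixels),
    n_frames = as.integer(n_frames),
    psf_sigma_px = psf_sigma_px,
    background_mean = background_mean,
    background_sd = background_sd,
    unit_intensity = unit_intensity,
    bleach_rate_per_frame = bleach_rate_per_frame
  ), class = "optics_params")
}

#' @export
print.optics_params <- function(x, ...) {
  cat("<optics_params> ", x$n_frames, " frames x ", x$n_pixels, " px, ",
      x$bp_per_pixel, " bp/px, dt = ", x$frame_interval_s, " s\n", sep = "")
  invisible(x)
}

#' Generative model for motor-protein trajectories on curtain DNA
#'
#' Parameters of the ground-truth trajectory generator for translocating
#' presynaptic complexes (PSCs): a truncated-Gaussian mixture of velocities,
#' a mixture of translocation distances, a pause model, Poisson binding
#' during an injection window, and optional capture at a homologous target
#' site by 1D sliding or direct 3D binding.
#'
#' Velocities and distances are drawn from the stated Gaussian mixtures
#' truncated below at zero (component means may be negative: they
#' parameterise the underlying normal, as produced by [truncnorm_match()];
#' the truncated draw is always non-negative). Defaults reproduce the wild-type Rad51/Rad54 PSC
#' populations measured in this assay: velocity components 114.3 +/- 73 and
#' 394 +/- 183 bp/s at equal weight, distance components 4.1 +/- 0.9 and
#' 6.2 +/- 1.9 kb.
#'
#' @param mixture_weights,mixture_means_bp_s,mixture_sds_bp_s Velocity mixture
#'   components (weights must sum to 1).
#' @param pause_prob_per_frame Probability per moving frame that a pause
#'   begins.
#' @param pause_len_frames_range Inclusive integer range of pause durations
#'   in frames.
#' @param track_len_weights,track_len_means_kb,track_len_sds_kb Translocation
#'   distance mixture, in kb.
#' @param binding_rate Expected new binding events per DNA per frame during
#'   the binding window.
#' @param bind_window_frames Number of frames at the start of the movie in
#'   which binding can occur (protein is delivered by flow at the start of
#'   acquisition and then washed out). `NULL` allows binding throughout.
#' @param target_pos_bp Coordinate of the homologous target site, or `NULL`
#'   for non-homologous DNA.
#' @param p_capture_1d Probability that a translocating PSC crossing the
#'   target site is captured there (1D alignment).
#' @param p_capture_3d Probability that a new binder lands directly at the
#'   target site from solution (3D alignment).
#' @param p_transient_release Probability that a captured PSC releases and
#'   dissociates after dwelling.
#' @param dwell_release_s Dwell time at the target before a transient release.
#' @param velocity_floor_bp_s Lower truncation of the velocity draw: the
#'   slowest translocation distinguishable from an immobile molecule in the
#'   assay. Molecules below the resolution floor are scored immobile, not
#'   slow, so a generator emulating a *measured* velocity population should
#'   carry no mass below it. Default 0 (no floor).
#' @returns An object of class `motor_params`.
#' @examples
#' motor_params(target_pos_bp = 24000)
#' @export
motor_params <- function(mixture_weights = c(0.5, 0.5),
                         mixture_means_bp_s = c(114.3, 394),
                         mixture_sds_bp_s = c(73, 183),
                         pause_prob_per_frame = 0.005,
                         pause_len_frames_range = c(2L, 4L),
                         track_len_weights = c(0.5, 0.5),
                         track_len_means_kb = c(4.1, 6.2),
                         track_len_sds_kb = c(0.9, 1.9),
                         binding_rate = 0.02,
                         bind_window_frames = 100L,
                         target_pos_bp = NULL,
                         p_capture_1d = 0.9,
                         p_capture_3d = 0.05,
                         p_transient_release = 0.18,
                         dwell_release_s = 30,
                         velocity_floor_bp_s = 0) {
  check_prob_vector(mixture_weights, "mixture_weights")
  k <- length(mixture_weights)
  if (length(mixture_means_bp_s) != k || length(mixture_sds_bp_s) != k) {
    abort("Velocity mixture weights, means and sds must have equal length.",
          class = "curtainr_invalid_parameter")
  }
  if (any(mixture_sds_bp_s < 0)) {
    abort("Velocity mixture sds must be >= 0.",
          class = "curtainr_invalid_parameter")
  }
  check_prob_vector(track_len_weights, "track_len_weights")
  if (length(track_len_means_kb) != length(track_len_weights) ||
      length(track_len_sds_kb) != length(track_len_weights)) {
    abort("Distance mixture weights, means and sds must have equal length.",
          class = "curtainr_invalid_parameter")
  }
  if (any(track_len_sds_kb < 0)) {
    abort("Distance mixture sds must be >= 0.",
          class = "curtainr_invalid_parameter")
  }
  check_scalar(pause_prob_per_frame, "pause_prob_per_frame", lower = 0, upper = 1)
  stopifnot(length(pause_len_frames_range) == 2L,
            pause_len_frames_range[1] >= 1,
            pause_len_frames_range[1] <= pause_len_frames_range[2])
  check_scalar(binding_rate, "binding_rate", lower = 0)
  check_scalar(bind_window_frames, "bind_window_frames", lower = 1, allow_null = TRUE)
  check_scalar(target_pos_bp, "target_pos_bp", lower = 0, allow_null = TRUE)
  check_scalar(p_capture_1d, "p_capture_1d", lower = 0, upper = 1)
  check_scalar(p_capture_3d, "p_capture_3d", lower = 0, upper = 1)
  check_scalar(p_transient_release, "p_transient_release", lower = 0, upper = 1)
  check_scalar(dwell_release_s, "dwell_release_s", lower = 0)
  check_scalar(velocity_floor_bp_s, "velocity_floor_bp_s", lower = 0)
  structure(list(
    mixture_weights = mixture_weights,
    mixture_means_bp_s = mixture_means_bp_s,
    mixture_sds_bp_s = mixture_sds_bp_s,
    pause_prob_per_frame = pause_prob_per_frame,
    pause_len_frames_range = as.integer(pause_len_frames_range),
    track_len_weights = track_len_weights,
    track_len_means_kb = track_len_means_kb,
    track_len_sds_kb = track_len_sds_kb,
    binding_rate = binding_rate,
    bind_window_frames = if (is.null(bind_window_frames)) NULL else as.integer(bind_window_frames),
    target_pos_bp = target_pos_bp,
    p_capture_1d = p_capture_1d,
    p_capture_3d = p_capture_3d,
    p_transient_release = p_transient_release,
    dwell_release_s = dwell_release_s,
    velocity_floor_bp_s = velocity_floor_bp_s
  ), class = "motor_params")
}

#' @export
print.motor_params <- function(x, ...) {
  cat("<motor_params> velocity mixture:",
      paste(sprintf("%.1f+/-%.1f bp/s (w=%.2f)", x$mixture_means_bp_s,
                    x$mixture_sds_bp_s, x$mixture_weights), collapse = ", "),
      "\n")
  invisible(x)
}

#' Generative model for RPA recruitment to translocating PSCs
#'
#' PSC translocation underwinds the duplex behind the motor; RPA binds the
#' transiently exposed single strand. Each moving track can acquire at most
#' one RPA episode, with a molecule count drawn from `stoich_probs`, an
#' association delay after PSC binding, and a finite lifetime. Events whose
#' lifetime outlasts the observation window are censored.
#'
#' @param stoich_probs Named probability vector over molecule counts
#'   `0..k` (the `"0"` entry is the probability that a track never recruits
#'   visible RPA). Defaults to [stoich_probs_nbinom()] with conditional mean
#'   2.5 and sd 1.5 molecules.
#' @param assoc_delay_mean_s Mean association delay in seconds.
#' @param assoc_delay_model `"exponential"` or `"fixed"` (point mass).
#' @param lifetime_mean_s Mean bound lifetime in seconds.
#' @param lifetime_model `"exponential"` or `"fixed"`.
#' @param footprint_nt Single-stranded DNA occluded per RPA heterotrimer, in
#'   nucleotides; used to convert molecule counts into an underwound-DNA
#'   extent.
#' @returns An object of class `rpa_gen_params`.
#' @examples
#' rpa_gen_params(lifetime_mean_s = 120)
#' @export
rpa_gen_params <- function(stoich_probs = stoich_probs_nbinom(2.5, 1.5, p_zero = 0.3),
                           assoc_delay_mean_s = 12.1,
                           assoc_delay_model = c("exponential", "fixed"),
                           lifetime_mean_s = 300,
                           lifetime_model = c("exponential", "fixed"),
                           footprint_nt = 30) {
  check_prob_vector(stoich_probs, "stoich_probs")
  if (is.null(names(stoich_probs))) {
    names(stoich_probs) <- seq_along(stoich_probs) - 1L
  }
  counts <- suppressWarnings(as.integer(names(stoich_probs)))
  if (any(is.na(counts)) || any(counts < 0)) {
    abort("`stoich_probs` must be named by non-negative molecule counts.",
          class = "curtainr_invalid_parameter")
  }
  check_scalar(assoc_delay_mean_s, "assoc_delay_mean_s", lower = 0)
  check_scalar(lifetime_mean_s, "lifetime_mean_s", lower = 0, strict_lower = TRUE)
  check_scalar(footprint_nt, "footprint_nt", lower = 0, strict_lower = TRUE)
  structure(list(
    stoich_probs = stoich_probs,
    stoich_counts = counts,
    assoc_delay_mean_s = assoc_delay_mean_s,
    assoc_delay_model = match.arg(assoc_delay_model),
    lifetime_mean_s = lifetime_mean_s,
    lifetime_model = match.arg(lifetime_model),
    footprint_nt = footprint_nt
  ), class = "rpa_gen_params")
}

#' Stoichiometry distribution with a target conditional mean and sd
#'
#' Builds a probability vector over RPA molecule counts `0..max_n` whose
#' positive part is a shifted negative-binomial (or shifted Poisson when the
#' target variance does not exceed the shifted mean) with the requested
#' conditional mean and standard deviation.
#'
#' @param mean,sd Target mean and sd of the molecule count, conditional on at
#'   least one molecule binding.
#' @param p_zero Probability that no RPA ever binds (no event).
#' @param max_n Largest molecule count retained (tail renormalised).
#' @returns A named probability vector over counts `0..max_n`.
#' @examples
#' p <- stoich_probs_nbinom(2.5, 1.5)
#' sum(p * as.numeric(names(p))) # close to 2.5
#' @export
stoich_probs_nbinom <- function(mean, sd, p_zero = 0, max_n = 8L) {
  check_scalar(mean, "mean", lower = 1)
  check_scalar(sd, "sd", lower = 0)
  check_scalar(p_zero, "p_zero", lower = 0, upper = 1)
  mu <- mean - 1
  v <- sd^2
  kk <- 0:(max_n - 1L)
  if (mu <= 0) {
    pos <- c(1, rep(0, max_n - 1L))
  } else if (v > mu) {
    size <- mu^2 / (v - mu)
    pos <- dnbinom(kk, size = size, mu = mu)
  } else {
    pos <- dpois(kk, lambda = mu)
  }
  pos <- pos / sum(pos)
  setNames(c(p_zero, (1 - p_zero) * pos), as.character(0:max_n))
}

#' Thresholds for kymograph track segmentation
#'
#' Pixel- and frame-scale rules used to annotate translocation: the start of
#' translocation is called when a molecule's net displacement from its
#' binding pixel first exceeds `start_displacement_px`; momentary stalls of
#' `pause_min_frames`..`pause_max_frames` are annotated as pauses; a final
#' static run longer than `termination_min_frames` marks termination.
#'
#' @param start_displacement_px Minimum net displacement (strictly greater
#'   than) in pixels to call a translocation start.
#' @param pause_min_frames,pause_max_frames Inclusive stall-duration window
#'   annotated as a pause.
#' @param termination_min_frames A final static run strictly longer than this
#'   marks termination, with the stop frame fixed at the run's first frame.
#' @param detection_snr Peak-detection threshold in robust standard
#'   deviations above the background level.
#' @param link_gate_px Maximum frame-to-frame movement allowed when linking
#'   detections into tracks. The default 3 px/frame covers the fastest
#'   measured velocities at the default optics.
#' @param max_gap_frames Frames a track may go undetected before it is closed.
#' @param max_step_px Frame-to-frame displacement above which a linked
#'   track is split: a jump larger than any physically plausible per-frame
#'   movement marks a linking artifact (detections swapped between
#'   neighbouring molecules), not motion.
#' @param min_track_frames Minimum number of detections for a track to be
#'   reported.
#' @returns An object of class `segmentation_thresholds`.
#' @examples
#' segmentation_thresholds()
#' @export
segmentation_thresholds <- function(start_displacement_px = 2,
                                    pause_min_frames = 2L,
                                    pause_max_frames = 4L,
                                    termination_min_frames = 10L,
                                    detection_snr = 5,
                                    link_gate_px = 3,
                                    max_gap_frames = 2L,
                                    max_step_px = 2,
                                    min_track_frames = 3L) {
  check_scalar(start_displacement_px, "start_displacement_px", lower = 1)
  check_scalar(pause_min_frames, "pause_min_frames", lower = 1)
  check_scalar(pause_max_frames, "pause_max_frames", lower = pause_min_frames)
  check_scalar(termination_min_frames, "termination_min_frames",
               lower = pause_max_frames, strict_lower = TRUE)
  check_scalar(detection_snr, "detection_snr", lower = 0)
  check_scalar(link_gate_px, "link_gate_px", lower = 0, strict_lower = TRUE)
  check_scalar(max_gap_frames, "max_gap_frames", lower = 0)
  check_scalar(max_step_px, "max_step_px", lower = 0, strict_lower = TRUE)
  check_scalar(min_track_frames, "min_track_frames", lower = 1)
  structure(list(
    start_displacement_px = start_displacement_px,
    pause_min_frames = as.integer(pause_min_frames),
    pause_max_frames = as.integer(pause_max_frames),
    termination_min_frames = as.integer(termination_min_frames),
    detection_snr = detection_snr,
    link_gate_px = link_gate_px,
    max_gap_frames = as.integer(max_gap_frames),
    max_step_px = max_step_px,
    min_track_frames = as.integer(min_track_frames)
  ), class = "segmentation_thresholds")
}
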