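#' Render a three-colour kymograph from ground-truth tracks
#'
#' Produces the three co-registered time-by-position intensity matrices of a
#' single DNA molecule's 1-pixel-wide line scan: green (GFP-Rad54 on the
#' PSC), blue (the Atto647N-labelled 90-mer ssDNA carried by the PSC) and
#' magenta (RPA-mCherry). Each fluorophore deposits `unit_intensity` spread
#' by a 1-D Gaussian point-spread function integrated over pixel bins (pixel
#' `p`, 0-based, covers `[p * bp_per_pixel, (p + 1) * bp_per_pixel)`).
#' Multi-molecule RPA episodes contribute one unit per unbleached molecule.
#' Fluorophores bleach independently with geometric survival; Gaussian
#' camera background is added and intensities floored at zero.
#'
#' @param tracks Rows of [simulate_tracks()] output for a single DNA
#'   molecule.
#' @param rpa_events Matching rows of [simulate_rpa()] output (optional).
#' @param optics An [optics_params()] object.
#' @param seed Optional integer seed (bleaching and camera noise).
#' @returns An object of class `kymograph`: a list with matrices `green`,
#'   `blue`, `magenta` (`n_frames` x `n_pixels`), the `optics`, `dna_id`,
#'   and the generating `truth` (tracks and RPA events) retained for
#'   round-trip testing.
#' @examples
#' op <- optics_params(n_frames = 150)
#' trk <- simulate_tracks(motor_params(), op, n_dna = 1, seed = 1)
#' ky <- render_kymograph(trk, optics = op, seed = 2)
#' dim(ky$green)
#' @export
render_kymograph <- function(tracks, rpa_events = NULL, optics, seed = NULL) {
  stopifnot(is.data.frame(tracks), inherits(optics, "optics_params"))
  if (nrow(tracks) == 0) {
    abort("`tracks` is empty; nothing to render.",
          class = "curtainr_invalid_parameter")
  }
  if (length(unique(tracks$dna_id)) > 1L) {
    abort("`render_kymograph()` renders one DNA molecule at a time.",
          class = "curtainr_invalid_parameter")
  }
  max_bp <- optics$n_pixels * optics$bp_per_pixel
  all_pos <- unlist(tracks$positions_bp)
  if (any(all_pos < 0 | all_pos >= max_bp)) {
    abort("Track positions fall outside the imaged DNA.",
          class = "curtainr_contract_violation")
  }
  set_seed_if(seed)
  n_frames <- optics$n_frames
  n_px <- optics$n_pixels

  emitters <- function(channel) {
    # (frame, bp, n_fluors) triplets for every visible emitter-frame
    fr <- integer(0); bp <- double(0); amp <- double(0)
    for (i in seq_len(nrow(tracks))) {
      pos <- tracks$positions_bp[[i]]
      frames <- tracks$bind_frame[i] + seq_along(pos) - 1L
      keep <- frames <= n_frames
      pos <- pos[keep]; frames <- frames[keep]
      if (length(frames) == 0) next
      if (channel %in% c("green", "blue")) {
        vis <- bleach_span(length(frames), optics$bleach_rate_per_frame)
        if (vis == 0) next
        fr <- c(fr, frames[seq_len(vis)])
        bp <- c(bp, pos[seq_len(vis)])
        amp <- c(amp, rep(1, vis))
      } else {
        if (is.null(rpa_events) || nrow(rpa_events) == 0) next
        ev <- rpa_events[rpa_events$track_id == tracks$track_id[i], , drop = FALSE]
        if (nrow(ev) == 0) next
        for (e in seq_len(nrow(ev))) {
          span <- ev$assoc_frame[e]:ev$obs_end_frame[e]
          span <- span[span >= frames[1] & span <= frames[length(frames)]]
          if (length(span) == 0) next
          n_surv <- rep(0L, length(span))
          for (m in seq_len(ev$n_molecules[e])) {
            vis <- bleach_span(length(span), optics$bleach_rate_per_frame)
            if (vis > 0) n_surv[seq_len(vis)] <- n_surv[seq_len(vis)] + 1L
          }
          alive <- n_surv > 0
          if (!any(alive)) next
          fr <- c(fr, span[alive])
          bp <- c(bp, pos[span[alive] - frames[1] + 1L])
          amp <- c(amp, n_surv[alive])
        }
      }
    }
    list(frame = fr, bp = bp, amp = amp)
  }

  deposit <- function(em) {
    m <- matrix(0, n_frames, n_px)
    if (length(em$frame) == 0) return(m)
    xc <- em$bp / optics$bp_per_pixel  # pixel-unit coordinate
    halfw <- max(3L, ceiling(4 * optics$psf_sigma_px))
    base <- floor(xc)
    for (off in (-halfw):halfw) {
      p <- base + off  # 0-based pixel index
      ok <- p >= 0 & p < n_px
      if (!any(ok)) next
      w <- pnorm(p[ok] + 1, xc[ok], optics$psf_sigma_px) -
        pnorm(p[ok], xc[ok], optics$psf_sigma_px)
      idx <- em$frame[ok] + p[ok] * n_frames  # linear index, column-major
      vals <- optics$unit_intensity * em$amp[ok] * w
      agg <- rowsum(vals, idx)
      m[as.integer(rownames(agg))] <- m[as.integer(rownames(agg))] + agg[, 1]
    }
    m
  }

  bg <- function() {
    if (optics$background_sd > 0) {
      matrix(rnorm(n_frames * n_px, optics$background_mean, optics$background_sd),
             n_frames, n_px)
    } else {
      matrix(optics$background_mean, n_frames, n_px)
    }
  }

  chans <- lapply(c("green", "blue", "magenta"), function(ch) {
    pmax(deposit(emitters(ch)) + bg(), 0)
  })
  structure(list(
    green = chans[[1]], blue = chans[[2]], magenta = chans[[3]],
    optics = optics,
    dna_id = tracks$dna_id[1],
    truth = list(tracks = tracks, rpa_events = rpa_events)
  ), class = "kymograph")
}

# Number of initial frames a fluorophore survives before bleaching.
bleach_span <- function(n, rate) {
  if (rate <= 0) return(n)
  min(n, rgeom(1, rate) + 1L)
}

#' @export
print.kymograph <- function(x, ...) {
  cat("<kymograph> dna ", x$dna_id, ": ", nrow(x$green), " frames x ",
      ncol(x$green), " px, 3 channels\n", sep = "")
  invisible(x)
}

#' Simulate and render a whole curtain experiment
#'
#' Convenience wrapper chaining [simulate_tracks()], [simulate_rpa()] and
#' [render_kymograph()] over several DNA molecules.
#'
#' @inheritParams simulate_tracks
#' @param rpa Optional [rpa_gen_params()]; when supplied, RPA episodes are
#'   simulated and rendered into the magenta channel.
#' @returns A list with `tracks`, `rpa_events` and `kymographs` (one
#'   [render_kymograph()] object per DNA that received at least one binder).
#' @examples
#' sim <- simulate_curtain(motor_params(), optics_params(n_frames = 150),
#'                         n_dna = 2, seed = 1)
#' length(sim$kymographs)
#' @export
simulate_curtain <- function(motor, optics, rpa = NULL, dna_length_bp = 48502,
                             n_dna = 1, seed = NULL) {
  set_seed_if(seed)
  tracks <- simulate_tracks(motor, optics, dna_length_bp, n_dna, seed = NULL)
  events <- if (!is.null(rpa) && nrow(tracks) > 0) {
    simulate_rpa(tracks, rpa, optics, seed = NULL)
  } else {
    empty_rpa_tbl()
  }
  kys <- lapply(unique(tracks$dna_id), function(d) {
    render_kymograph(tracks[tracks$dna_id == d, , drop = FALSE],
                     events[events$dna_id == d, , drop = FALSE],
                     optics, seed = NULL)
  })
  list(tracks = tracks, rpa_events = events, kymographs = kys)
}
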