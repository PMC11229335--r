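#' Recover and annotate tracks from a kymograph
#'
#' Detects intensity peaks frame by frame, links them into tracks by
#' nearest-position association within a gating radius, and annotates each
#' track with the translocation rules used throughout this analysis:
#'
#' * the **start** of translocation is the first frame at which the net
#'   displacement from the binding pixel exceeds `start_displacement_px`
#'   (strictly greater than); the start pixel `Yi` is the pixel at that
#'   frame;
#' * momentary stalls lasting `pause_min_frames`..`pause_max_frames` after
#'   the start are annotated as **pauses**;
#' * a molecule whose final static run is longer than
#'   `termination_min_frames` is **terminated**, with the stop frame `Xf`
#'   fixed at that run's first frame. Long dwells in the middle of a track
#'   (unavoidable for slow molecules at ~1 kb/pixel resolution, where one
#'   pixel can take tens of frames to traverse) do not truncate the track;
#'   termination is the plateau the molecule never leaves.
#'
#' Sub-pixel centroid positions are computed but rounded to the nearest
#' pixel for rule evaluation, since all thresholds are stated in pixels.
#'
#' @param kymo A [render_kymograph()] object, or a bare numeric matrix
#'   (frames x pixels).
#' @param channel Which channel to segment (`"green"`, `"blue"` or
#'   `"magenta"`); ignored for bare matrices.
#' @param thresholds A [segmentation_thresholds()] object.
#' @returns A tibble with one row per recovered track: identifiers, presence
#'   bounds, binding pixel, list-columns `frames`, `px` (pixel-rounded) and
#'   `subpx` (centroid) positions, the start annotation (`started`,
#'   `start_frame`, `start_px`), the stop annotation (`stop_frame`,
#'   `stop_px`, `terminated`), `pauses` (list of tibbles) and the movie
#'   length `movie_frames`.
#' @examples
#' op <- optics_params(n_frames = 150, background_sd = 0)
#' trk <- simulate_tracks(motor_params(), op, n_dna = 1, seed = 1)
#' ky <- render_kymograph(trk, optics = op, seed = 2)
#' detect_tracks(ky)
#' @export
detect_tracks <- function(kymo, channel = c("green", "blue", "magenta"),
                          thresholds = segmentation_thresholds()) {
  channel <- match.arg(channel)
  stopifnot(inherits(thresholds, "segmentation_thresholds"))
  if (inherits(kymo, "kymograph")) {
    m <- kymo[[channel]]
    dna_id <- kymo$dna_id
  } else if (is.matrix(kymo) && is.numeric(kymo)) {
    m <- kymo
    dna_id <- NA_integer_
  } else {
    abort("`kymo` must be a kymograph object or a numeric matrix.",
          class = "curtainr_invalid_input")
  }
  if (length(m) == 0) {
    abort("Empty kymograph.", class = "curtainr_invalid_input")
  }
  if (any(!is.finite(m)) || any(m < 0)) {
    abort("Kymograph intensities must be finite and non-negative.",
          class = "curtainr_invalid_input")
  }

  det <- find_peaks(m, thresholds$detection_snr)
  if (nrow(det) == 0) return(empty_segmented_tbl())
  linked <- link_detections(det, thresholds$link_gate_px,
                            thresholds$max_gap_frames)
  linked <- split_artifact_jumps(linked, thresholds$max_step_px)
  linked <- linked[vapply(linked, function(t) length(t$frame), 1L) >=
                     thresholds$min_track_frames]
  if (length(linked) == 0) return(empty_segmented_tbl())

  rows <- lapply(seq_along(linked), function(i) {
    annotate_track(linked[[i]], thresholds, nrow(m), ncol(m), dna_id,
                   sprintf("s%03d", i), channel)
  })
  bind_rows(rows)
}

empty_segmented_tbl <- function() {
  tibble(dna_id = integer(), track_id = character(), channel = character(),
         first_frame = integer(), last_frame = integer(),
         n_detected = integer(), bind_px = integer(),
         frames = list(), px = list(), subpx = list(),
         started = logical(), start_frame = integer(), start_px = integer(),
         start_subpx = double(), stop_frame = integer(), stop_px = integer(),
         stop_subpx = double(), terminated = logical(),
         pauses = list(), movie_frames = integer())
}

# Per-frame local maxima above a robust background threshold, with 3-point
# centroid sub-pixel refinement. Background level/scale from the median/MAD
# of the whole matrix (tracks occupy a small minority of pixels).
find_peaks <- function(m, snr) {
  bg <- median(m)
  noise <- mad(m)
  thr <- bg + snr * noise
  n_px <- ncol(m)
  left <- cbind(-Inf, m[, -n_px, drop = FALSE])
  right <- cbind(m[, -1, drop = FALSE], -Inf)
  is_peak <- m > thr & m > left & m >= right
  idx <- which(is_peak, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble(frame = integer(), px = integer(), subpx = double()))
  }
  i <- idx[, 1]; j <- idx[, 2]
  wl <- ifelse(j > 1, pmax(m[cbind(i, pmax(j - 1, 1))] - bg, 0), 0)
  wc <- pmax(m[cbind(i, j)] - bg, 0)
  wr <- ifelse(j < n_px, pmax(m[cbind(i, pmin(j + 1, n_px))] - bg, 0), 0)
  subpx <- j + (wr - wl) / pmax(wl + wc + wr, .Machine$double.eps)
  ord <- order(i, j)
  tibble(frame = as.integer(i[ord]), px = as.integer(j[ord]),
         subpx = subpx[ord])
}

# Greedy nearest-position frame-to-frame linking with a gating radius and a
# small tolerated detection gap. Association is predictive: each open track
# extrapolates its recent per-frame drift, which keeps identities straight
# when two molecules cross.
link_detections <- function(det, gate_px, max_gap) {
  tracks <- list()   # closed + open tracks
  open_ids <- integer(0)
  last_frame <- integer(0)
  by_frame <- split(seq_len(nrow(det)), det$frame)

  predict_pos <- function(id, f) {
    t <- tracks[[id]]
    n <- length(t$frame)
    if (n < 3) return(t$subpx[n])
    j <- max(1L, n - 4L)
    slope <- (t$subpx[n] - t$subpx[j]) / (t$frame[n] - t$frame[j])
    t$subpx[n] + slope * (f - t$frame[n])
  }

  for (fch in names(by_frame)) {
    f <- as.integer(fch)
    rows <- by_frame[[fch]]
    # close stale tracks
    stale <- last_frame < f - 1L - max_gap
    open_ids <- open_ids[!stale]
    last_frame <- last_frame[!stale]

    pos <- det$subpx[rows]
    assigned_det <- rep(FALSE, length(rows))
    if (length(open_ids) > 0 && length(rows) > 0) {
      pred <- vapply(open_ids, predict_pos, 1, f = f)
      dmat <- abs(outer(pred, pos, "-"))
      repeat {
        dmin <- min(dmat)
        if (!is.finite(dmin) || dmin > gate_px) break
        hit <- arrayInd(which.min(dmat), dim(dmat))
        ti <- hit[1, 1]; di <- hit[1, 2]
        id <- open_ids[ti]
        tracks[[id]]$frame <- c(tracks[[id]]$frame, f)
        tracks[[id]]$px <- c(tracks[[id]]$px, det$px[rows[di]])
        tracks[[id]]$subpx <- c(tracks[[id]]$subpx, det$subpx[rows[di]])
        last_frame[ti] <- f
        assigned_det[di] <- TRUE
        dmat[ti, ] <- Inf
        dmat[, di] <- Inf
      }
    }
    for (di in which(!assigned_det)) {
      id <- length(tracks) + 1L
      tracks[[id]] <- list(frame = f, px = det$px[rows[di]],
                           subpx = det$subpx[rows[di]])
      open_ids <- c(open_ids, id)
      last_frame <- c(last_frame, f)
    }
  }
  tracks
}

# A frame-to-frame displacement beyond max_step_px cannot be real motion at
# this pixel scale; it marks detections stolen from a neighbouring molecule.
# The linked track is split at every such jump.
split_artifact_jumps <- function(tracks, max_step_px) {
  out <- list()
  for (t in tracks) {
    jumps <- which(abs(diff(t$subpx)) > max_step_px)
    if (length(jumps) == 0) {
      out[[length(out) + 1L]] <- t
      next
    }
    bounds <- c(0L, jumps, length(t$frame))
    for (b in seq_len(length(bounds) - 1L)) {
      idx <- (bounds[b] + 1L):bounds[b + 1L]
      out[[length(out) + 1L]] <- list(frame = t$frame[idx], px = t$px[idx],
                                      subpx = t$subpx[idx])
    }
  }
  out
}

annotate_track <- function(t, thr, n_frames, n_px, dna_id, track_id, channel) {
  px <- as.integer(pmin(pmax(round(t$subpx), 1L), n_px))
  # single-frame localization flickers (+/-1 px) would fragment static runs;
  # a width-3 median filter removes them without distorting real motion
  if (length(px) >= 3) px <- as.integer(stats::runmed(px, 3))
  frames <- t$frame
  bind_px <- px[1]
  net <- abs(px - bind_px)
  start_idx <- which(net > thr$start_displacement_px)[1]
  started <- !is.na(start_idx)

  # termination = the final plateau the molecule never leaves. The plateau
  # is anchored at the final position (mode of the trailing frames) and its
  # first frame is the molecule's first arrival there after which it never
  # strays beyond +/-1 px (localization jitter); anchoring at the end keeps
  # the approach dwell in the penultimate pixel out of the plateau, and
  # long mid-track dwells of slowly moving molecules never truncate the
  # track.
  n_det <- length(px)
  y_end <- as.integer(round(median(tail(px, 11L))))
  outside <- which(abs(px - y_end) > 1L)
  last_out <- if (length(outside) > 0) outside[length(outside)] else 0L
  arrivals <- which(px == y_end & seq_len(n_det) > last_out)
  plateau_start <- if (length(arrivals) > 0) arrivals[1] else n_det
  terminated <- (n_det - plateau_start + 1L) > thr$termination_min_frames
  stop_idx <- if (terminated) plateau_start else n_det

  runs <- value_runs(px)
  k <- nrow(runs)
  pauses <- tibble(start_frame = integer(), n_frames = integer())
  if (started && k > 2) {
    interior <- runs[-c(1, k), , drop = FALSE]
    keep <- interior$length >= thr$pause_min_frames &
      interior$length <= thr$pause_max_frames &
      interior$start >= start_idx &
      interior$start < stop_idx
    if (any(keep)) {
      pauses <- tibble(start_frame = frames[interior$start[keep]],
                       n_frames = as.integer(interior$length[keep]))
    }
  }

  start_frame <- if (started) frames[start_idx] else NA_integer_
  start_px <- if (started) px[start_idx] else NA_integer_
  start_subpx <- if (started) t$subpx[start_idx] else NA_real_
  stop_frame <- frames[stop_idx]
  stop_px <- px[stop_idx]
  # a terminated molecule is static over its plateau, so its final position
  # is localized by averaging the early plateau frames
  stop_subpx <- if (terminated) {
    mean(t$subpx[stop_idx:min(stop_idx + 19L, n_det)])
  } else {
    t$subpx[n_det]
  }
  first_frame <- frames[1]
  last_frame <- frames[length(frames)]
  n_detected <- length(frames)
  tibble(
    dna_id = dna_id, track_id = track_id, channel = channel,
    first_frame = first_frame, last_frame = last_frame,
    n_detected = n_detected, bind_px = bind_px,
    frames = list(frames), px = list(px), subpx = list(t$subpx),
    started = started,
    start_frame = start_frame, start_px = start_px,
    start_subpx = start_subpx,
    stop_frame = stop_frame, stop_px = stop_px,
    stop_subpx = stop_subpx,
    terminated = terminated,
    pauses = list(pauses),
    movie_frames = as.integer(n_frames)
  )
}

#' Endpoint translocation velocity of segmented tracks
#'
#' Computes the translocation velocity of each segmented track from its
#' start/stop endpoints: `|Yf - Yi| * bp_per_pixel / elapsed seconds`, where
#' `Yi`/`Yf` are the start/stop pixel positions, and elapsed seconds is
#' `(Xf - Xi)` frames times the frame interval. Pauses are included in the
#' elapsed time by default, exactly as the endpoint formula implies; set
#' `exclude_pauses = TRUE` for a pause-excluded variant. Tracks that never
#' started translocating get `NA` (the velocity of a non-mover cannot be
#' measured); a started track with zero elapsed time also gets `NA`, with a
#' warning.
#'
#' @param tracks Output of [detect_tracks()].
#' @param optics The [optics_params()] describing the kymograph.
#' @param exclude_pauses Subtract annotated pause time from the elapsed time.
#' @param min_displacement_px Minimum measured displacement `|Yf - Yi|` for
#'   an accurate endpoint velocity; molecules that moved less than this
#'   between start and stop get `NA`. The default 0 evaluates the formula
#'   unconditionally (zero displacement gives 0 bp/s); population analyses
#'   use 2, because a 1-pixel displacement timed over a handful of frames is
#'   dominated by pixel-quantisation noise and such molecules have not moved
#'   far enough for an accurate velocity.
#' @returns `tracks` with a `velocity_bp_s` column added.
#' @examples
#' op <- optics_params(n_frames = 150, background_sd = 0)
#' trk <- simulate_tracks(motor_params(), op, n_dna = 1, seed = 1)
#' seg <- detect_tracks(render_kymograph(trk, optics = op, seed = 2))
#' compute_velocity(seg, op)$velocity_bp_s
#' @export
compute_velocity <- function(tracks, optics, exclude_pauses = FALSE,
                             min_displacement_px = 0) {
  stopifnot(is.data.frame(tracks), inherits(optics, "optics_params"))
  dt <- optics$frame_interval_s
  elapsed_frames <- tracks$stop_frame - tracks$start_frame
  if (exclude_pauses && nrow(tracks) > 0) {
    pause_frames <- map_dbl(seq_len(nrow(tracks)), function(i) {
      p <- tracks$pauses[[i]]
      if (nrow(p) == 0) return(0)
      keep <- p$start_frame >= tracks$start_frame[i] &
        p$start_frame <= tracks$stop_frame[i]
      sum(p$n_frames[keep])
    })
    elapsed_frames <- elapsed_frames - pause_frames
  }
  dy <- endpoint_displacement(tracks)
  v <- dy * optics$bp_per_pixel / (elapsed_frames * dt)
  v[!tracks$started] <- NA_real_
  v[tracks$started & dy < min_displacement_px] <- NA_real_
  bad <- tracks$started & elapsed_frames <= 0
  if (any(bad, na.rm = TRUE)) {
    warn(sprintf("%d track(s) have zero elapsed time; velocity set to NA.",
                 sum(bad, na.rm = TRUE)))
    v[bad] <- NA_real_
  }
  mutate(tracks, velocity_bp_s = v)
}

#' Endpoint translocation distance of segmented tracks
#'
#' Distance travelled between the start and stop pixels,
#' `|Yf - Yi| * bp_per_pixel / 1000` kb. Tracks that never started have
#' distance 0.
#'
#' @inheritParams compute_velocity
#' @returns `tracks` with a `distance_kb` column added.
#' @examples
#' op <- optics_params(n_frames = 150, background_sd = 0)
#' trk <- simulate_tracks(motor_params(), op, n_dna = 1, seed = 1)
#' seg <- detect_tracks(render_kymograph(trk, optics = op, seed = 2))
#' compute_distance(seg, op)$distance_kb
#' @export
compute_distance <- function(tracks, optics) {
  stopifnot(is.data.frame(tracks), inherits(optics, "optics_params"))
  d <- endpoint_displacement(tracks) * optics$bp_per_pixel / 1000
  d[!tracks$started] <- 0
  mutate(tracks, distance_kb = d)
}

# |Yf - Yi| in pixels. Pixel-rounded endpoints: the 3-point centroid is
# compressed toward pixel centres (pixel locking), which distorts short
# displacements, so the formula sticks to the pixel positions its
# thresholds are stated in.
endpoint_displacement <- function(tracks) {
  abs(tracks$stop_px - tracks$start_px)
}
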