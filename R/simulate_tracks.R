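#' Simulate ground-truth PSC trajectories on curtain DNA
#'
#' Generates motor-protein trajectories on doubly tethered DNA molecules with
#' the statistical structure the downstream analyses assume: binding during
#' an injection window, velocities and distances drawn from truncated
#' Gaussian mixtures, random direction, occasional pauses, termination at the
#' drawn distance or at a DNA end, and (when a target coordinate is set)
#' capture at the homologous site by 1D sliding or direct 3D binding.
#' Captured molecules may transiently release and dissociate.
#'
#' @param motor A [motor_params()] object.
#' @param optics An [optics_params()] object.
#' @param dna_length_bp Length of the tethered DNA (default: lambda phage,
#'   48,502 bp).
#' @param n_dna Number of independent DNA molecules.
#' @param seed Optional integer seed; fixed seeds give bit-identical output.
#' @returns A tibble with one row per trajectory: identifiers, `bind_frame`,
#'   `start_pos_bp`, `direction`, the drawn velocity (bp/s) and distance
#'   (kb), a `positions_bp` list-column (one position per frame from binding
#'   to disappearance), `pause_intervals` (list of tibbles), the frame at
#'   which motion stopped, presence bounds, and capture annotations
#'   (`captured_at_target`, `capture_mode` in `none/1D/3D`, `released`).
#' @examples
#' trk <- simulate_tracks(motor_params(), optics_params(n_frames = 200),
#'                        n_dna = 2, seed = 1)
#' trk
#' @export
simulate_tracks <- function(motor, optics, dna_length_bp = 48502,
                            n_dna = 1, seed = NULL) {
  stopifnot(inherits(motor, "motor_params"), inherits(optics, "optics_params"))
  check_scalar(dna_length_bp, "dna_length_bp", lower = 0, strict_lower = TRUE)
  check_scalar(n_dna, "n_dna", lower = 1)
  if (optics$n_frames < 1) {
    abort("`n_frames` must be positive.", class = "curtainr_invalid_parameter")
  }
  if (optics$n_pixels * optics$bp_per_pixel < dna_length_bp) {
    abort("Pixel range does not cover the DNA length.",
          class = "curtainr_invalid_parameter")
  }
  if (!is.null(motor$target_pos_bp) && motor$target_pos_bp > dna_length_bp) {
    abort("`target_pos_bp` lies outside the DNA.",
          class = "curtainr_invalid_parameter")
  }
  set_seed_if(seed)

  n_frames <- optics$n_frames
  dt <- optics$frame_interval_s
  window <- min(motor$bind_window_frames %||% n_frames, n_frames)

  rows <- list()
  for (d in seq_len(n_dna)) {
    n_bind <- rpois(1, motor$binding_rate * window)
    if (n_bind == 0) next
    bind_frames <- sort(sample.int(window, n_bind, replace = TRUE))
    for (i in seq_len(n_bind)) {
      tr <- one_track(motor, dna_length_bp, bind_frames[i], n_frames, dt)
      tr$dna_id <- d
      tr$track_id <- sprintf("d%03d_t%02d", d, i)
      rows[[length(rows) + 1L]] <- tr
    }
  }
  if (length(rows) == 0) return(empty_tracks_tbl())
  out <- bind_rows(rows)
  out <- out[, c("dna_id", "track_id", "bind_frame", "start_pos_bp",
                 "direction", "drawn_velocity_bp_s", "drawn_distance_kb",
                 "positions_bp", "pause_intervals", "motion_stop_frame",
                 "last_frame", "captured_at_target", "capture_mode",
                 "released")]
  out
}

empty_tracks_tbl <- function() {
  tibble(dna_id = integer(), track_id = character(), bind_frame = integer(),
         start_pos_bp = double(), direction = integer(),
         drawn_velocity_bp_s = double(), drawn_distance_kb = double(),
         positions_bp = list(), pause_intervals = list(),
         motion_stop_frame = integer(), last_frame = integer(),
         captured_at_target = logical(), capture_mode = character(),
         released = logical())
}

draw_mixture_trunc <- function(weights, means, sds, lower = 0) {
  comp <- sample.int(length(weights), 1L, prob = weights)
  rtnorm(1, means[comp], sds[comp], lower = lower)
}

# Build one trajectory as a per-frame position vector (bp), from bind_frame
# until the molecule disappears or the movie ends.
one_track <- function(motor, L, bind_frame, n_frames, dt) {
  v <- draw_mixture_trunc(motor$mixture_weights, motor$mixture_means_bp_s,
                          motor$mixture_sds_bp_s,
                          lower = motor$velocity_floor_bp_s)
  d_bp <- 1000 * draw_mixture_trunc(motor$track_len_weights,
                                    motor$track_len_means_kb,
                                    motor$track_len_sds_kb)
  dir <- sample(c(-1L, 1L), 1L)
  has_target <- !is.null(motor$target_pos_bp)
  target <- motor$target_pos_bp

  captured <- FALSE
  mode <- "none"
  released <- FALSE
  avail <- n_frames - bind_frame  # frames after binding

  if (has_target && runif(1) < motor$p_capture_3d) {
    # direct binding at the target from solution
    start <- target
    pos <- rep(target, avail + 1L)
    captured <- TRUE
    mode <- "3D"
    stop_rel <- 0L
    pauses <- tibble(start_frame = integer(), n_frames = integer())
  } else {
    start <- runif(1, 0, L)
    if (v <= 0 || d_bp <= 0 || avail < 1L) {
      pos <- rep(start, avail + 1L)
      stop_rel <- 0L
      pauses <- tibble(start_frame = integer(), n_frames = integer())
    } else {
      step_bp <- v * dt
      n_move <- ceiling(d_bp / step_bp)
      steps <- rep(step_bp, n_move)
      steps[n_move] <- d_bp - step_bp * (n_move - 1)
      # insert pauses as zero-step stretches
      pause_tbl <- tibble(start_frame = integer(), n_frames = integer())
      if (motor$pause_prob_per_frame > 0 && n_move > 1) {
        n_p <- rbinom(1, n_move, motor$pause_prob_per_frame)
        if (n_p > 0) {
          at <- sort(sample.int(n_move, min(n_p, n_move)))
          lens <- sample(seq(motor$pause_len_frames_range[1],
                             motor$pause_len_frames_range[2]),
                         length(at), replace = TRUE)
          new_steps <- vector("list", 2L * length(at) + 1L)
          prev <- 1L
          pause_starts <- integer(length(at))
          inserted <- 0L
          for (j in seq_along(at)) {
            new_steps[[2L * j - 1L]] <- steps[prev:at[j]]
            new_steps[[2L * j]] <- rep(0, lens[j])
            pause_starts[j] <- at[j] + inserted + 1L
            inserted <- inserted + lens[j]
            prev <- at[j] + 1L
          }
          new_steps[[2L * length(at) + 1L]] <-
            if (prev <= n_move) steps[prev:n_move] else numeric()
          steps <- unlist(new_steps)
          pause_tbl <- tibble(start_frame = bind_frame + pause_starts,
                              n_frames = as.integer(lens))
        }
      }
      traj <- start + dir * cumsum(steps)
      pos <- c(start, traj)

      # a motor reaching a tether end stalls there (no reflection)
      out_idx <- which(traj < 0 | traj > L)
      stop_rel <- length(pos) - 1L
      if (length(out_idx) > 0) {
        first_out <- out_idx[1]
        bound <- min(max(traj[first_out], 0), L)
        pos[(first_out + 1L):length(pos)] <- bound
        stop_rel <- first_out
      }

      # 1D capture: evaluate each crossing of the target until captured
      if (has_target && !captured) {
        rel <- pos - target
        crossings <- which(rel[-1] * rel[-length(rel)] <= 0 & rel[-1] != rel[-length(rel)])
        for (ci in crossings) {
          if (ci > stop_rel) break
          if (runif(1) < motor$p_capture_1d) {
            pos[(ci + 1L):length(pos)] <- target
            stop_rel <- ci
            captured <- TRUE
            mode <- "1D"
            break
          }
        }
      }

      # keep only frames within the movie
      if (length(pos) > avail + 1L) {
        pos <- pos[seq_len(avail + 1L)]
        stop_rel <- min(stop_rel, avail)
      } else if (length(pos) < avail + 1L) {
        pos <- c(pos, rep(pos[length(pos)], avail + 1L - length(pos)))
      }
      pause_tbl <- pause_tbl[pause_tbl$start_frame <= n_frames, , drop = FALSE]
      pauses <- pause_tbl
    }
  }

  # transient release after capture
  if (captured && runif(1) < motor$p_transient_release) {
    released <- TRUE
    dwell_frames <- max(1L, round(motor$dwell_release_s / dt))
    end_rel <- min(stop_rel + dwell_frames, length(pos) - 1L)
    pos <- pos[seq_len(end_rel + 1L)]
  }

  tibble(
    bind_frame = as.integer(bind_frame),
    start_pos_bp = start,
    direction = dir,
    drawn_velocity_bp_s = v,
    drawn_distance_kb = d_bp / 1000,
    positions_bp = list(pos),
    pause_intervals = list(pauses),
    motion_stop_frame = as.integer(bind_frame + stop_rel),
    last_frame = as.integer(bind_frame + length(pos) - 1L),
    captured_at_target = captured,
    capture_mode = mode,
    released = released
  )
}
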