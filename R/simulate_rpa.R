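#' Simulate ground-truth RPA binding episodes on moving PSCs
#'
#' Each translocating track receives at most one RPA episode. The molecule
#' count is drawn from the stoichiometry distribution (a count of zero means
#' no visible episode), the association delay from the configured delay
#' model, and the bound lifetime from the configured lifetime model. Episodes
#' whose lifetime outlasts the observable span of the track (movie end, or
#' earlier disappearance of the PSC) are flagged censored.
#'
#' @param tracks Output of [simulate_tracks()].
#' @param rpa An [rpa_gen_params()] object.
#' @param optics The [optics_params()] used for the tracks.
#' @param seed Optional integer seed.
#' @returns A tibble with one row per episode: `track_id`, `dna_id`,
#'   `n_molecules`, `assoc_frame`, `dissoc_frame` (`NA` when censored),
#'   `censored`, and `obs_end_frame`, the last frame at which the episode is
#'   visible.
#' @examples
#' op <- optics_params(n_frames = 200)
#' trk <- simulate_tracks(motor_params(), op, n_dna = 2, seed = 1)
#' simulate_rpa(trk, rpa_gen_params(), op, seed = 2)
#' @export
simulate_rpa <- function(tracks, rpa, optics, seed = NULL) {
  stopifnot(is.data.frame(tracks), inherits(rpa, "rpa_gen_params"),
            inherits(optics, "optics_params"))
  if (nrow(tracks) == 0) return(empty_rpa_tbl())
  set_seed_if(seed)
  dt <- optics$frame_interval_s
  n_frames <- optics$n_frames

  moving <- tracks$drawn_velocity_bp_s > 0 & tracks$drawn_distance_kb > 0 &
    tracks$capture_mode != "3D" & tracks$motion_stop_frame > tracks$bind_frame
  rows <- vector("list", sum(moving))
  j <- 0L
  for (i in which(moving)) {
    n_mol <- sample(rpa$stoich_counts, 1L, prob = rpa$stoich_probs)
    if (n_mol < 1L) next
    delay_s <- switch(rpa$assoc_delay_model,
                      exponential = if (rpa$assoc_delay_mean_s > 0)
                        rexp(1, 1 / rpa$assoc_delay_mean_s) else 0,
                      fixed = rpa$assoc_delay_mean_s)
    life_s <- switch(rpa$lifetime_model,
                     exponential = rexp(1, 1 / rpa$lifetime_mean_s),
                     fixed = rpa$lifetime_mean_s)
    assoc <- tracks$bind_frame[i] + as.integer(ceiling(delay_s / dt))
    track_end <- min(tracks$last_frame[i], n_frames)
    if (assoc > track_end) next
    end_frame <- assoc + max(1L, as.integer(round(life_s / dt)))
    censored <- end_frame > track_end
    j <- j + 1L
    rows[[j]] <- tibble(
      track_id = tracks$track_id[i],
      dna_id = tracks$dna_id[i],
      n_molecules = as.integer(n_mol),
      assoc_frame = as.integer(assoc),
      dissoc_frame = if (censored) NA_integer_ else as.integer(end_frame),
      censored = censored,
      obs_end_frame = as.integer(min(end_frame, track_end))
    )
  }
  if (j == 0L) return(empty_rpa_tbl())
  bind_rows(rows[seq_len(j)])
}

empty_rpa_tbl <- function() {
  tibble(track_id = character(), dna_id = integer(), n_molecules = integer(),
         assoc_frame = integer(), dissoc_frame = integer(),
         censored = logical(), obs_end_frame = integer())
}
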