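test_that("no magenta signal means no colocalization events", {
  op <- quiet_optics(120)
  trk <- simulate_tracks(single_speed_motor(300, binding_rate = 0.05), op,
                         n_dna = 1, seed = 8)
  ky <- render_kymograph(trk, rpa_events = NULL, optics = op, seed = 9)
  seg <- detect_tracks(ky)
  ev <- detect_colocalization(seg, ky)
  expect_equal(nrow(ev), 0L)
})

test_that("a rendered RPA episode is recovered with matching frames", {
  op <- quiet_optics(200)
  # pick a molecule whose whole path keeps its PSF inside the imaged pixels
  # (a molecule at the DNA end loses part of its flux off the line scan)
  cand <- simulate_tracks(single_speed_motor(250, binding_rate = 0.2), op,
                          n_dna = 10, seed = 21)
  mid <- vapply(cand$positions_bp,
                function(p) min(p) > 6000 && max(p) < 42000, TRUE)
  trk <- cand[which(mid)[1], ]
  trk$dna_id <- 1L
  rp <- rpa_gen_params(stoich_probs = c(`0` = 0, `2` = 1),
                       assoc_delay_mean_s = 4, assoc_delay_model = "fixed",
                       lifetime_mean_s = 30, lifetime_model = "fixed")
  truth <- simulate_rpa(trk, rp, op, seed = 22)
  expect_equal(nrow(truth), 1L)
  ky <- render_kymograph(trk, truth, op, seed = 23)
  seg <- detect_tracks(ky)
  ev <- detect_colocalization(seg, ky)
  expect_equal(nrow(ev), 1L)
  expect_lte(abs(ev$assoc_frame - truth$assoc_frame), 1L)
  expect_lte(abs(ev$dissoc_frame - truth$dissoc_frame), 1L)
  expect_false(ev$censored)
  # stoichiometry from the rendered intensity recovers the molecule count
  st <- estimate_stoichiometry(ev$peak_intensity, 0, op$unit_intensity)
  expect_equal(st$quant_low, 2L)
  expect_equal(st$quant_high, 2L)
})

test_that("association delays convert frames to seconds with a median", {
  ev <- tibble::tibble(track_id = c("a", "b"),
                       assoc_frame = c(1L, 22L), bind_frame = c(1L, 1L))
  at <- association_times(ev, 0.4)
  expect_equal(at$assoc_delay_s, c(0, 8.4))
  expect_equal(attr(at, "median_s"), 4.2)
  bad <- tibble::tibble(track_id = "x", assoc_frame = 1L, bind_frame = 5L)
  expect_error(association_times(bad, 0.4),
               class = "curtainr_contract_violation")
  expect_error(association_times(ev[0, ], 0.4),
               class = "curtainr_invalid_parameter")
})

test_that("dissociated fraction counts uncensored events", {
  ev <- tibble::tibble(censored = c(rep(FALSE, 11), rep(TRUE, 9)))
  expect_equal(fraction_dissociated(ev), 0.55)
  expect_equal(fraction_dissociated(tibble::tibble(censored = rep(TRUE, 5))), 0)
})

test_that("dissociated fraction matches the exponential model", {
  # events with exponential lifetimes observed over a finite window:
  # the dissociated fraction estimates the CDF at the window end
  op <- optics_params(n_frames = 600, background_sd = 5)
  mo <- single_speed_motor(200, d_kb = 8, binding_rate = 3,
                           bind_window_frames = 1)
  trk <- simulate_tracks(mo, op, n_dna = 60, seed = 51)
  mean_life <- 120
  rp <- rpa_gen_params(stoich_probs = c(`0` = 0, `2` = 1),
                       assoc_delay_mean_s = 0, assoc_delay_model = "fixed",
                       lifetime_mean_s = mean_life)
  ev <- simulate_rpa(trk, rp, op, seed = 52)
  expect_gte(nrow(ev), 100)
  window_s <- (op$n_frames - 1) * op$frame_interval_s
  expected <- stats::pexp(window_s, 1 / mean_life)
  se <- sqrt(expected * (1 - expected) / nrow(ev))
  expect_lt(abs(fraction_dissociated(ev) - expected), 4 * se)
})

test_that("dissociated fraction is monotone in the observation window", {
  # truncating the same event set at successively earlier frames can only
  # censor more events
  op <- optics_params(n_frames = 500)
  mo <- single_speed_motor(200, d_kb = 8, binding_rate = 2,
                           bind_window_frames = 1)
  trk <- simulate_tracks(mo, op, n_dna = 30, seed = 61)
  rp <- rpa_gen_params(stoich_probs = c(`0` = 0, `1` = 1),
                       assoc_delay_mean_s = 0, assoc_delay_model = "fixed",
                       lifetime_mean_s = 100)
  ev <- simulate_rpa(trk, rp, op, seed = 62)
  fracs <- vapply(c(100, 250, 500), function(cut) {
    trunc_ev <- ev
    trunc_ev$censored <- ev$censored |
      (!is.na(ev$dissoc_frame) & ev$dissoc_frame > cut)
    fraction_dissociated(trunc_ev)
  }, 1)
  expect_true(all(diff(fracs) >= 0))
})

test_that("stoichiometry quantization and footprint conversion", {
  u <- 800
  st0 <- estimate_stoichiometry(1000, 1000, u)
  expect_equal(st0$estimated_molecules, 0)
  expect_equal(st0$underwound_high_nt, 0)

  st <- estimate_stoichiometry(1000 + 2.5 * u, 1000, u, footprint_nt = 30)
  expect_equal(st$estimated_molecules, 2.5)
  expect_equal(c(st$quant_low, st$quant_high), c(2L, 3L))
  expect_equal(c(st$underwound_low_nt, st$underwound_high_nt), c(60, 90))

  st12 <- estimate_stoichiometry(1000 + 1.4 * u, 1000, u)
  expect_equal(c(st12$underwound_low_nt, st12$underwound_high_nt), c(30, 60))

  st_exact <- estimate_stoichiometry(3 * u, 0, u)
  expect_equal(st_exact$quant_low, st_exact$quant_high)

  expect_error(estimate_stoichiometry(100, 0, 0),
               class = "curtainr_invalid_parameter")
})

test_that("stoichiometry is exact on noiseless synthetic intensities", {
  u <- 1234.5
  n_true <- c(1, 2, 3, 4)
  st <- estimate_stoichiometry(500 + n_true * u, 500, u)
  expect_equal(st$estimated_molecules, n_true)
  expect_equal(st$quant_low, st$quant_high)
})
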