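test_that("a stationary emitter yields one non-started, terminated track", {
  seg <- segment_path(rep(20L, 50))
  expect_equal(nrow(seg), 1L)
  expect_false(seg$started)
  expect_true(seg$terminated)
  op <- optics_params(n_frames = 50)
  expect_equal(compute_distance(seg, op)$distance_kb, 0)
  expect_true(is.na(suppressWarnings(compute_velocity(seg, op))$velocity_bp_s))
})

test_that("translocation start fires at net displacement > 2 px", {
  # moving 1 px/frame from pixel 6; net displacement exceeds 2 px on the
  # third frame after first detection
  seg <- segment_path(c(6L, 7L, 8L, 9L, 10L, 11L, 12L, rep(13L, 15)))
  expect_true(seg$started)
  expect_equal(seg$start_frame, seg$first_frame + 3L)
  expect_equal(seg$start_px, 9L)
  expect_true(seg$terminated)
  expect_equal(seg$stop_px, 13L)
})

test_that("a 2-4 frame stall is a pause, not termination", {
  path <- c(6:10, rep(10L, 3), 11:20, rep(20L, 15))
  seg <- segment_path(path)
  expect_equal(nrow(seg), 1L)
  p <- seg$pauses[[1]]
  expect_equal(nrow(p), 1L)
  expect_equal(p$n_frames, 4L)  # 1 moving arrival frame + 3 stalled repeats
  expect_true(seg$terminated)
  expect_equal(seg$stop_px, 20L)
})

test_that("velocity implements the endpoint formula", {
  op <- optics_params(n_frames = 400, frame_interval_s = 0.4)
  trk <- tibble::tibble(
    started = TRUE, start_frame = 10L, stop_frame = 260L,
    start_px = 5L, stop_px = 15L,
    pauses = list(tibble::tibble(start_frame = integer(),
                                 n_frames = integer()))
  )
  # |dY| = 10 px * 1000 bp over 250 frames * 0.4 s = 100 s -> 100 bp/s
  expect_equal(compute_velocity(trk, op)$velocity_bp_s, 100)

  # zero displacement -> 0 bp/s under the bare formula
  trk0 <- dplyr::mutate(trk, stop_px = 5L)
  expect_equal(compute_velocity(trk0, op)$velocity_bp_s, 0)
  # ... and NA under the accuracy rule used for population analyses
  expect_true(is.na(compute_velocity(trk0, op,
                                     min_displacement_px = 2)$velocity_bp_s))

  # zero elapsed time cannot define a velocity
  trk_bad <- dplyr::mutate(trk, stop_frame = 10L)
  expect_warning(v <- compute_velocity(trk_bad, op)$velocity_bp_s,
                 "zero elapsed")
  expect_true(is.na(v))
})

test_that("distance is displacement times pixel size", {
  op <- optics_params(n_frames = 100)
  trk <- tibble::tibble(started = TRUE, start_px = 5L, stop_px = 9L)
  expect_equal(compute_distance(trk, op)$distance_kb, 4)
  trk_ns <- dplyr::mutate(trk, started = FALSE)
  expect_equal(compute_distance(trk_ns, op)$distance_kb, 0)
})

test_that("distance, elapsed time and velocity satisfy the internal identity", {
  op <- quiet_optics(300)
  mo <- motor_params(binding_rate = 0.05, pause_prob_per_frame = 0)
  sim <- simulate_curtain(mo, op, n_dna = 6, seed = 31)
  seg <- dplyr::bind_rows(lapply(sim$kymographs, detect_tracks))
  seg <- suppressWarnings(compute_velocity(seg, op))
  seg <- compute_distance(seg, op)
  ok <- !is.na(seg$velocity_bp_s) & seg$velocity_bp_s > 0
  elapsed_s <- (seg$stop_frame - seg$start_frame) * op$frame_interval_s
  expect_equal(seg$distance_kb[ok] * 1000 / elapsed_s[ok],
               seg$velocity_bp_s[ok])
})

test_that("velocity is invariant to time translation and axis reflection", {
  base <- c(6:16, rep(16L, 15))
  op <- optics_params(n_frames = length(base) + 10)
  v1 <- suppressWarnings(
    compute_velocity(segment_path(base), op))$velocity_bp_s
  shifted <- c(rep(NA_integer_, 10), base)
  v2 <- suppressWarnings(
    compute_velocity(segment_path(shifted), op))$velocity_bp_s
  reflected <- 49L - base + 1L
  v3 <- suppressWarnings(
    compute_velocity(segment_path(reflected), op))$velocity_bp_s
  expect_equal(v1, v2)
  expect_equal(v1, v3)
})

test_that("raising the detection SNR never increases the track count", {
  op <- optics_params(n_frames = 200)
  sim <- simulate_curtain(motor_params(binding_rate = 0.05), op,
                          n_dna = 2, seed = 13)
  counts <- vapply(c(2, 5, 10, 30), function(snr) {
    thr <- segmentation_thresholds(detection_snr = snr)
    sum(vapply(sim$kymographs,
               function(k) nrow(detect_tracks(k, thresholds = thr)), 1L))
  }, 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("degenerate kymograph inputs are handled", {
  thr <- segmentation_thresholds()
  flat <- matrix(100, 50, 49)
  expect_equal(nrow(detect_tracks(flat, thresholds = thr)), 0L)
  bad <- flat; bad[3, 4] <- -1
  expect_error(detect_tracks(bad, thresholds = thr),
               class = "curtainr_invalid_input")
  expect_error(segmentation_thresholds(pause_min_frames = 5,
                                       pause_max_frames = 4),
               class = "curtainr_invalid_parameter")
  expect_error(segmentation_thresholds(termination_min_frames = 4),
               class = "curtainr_invalid_parameter")
})
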