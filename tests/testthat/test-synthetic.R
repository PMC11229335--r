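test_that("degenerate velocity mixture gives stationary tracks", {
  op <- quiet_optics(50)
  mo <- single_speed_motor(0)
  trk <- simulate_tracks(mo, op, n_dna = 3, seed = 1)
  expect_gt(nrow(trk), 0)
  for (p in trk$positions_bp) {
    expect_equal(length(unique(p)), 1L)
  }
  expect_true(all(trk$motion_stop_frame == trk$bind_frame))
})

test_that("drawn velocities match analytic truncated-mixture moments", {
  w <- c(0.5, 0.5); mu <- c(114.3, 394); sg <- c(73, 183)
  op <- quiet_optics(50)
  mo <- motor_params(mixture_weights = w, mixture_means_bp_s = mu,
                     mixture_sds_bp_s = sg, binding_rate = 0.2)
  trk <- simulate_tracks(mo, op, n_dna = 300, seed = 42)
  expect_gte(nrow(trk), 500)
  # oracle: mixture mean by numeric integration of the zero-truncated
  # component densities
  comp_mean <- vapply(1:2, function(j) {
    z <- 1 - pnorm(0, mu[j], sg[j])
    integrate(function(x) x * dnorm(x, mu[j], sg[j]) / z, 0, Inf)$value
  }, 1)
  true_mean <- sum(w * comp_mean)
  comp_m2 <- vapply(1:2, function(j) {
    z <- 1 - pnorm(0, mu[j], sg[j])
    integrate(function(x) x^2 * dnorm(x, mu[j], sg[j]) / z, 0, Inf)$value
  }, 1)
  true_sd <- sqrt(sum(w * comp_m2) - true_mean^2)
  se <- true_sd / sqrt(nrow(trk))
  expect_lt(abs(mean(trk$drawn_velocity_bp_s) - true_mean), 3 * se)
})

test_that("empirical velocity distribution matches the mixture CDF (KS)", {
  w <- c(0.5, 0.5); mu <- c(114.3, 394); sg <- c(73, 183)
  op <- quiet_optics(30)
  mo <- motor_params(mixture_weights = w, mixture_means_bp_s = mu,
                     mixture_sds_bp_s = sg, binding_rate = 1.2,
                     bind_window_frames = 30)
  trk <- simulate_tracks(mo, op, n_dna = 300, seed = 9)
  expect_gte(nrow(trk), 1e4)
  cdf <- function(x) {
    vapply(x, function(xx) {
      sum(w * (pnorm(xx, mu, sg) - pnorm(0, mu, sg)) /
            (1 - pnorm(0, mu, sg)))
    }, 1)
  }
  ks <- suppressWarnings(stats::ks.test(trk$drawn_velocity_bp_s, cdf))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("simulation is bit-identical for a fixed seed", {
  op <- optics_params(n_frames = 80)
  mo <- motor_params()
  rp <- rpa_gen_params()
  a <- simulate_curtain(mo, op, rpa = rp, n_dna = 3, seed = 77)
  b <- simulate_curtain(mo, op, rpa = rp, n_dna = 3, seed = 77)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$rpa_events, b$rpa_events)
  expect_identical(a$kymographs[[1]]$green, b$kymographs[[1]]$green)
  expect_identical(a$kymographs[[1]]$magenta, b$kymographs[[1]]$magenta)
})

test_that("invalid generator parameters are rejected", {
  op <- quiet_optics(50)
  expect_error(simulate_tracks(motor_params(), op, n_dna = 0),
               class = "curtainr_invalid_parameter")
  expect_error(motor_params(mixture_weights = c(0.7, 0.7)),
               class = "curtainr_invalid_parameter")
  expect_error(optics_params(bleach_rate_per_frame = 1),
               class = "curtainr_invalid_parameter")
  expect_error(simulate_tracks(motor_params(target_pos_bp = 1e6), op),
               class = "curtainr_invalid_parameter")
})

test_that("RPA generator honours point-mass distributions and censoring", {
  op <- quiet_optics(100)
  mo <- single_speed_motor(300, binding_rate = 0.3)
  trk <- simulate_tracks(mo, op, n_dna = 10, seed = 3)

  rp2 <- rpa_gen_params(stoich_probs = c(`0` = 0, `2` = 1),
                        assoc_delay_mean_s = 0, assoc_delay_model = "fixed")
  ev <- simulate_rpa(trk, rp2, op, seed = 4)
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$n_molecules == 2L))

  rp_long <- rpa_gen_params(stoich_probs = c(`0` = 0, `1` = 1),
                            assoc_delay_mean_s = 0, assoc_delay_model = "fixed",
                            lifetime_mean_s = 1e6, lifetime_model = "fixed")
  ev_long <- simulate_rpa(trk, rp_long, op, seed = 5)
  expect_true(all(ev_long$censored))
  expect_equal(fraction_dissociated(ev_long), 0)

  expect_equal(nrow(simulate_rpa(trk[0, ], rp2, op)), 0L)
})

test_that("noiseless rendering puts the expected intensity at the peak", {
  op <- quiet_optics(20, psf_sigma_px = 0.8, background_mean = 50)
  trk <- simulate_tracks(single_speed_motor(0), op, n_dna = 1, seed = 2)
  trk <- trk[1, ]
  ky <- render_kymograph(trk, optics = op, seed = 1)
  xc <- trk$positions_bp[[1]][1] / op$bp_per_pixel
  p <- floor(xc)  # 0-based peak pixel
  expected <- op$background_mean + op$unit_intensity *
    (pnorm(p + 1, xc, op$psf_sigma_px) - pnorm(p, xc, op$psf_sigma_px))
  f <- trk$bind_frame + 2
  expect_equal(ky$green[f, p + 1], expected, tolerance = 1e-10)
  expect_identical(dim(ky$green), dim(ky$blue))
  expect_identical(dim(ky$green), dim(ky$magenta))
})

test_that("rendering rejects positions outside the imaged DNA", {
  op <- quiet_optics(20)
  trk <- simulate_tracks(single_speed_motor(0), op, n_dna = 1, seed = 2)[1, ]
  trk$positions_bp[[1]][3] <- 49 * 1000 + 5
  expect_error(render_kymograph(trk, optics = op),
               class = "curtainr_contract_violation")
})

test_that("noiseless kymographs segment back to ground truth", {
  op <- quiet_optics(250)
  mo <- motor_params(binding_rate = 0.015, pause_prob_per_frame = 0)
  total_true <- 0L
  total_rec <- 0L
  for (s in 1:6) {
    trk <- simulate_tracks(mo, op, n_dna = 1, seed = 100 + s)
    if (nrow(trk) == 0) next
    ky <- render_kymograph(trk, optics = op, seed = 200 + s)
    seg <- detect_tracks(ky)
    total_true <- total_true + nrow(trk)
    total_rec <- total_rec + nrow(seg)
    for (i in seq_len(nrow(trk))) {
      j <- which.min(abs(seg$first_frame - trk$bind_frame[i]))
      expect_lte(abs(seg$first_frame[j] - trk$bind_frame[i]), 1L)
      true_px0 <- floor(trk$positions_bp[[i]][1] / op$bp_per_pixel) + 1L
      expect_lte(abs(seg$bind_px[j] - true_px0), 1L)
      # recovered per-frame positions track the truth within one pixel
      frames <- seg$frames[[j]]
      rel <- frames - trk$bind_frame[i] + 1L
      ok <- rel >= 1 & rel <= length(trk$positions_bp[[i]])
      true_px <- floor(trk$positions_bp[[i]][rel[ok]] / op$bp_per_pixel) + 1L
      expect_true(all(abs(seg$px[[j]][ok] - true_px) <= 1L))
    }
  }
  expect_identical(total_rec, total_true)
})
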