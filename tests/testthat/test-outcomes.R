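test_that("marker decision tree classifies the canonical patterns", {
  rec <- tibble::tibble(
    color = c("sectored", "sectored", "sectored", "red", "white", "sectored"),
    red_hyg = c(TRUE, TRUE, TRUE, NA, NA, FALSE),
    red_nat = c(FALSE, TRUE, TRUE, NA, NA, FALSE),
    white_hyg = c(FALSE, TRUE, TRUE, NA, NA, FALSE),
    white_nat = c(TRUE, TRUE, FALSE, NA, NA, FALSE),
    hyg = c(NA, NA, NA, TRUE, TRUE, NA),
    nat = c(NA, NA, NA, TRUE, FALSE, NA),
    ura_met_ok = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  )
  out <- classify_colony(rec)$outcome
  expect_equal(out, c("CO",            # sectors resistant to different drugs
                      "NCO",           # both sectors doubly resistant
                      "BIR",           # red double, white single
                      "NCO", "CO",     # unsectored marker logic
                      "unclassifiable"))
})

test_that("chromosome loss takes precedence over marker logic", {
  rec <- tibble::tibble(
    color = "sectored",
    red_hyg = TRUE, red_nat = TRUE, white_hyg = TRUE, white_nat = TRUE,
    hyg = NA, nat = NA, ura_met_ok = FALSE
  )
  expect_equal(classify_colony(rec)$outcome, "chromosome_loss")
})

test_that("classifier inverts the simulator on every record", {
  for (s in c(1, 2, 3)) {
    rec <- simulate_colony_assay(colony_probs_uniformish(),
                                 n_colonies = 150, n_replicates = 2, seed = s)
    cls <- classify_colony(rec)
    expect_identical(cls$outcome, cls$generating_outcome)
  }
})

test_that("simulator rejects inconsistent probability tables", {
  bad_sum <- colony_probs_uniformish()
  bad_sum$prob[1] <- 0.5
  expect_error(simulate_colony_assay(bad_sum, 10, 1),
               class = "curtainr_invalid_parameter")
  bad_bir <- tibble::tibble(outcome = c("BIR", "NCO"),
                            colony_class = c("solid_red", "sectored"),
                            prob = c(0.5, 0.5))
  expect_error(simulate_colony_assay(bad_bir, 10, 1),
               class = "curtainr_invalid_parameter")
})

test_that("tallies compute per-replicate fractions and summaries", {
  rec <- simulate_colony_assay(sectored_outcome_probs(co = 1),
                               n_colonies = 50, n_replicates = 3, seed = 4)
  tl <- tally_outcomes(classify_colony(rec))
  co <- tl$summary[tl$summary$outcome == "CO", ]
  expect_equal(co$mean_fraction, 1)
  expect_equal(co$sd_fraction, 0)

  # hand-computed oracle: replicate CO fractions 0.4 and 0.6
  rec2 <- dplyr::bind_rows(
    simulate_colony_assay(sectored_outcome_probs(co = 1), 4, 1, seed = 1),
    simulate_colony_assay(sectored_outcome_probs(co = 0), 6, 1, seed = 2),
    dplyr::mutate(
      simulate_colony_assay(sectored_outcome_probs(co = 1), 6, 1, seed = 3),
      replicate_id = 2L),
    dplyr::mutate(
      simulate_colony_assay(sectored_outcome_probs(co = 0), 4, 1, seed = 4),
      replicate_id = 2L)
  )
  tl2 <- tally_outcomes(classify_colony(rec2))
  co2 <- tl2$summary[tl2$summary$outcome == "CO", ]
  expect_equal(co2$mean_fraction, 0.5)
  expect_equal(co2$sd_fraction, sd(c(0.4, 0.6)))
  expect_equal(round(co2$sd_fraction, 4), 0.1414)

  # fractions sum to one within each replicate
  sums <- tl2$by_replicate |>
    dplyr::group_by(replicate_id) |>
    dplyr::summarise(s = sum(fraction))
  expect_true(all(abs(sums$s - 1) < 1e-12))

  # record order does not matter
  shuffled <- rec2[sample(nrow(rec2)), ]
  tl3 <- tally_outcomes(classify_colony(shuffled))
  expect_equal(tl3$summary, tl2$summary)
})

test_that("empty populations are excluded with a warning", {
  rec <- simulate_colony_assay(sectored_outcome_probs(co = 0.5),
                               n_colonies = 10, n_replicates = 2, seed = 5)
  expect_warning(tl <- tally_outcomes(classify_colony(rec), "solid_red"),
                 "no classifiable colonies")
  expect_equal(tl$n_replicates, 0)
})

test_that("strain comparison handles identical and separated inputs", {
  a <- tally_outcomes(simulate_colony_assay(
    sectored_outcome_probs(co = 0.5), 300, 3, seed = 6))
  same <- compare_strains(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  b <- tally_outcomes(simulate_colony_assay(
    sectored_outcome_probs(co = 0.85), 300, 3, seed = 7))
  diff_w <- compare_strains(a, b)
  expect_lt(diff_w$p_value, 0.01)
})

test_that("Welch and permutation tests agree within Monte-Carlo error", {
  set.seed(8)
  a <- tally_outcomes(simulate_colony_assay(
    sectored_outcome_probs(co = 0.45), 200, 6, seed = 9))
  b <- tally_outcomes(simulate_colony_assay(
    sectored_outcome_probs(co = 0.55), 200, 6, seed = 10))
  w <- compare_strains(a, b, method = "welch")
  p <- compare_strains(a, b, method = "permutation", n_perm = 20000, seed = 11)
  # permutation p has MC error ~ sqrt(p(1-p)/B); Welch should sit within a
  # few times that plus small-sample slack
  tol <- 4 * sqrt(max(w$p_value * (1 - w$p_value), 1e-4) / 20000) + 0.02
  expect_lt(abs(w$p_value - p$p_value), tol)
})

test_that("insufficient replicates are rejected", {
  a <- tally_outcomes(simulate_colony_assay(
    sectored_outcome_probs(co = 0.5), 50, 1, seed = 12))
  expect_error(compare_strains(a, a),
               class = "curtainr_insufficient_replicates")
})
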