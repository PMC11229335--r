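#' Simulate red/white colony-assay records
#'
#' Generates colony phenotype records for the diploid red/white reporter
#' assay: after an induced double-strand break, each sister chromatid is
#' repaired by long- or short-tract gene conversion, yielding white, red or
#' red/white sectored colonies; hygromycin and nourseothricin markers on the
#' homologous chromosomes report the exchange outcome, and growth on
#' -Ura/-Met medium checks chromosome segregation. Phenotypes are generated
#' so that the decision tree in [classify_colony()] maps each record back to
#' its generating outcome.
#'
#' Break-induced replication is only inferable from sectored colonies (a
#' solid colony's marker pattern after BIR is indistinguishable from NCO),
#' so BIR probability mass on solid or white classes is rejected.
#'
#' @param outcome_probs A data frame with columns `outcome` (one of `"NCO"`,
#'   `"CO"`, `"BIR"`, `"chromosome_loss"`), `colony_class` (`"sectored"`,
#'   `"solid_red"`, `"white"`) and `prob`, summing to 1.
#' @param n_colonies Colonies per replicate.
#' @param n_replicates Number of independent replicates; replicate labels
#'   are assigned round-robin.
#' @param seed Optional integer seed.
#' @param strain Strain label stored on each record.
#' @returns A tibble with one row per colony: `replicate_id`, `strain`,
#'   `colony_id`, `color`, sector marker flags (`red_hyg`, `red_nat`,
#'   `white_hyg`, `white_nat`; `NA` unless sectored), whole-colony flags
#'   (`hyg`, `nat`; `NA` when sectored), `ura_met_ok` and
#'   `generating_outcome`.
#' @examples
#' pr <- sectored_outcome_probs(co = 0.504)
#' simulate_colony_assay(pr, n_colonies = 20, n_replicates = 2, seed = 1)
#' @export
simulate_colony_assay <- function(outcome_probs, n_colonies, n_replicates,
                                  seed = NULL, strain = "WT") {
  stopifnot(is.data.frame(outcome_probs),
            all(c("outcome", "colony_class", "prob") %in% names(outcome_probs)))
  check_scalar(n_colonies, "n_colonies", lower = 1)
  check_scalar(n_replicates, "n_replicates", lower = 1)
  if (!all(outcome_probs$outcome %in% c("NCO", "CO", "BIR", "chromosome_loss"))) {
    abort("Unknown outcome label in `outcome_probs`.",
          class = "curtainr_invalid_parameter")
  }
  if (!all(outcome_probs$colony_class %in% c("sectored", "solid_red", "white"))) {
    abort("Unknown colony class in `outcome_probs`.",
          class = "curtainr_invalid_parameter")
  }
  check_prob_vector(outcome_probs$prob, "outcome_probs$prob", tol = 1e-6)
  bad_bir <- outcome_probs$outcome == "BIR" &
    outcome_probs$colony_class != "sectored" & outcome_probs$prob > 0
  if (any(bad_bir)) {
    abort("BIR is only inferable from sectored colonies.",
          class = "curtainr_invalid_parameter")
  }
  set_seed_if(seed)

  n_total <- as.integer(n_colonies) * as.integer(n_replicates)
  pick <- sample.int(nrow(outcome_probs), n_total, replace = TRUE,
                     prob = outcome_probs$prob)
  rows <- lapply(seq_len(n_total), function(i) {
    make_colony(outcome_probs$outcome[pick[i]],
                outcome_probs$colony_class[pick[i]])
  })
  out <- bind_rows(rows)
  out$replicate_id <- rep_len(seq_len(n_replicates), n_total)
  out$strain <- strain
  out$colony_id <- sprintf("c%05d", seq_len(n_total))
  out[, c("replicate_id", "strain", "colony_id", "color",
          "red_hyg", "red_nat", "white_hyg", "white_nat",
          "hyg", "nat", "ura_met_ok", "generating_outcome")]
}

# One colony's phenotype, chosen so the classifier inverts it exactly.
make_colony <- function(outcome, colony_class) {
  color <- switch(colony_class, sectored = "sectored",
                  solid_red = "red", white = "white")
  swap <- runif(1) < 0.5  # which antibiotic ends up where is arbitrary
  r <- c(NA, NA); w <- c(NA, NA); whole <- c(NA, NA)
  ura_ok <- TRUE
  if (outcome == "chromosome_loss") {
    ura_ok <- FALSE
    if (color == "sectored") {
      r <- c(TRUE, FALSE); w <- c(TRUE, FALSE)
    } else {
      whole <- c(TRUE, FALSE)
    }
  } else if (color == "sectored") {
    if (outcome == "CO") {
      # reciprocal exchange: sectors homozygous for opposite markers
      r <- if (swap) c(TRUE, FALSE) else c(FALSE, TRUE)
      w <- !r
    } else if (outcome == "NCO") {
      r <- c(TRUE, TRUE); w <- c(TRUE, TRUE)
    } else if (outcome == "BIR") {
      r <- c(TRUE, TRUE)
      w <- if (swap) c(TRUE, FALSE) else c(FALSE, TRUE)
    }
  } else {
    if (outcome == "NCO") {
      whole <- c(TRUE, TRUE)
    } else if (outcome == "CO") {
      whole <- if (swap) c(TRUE, FALSE) else c(FALSE, TRUE)
    }
  }
  tibble(color = color,
         red_hyg = r[1], red_nat = r[2],
         white_hyg = w[1], white_nat = w[2],
         hyg = whole[1], nat = whole[2],
         ura_met_ok = ura_ok,
         generating_outcome = outcome)
}

#' Convenience outcome probabilities for a sectored-only assay
#'
#' @param co,bir,chromosome_loss Sectored-colony probabilities of crossover,
#'   break-induced replication and chromosome loss; the remainder is
#'   non-crossover.
#' @returns An `outcome_probs` data frame for [simulate_colony_assay()].
#' @examples
#' sectored_outcome_probs(co = 0.504)
#' @export
sectored_outcome_probs <- function(co, bir = 0, chromosome_loss = 0) {
  nco <- 1 - co - bir - chromosome_loss
  if (nco < 0) {
    abort("Probabilities exceed 1.", class = "curtainr_invalid_parameter")
  }
  tibble(outcome = c("CO", "NCO", "BIR", "chromosome_loss"),
         colony_class = "sectored",
         prob = c(co, nco, bir, chromosome_loss))
}

#' Classify colonies into recombination outcomes
#'
#' Applies the marker decision tree to each record:
#' 1. failure of the -Ura/-Met segregation control means chromosome loss,
#'    taking precedence over marker logic;
#' 2. a sectored colony whose two sectors are each resistant to exactly one,
#'    different, antibiotic is a crossover (the markers switched
#'    chromosomes);
#' 3. a sectored colony whose red sector resists both antibiotics while the
#'    white sector resists only one is break-induced replication (a
#'    long-tract copy duplicated a marker);
#' 4. unchanged marker segregation (resistant to both) is a non-crossover;
#'    unsectored colonies are classified by the same marker logic on their
#'    single phenotype (both markers: NCO; exactly one: CO).
#' Any other pattern is labelled `"unclassifiable"` and counted rather than
#' dropped.
#'
#' @param records Colony records ([simulate_colony_assay()] output, or a
#'   data frame with the same phenotype columns).
#' @returns `records` with an `outcome` column added.
#' @examples
#' rec <- simulate_colony_assay(sectored_outcome_probs(co = 0.5), 10, 1, seed = 1)
#' classify_colony(rec)$outcome
#' @export
classify_colony <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("color", "red_hyg", "red_nat", "white_hyg", "white_nat",
              "hyg", "nat", "ura_met_ok")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing phenotype columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "curtainr_invalid_input")
  }
  one <- function(i) {
    if (!isTRUE(records$ura_met_ok[i])) return("chromosome_loss")
    if (records$color[i] == "sectored") {
      r <- c(records$red_hyg[i], records$red_nat[i])
      w <- c(records$white_hyg[i], records$white_nat[i])
      if (any(is.na(r)) || any(is.na(w))) return("unclassifiable")
      if (sum(r) == 1 && sum(w) == 1 && !identical(r, w)) return("CO")
      if (all(r) && all(w)) return("NCO")
      if (all(r) && sum(w) == 1) return("BIR")
      return("unclassifiable")
    }
    ph <- c(records$hyg[i], records$nat[i])
    if (any(is.na(ph))) return("unclassifiable")
    if (all(ph)) return("NCO")
    if (sum(ph) == 1) return("CO")
    "unclassifiable"
  }
  mutate(records, outcome = vapply(seq_len(nrow(records)), one, character(1)))
}

#' Per-replicate outcome fractions and across-replicate summaries
#'
#' Computes, within the chosen colony population, each replicate's outcome
#' counts and fractions (over the four classifiable outcomes), and the mean
#' and unbiased standard deviation of the fractions across replicates.
#' Replicates with no colonies in the population are excluded with a
#' warning; unclassifiable colonies are reported in `n_unclassifiable` and
#' excluded from the fractions.
#'
#' @param records Classified colony records (an `outcome` column is added
#'   via [classify_colony()] if absent).
#' @param population `"sectored"` (sectored colonies only), `"solid_red"`
#'   (solid red colonies), or `"total"` (all colonies).
#' @returns An object of class `outcome_tally`: a list with `by_replicate`
#'   and `summary` tibbles, the population, replicate count and
#'   unclassifiable count. [tidy()] returns the summary; [glance()] the
#'   one-row overview.
#' @examples
#' rec <- simulate_colony_assay(sectored_outcome_probs(co = 0.5), 200, 3, seed = 1)
#' tidy(tally_outcomes(rec))
#' @export
tally_outcomes <- function(records,
                           population = c("sectored", "solid_red", "total")) {
  population <- match.arg(population)
  stopifnot(is.data.frame(records))
  if (!"outcome" %in% names(records)) records <- classify_colony(records)
  if (nrow(records) == 0) {
    abort("No colony records.", class = "curtainr_invalid_parameter")
  }
  sel <- switch(population,
                sectored = records$color == "sectored",
                solid_red = records$color == "red",
                total = rep(TRUE, nrow(records)))
  pop <- records[sel, , drop = FALSE]
  all_reps <- sort(unique(records$replicate_id))
  have <- sort(unique(pop$replicate_id[pop$outcome != "unclassifiable"]))
  dropped <- setdiff(all_reps, have)
  if (length(dropped) > 0) {
    warn(sprintf("Replicate(s) %s have no classifiable colonies in population '%s'; excluded.",
                 paste(dropped, collapse = ", "), population))
  }
  n_unclass <- sum(pop$outcome == "unclassifiable")
  pop <- pop[pop$outcome != "unclassifiable", , drop = FALSE]

  cats <- c("CO", "NCO", "BIR", "chromosome_loss")
  by_rep <- pop |>
    count(.data$replicate_id, .data$outcome, name = "n") |>
    tidyr::complete(replicate_id = have,
                    outcome = cats, fill = list(n = 0L)) |>
    group_by(.data$replicate_id) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup() |>
    mutate(outcome = factor(.data$outcome, levels = cats)) |>
    arrange(.data$replicate_id, .data$outcome)

  summ <- by_rep |>
    group_by(.data$outcome) |>
    summarise(mean_fraction = mean(.data$fraction),
              sd_fraction = if (length(have) > 1) sd(.data$fraction) else NA_real_,
              .groups = "drop") |>
    mutate(mean_pct = 100 * .data$mean_fraction,
           sd_pct = 100 * .data$sd_fraction)

  structure(list(by_replicate = by_rep, summary = summ,
                 population = population,
                 n_replicates = length(have),
                 n_colonies = nrow(pop),
                 n_unclassifiable = n_unclass),
            class = "outcome_tally")
}

#' @export
print.outcome_tally <- function(x, ...) {
  cat("<outcome_tally> population =", x$population,
      " replicates =", x$n_replicates,
      " colonies =", x$n_colonies, "\n")
  print(x$summary)
  invisible(x)
}

#' Compare an outcome category between two strains
#'
#' Two-sided test on the per-replicate outcome fractions of two tallies.
#' The default is Welch's t-test (robust to unequal replicate variance); a
#' label-permutation test on the difference in means is available as an
#' assumption-free alternative.
#'
#' @param tally_a,tally_b [tally_outcomes()] objects with >= 2 replicates
#'   each.
#' @param category Outcome category to compare.
#' @param method `"welch"` or `"permutation"`.
#' @param n_perm Permutations for the permutation test.
#' @param seed Optional seed for the permutation draw.
#' @returns A one-row tibble: per-strain means, `statistic` (t or observed
#'   mean difference), `df` (Welch only) and `p_value`.
#' @examples
#' a <- tally_outcomes(simulate_colony_assay(sectored_outcome_probs(0.5), 200, 3, seed = 1))
#' b <- tally_outcomes(simulate_colony_assay(sectored_outcome_probs(0.61), 200, 3, seed = 2))
#' compare_strains(a, b)
#' @export
compare_strains <- function(tally_a, tally_b, category = "CO",
                            method = c("welch", "permutation"),
                            n_perm = 10000, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(tally_a, "outcome_tally"), inherits(tally_b, "outcome_tally"))
  fa <- rep_fractions(tally_a, category)
  fb <- rep_fractions(tally_b, category)
  if (length(fa) < 2 || length(fb) < 2) {
    abort("Both tallies need at least two replicates.",
          class = "curtainr_insufficient_replicates")
  }
  if (method == "welch") {
    if (sd(fa) == 0 && sd(fb) == 0) {
      same <- isTRUE(all.equal(mean(fa), mean(fb)))
      return(tibble(method = "welch", mean_a = mean(fa), mean_b = mean(fb),
                    statistic = if (same) 0 else Inf, df = NA_real_,
                    p_value = if (same) 1 else 0))
    }
    tt <- t.test(fa, fb)
    tibble(method = "welch", mean_a = mean(fa), mean_b = mean(fb),
           statistic = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value)
  } else {
    set_seed_if(seed)
    obs <- mean(fa) - mean(fb)
    pooled <- c(fa, fb)
    na <- length(fa)
    diffs <- map_dbl(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), na)
      mean(pooled[idx]) - mean(pooled[-idx])
    })
    p <- (1 + sum(abs(diffs) >= abs(obs) - 1e-12)) / (n_perm + 1)
    tibble(method = "permutation", mean_a = mean(fa), mean_b = mean(fb),
           statistic = obs, df = NA_real_, p_value = p)
  }
}

rep_fractions <- function(tally, category) {
  br <- tally$by_replicate
  br$fraction[br$outcome == category]
}
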