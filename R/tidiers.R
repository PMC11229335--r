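#' Tidy a mixture fit into its component table
#'
#' @param x A `mixture_fit` from [fit_mixture()] or [select_model()].
#' @param ... Unused.
#' @returns A tibble with one row per component: `component`, `mean`, `sd`,
#'   `weight`.
#' @examples
#' tidy(fit_mixture(rnorm(100, 5), k = 1))
#' @export
tidy.mixture_fit <- function(x, ...) {
  mutate(x$components, component = row_number(), .before = 1)
}

#' One-row summary of a mixture fit
#'
#' @inheritParams tidy.mixture_fit
#' @returns A one-row tibble: `model`, `k`, `loglik`, `bic`, `n`,
#'   `converged`.
#' @examples
#' glance(fit_mixture(rnorm(100, 5), k = 1))
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(model = x$model, k = nrow(x$components), loglik = x$loglik,
         bic = x$bic, n = x$n, converged = x$converged)
}

#' Tidy an outcome tally into its across-replicate summary
#'
#' @param x An `outcome_tally` from [tally_outcomes()].
#' @param ... Unused.
#' @returns The summary tibble (mean and sd of each outcome fraction).
#' @export
tidy.outcome_tally <- function(x, ...) {
  x$summary
}

#' One-row overview of an outcome tally
#'
#' @inheritParams tidy.outcome_tally
#' @returns A one-row tibble: `population`, `n_replicates`, `n_colonies`,
#'   `n_unclassifiable`.
#' @export
glance.outcome_tally <- function(x, ...) {
  tibble(population = x$population, n_replicates = x$n_replicates,
         n_colonies = x$n_colonies, n_unclassifiable = x$n_unclassifiable)
}
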