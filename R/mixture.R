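#' Fit a Gaussian mixture (or single Gaussian) by maximum likelihood
#'
#' Fits a `k`-component univariate Gaussian mixture by
#' expectation-maximisation with multiple restarts: the first initialisation
#' splits the sample at quantiles, the remainder use randomly chosen data
#' points as component means. Component standard deviations are floored at
#' `1e-6` times the sample SD to prevent collapse onto single points.
#' Components are reported in increasing order of mean.
#'
#' @param samples Numeric vector of observations (finite).
#' @param k Number of components (1-3 supported in practice, any `k >= 1`
#'   with `length(samples) >= 5 * k` accepted).
#' @param seed Optional integer seed controlling the random restarts; fixed
#'   seeds give deterministic fits.
#' @param n_init Number of EM restarts.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @returns An object of class `mixture_fit` with the model name, a
#'   component table (mean, sd, weight), log-likelihood, BIC, sample size,
#'   convergence flag, and the sample itself (for plotting).
#' @examples
#' x <- c(rnorm(200, 114, 73), rnorm(200, 394, 183))
#' fit <- fit_mixture(x, k = 2, seed = 1)
#' tidy(fit)
#' @export
fit_mixture <- function(samples, k, seed = NULL, n_init = 10,
                        max_iter = 1000, tol = 1e-8) {
  if (!is.numeric(samples) || any(!is.finite(samples))) {
    abort("`samples` must be finite numeric values.",
          class = "curtainr_invalid_parameter")
  }
  check_scalar(k, "k", lower = 1)
  k <- as.integer(k)
  n <- length(samples)
  if (n < 5L * k) {
    abort(sprintf("Need at least %d samples to fit %d component(s).", 5L * k, k),
          class = "curtainr_invalid_parameter")
  }
  set_seed_if(seed)
  x <- as.numeric(samples)
  s_all <- sd(x)
  sd_floor <- max(1e-6 * s_all, .Machine$double.eps)

  if (k == 1L) {
    mu <- mean(x)
    sig <- max(sqrt(mean((x - mu)^2)), sd_floor)
    ll <- sum(dnorm(x, mu, sig, log = TRUE))
    return(new_mixture_fit("gaussian", tibble(mean = mu, sd = sig, weight = 1),
                           ll, n_params = 2L, n = n, converged = TRUE,
                           iterations = 0L, data = x))
  }

  best <- NULL
  for (init in seq_len(n_init)) {
    if (init == 1L) {
      qs <- quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k), names = FALSE)
      mu <- qs
    } else {
      mu <- sort(x[sample.int(n, k)])
    }
    sig <- rep(max(s_all / k, sd_floor), k)
    w <- rep(1 / k, k)
    fit <- em_run(x, mu, sig, w, sd_floor, max_iter, tol)
    # a component collapsed onto a handful of duplicated values is a
    # degenerate likelihood spike, not a population; prefer proper optima
    if (fit$degenerate && !(is.null(best) || best$degenerate)) next
    better <- is.null(best) || fit$ll > best$ll ||
      (best$degenerate && !fit$degenerate)
    if (better) best <- fit
  }

  ord <- order(best$mu)
  comp <- tibble(mean = best$mu[ord], sd = best$sig[ord], weight = best$w[ord])
  new_mixture_fit(paste0("gauss", k), comp, best$ll, n_params = 3L * k - 1L,
                  n = n, converged = best$converged,
                  iterations = best$iterations, data = x)
}

em_run <- function(x, mu, sig, w, sd_floor, max_iter, tol) {
  n <- length(x)
  k <- length(mu)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * dnorm(x, mu[j], sig[j]),
                   numeric(n))
    rowsum_d <- pmax(rowSums(dens), .Machine$double.xmin)
    resp <- dens / rowsum_d
    ll <- sum(log(rowsum_d))
    nk <- colSums(resp)
    nk <- pmax(nk, .Machine$double.xmin)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sig <- sqrt(colSums(resp * sweep(matrix(x, n, k), 2, mu, "-")^2) / nk)
    sig <- pmax(sig, sd_floor)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  degenerate <- any(nk < 2) || any(sig <= 1.05 * sd_floor)
  list(mu = mu, sig = sig, w = w, ll = ll_old, converged = converged,
       iterations = iter, degenerate = degenerate)
}

new_mixture_fit <- function(model, components, loglik, n_params, n,
                            converged, iterations, data) {
  structure(list(
    model = model,
    components = components,
    loglik = loglik,
    n_params = n_params,
    bic = -2 * loglik + n_params * log(n),
    n = n,
    converged = converged,
    iterations = iterations,
    data = data
  ), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit> model =", x$model, " n =", x$n,
      " logLik =", format(x$loglik, digits = 6),
      " BIC =", format(x$bic, digits = 6),
      if (!x$converged) " (not converged)" else "", "\n")
  print(x$components)
  invisible(x)
}

fit_lognormal <- function(samples) {
  if (any(samples <= 0)) {
    abort("Lognormal fit requires strictly positive samples.",
          class = "curtainr_invalid_parameter")
  }
  lx <- log(samples)
  mu <- mean(lx)
  sig <- sqrt(mean((lx - mu)^2))
  sig <- max(sig, .Machine$double.eps)
  ll <- sum(dlnorm(samples, mu, sig, log = TRUE))
  new_mixture_fit("lognormal",
                  tibble(mean = exp(mu + sig^2 / 2),
                         sd = sqrt((exp(sig^2) - 1) * exp(2 * mu + sig^2)),
                         weight = 1),
                  ll, n_params = 2L, n = length(samples), converged = TRUE,
                  iterations = 0L, data = as.numeric(samples))
}

#' Select the best-fitting population model
#'
#' Fits each candidate model (single Gaussian, lognormal, sum of two or
#' three Gaussians) and returns the fit with the lowest Bayesian information
#' criterion; ties are broken toward the model with fewer parameters. The
#' lognormal candidate is skipped (with a message) when the sample contains
#' non-positive values.
#'
#' @inheritParams fit_mixture
#' @param candidates Model names among `"gaussian"`, `"lognormal"`,
#'   `"gauss2"`, `"gauss3"`.
#' @returns The winning `mixture_fit`, with the comparison table attached as
#'   attribute `"selection"`.
#' @examples
#' x <- rnorm(500, 100, 10)
#' sel <- select_model(x, seed = 1)
#' sel$model
#' @export
select_model <- function(samples,
                         candidates = c("gaussian", "lognormal", "gauss2", "gauss3"),
                         seed = NULL, n_init = 10) {
  candidates <- match.arg(candidates, several.ok = TRUE)
  if (length(candidates) == 0) {
    abort("`candidates` must be non-empty.", class = "curtainr_invalid_parameter")
  }
  set_seed_if(seed)
  fits <- list()
  for (cand in candidates) {
    fit <- switch(cand,
      gaussian = fit_mixture(samples, 1L),
      lognormal = {
        if (any(samples <= 0)) {
          inform("Skipping lognormal candidate: sample contains non-positive values.")
          NULL
        } else {
          fit_lognormal(samples)
        }
      },
      gauss2 = fit_mixture(samples, 2L, n_init = n_init),
      gauss3 = fit_mixture(samples, 3L, n_init = n_init)
    )
    if (!is.null(fit)) fits[[cand]] <- fit
  }
  if (length(fits) == 0) {
    abort("No candidate model could be fitted.", class = "curtainr_invalid_parameter")
  }
  tab <- tibble(
    model = names(fits),
    n_params = map_int(fits, "n_params"),
    loglik = map_dbl(fits, "loglik"),
    bic = map_dbl(fits, "bic")
  ) |> arrange(.data$bic, .data$n_params)
  best <- fits[[tab$model[1]]]
  attr(best, "selection") <- tab
  best
}

#' Summary statistics of a population sample
#'
#' @param samples Numeric vector with at least one finite value.
#' @returns A one-row tibble with `n`, `mean`, `sd` (unbiased; `NA` for a
#'   single observation), `se`, and `median` (midpoint rule for even `n`).
#' @examples
#' population_summary(c(1, 2, 3))
#' @export
population_summary <- function(samples) {
  if (length(samples) < 1 || any(!is.finite(samples))) {
    abort("`samples` must contain at least one finite value.",
          class = "curtainr_invalid_parameter")
  }
  n <- length(samples)
  s <- if (n > 1) sd(samples) else NA_real_
  tibble(n = n, mean = mean(samples), sd = s,
         se = if (n > 1) s / sqrt(n) else NA_real_,
         median = median(samples))
}
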