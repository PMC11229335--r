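# Internal helpers shared across modules.

# Validate a single finite numeric scalar.
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    abort(sprintf("`%s` must be supplied.", name), class = "curtainr_invalid_parameter")
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "curtainr_invalid_parameter")
  }
  low_ok <- if (strict_lower) x > lower else x >= lower
  if (!low_ok || x > upper) {
    abort(sprintf("`%s` = %g is outside its allowed range.", name, x),
          class = "curtainr_invalid_parameter")
  }
  invisible(x)
}

check_prob_vector <- function(p, name, tol = 1e-6) {
  if (!is.numeric(p) || length(p) < 1L || any(!is.finite(p)) || any(p < 0)) {
    abort(sprintf("`%s` must be non-negative finite probabilities.", name),
          class = "curtainr_invalid_parameter")
  }
  if (abs(sum(p) - 1) > tol) {
    abort(sprintf("`%s` must sum to 1 (got %.6f).", name, sum(p)),
          class = "curtainr_invalid_parameter")
  }
  invisible(p)
}

# Draw from a normal truncated below at `lower`; sd = 0 collapses to the mean.
rtnorm <- function(n, mean, sd, lower = 0) {
  if (sd <= 0) return(rep(mean, n))
  p_low <- pnorm(lower, mean, sd)
  if (p_low >= 1) {
    abort("Truncated-normal draw has no mass above the truncation point.",
          class = "curtainr_invalid_parameter")
  }
  qnorm(runif(n, p_low, 1), mean, sd)
}

# Mean and sd of a normal truncated below at `lower`.
tnorm_moments <- function(mu, sigma, lower = 0) {
  a <- (lower - mu) / sigma
  # Mills ratio on the log scale; stable far into the tail
  lam <- exp(dnorm(a, log = TRUE) -
               pnorm(a, lower.tail = FALSE, log.p = TRUE))
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + a * lam - lam^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

#' Solve for truncated-normal parameters matching target moments
#'
#' Finds the parameters `(mu, sigma)` of a normal distribution truncated below
#' at zero whose truncated mean equals `mean` and whose truncated standard
#' deviation is as close as possible to `sd`. Useful for simulating velocity
#' or distance populations reported as sample `mean +/- sd` on a non-negative
#' scale. A zero-truncated normal cannot exceed a coefficient of variation of
#' 1; when `sd/mean >= 1` the mean is matched exactly and the closest
#' attainable sd is used.
#'
#' @param mean,sd Target mean and standard deviation of the truncated draw.
#' @param lower Truncation point (default 0).
#' @returns A list with elements `mu`, `sigma` (untruncated parameters) and
#'   `achieved_mean`, `achieved_sd` (moments of the truncated distribution).
#' @examples
#' p <- truncnorm_match(65, 67)
#' p$achieved_mean
#' @export
truncnorm_match <- function(mean, sd, lower = 0) {
  check_scalar(mean, "mean", lower = lower, strict_lower = TRUE)
  check_scalar(sd, "sd", lower = 0, strict_lower = TRUE)
  if (lower != 0) {
    shifted <- truncnorm_match(mean - lower, sd, lower = 0)
    mom <- tnorm_moments(shifted$mu + lower, shifted$sigma, lower = lower)
    return(list(mu = shifted$mu + lower, sigma = shifted$sigma,
                achieved_mean = mom[["mean"]], achieved_sd = mom[["sd"]]))
  }
  # Parameterise by the standardised truncation point a = -mu/sigma: the CV
  # of the truncated distribution depends on a alone and increases in a, so
  # a is solved from the target CV and sigma then rescales the mean.
  mills <- function(a) {
    exp(dnorm(a, log = TRUE) - pnorm(a, lower.tail = FALSE, log.p = TRUE))
  }
  cv_of_a <- function(a) {
    lam <- mills(a)
    sqrt(pmax(1 + a * lam - lam^2, 0)) / (lam - a)
  }
  target_cv <- sd / mean  # mean here is the distance above the truncation
  a_lim <- c(-8, 5)  # pnorm() stays resolvable; a = 5 is CV ~ 1 already
  a <- if (target_cv <= cv_of_a(a_lim[1])) {
    a_lim[1]
  } else if (target_cv >= cv_of_a(a_lim[2])) {
    a_lim[2]
  } else {
    uniroot(function(a) cv_of_a(a) - target_cv,
            lower = a_lim[1], upper = a_lim[2], tol = 1e-12)$root
  }
  sigma <- mean / (mills(a) - a)
  mu <- -a * sigma
  mom <- tnorm_moments(mu, sigma)
  list(mu = mu, sigma = sigma,
       achieved_mean = mom[["mean"]], achieved_sd = mom[["sd"]])
}

# Maximal runs of identical values; returns start index, length, value.
value_runs <- function(x) {
  r <- rle(x)
  len <- r$lengths
  tibble(start = cumsum(c(1L, len[-length(len)])), length = len, value = r$values)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    check_scalar(seed, "seed")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
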