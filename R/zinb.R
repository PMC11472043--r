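#' Zero-inflated negative binomial count machinery
#'
#' The observation model for off-target cleavage read counts is a mixture of
#' a point mass at zero (weight `pi`, the technical-zero component) and a
#' negative binomial with mean `mu` and dispersion `theta`:
#'
#'   ZINB(k; pi, mu, theta) = pi * d0(k) + (1 - pi) * NB(k; mu, theta)
#'
#' with NB(k; mu, theta) = Gamma(k + theta) / (Gamma(theta) k!) *
#' (mu / (mu + theta))^k * (theta / (mu + theta))^theta. All pmfs here are
#' computed in log space via `lgamma`. Ablation heads (zero-inflated
#' Poisson, plain negative binomial, Poisson) share the same conventions.
#'
#' @name zinb-distributions
NULL

check_zinb_params <- function(pi, mu, theta) {
  if (any(!is.finite(pi)) || any(pi < 0) || any(pi > 1))
    stop("'pi' must be in [0, 1]")
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("'mu' must be positive and finite")
  if (any(!is.finite(theta)) || any(theta <= 0)) stop("'theta' must be positive and finite")
  invisible(NULL)
}

#' Negative binomial log-pmf (mean/dispersion parameterization)
#'
#' @param k Nonnegative integer counts (vectorized).
#' @param mu Positive NB mean.
#' @param theta Positive NB dispersion (variance is `mu + mu^2/theta`).
#' @return Log probabilities, same length as the longest argument.
#' @examples
#' nb_log_pmf(0, 1, 1)  # log(0.5)
#' @export
nb_log_pmf <- function(k, mu, theta) {
  k <- check_counts(k)
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("'mu' must be positive and finite")
  if (any(!is.finite(theta)) || any(theta <= 0)) stop("'theta' must be positive and finite")
  lgamma(k + theta) - lgamma(theta) - lgamma(k + 1) +
    k * (log(mu) - log(mu + theta)) +
    theta * (log(theta) - log(mu + theta))
}

#' Zero-inflated negative binomial log-pmf
#'
#' At `k = 0` the zero atom and the NB zero mass are combined with a
#' log-sum-exp for numerical stability; at `k > 0` the result is
#' `log(1 - pi) + nb_log_pmf(k, mu, theta)`.
#'
#' @inheritParams nb_log_pmf
#' @param pi Zero-inflation mixture weight in `[0, 1]`.
#' @export
zinb_log_pmf <- function(k, pi, mu, theta) {
  k <- check_counts(k)
  check_zinb_params(pi, mu, theta)
  n <- max(length(k), length(pi), length(mu), length(theta))
  k <- rep_len(k, n); pi <- rep_len(pi, n)
  mu <- rep_len(mu, n); theta <- rep_len(theta, n)
  out <- log1p(-pi) + nb_log_pmf(k, mu, theta)
  z <- k == 0
  if (any(z)) {
    nb0 <- theta[z] * (log(theta[z]) - log(mu[z] + theta[z]))
    out[z] <- logspace_add(log(pi[z]), log1p(-pi[z]) + nb0)
  }
  out
}

#' Zero-inflated Poisson log-pmf
#' @inheritParams zinb_log_pmf
#' @param lambda Positive Poisson mean.
#' @export
zip_log_pmf <- function(k, pi, lambda) {
  k <- check_counts(k)
  if (any(!is.finite(pi)) || any(pi < 0) || any(pi > 1)) stop("'pi' must be in [0, 1]")
  if (any(!is.finite(lambda)) || any(lambda <= 0)) stop("'lambda' must be positive and finite")
  n <- max(length(k), length(pi), length(lambda))
  k <- rep_len(k, n); pi <- rep_len(pi, n); lambda <- rep_len(lambda, n)
  out <- log1p(-pi) + poisson_log_pmf(k, lambda)
  z <- k == 0
  if (any(z)) out[z] <- logspace_add(log(pi[z]), log1p(-pi[z]) - lambda[z])
  out
}

#' Poisson log-pmf
#' @inheritParams zip_log_pmf
#' @export
poisson_log_pmf <- function(k, lambda) {
  k <- check_counts(k)
  if (any(!is.finite(lambda)) || any(lambda <= 0)) stop("'lambda' must be positive and finite")
  k * log(lambda) - lambda - lgamma(k + 1)
}

#' Log-pmf for any model head
#'
#' @param head One of `"zinb"`, `"zip"`, `"nb"`, `"poisson"`.
#' @param k Nonnegative integer counts.
#' @param params Data frame (or list) of per-observation parameters with the
#'   columns the head requires: `pi, mu, theta` (zinb), `pi, lambda` (zip),
#'   `mu, theta` (nb), `lambda` (poisson).
#' @export
head_log_pmf <- function(head, k, params) {
  switch(match.arg(head, c("zinb", "zip", "nb", "poisson")),
    zinb = zinb_log_pmf(k, params$pi, params$mu, params$theta),
    zip = zip_log_pmf(k, params$pi, params$lambda),
    nb = nb_log_pmf(k, params$mu, params$theta),
    poisson = poisson_log_pmf(k, params$lambda)
  )
}

#' Negative log-likelihood of a ZINB parameter batch
#'
#' `-sum_i log ZINB(y_i; pi_i, mu_i, theta_i)`, the training loss of the
#' zero-inflated head.
#'
#' @param pi,mu,theta Parameter vectors (length 1 or `length(y)`).
#' @param y Observed counts.
#' @export
zinb_nll <- function(pi, mu, theta, y) {
  if (length(y) == 0L) stop("empty observation batch")
  for (p in list(pi, mu, theta))
    if (!(length(p) %in% c(1L, length(y))))
      stop("parameter/observation length mismatch")
  -sum(zinb_log_pmf(y, pi, mu, theta))
}

#' Negative log-likelihood under any head
#' @inheritParams head_log_pmf
#' @param y Observed counts.
#' @export
head_nll <- function(head, params, y) {
  if (length(y) == 0L) stop("empty observation batch")
  -sum(head_log_pmf(head, y, params))
}

#' Closed-form ZINB moments
#'
#' Mean `(1 - pi) mu`, variance `(1 - pi) mu (1 + mu/theta + pi mu)` and
#' coefficient of variation `sd/mean` (`Inf` when the mean is 0).
#'
#' @inheritParams zinb_nll
#' @return List with vectors `mean`, `variance`, `cv`.
#' @export
zinb_moments <- function(pi, mu, theta) {
  check_zinb_params(pi, mu, theta)
  m <- (1 - pi) * mu
  v <- (1 - pi) * mu * (1 + mu / theta + pi * mu)
  cv <- ifelse(m > 0, sqrt(v) / m, Inf)
  list(mean = m, variance = v, cv = cv)
}

#' Sample from a ZINB distribution
#'
#' With probability `pi` emits 0, otherwise draws from the negative binomial
#' via its gamma-Poisson mixture representation.
#'
#' @inheritParams zinb_nll
#' @param n Number of draws.
#' @param seed Optional integer seed (draws are reproducible given the seed
#'   and leave the caller's RNG untouched).
#' @export
zinb_sample <- function(n, pi, mu, theta, seed = NULL) {
  check_zinb_params(pi, mu, theta)
  if (n < 1) stop("'n' must be >= 1")
  with_seed(seed, {
    zero <- stats::runif(n) < pi
    lam <- stats::rgamma(n, shape = theta, rate = theta / mu)
    draws <- stats::rpois(n, lam)
    draws[zero] <- 0L
    draws
  })
}

#' Sample from any model head
#' @inheritParams head_log_pmf
#' @param n Number of draws per parameter row; if `params` has one row the
#'   result is a vector of `n` draws, otherwise an `nrow(params) x n` matrix.
#' @param seed Optional seed.
#' @export
head_sample <- function(head, params, n, seed = NULL) {
  head <- match.arg(head, c("zinb", "zip", "nb", "poisson"))
  m <- length(params[[1]])
  with_seed(seed, {
    draw1 <- function(i) {
      switch(head,
        zinb = zinb_sample(n, params$pi[i], params$mu[i], params$theta[i]),
        zip = {
          z <- stats::runif(n) < params$pi[i]
          d <- stats::rpois(n, params$lambda[i]); d[z] <- 0L; d
        },
        nb = zinb_sample(n, 0, params$mu[i], params$theta[i]),
        poisson = stats::rpois(n, params$lambda[i])
      )
    }
    if (m == 1L) draw1(1L) else t(vapply(seq_len(m), draw1, numeric(n)))
  })
}

# pmf of head over 0..K (linear scale)
head_pmf_upto <- function(head, K, params) {
  exp(head_log_pmf(head, 0:K, lapply(params, rep_len, K + 1L)))
}

# upper support bound covering at least `level` of the mass
quantile_support_bound <- function(head, params, level) {
  mom <- switch(head,
    zinb = zinb_moments(params$pi, params$mu, params$theta),
    zip = list(mean = (1 - params$pi) * params$lambda,
               variance = (1 - params$pi) * params$lambda * (1 + params$pi * params$lambda)),
    nb = zinb_moments(0, params$mu, params$theta),
    poisson = list(mean = params$lambda, variance = params$lambda)
  )
  max(20, ceiling(mom$mean + 20 * sqrt(mom$variance) + 20))
}

#' Discrete quantile of a predictive count distribution
#'
#' Right-continuous cdf inversion: the smallest `k` with `CDF(k) >= level`,
#' so that coverage of `[0, q]` is never below `level`.
#'
#' @inheritParams head_log_pmf
#' @param level Probability level in (0, 1); vectorized.
#' @param params Single-site parameter list/row.
#' @export
dist_quantile <- function(level, params, head = "zinb") {
  head <- match.arg(head, c("zinb", "zip", "nb", "poisson"))
  if (any(level <= 0 | level >= 1)) stop("'level' must be in (0, 1)")
  K <- quantile_support_bound(head, params, max(level))
  repeat {
    cdf <- cumsum(head_pmf_upto(head, K, params))
    if (cdf[K + 1L] >= max(level) || K > 1e7) break
    K <- K * 2L
  }
  vapply(level, function(p) {
    i <- which(cdf >= p - 1e-12)
    if (length(i) == 0L) K else i[1L] - 1L
  }, numeric(1))
}

# CDF at integer k (vectorized over k) for one parameter row
dist_cdf <- function(k, params, head = "zinb") {
  K <- max(0, max(k))
  cdf <- cumsum(head_pmf_upto(head, K, params))
  out <- numeric(length(k))
  neg <- k < 0
  out[!neg] <- cdf[pmin(floor(k[!neg]), K) + 1L]
  pmin(out, 1)
}
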