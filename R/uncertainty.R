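#' Per-site posterior uncertainty outputs
#'
#' A site's predictive distribution is summarized the way guide designers
#' consume it: the expected activity as point prediction, a one-sided 95%
#' credible interval whose lower bound is pinned at zero (for off-targets
#' only the upper bound matters), the coefficient of variation as a
#' scale-free uncertainty summary, and a calibration diagnostic comparing
#' nominal and observed coverage.
#'
#' @name uncertainty
NULL

#' Construct a site posterior
#'
#' @param pi,mu,theta ZINB parameters (use `pi = 0` for an NB posterior).
#' @param scale Count-to-frequency divisor: reported activity is
#'   `count / scale` (e.g. 10 000, the normalization ceiling, to express
#'   activity as a frequency in [0, 1]).
#' @export
site_posterior <- function(pi, mu, theta, scale = 1) {
  check_zinb_params(pi, mu, theta)
  if (scale <= 0) stop("'scale' must be positive")
  structure(list(pi = pi, mu = mu, theta = theta, scale = scale),
            class = "site_posterior")
}

#' Expected activity of a site posterior
#'
#' Closed-form mean `(1 - pi) * mu / scale`.
#'
#' @param post A [site_posterior()].
#' @export
point_prediction <- function(post) {
  stopifnot(inherits(post, "site_posterior"))
  (1 - post$pi) * post$mu / post$scale
}

#' One-sided credible interval for an off-target site
#'
#' The lower bound is fixed at minimum activity (0); the upper bound is the
#' `level`-quantile of the predictive distribution by right-continuous cdf
#' inversion, so coverage of `[0, ucb]` is at least `level`.
#'
#' @inheritParams point_prediction
#' @param level Credible level in (0, 1); default 0.95.
#' @return List with `lcb`, `ucb`, `level`.
#' @export
off_target_interval <- function(post, level = 0.95) {
  stopifnot(inherits(post, "site_posterior"))
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)")
  q <- dist_quantile(level, list(pi = post$pi, mu = post$mu, theta = post$theta),
                     head = "zinb")
  list(lcb = 0, ucb = q / post$scale, level = level)
}

#' Coefficient of variation of a site posterior
#'
#' `sd / mean` of the predictive distribution; scale-invariant, `Inf` when
#' the mean is zero.
#'
#' @inheritParams point_prediction
#' @export
coefficient_of_variation <- function(post) {
  stopifnot(inherits(post, "site_posterior"))
  zinb_moments(post$pi, post$mu, post$theta)$cv
}

#' Calibration curve of predictive distributions
#'
#' For well-calibrated uncertainty, N percent of observations should fall
#' inside the N percent (one-sided, lower-bound-zero) interval. Two
#' estimators of observed coverage are provided. `method = "pit"` (default)
#' uses the randomized probability integral transform
#' `u_i = F_i(y_i - 1) + V_i * p_i(y_i)`, `V_i ~ U(0, 1)`, the standard
#' calibration diagnostic for discrete count forecasts: under a perfectly
#' calibrated model the `u_i` are exactly uniform, so the curve matches the
#' identity up to sampling noise even when the distributions carry large
#' atoms (such as the zero mass). `method = "quantile"` counts
#' `y_i <= Q_i(p)` with the right-continuous quantile; it is conservative
#' on discrete support (observed coverage >= nominal by construction) and
#' over-covers at levels below a site's zero mass.
#'
#' @param params Data frame of per-site predictive parameters (columns per
#'   `head`).
#' @param y Observed counts (same length as `nrow(params)`).
#' @param grid Nominal levels; default 0.05, 0.10, ..., 0.95.
#' @param head Distribution head.
#' @param method `"pit"` or `"quantile"`.
#' @param seed Seed for the PIT randomization.
#' @return Data frame with columns `level` and `observed`.
#' @export
calibration_curve <- function(params, y, grid = seq(0.05, 0.95, by = 0.05),
                              head = "zinb", method = c("pit", "quantile"),
                              seed = 1L) {
  method <- match.arg(method)
  n <- length(y)
  if (nrow(as.data.frame(params)) != n)
    stop("length mismatch between 'params' and 'y'")
  if (any(diff(grid) <= 0) || any(grid <= 0 | grid >= 1))
    stop("'grid' must be strictly increasing within (0, 1)")
  y <- check_counts(y)
  params <- as.data.frame(params)
  if (method == "pit") {
    u <- with_seed(seed, {
      v <- stats::runif(n)
      vapply(seq_len(n), function(i) {
        pr <- as.list(params[i, , drop = FALSE])
        lp <- head_log_pmf(head, 0:y[i], lapply(pr, rep_len, y[i] + 1L))
        pm <- exp(lp)
        Flo <- if (y[i] == 0) 0 else sum(pm[seq_len(y[i])])
        min(Flo + v[i] * pm[y[i] + 1L], 1)
      }, numeric(1))
    })
    obs <- vapply(grid, function(p) mean(u <= p), numeric(1))
  } else {
    cov <- vapply(seq_len(n), function(i) {
      pr <- as.list(params[i, , drop = FALSE])
      q <- dist_quantile(grid, pr, head = head)
      as.numeric(y[i] <= q)
    }, numeric(length(grid)))
    obs <- rowMeans(cov)
  }
  data.frame(level = grid, observed = obs)
}

#' Score a site table with a trained model
#'
#' End-to-end per-site pipeline: encode the interfaces, compute normalized
#' descriptor matrices, run the model, and derive the uncertainty summary.
#'
#' @param model Trained `ot_model` (its stored `norm_stats` provide the
#'   descriptor normalization and, when present, the count scale).
#' @param sites Site table data frame.
#' @param genome Reference genome.
#' @param level Credible level for the upper bound column.
#' @return Data frame with columns `site_id`, `pi`, `mu`, `theta`, `mean`,
#'   `cv`, `ucb95`, `mismatches`, sorted as the input.
#' @export
score_sites <- function(model, sites, genome, level = 0.95) {
  stopifnot(inherits(model, "ot_model"))
  if (model$head != "zinb")
    stop("score_sites requires a zinb-head model")
  xs <- encode_pairs(sites)
  cfg <- model$norm_stats$descriptor_config %||% descriptor_config()
  cfg$norm <- model$norm_stats$descriptor_norm
  xp <- descriptor_matrices(genome, sites, cfg)
  params <- model_predict(model, xs, xp)
  scale <- model$norm_stats$count_scale %||% 1
  mom <- zinb_moments(params$pi, params$mu, params$theta)
  ucb <- vapply(seq_len(nrow(params)), function(i)
    dist_quantile(level, list(pi = params$pi[i], mu = params$mu[i],
                              theta = params$theta[i])) / scale, numeric(1))
  data.frame(site_id = sites$site_id %||% seq_len(nrow(sites)),
             pi = params$pi, mu = params$mu, theta = params$theta,
             mean = mom$mean / scale, cv = mom$cv, ucb95 = ucb,
             mismatches = mismatch_count(sites$sgrna_seq, sites$target_seq),
             stringsAsFactors = FALSE)
}
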