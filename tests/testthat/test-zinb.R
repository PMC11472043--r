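# Count-distribution machinery against independent oracles.

test_that("nb_log_pmf matches closed forms and the stats oracle", {
  expect_equal(nb_log_pmf(0, 1, 1), log(0.5), tolerance = 1e-12)
  # closed form at zero: theta * (log theta - log(mu + theta))
  for (p in list(c(2, 5), c(0.3, 0.7), c(1000, 2))) {
    expect_equal(nb_log_pmf(0, p[1], p[2]),
                 p[2] * (log(p[2]) - log(p[1] + p[2])), tolerance = 1e-12)
  }
  # explicit gamma-function evaluation at (k = 3, mu = 2, theta = 5)
  direct <- log(gamma(3 + 5) / (gamma(5) * factorial(3)) *
                (2 / 7)^3 * (5 / 7)^5)
  expect_equal(nb_log_pmf(3, 2, 5), direct, tolerance = 1e-12)
  # independent library implementation over a random grid
  set.seed(5)
  k <- rpois(100, 10)
  mu <- exp(runif(100, log(0.1), log(500)))
  th <- exp(runif(100, log(0.2), log(50)))
  expect_equal(nb_log_pmf(k, mu, th),
               dnbinom(k, size = th, mu = mu, log = TRUE), tolerance = 1e-12)
  expect_error(nb_log_pmf(2, -1, 1), "positive")
  expect_error(nb_log_pmf(-1, 1, 1), ">= 0")
})

test_that("zinb_log_pmf handles the zero atom and degenerate mixtures", {
  expect_equal(zinb_log_pmf(0, 1, 5, 2), 0, tolerance = 1e-12)
  expect_equal(zinb_log_pmf(0, 0.5, 1, 1), log(0.75), tolerance = 1e-12)
  set.seed(6)
  k <- c(0, rpois(50, 4))
  mu <- exp(runif(51, -1, 4)); th <- exp(runif(51, -1, 2))
  expect_equal(zinb_log_pmf(k, 0, mu, th), nb_log_pmf(k, mu, th),
               tolerance = 1e-12)
  pi <- runif(51, 0.05, 0.9)
  oracle <- log(pi * (k == 0) + (1 - pi) * dnbinom(k, size = th, mu = mu))
  expect_equal(zinb_log_pmf(k, pi, mu, th), oracle, tolerance = 1e-10)
})

test_that("zip and poisson log-pmfs match their closed forms", {
  expect_equal(poisson_log_pmf(0, 3.2), -3.2, tolerance = 1e-12)
  set.seed(8)
  k <- rpois(60, 3); lam <- exp(runif(60, -2, 3))
  expect_equal(poisson_log_pmf(k, lam), dpois(k, lam, log = TRUE),
               tolerance = 1e-12)
  expect_equal(zip_log_pmf(k, 0, lam), poisson_log_pmf(k, lam), tolerance = 1e-12)
  expect_equal(zip_log_pmf(2, 0.3, 1.5),
               log(0.7 * exp(-1.5) * 1.5^2 / 2), tolerance = 1e-12)
  pi <- runif(60, 0, 0.8)
  expect_equal(zip_log_pmf(k, pi, lam),
               log(pi * (k == 0) + (1 - pi) * dpois(k, lam)), tolerance = 1e-10)
})

test_that("pmfs are normalized and NB converges to Poisson for large theta", {
  grid <- expand.grid(pi = c(0, 0.3, 0.9), mu = c(0.5, 8, 300),
                      theta = c(0.3, 2, 50))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    K <- ceiling(g$mu + 40 * sqrt(g$mu + g$mu^2 / g$theta) + 100)
    s <- sum(exp(zinb_log_pmf(0:K, g$pi, g$mu, g$theta)))
    expect_lt(abs(s - 1), 1e-6)
  }
  k <- 0:60
  expect_lt(max(abs(exp(nb_log_pmf(k, 10, 1e6)) - dpois(k, 10))), 1e-4)
})

test_that("zinb_nll is additive and matches a naive loop", {
  set.seed(9)
  n <- 40
  pi <- runif(n, 0, 0.6); mu <- exp(runif(n, 0, 4)); th <- exp(runif(n, -1, 2))
  y <- zinb_sample(n, 0.3, 10, 1, seed = 2)
  loop <- -sum(vapply(seq_len(n), function(i)
    zinb_log_pmf(y[i], pi[i], mu[i], th[i]), numeric(1)))
  batch <- zinb_nll(pi, mu, th, y)
  expect_equal(batch, loop, tolerance = 1e-10)
  expect_equal(zinb_nll(pi[1], mu[1], th[1], y[1]),
               -zinb_log_pmf(y[1], pi[1], mu[1], th[1]))
  half <- zinb_nll(pi[1:20], mu[1:20], th[1:20], y[1:20]) +
    zinb_nll(pi[21:40], mu[21:40], th[21:40], y[21:40])
  expect_equal(batch, half, tolerance = 1e-10)
  expect_error(zinb_nll(pi[1:3], mu[1:3], th[1:3], y), "mismatch")
  expect_error(zinb_nll(0.1, 1, 1, numeric(0)), "empty")
})

test_that("closed-form moments match limits and Monte-Carlo", {
  m0 <- zinb_moments(0, 7, 3)
  expect_equal(m0$mean, 7)
  expect_equal(m0$variance, 7 + 49 / 3)
  m1 <- zinb_moments(1, 7, 3)
  expect_equal(m1$mean, 0)
  expect_true(is.infinite(m1$cv))
  set.seed(10)
  for (rep in 1:3) {
    pi <- runif(1, 0, 0.7); mu <- exp(runif(1, 0, 4)); th <- exp(runif(1, -1, 2))
    mom <- zinb_moments(pi, mu, th)
    d <- zinb_sample(1e5, pi, mu, th, seed = 100 + rep)
    se_mean <- sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - mom$mean), 3 * se_mean + 1e-9)
    m4 <- mean((d - mean(d))^4)
    se_var <- sqrt(max(m4 - var(d)^2, 0) / length(d))
    expect_lt(abs(var(d) - mom$variance), 3 * se_var + 1e-9)
  }
})

test_that("the sampler is seeded, respects degenerate pi, and hits the mean", {
  expect_true(all(zinb_sample(500, 1, 10, 2, seed = 1) == 0))
  expect_identical(zinb_sample(1000, 0.3, 20, 2, seed = 3),
                   zinb_sample(1000, 0.3, 20, 2, seed = 3))
  d <- zinb_sample(2e5, 0.25, 30, 2, seed = 4)
  expect_lt(abs(mean(d) - 0.75 * 30), 3 * sd(d) / sqrt(length(d)))
})

test_that("discrete quantiles invert the cdf right-continuously", {
  # pure NB: agrees with the library quantile function
  for (lv in c(0.1, 0.5, 0.9, 0.95, 0.99))
    expect_equal(dist_quantile(lv, list(pi = 0, mu = 17, theta = 2.5)),
                 qnbinom(lv, size = 2.5, mu = 17))
  p <- list(pi = 0.4, mu = 12, theta = 1.5)
  lv <- seq(0.05, 0.99, by = 0.02)
  q <- dist_quantile(lv, p)
  expect_true(all(diff(q) >= 0))       # nondecreasing in level
  cdf <- crisprZINB:::dist_cdf(q, p)
  expect_true(all(cdf >= lv - 1e-12))  # coverage never below nominal
  # levels below the zero atom give quantile 0
  expect_equal(dist_quantile(0.3, list(pi = 0.5, mu = 50, theta = 2)), 0)
  expect_error(dist_quantile(1.2, p), "in \\(0, 1\\)")
})

test_that("head_sample and head_log_pmf stay consistent across heads", {
  params <- list(zinb = list(pi = 0.3, mu = 8, theta = 2),
                 zip = list(pi = 0.3, lambda = 5),
                 nb = list(mu = 8, theta = 2),
                 poisson = list(lambda = 5))
  means <- c(zinb = 0.7 * 8, zip = 0.7 * 5, nb = 8, poisson = 5)
  for (h in names(params)) {
    d <- head_sample(h, params[[h]], 5e4, seed = 12)
    expect_lt(abs(mean(d) - means[[h]]), 4 * sd(d) / sqrt(length(d)))
    lp <- head_log_pmf(h, 0:50, lapply(params[[h]], rep_len, 51))
    expect_true(all(lp <= 1e-12))
    expect_equal(predicted_mean(h, as.data.frame(params[[h]])),
                 unname(means[[h]]))
  }
})
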