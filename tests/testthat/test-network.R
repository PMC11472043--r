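# The CNN + bi-LSTM fusion regressor and its training loop.

ns <- asNamespace("crisprZINB")

tiny_cfg <- network_config(conv1_kernels = 4L, conv2_kernels = 3L,
                           lstm_hidden = 3L, fc_seq = 5L, fc_phys = 5L,
                           fc_joint = 4L, phys_kernels = 3L)

rand_inputs <- function(B, seed = 1) {
  set.seed(seed)
  list(xs = array(as.numeric(runif(B * 23 * 6) < 0.4), c(B, 23, 6)),
       xp = array(runif(B * 23 * 4), c(B, 23, 4)))
}

test_that("forward outputs live in the parameter domains and are deterministic", {
  inp <- rand_inputs(8)
  for (head in c("zinb", "zip", "nb", "poisson")) {
    net <- init_network(tiny_cfg, head, seed = 2)
    model <- structure(list(net = net, head = head), class = "ot_model")
    p1 <- model_predict(model, inp$xs, inp$xp)
    p2 <- model_predict(model, inp$xs, inp$xp)
    expect_identical(p1, p2)
    if ("pi" %in% names(p1)) expect_true(all(p1$pi >= 0 & p1$pi <= 1))
    for (cl in intersect(names(p1), c("mu", "theta", "lambda")))
      expect_true(all(p1[[cl]] > 0))
  }
})

test_that("a zero-head untrained zinb model outputs pi = 0.5, mu = 1, theta = 1", {
  net <- init_network(tiny_cfg, "zinb", seed = 3)
  model <- structure(list(net = net, head = "zinb"), class = "ot_model")
  inp <- rand_inputs(5)
  p <- model_predict(model, inp$xs, inp$xp)
  expect_equal(p$pi, rep(0.5, 5))
  expect_equal(p$mu, rep(1, 5))
  expect_equal(p$theta, rep(1, 5))
  # single-matrix interface (6 x 23 and 4 x 23)
  single <- model_predict(model, t(inp$xs[1, , ]), t(inp$xp[1, , ]))
  expect_equal(unlist(single), c(pi = 0.5, mu = 1, theta = 1))
})

test_that("analytic gradients match finite differences through the whole network", {
  inp <- rand_inputs(5, seed = 4)
  y <- c(0, 3, 10, 0, 120)
  for (head in c("zinb", "poisson")) {
    net <- init_network(tiny_cfg, head, seed = 7)
    set.seed(8)
    net$head_fc$par$W <- matrix(rnorm(length(net$head_fc$par$W), 0, 0.3),
                                nrow(net$head_fc$par$W))
    fw <- ns$net_forward(net, inp$xs, inp$xp, train = TRUE)
    lg <- ns$head_loss_grad(head, fw$raw, y)
    g <- ns$net_backward(net, fw$cache, lg$draw)
    par <- ns$net_params(net)
    loss_with <- function(ptree) {
      f <- ns$net_forward(ns$net_set_params(net, ptree), inp$xs, inp$xp, train = TRUE)
      ns$head_loss_grad(head, f$raw, y)$nll
    }
    check <- function(layer, field, sub = NULL) {
      leaf <- if (is.null(sub)) par[[layer]][[field]] else par[[layer]][[field]][[sub]]
      gleaf <- if (is.null(sub)) g[[layer]][[field]] else g[[layer]][[field]][[sub]]
      set.seed(9)
      for (i in sample(length(leaf), min(2, length(leaf)))) {
        eps <- 1e-5
        pp <- par
        if (is.null(sub)) pp[[layer]][[field]][i] <- leaf[i] + eps
        else pp[[layer]][[field]][[sub]][i] <- leaf[i] + eps
        up <- loss_with(pp)
        if (is.null(sub)) pp[[layer]][[field]][i] <- leaf[i] - eps
        else pp[[layer]][[field]][[sub]][i] <- leaf[i] - eps
        dn <- loss_with(pp)
        num <- (up - dn) / (2 * eps)
        expect_lt(abs(num - gleaf[i]) / max(1e-4, abs(num) + abs(gleaf[i])), 2e-3)
      }
    }
    check("conv1", "W", 1); check("conv1", "b")
    check("bn1", "gamma"); check("bn1", "beta")
    check("conv2", "W", 2)
    check("bilstm", "fwd", "Wx"); check("bilstm", "fwd", "Wh")
    check("bilstm", "bwd", "b")
    check("fc_seq", "W"); check("pconv", "W", 3); check("pbn", "gamma")
    check("fc_phys", "W"); check("fc_joint", "W")
    check("head_fc", "W"); check("head_fc", "b")
  }
})

test_that("split_dataset sizes, determinism and multiset preservation", {
  s <- split_dataset(1000, c(0.7, 0.2, 0.1), seed = 4)
  expect_length(s$train, 700)
  expect_length(s$val, 200)
  expect_length(s$test, 100)
  expect_identical(sort(c(s$train, s$val, s$test)), 1:1000)
  expect_identical(s, split_dataset(1000, c(0.7, 0.2, 0.1), seed = 4))
  all_train <- split_dataset(50, c(1, 0, 0), seed = 1)
  expect_length(all_train$train, 50)
  expect_length(all_train$val, 0)
  # remainder goes to train
  s2 <- split_dataset(103, c(0.7, 0.2, 0.1), seed = 2)
  expect_length(s2$val, 20)
  expect_length(s2$test, 10)
  expect_length(s2$train, 73)
  expect_error(split_dataset(10, c(0.5, 0.2, 0.1)), "sum to 1")
  expect_error(train_config(fractions = c(0.6, 0.3, 0.2)), "sum to 1")
})

test_that("training descends, early-stops and is reproducible from the seed", {
  sim <- small_sim()
  f <- small_features()
  y <- sim$sites$read_count
  tc <- train_config(lr = 2e-3, max_epochs = 4L, patience = 3L,
                     batch_size = 64L, seed = 21L)
  m1 <- train_model(f$xs, f$xp, y, "zinb", tiny_cfg, tc)
  # epoch-1 loss beats the untrained model (pi = .5, mu = 1, theta = 1)
  init_nll <- head_nll("zinb", data.frame(pi = 0.5, mu = 1, theta = 1)[rep(1, length(m1$split$train)), ],
                       y[m1$split$train]) / length(m1$split$train)
  expect_lt(m1$history$train_nll[1], init_nll)
  expect_lt(min(m1$history$train_nll), m1$history$train_nll[1])
  m2 <- train_model(f$xs, f$xp, y, "zinb", tiny_cfg, tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$metadata$best_monitor_nll, m2$metadata$best_monitor_nll)
  p1 <- model_predict(m1, f$xs[1:10, , ], f$xp[1:10, , ])
  p2 <- model_predict(m2, f$xs[1:10, , ], f$xp[1:10, , ])
  expect_identical(p1, p2)
  expect_error(train_model(f$xs, f$xp, y, "zinb", tiny_cfg,
                           train_config(fractions = c(1, 0, 0), seed = 1)),
               "validation split is empty")
  expect_error(train_model(f$xs, f$xp, numeric(0)), "empty dataset")
  expect_error(train_model(f$xs, f$xp, y[-1]), "matching first dimensions")
})

test_that("a trained model recovers marginal ZINB parameters without covariate signal", {
  # no-signal dataset from one fixed ZINB: the network should converge to
  # the marginal fit, with average predicted (pi, mean) near the truth
  n <- 20000
  y <- zinb_sample(n, 0.3, 20, 2, seed = 5)
  set.seed(6)
  xs <- array(as.numeric(runif(n * 23 * 6) < 0.3), c(n, 23, 6))
  xp <- array(runif(n * 23 * 4), c(n, 23, 4))
  m <- train_model(xs, xp, y, "zinb", small_net_config(),
                   train_config(lr = 3e-3, max_epochs = 8L, patience = 8L,
                                batch_size = 256L, fractions = c(0.8, 0.1, 0.1),
                                seed = 7L))
  p <- model_predict(m, xs[m$split$test, , ], xp[m$split$test, , ])
  expect_lt(abs(mean(p$pi) - 0.3) / 0.3, 0.1)
  expect_lt(abs(mean(predicted_mean("zinb", p)) - 0.7 * 20) / (0.7 * 20), 0.1)
})
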