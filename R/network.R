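#' Network architecture and training configuration
#'
#' The regressor maps the 6 x 23 interface encoding and the 4 x 23
#' descriptor matrix to the parameters of a count distribution. The
#' sequence branch applies two convolution stages (128 kernels of width 1,
#' then 32 of width 3, each batch-normalized and rectified, the second
#' max-pooled with window 2 stride 2), a bidirectional LSTM with 128 hidden
#' units per direction whose final states are concatenated, and a 128-unit
#' projection. The descriptor branch applies one 32-kernel width-3
#' convolution stage and a 128-unit projection. The two 128-dim encodings
#' are concatenated (256-dim), passed through a 64-unit joint layer, and
#' read out by one scalar head per distribution parameter: a sigmoid for
#' the zero-inflation weight `pi` and exponentials for `mu` and `theta`
#' (clamped to keep the likelihood finite). Defaults follow that plan;
#' smaller values give the scaled-down architecture used for fast offline
#' runs.
#'
#' @param conv1_kernels,conv2_kernels Kernels of the two sequence-branch
#'   convolution stages (widths 1 and 3).
#' @param lstm_hidden Hidden units per LSTM direction.
#' @param fc_seq,fc_phys Units of the per-branch projection layers.
#' @param fc_joint Units of the joint layer.
#' @param phys_kernels Kernels of the descriptor-branch convolution
#'   (width 3).
#' @export
network_config <- function(conv1_kernels = 128L, conv2_kernels = 32L,
                           lstm_hidden = 128L, fc_seq = 128L, fc_phys = 128L,
                           fc_joint = 64L, phys_kernels = 32L) {
  structure(list(conv1_kernels = conv1_kernels, conv2_kernels = conv2_kernels,
                 lstm_hidden = lstm_hidden, fc_seq = fc_seq, fc_phys = fc_phys,
                 fc_joint = fc_joint, phys_kernels = phys_kernels),
            class = "network_config")
}

#' @rdname network_config
#' @param lr Adam learning rate (default 1e-5).
#' @param max_epochs Maximum training epochs (default 500).
#' @param patience Early-stopping patience in epochs (default 50).
#' @param batch_size Mini-batch size (default 128).
#' @param fractions Train/validation/test split fractions (default
#'   0.70/0.20/0.10).
#' @param monitor Loss watched for early stopping: `"val"` or `"train"`.
#' @param seed Integer seed controlling initialization, the split and batch
#'   shuffling; identical seeds give identical training runs.
#' @export
train_config <- function(lr = 1e-5, max_epochs = 500L, patience = 50L,
                         batch_size = 128L, fractions = c(0.7, 0.2, 0.1),
                         monitor = c("val", "train"), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("'fractions' must sum to 1")
  if (any(fractions < 0)) stop("'fractions' must be nonnegative")
  structure(list(lr = lr, max_epochs = max_epochs, patience = patience,
                 batch_size = batch_size, fractions = fractions,
                 monitor = match.arg(monitor), seed = seed),
            class = "train_config")
}

HEADS <- c("zinb", "zip", "nb", "poisson")
head_n_out <- function(head) switch(head, zinb = 3L, zip = 2L, nb = 2L, poisson = 1L)

LOG_LO <- log(1e-6)
LOG_HI <- log(1e6)
LOGIT_LIM <- stats::qlogis(1 - 1e-6)

NET_LAYERS <- c("conv1", "bn1", "conv2", "bn2", "bilstm", "fc_seq",
                "pconv", "pbn", "fc_phys", "fc_joint", "head_fc")

#' Initialize network weights
#'
#' Fan-in-scaled uniform initialization (LSTM forget-gate biases start at
#' 1); head weights start at zero, so an untrained zinb model outputs
#' exactly `pi = 0.5, mu = 1, theta = 1`.
#'
#' @param config A [network_config()].
#' @param head One of `"zinb"`, `"zip"`, `"nb"`, `"poisson"`.
#' @param seed Optional seed.
#' @export
init_network <- function(config = network_config(), head = "zinb", seed = NULL) {
  head <- match.arg(head, HEADS)
  with_seed(seed, {
    K1 <- config$conv1_kernels; K2 <- config$conv2_kernels
    H <- config$lstm_hidden; Kp <- config$phys_kernels
    net <- list(
      conv1 = conv1d_init(1L, 6L, K1),
      bn1 = bn_init(K1),
      conv2 = conv1d_init(3L, K1, K2),
      bn2 = bn_init(K2),
      bilstm = bilstm_init(K2, H),
      fc_seq = dense_init(2L * H, config$fc_seq),
      pconv = conv1d_init(3L, 4L, Kp),
      pbn = bn_init(Kp),
      fc_phys = dense_init(23L * Kp, config$fc_phys),
      fc_joint = dense_init(config$fc_seq + config$fc_phys, config$fc_joint),
      head_fc = dense_init(config$fc_joint, head_n_out(head), zero = TRUE)
    )
    attr(net, "config") <- config
    attr(net, "head") <- head
    net
  })
}

net_params <- function(net) lapply(net[NET_LAYERS], `[[`, "par")
net_set_params <- function(net, par) {
  for (nm in NET_LAYERS) net[[nm]]$par <- par[[nm]]
  net
}

# forward pass; returns raw head outputs, cache, and the net (running BN
# statistics update in train mode)
net_forward <- function(net, xs, xp, train = FALSE) {
  B <- dim(xs)[1]
  c1 <- conv1d_forward(net$conv1, xs)
  b1 <- bn_forward(net$bn1, c1$out, train); net$bn1 <- b1$layer
  r1 <- relu_forward(b1$out)
  c2 <- conv1d_forward(net$conv2, mat_to_arr(r1$out, B, 23L))
  b2 <- bn_forward(net$bn2, c2$out, train); net$bn2 <- b2$layer
  r2 <- relu_forward(b2$out)
  mp <- maxpool_forward(mat_to_arr(r2$out, B, 23L))
  bl <- bilstm_forward(net$bilstm, mp$out)
  r3 <- relu_forward(bl$out)
  f1 <- dense_forward(net$fc_seq, r3$out)
  r4 <- relu_forward(f1$out)

  pc <- conv1d_forward(net$pconv, xp)
  pb <- bn_forward(net$pbn, pc$out, train); net$pbn <- pb$layer
  pr <- relu_forward(pb$out)
  flat <- mat_to_arr(pr$out, B, 23L)
  dim(flat) <- c(B, 23L * dim(flat)[3])
  f2 <- dense_forward(net$fc_phys, flat)
  r5 <- relu_forward(f2$out)

  et <- cbind(r4$out, r5$out)
  f3 <- dense_forward(net$fc_joint, et)
  r6 <- relu_forward(f3$out)
  hd <- dense_forward(net$head_fc, r6$out)

  list(raw = hd$out, net = net,
       cache = list(B = B, c1 = c1, b1 = b1, r1 = r1, c2 = c2, b2 = b2,
                    r2 = r2, mp = mp, bl = bl, r3 = r3, f1 = f1, r4 = r4,
                    pc = pc, pb = pb, pr = pr, flat = flat, f2 = f2, r5 = r5,
                    et = et, f3 = f3, r6 = r6))
}

# backward pass from d(loss)/d(raw); returns gradient tree matching net_params
net_backward <- function(net, cache, draw) {
  B <- cache$B
  g <- list()
  dh <- dense_backward(net$head_fc, cache$r6$out, draw)
  g$head_fc <- dh$grads
  d6 <- relu_backward(cache$r6$mask, dh$dX)
  d3 <- dense_backward(net$fc_joint, cache$et, d6)
  g$fc_joint <- d3$grads
  ns <- ncol(cache$r4$out)
  dEs <- d3$dX[, seq_len(ns), drop = FALSE]
  dEp <- d3$dX[, -seq_len(ns), drop = FALSE]

  d5 <- relu_backward(cache$r5$mask, dEp)
  dfp <- dense_backward(net$fc_phys, cache$flat, d5)
  g$fc_phys <- dfp$grads
  dflat <- dfp$dX
  Kp <- length(net$pbn$par$gamma)
  dim(dflat) <- c(B, 23L, Kp)
  dpr <- relu_backward(cache$pr$mask, arr_to_mat(dflat))
  dpb <- bn_backward(net$pbn, cache$pb$cache, dpr)
  g$pbn <- dpb$grads
  dpc <- conv1d_backward(net$pconv, cache$pc$cache, dpb$dX)
  g$pconv <- dpc$grads

  d4 <- relu_backward(cache$r4$mask, dEs)
  df1 <- dense_backward(net$fc_seq, cache$r3$out, d4)
  g$fc_seq <- df1$grads
  d3b <- relu_backward(cache$r3$mask, df1$dX)
  dbl <- bilstm_backward(net$bilstm, cache$bl$cache, d3b)
  g$bilstm <- dbl$grads
  dmp <- maxpool_backward(cache$mp$cache, dbl$dX)
  dr2 <- relu_backward(cache$r2$mask, arr_to_mat(dmp))
  db2 <- bn_backward(net$bn2, cache$b2$cache, dr2)
  g$bn2 <- db2$grads
  dc2 <- conv1d_backward(net$conv2, cache$c2$cache, db2$dX)
  g$conv2 <- dc2$grads
  dr1 <- relu_backward(cache$r1$mask, arr_to_mat(dc2$dA))
  db1 <- bn_backward(net$bn1, cache$b1$cache, dr1)
  g$bn1 <- db1$grads
  dc1 <- conv1d_backward(net$conv1, cache$c1$cache, db1$dX)
  g$conv1 <- dc1$grads
  g[NET_LAYERS]
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# zero the gradient components that would push a clamped raw output
# further outside its bounds
gate_clamped <- function(g, raw, lo, hi) {
  g[raw > hi & g < 0] <- 0
  g[raw < lo & g > 0] <- 0
  g
}

# map raw head outputs to distribution parameters (with clamps)
raw_to_params <- function(head, raw) {
  switch(head,
    zinb = data.frame(pi = stats::plogis(clamp(raw[, 1], -LOGIT_LIM, LOGIT_LIM)),
                      mu = exp(clamp(raw[, 2], LOG_LO, LOG_HI)),
                      theta = exp(clamp(raw[, 3], LOG_LO, LOG_HI))),
    zip = data.frame(pi = stats::plogis(clamp(raw[, 1], -LOGIT_LIM, LOGIT_LIM)),
                     lambda = exp(clamp(raw[, 2], LOG_LO, LOG_HI))),
    nb = data.frame(mu = exp(clamp(raw[, 1], LOG_LO, LOG_HI)),
                    theta = exp(clamp(raw[, 2], LOG_LO, LOG_HI))),
    poisson = data.frame(lambda = exp(clamp(raw[, 1], LOG_LO, LOG_HI)))
  )
}

#' Expected count under any head's parameters
#' @inheritParams head_log_pmf
#' @export
predicted_mean <- function(head, params) {
  switch(match.arg(head, HEADS),
    zinb = (1 - params$pi) * params$mu,
    zip = (1 - params$pi) * params$lambda,
    nb = params$mu,
    poisson = params$lambda
  )
}

# per-batch mean NLL and gradient wrt raw outputs
head_loss_grad <- function(head, raw, y) {
  B <- length(y)
  params <- raw_to_params(head, raw)
  nll <- -mean(head_log_pmf(head, y, params))
  pos <- y > 0
  gr <- matrix(0, B, ncol(raw))
  if (head %in% c("zinb", "zip")) {
    pi <- params$pi
    if (head == "zinb") { mu <- params$mu; th <- params$theta } else lam <- params$lambda
    ds <- numeric(B); ds[pos] <- pi[pos]
    if (any(!pos)) {
      z <- !pos
      if (head == "zinb") {
        l0 <- th[z] * (log(th[z]) - log(mu[z] + th[z]))
        n0 <- exp(l0)
      } else n0 <- exp(-lam[z])
      p0 <- pmax(pi[z] + (1 - pi[z]) * n0, 1e-300)
      ds[z] <- -pi[z] * (1 - pi[z]) * (1 - n0) / p0
      r <- (1 - pi[z]) * n0 / p0
      if (head == "zinb") {
        da0 <- r * mu[z] * th[z] / (mu[z] + th[z])
        db0 <- -r * th[z] * (log(th[z]) - log(mu[z] + th[z]) + 1 - th[z] / (mu[z] + th[z]))
      } else da0 <- r * lam[z]
    }
    da <- numeric(B)
    if (head == "zinb") {
      db <- numeric(B)
      da[pos] <- mu[pos] * (y[pos] + th[pos]) / (mu[pos] + th[pos]) - y[pos]
      db[pos] <- -th[pos] * (digamma(y[pos] + th[pos]) - digamma(th[pos]) +
                             log(th[pos]) + 1 - log(mu[pos] + th[pos]) -
                             (y[pos] + th[pos]) / (mu[pos] + th[pos]))
      if (any(!pos)) { da[!pos] <- da0; db[!pos] <- db0 }
      gr[, 1] <- gate_clamped(ds, raw[, 1], -LOGIT_LIM, LOGIT_LIM)
      gr[, 2] <- gate_clamped(da, raw[, 2], LOG_LO, LOG_HI)
      gr[, 3] <- gate_clamped(db, raw[, 3], LOG_LO, LOG_HI)
    } else {
      da[pos] <- lam[pos] - y[pos]
      if (any(!pos)) da[!pos] <- da0
      gr[, 1] <- gate_clamped(ds, raw[, 1], -LOGIT_LIM, LOGIT_LIM)
      gr[, 2] <- gate_clamped(da, raw[, 2], LOG_LO, LOG_HI)
    }
  } else if (head == "nb") {
    mu <- params$mu; th <- params$theta
    da <- mu * (y + th) / (mu + th) - y
    db <- -th * (digamma(y + th) - digamma(th) + log(th) + 1 -
                 log(mu + th) - (y + th) / (mu + th))
    gr[, 1] <- gate_clamped(da, raw[, 1], LOG_LO, LOG_HI)
    gr[, 2] <- gate_clamped(db, raw[, 2], LOG_LO, LOG_HI)
  } else {
    lam <- params$lambda
    gr[, 1] <- gate_clamped(lam - y, raw[, 1], LOG_LO, LOG_HI)
  }
  list(nll = nll, draw = gr / B)
}

#' Split a dataset into train/validation/test indices
#'
#' A seeded random permutation sliced contiguously; validation and test
#' sizes are floor-based and the remainder goes to the training split, so
#' 1000 records at 0.70/0.20/0.10 give 700/200/100.
#'
#' @param n Number of records.
#' @param fractions Length-3 nonnegative fractions summing to 1.
#' @param seed Integer seed.
#' @return List of integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(n, fractions = c(0.7, 0.2, 0.1), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("'fractions' must sum to 1")
  if (any(fractions < 0)) stop("'fractions' must be nonnegative")
  perm <- with_seed(seed, sample.int(n))
  n_val <- floor(n * fractions[2])
  n_test <- floor(n * fractions[3])
  n_train <- n - n_val - n_test
  list(train = perm[seq_len(n_train)],
       val = perm[n_train + seq_len(n_val)],
       test = perm[n_train + n_val + seq_len(n_test)])
}

# mean NLL over a dataset in inference mode, chunked
eval_nll <- function(net, head, xs, xp, y, chunk = 2048L) {
  n <- length(y)
  tot <- 0
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    raw <- net_forward(net, xs[s:e, , , drop = FALSE],
                       xp[s:e, , , drop = FALSE], train = FALSE)$raw
    tot <- tot + head_loss_grad(head, raw, y[s:e])$nll * (e - s + 1L)
  }
  tot / n
}

#' Train the count-regression network
#'
#' Mini-batch Adam on the selected head's negative log-likelihood with
#' early stopping on the monitored loss; the weights achieving the best
#' monitored loss are returned. Fully reproducible from
#' `train_config$seed`.
#'
#' @param x_s Array `(n, 23, 6)` of interface encodings
#'   ([encode_pairs()]).
#' @param x_p Array `(n, 23, 4)` of normalized descriptor matrices
#'   ([descriptor_matrices()]).
#' @param y Nonnegative integer counts.
#' @param head Distribution head: `"zinb"`, `"zip"`, `"nb"`, `"poisson"`.
#' @param net_config A [network_config()].
#' @param config A [train_config()].
#' @param norm_stats Optional descriptor normalization statistics to store
#'   with the model.
#' @param verbose Print per-epoch losses.
#' @return An object of class `ot_model`: network weights at the best
#'   monitored epoch, configuration snapshots, split indices, loss history
#'   and provenance metadata.
#' @export
train_model <- function(x_s, x_p, y, head = "zinb",
                        net_config = network_config(),
                        config = train_config(), norm_stats = NULL,
                        verbose = FALSE) {
  head <- match.arg(head, HEADS)
  n <- length(y)
  if (n == 0L) stop("empty dataset")
  if (dim(x_s)[1] != n || dim(x_p)[1] != n)
    stop("x_s, x_p and y must have matching first dimensions")
  y <- check_counts(y, "y")
  idx <- split_dataset(n, config$fractions, config$seed)
  if (length(idx$train) == 0L) stop("empty training split")
  if (config$monitor == "val" && length(idx$val) == 0L)
    stop("validation split is empty but monitor = 'val'")

  with_seed(config$seed + 1L, {
    net <- init_network(net_config, head)
    # data-driven initialization of the mean head's bias
    mean_col <- switch(head, zinb = 2L, zip = 2L, nb = 1L, poisson = 1L)
    net$head_fc$par$b[mean_col] <- log(mean(y[idx$train]) + 1e-3)

    tr_xs <- x_s[idx$train, , , drop = FALSE]
    tr_xp <- x_p[idx$train, , , drop = FALSE]
    tr_y <- y[idx$train]
    astate <- adam_state_like(net_params(net))
    step <- 0L
    best <- Inf; best_par <- net_params(net); best_epoch <- 0L
    wait <- 0L
    hist <- data.frame(epoch = integer(), train_nll = numeric(),
                       monitor_nll = numeric())
    ntr <- length(tr_y)
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(ntr)
      ep_loss <- 0
      starts <- seq(1L, ntr, by = config$batch_size)
      for (bi in seq_along(starts)) {
        sel <- perm[starts[bi]:min(starts[bi] + config$batch_size - 1L, ntr)]
        fw <- net_forward(net, tr_xs[sel, , , drop = FALSE],
                          tr_xp[sel, , , drop = FALSE], train = TRUE)
        net <- fw$net
        lg <- head_loss_grad(head, fw$raw, tr_y[sel])
        if (!is.finite(lg$nll))
          stop(sprintf("training diverged: non-finite loss at epoch %d, batch %d",
                       epoch, bi))
        grads <- net_backward(net, fw$cache, lg$draw)
        step <- step + 1L
        upd <- adam_step(net_params(net), grads, astate, config$lr, step)
        net <- net_set_params(net, upd$par)
        astate <- upd$state
        ep_loss <- ep_loss + lg$nll * length(sel)
      }
      ep_loss <- ep_loss / ntr
      mon <- if (config$monitor == "val")
        eval_nll(net, head, x_s[idx$val, , , drop = FALSE],
                 x_p[idx$val, , , drop = FALSE], y[idx$val])
      else ep_loss
      hist <- rbind(hist, data.frame(epoch = epoch, train_nll = ep_loss,
                                     monitor_nll = mon))
      if (verbose)
        message(sprintf("epoch %d: train %.4f, %s %.4f", epoch, ep_loss,
                        config$monitor, mon))
      if (mon < best - 1e-8) {
        best <- mon; best_par <- net_params(net); best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    net <- net_set_params(net, best_par)
    structure(list(net = net, head = head, net_config = net_config,
                   train_config = config, split = idx,
                   norm_stats = norm_stats, history = hist,
                   metadata = list(seed = config$seed, best_epoch = best_epoch,
                                   best_monitor_nll = best,
                                   package_version = "0.1.0")),
              class = "ot_model")
  })
}

#' Predict distribution parameters for sites
#'
#' Deterministic inference-mode forward pass (batch normalization uses the
#' stored running statistics).
#'
#' @param model An `ot_model` from [train_model()].
#' @param x_s Interface encodings: array `(n, 23, 6)`, or a single 6 x 23
#'   matrix from [encode_pair()].
#' @param x_p Descriptor matrices: array `(n, 23, 4)`, or a single 4 x 23
#'   matrix from [descriptor_matrix()].
#' @return Data frame of per-site parameters (columns depend on the head;
#'   for zinb: `pi`, `mu`, `theta`).
#' @export
model_predict <- function(model, x_s, x_p) {
  stopifnot(inherits(model, "ot_model"))
  if (is.matrix(x_s)) {
    if (!all(dim(x_s) == c(6L, 23L))) stop("single x_s must be a 6 x 23 matrix")
    x_s <- array(t(x_s), dim = c(1L, 23L, 6L))
  }
  if (is.matrix(x_p)) {
    if (!all(dim(x_p) == c(4L, 23L))) stop("single x_p must be a 4 x 23 matrix")
    x_p <- array(t(x_p), dim = c(1L, 23L, 4L))
  }
  if (!all(dim(x_s)[2:3] == c(23L, 6L)) || !all(dim(x_p)[2:3] == c(23L, 4L)))
    stop("x_s must be (n, 23, 6) and x_p (n, 23, 4)")
  n <- dim(x_s)[1]
  out <- NULL
  for (s in seq(1L, n, by = 2048L)) {
    e <- min(s + 2047L, n)
    raw <- net_forward(model$net, x_s[s:e, , , drop = FALSE],
                       x_p[s:e, , , drop = FALSE], train = FALSE)$raw
    p <- raw_to_params(model$head, raw)
    out <- if (is.null(out)) p else rbind(out, p)
  }
  out
}
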