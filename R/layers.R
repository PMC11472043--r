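# Vectorized network layers with analytic gradients.
#
# Batch tensors are base-R arrays of dim (B, L, C): sample, position,
# channel. dim-collapse of the first two axes gives the (B*L) x C matrix
# view used for the channel-mixing matrix products (column-major order
# keeps rows of equal position contiguous). Gradients of every layer are
# validated against central finite differences in the test suite.

arr_to_mat <- function(A) { d <- dim(A); dim(A) <- c(d[1] * d[2], d[3]); A }
mat_to_arr <- function(M, B, L) { C <- ncol(M); dim(M) <- c(B, L, C); M }

init_mat <- function(nr, nc, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

## ---- 1-D convolution ('same' padding, odd width) ----

conv1d_init <- function(width, c_in, c_out) {
  list(type = "conv1d", width = width,
       par = list(W = lapply(seq_len(width), function(o) init_mat(c_in, c_out, c_in * width)),
                  b = numeric(c_out)))
}

conv1d_forward <- function(layer, A) {
  d <- dim(A); B <- d[1]; L <- d[2]
  w <- layer$width; pad <- (w - 1L) %/% 2L
  K <- length(layer$par$b)
  out <- matrix(rep(layer$par$b, each = B * L), B * L, K)
  for (o in seq_len(w)) {
    off <- o - 1L - pad
    ls <- max(1L, 1L - off):min(L, L - off)
    Xs <- arr_to_mat(A[, ls + off, , drop = FALSE])
    rows <- rep((ls - 1L) * B, each = B) + seq_len(B)
    out[rows, ] <- out[rows, ] + Xs %*% layer$par$W[[o]]
  }
  list(out = out, cache = list(A = A, B = B, L = L))
}

conv1d_backward <- function(layer, cache, dOut) {
  A <- cache$A; B <- cache$B; L <- cache$L
  w <- layer$width; pad <- (w - 1L) %/% 2L
  dA <- array(0, dim(A))
  dW <- vector("list", w)
  for (o in seq_len(w)) {
    off <- o - 1L - pad
    ls <- max(1L, 1L - off):min(L, L - off)
    rows <- rep((ls - 1L) * B, each = B) + seq_len(B)
    Xs <- arr_to_mat(A[, ls + off, , drop = FALSE])
    dRows <- dOut[rows, , drop = FALSE]
    dW[[o]] <- crossprod(Xs, dRows)
    dA[, ls + off, ] <- dA[, ls + off, ] +
      mat_to_arr(tcrossprod(dRows, layer$par$W[[o]]), B, length(ls))
  }
  list(dA = dA, grads = list(W = dW, b = colSums(dOut)))
}

## ---- batch normalization (per channel over all rows) ----

bn_init <- function(C) {
  list(type = "bn",
       par = list(gamma = rep(1, C), beta = numeric(C)),
       state = list(rm = numeric(C), rv = rep(1, C)),
       momentum = 0.1, eps = 1e-5)
}

bn_forward <- function(layer, X, train) {
  N <- nrow(X)
  if (train) {
    mu <- colMeans(X)
    Xc <- X - rep(mu, each = N)
    v <- colMeans(Xc * Xc)
    layer$state$rm <- (1 - layer$momentum) * layer$state$rm + layer$momentum * mu
    layer$state$rv <- (1 - layer$momentum) * layer$state$rv + layer$momentum * v
  } else {
    mu <- layer$state$rm
    v <- layer$state$rv
    Xc <- X - rep(mu, each = N)
  }
  isd <- 1 / sqrt(v + layer$eps)
  xhat <- Xc * rep(isd, each = N)
  out <- xhat * rep(layer$par$gamma, each = N) + rep(layer$par$beta, each = N)
  list(out = out, layer = layer, cache = list(xhat = xhat, isd = isd, N = N))
}

bn_backward <- function(layer, cache, dY) {
  N <- cache$N
  dbeta <- colSums(dY)
  dgamma <- colSums(dY * cache$xhat)
  coef <- layer$par$gamma * cache$isd / N
  dX <- rep(coef, each = N) *
    (N * dY - rep(dbeta, each = N) - cache$xhat * rep(dgamma, each = N))
  list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
}

## ---- ReLU / max-pooling ----

relu_forward <- function(X) list(out = pmax(X, 0), mask = X > 0)
relu_backward <- function(mask, dY) dY * mask

maxpool_forward <- function(A) {
  d <- dim(A); B <- d[1]; L <- d[2]
  Lo <- L %/% 2L
  A1 <- A[, seq(1L, 2L * Lo, 2L), , drop = FALSE]
  A2 <- A[, seq(2L, 2L * Lo, 2L), , drop = FALSE]
  m <- A1 >= A2
  list(out = A1 * m + A2 * !m, cache = list(mask = m, L = L))
}

maxpool_backward <- function(cache, dOut) {
  d <- dim(dOut); B <- d[1]; Lo <- d[2]; C <- d[3]
  dA <- array(0, c(B, cache$L, C))
  dA[, seq(1L, 2L * Lo, 2L), ] <- dOut * cache$mask
  dA[, seq(2L, 2L * Lo, 2L), ] <- dOut * !cache$mask
  dA
}

## ---- dense ----

dense_init <- function(n_in, n_out, zero = FALSE) {
  list(type = "dense",
       par = list(W = if (zero) matrix(0, n_in, n_out) else init_mat(n_in, n_out, n_in),
                  b = numeric(n_out)))
}

dense_forward <- function(layer, X)
  list(out = X %*% layer$par$W + rep(layer$par$b, each = nrow(X)), cache = X)

dense_backward <- function(layer, X, dY)
  list(dX = tcrossprod(dY, layer$par$W),
       grads = list(W = crossprod(X, dY), b = colSums(dY)))

## ---- LSTM (one direction) ----

lstm_init <- function(c_in, H) {
  b <- numeric(4L * H)
  b[(H + 1L):(2L * H)] <- 1  # forget-gate bias
  list(Wx = init_mat(c_in, 4L * H, c_in + H),
       Wh = init_mat(H, 4L * H, c_in + H),
       b = b)
}

sigm <- function(x) 1 / (1 + exp(-x))

# X: (B, T, C); returns final hidden state (B, H) and per-step cache
lstm_forward <- function(par, X) {
  d <- dim(X); B <- d[1]; Tn <- d[2]; H <- length(par$b) %/% 4L
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  steps <- vector("list", Tn)
  gi <- 1:H; gf <- H + gi; gg <- 2L * H + gi; go <- 3L * H + gi
  for (t in seq_len(Tn)) {
    Xt <- X[, t, ]
    if (is.null(dim(Xt))) Xt <- matrix(Xt, B)
    Z <- Xt %*% par$Wx + h %*% par$Wh + rep(par$b, each = B)
    i <- sigm(Z[, gi, drop = FALSE]); f <- sigm(Z[, gf, drop = FALSE])
    g <- tanh(Z[, gg, drop = FALSE]); o <- sigm(Z[, go, drop = FALSE])
    c_prev <- cc; h_prev <- h
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    steps[[t]] <- list(Xt = Xt, i = i, f = f, g = g, o = o,
                       c_prev = c_prev, h_prev = h_prev, tc = tc)
  }
  list(h = h, cache = list(steps = steps, B = B, Tn = Tn, H = H, Cin = dim(X)[3]))
}

# dh_final: gradient at the last hidden state
lstm_backward <- function(par, cache, dh_final) {
  B <- cache$B; Tn <- cache$Tn; H <- cache$H
  dWx <- matrix(0, nrow(par$Wx), ncol(par$Wx))
  dWh <- matrix(0, nrow(par$Wh), ncol(par$Wh))
  db <- numeric(length(par$b))
  dX <- array(0, c(B, Tn, cache$Cin))
  dh <- dh_final
  dc <- matrix(0, B, H)
  for (t in rev(seq_len(Tn))) {
    s <- cache$steps[[t]]
    do <- dh * s$tc
    dc <- dc + dh * s$o * (1 - s$tc^2)
    di <- dc * s$g
    dg <- dc * s$i
    df <- dc * s$c_prev
    dZ <- cbind(di * s$i * (1 - s$i), df * s$f * (1 - s$f),
                dg * (1 - s$g^2), do * s$o * (1 - s$o))
    dWx <- dWx + crossprod(s$Xt, dZ)
    dWh <- dWh + crossprod(s$h_prev, dZ)
    db <- db + colSums(dZ)
    dX[, t, ] <- tcrossprod(dZ, par$Wx)
    dh <- tcrossprod(dZ, par$Wh)
    dc <- dc * s$f
  }
  list(dX = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
}

## ---- bidirectional LSTM (concatenated final states) ----

bilstm_init <- function(c_in, H)
  list(type = "bilstm", H = H,
       par = list(fwd = lstm_init(c_in, H), bwd = lstm_init(c_in, H)))

bilstm_forward <- function(layer, X) {
  Tn <- dim(X)[2]
  f <- lstm_forward(layer$par$fwd, X)
  b <- lstm_forward(layer$par$bwd, X[, rev(seq_len(Tn)), , drop = FALSE])
  list(out = cbind(f$h, b$h), cache = list(f = f$cache, b = b$cache, Tn = Tn))
}

bilstm_backward <- function(layer, cache, dOut) {
  H <- layer$H
  bf <- lstm_backward(layer$par$fwd, cache$f, dOut[, 1:H, drop = FALSE])
  bb <- lstm_backward(layer$par$bwd, cache$b, dOut[, H + (1:H), drop = FALSE])
  dX <- bf$dX + bb$dX[, rev(seq_len(cache$Tn)), , drop = FALSE]
  list(dX = dX, grads = list(fwd = bf$grads, bwd = bb$grads))
}

## ---- Adam over a nested parameter tree ----

adam_state_like <- function(par) {
  if (is.list(par)) lapply(par, adam_state_like)
  else list(m = par * 0, v = par * 0)
}

adam_step <- function(par, grad, state, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.list(par)) {
    for (i in seq_along(par)) {
      res <- adam_step(par[[i]], grad[[i]], state[[i]], lr, t, b1, b2, eps)
      par[[i]] <- res$par
      state[[i]] <- res$state
    }
    return(list(par = par, state = state))
  }
  state$m <- b1 * state$m + (1 - b1) * grad
  state$v <- b2 * state$v + (1 - b2) * grad * grad
  mhat <- state$m / (1 - b1^t)
  vhat <- state$v / (1 - b2^t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), state = state)
}
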