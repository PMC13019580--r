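# Minimal dense/LSTM autograd-by-hand engine.
#
# All layers follow the same contract: `*_forward` returns list(out, cache);
# `*_backward(dout, cache)` returns list(dx, grads) with grads shaped like
# the parameter list. Everything is plain base-R matrix algebra so a single
# BLAS thread gives bitwise-reproducible runs.

# --- initializers ------------------------------------------------------------

glorot_uniform <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# orthogonal init for recurrent maps (QR of a gaussian matrix)
orthogonal_init <- function(n, m) {
  a <- matrix(stats::rnorm(n * m), n, m)
  qr_ <- qr(a)
  q <- qr.Q(qr_)
  # fix sign convention so the draw is a deterministic function of `a`
  q <- q %*% diag(sign(diag(qr.R(qr_))), ncol(q))
  if (ncol(q) < m) q <- cbind(q, matrix(0, n, m - ncol(q)))
  q[seq_len(n), seq_len(m), drop = FALSE]
}

# --- dense -------------------------------------------------------------------

dense_init <- function(nin, nout) {
  list(W = glorot_uniform(nin, nout), b = numeric(nout))
}

dense_forward <- function(x, p, activation = c("linear", "relu")) {
  activation <- match.arg(activation)
  z <- x %*% p$W
  z <- sweep(z, 2L, p$b, "+")
  out <- if (activation == "relu") pmax(z, 0) else z
  list(out = out, cache = list(x = x, z = z, activation = activation, p = p))
}

dense_backward <- function(dout, cache) {
  dz <- if (cache$activation == "relu") dout * (cache$z > 0) else dout
  list(dx = dz %*% t(cache$p$W),
       grads = list(W = crossprod(cache$x, dz), b = colSums(dz)))
}

# --- dropout (inverted; identity in eval mode) -------------------------------

dropout_forward <- function(x, rate, train) {
  if (!train || rate <= 0) {
    return(list(out = x, cache = list(mask = NULL)))
  }
  mask <- (matrix(stats::runif(length(x)), nrow(x), ncol(x)) >= rate) / (1 - rate)
  list(out = x * mask, cache = list(mask = mask))
}

dropout_backward <- function(dout, cache) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

# --- LSTM --------------------------------------------------------------------
# Gate order in the fused 4U weight blocks: input (i), forget (f),
# output (o), candidate (g). Forward per step:
#   z = x_t Wx + h_{t-1} Wh + b
#   i = sigma(z_i); f = sigma(z_f); o = sigma(z_o); g = tanh(z_g)
#   c_t = f * c_{t-1} + i * g;  h_t = o * tanh(c_t)

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_init <- function(input_dim, units) {
  list(Wx = glorot_uniform(input_dim, 4L * units),
       Wh = do.call(cbind, replicate(4L, orthogonal_init(units, units),
                                     simplify = FALSE)),
       b = numeric(4L * units))
}

# x: B x S x D array; returns h_seq: B x S x U with all step outputs
lstm_forward <- function(x, p) {
  d <- dim(x); B <- d[1L]; S <- d[2L]; D <- d[3L]
  U <- ncol(p$Wx) %/% 4L
  # one big input matmul for all steps (rows are b-major within each step)
  zx_all <- matrix(x, B * S, D) %*% p$Wx
  h <- matrix(0, B, U); c_ <- matrix(0, B, U)
  h_seq <- array(0, c(B, S, U))
  steps <- vector("list", S)
  idx <- seq_len(B)
  iU <- seq_len(U); fU <- U + iU; oU <- 2L * U + iU; gU <- 3L * U + iU
  for (t in seq_len(S)) {
    z <- zx_all[(t - 1L) * B + idx, , drop = FALSE] + h %*% p$Wh
    z <- sweep(z, 2L, p$b, "+")
    i_ <- sigmoid(z[, iU, drop = FALSE])
    f_ <- sigmoid(z[, fU, drop = FALSE])
    o_ <- sigmoid(z[, oU, drop = FALSE])
    g_ <- tanh(z[, gU, drop = FALSE])
    c_prev <- c_
    c_ <- f_ * c_prev + i_ * g_
    tc <- tanh(c_)
    h_prev <- h
    h <- o_ * tc
    h_seq[, t, ] <- h
    steps[[t]] <- list(i = i_, f = f_, o = o_, g = g_, c = c_,
                       c_prev = c_prev, tc = tc, h_prev = h_prev)
  }
  list(out = h_seq, cache = list(x = x, steps = steps, p = p,
                                 dims = c(B = B, S = S, D = D, U = U)))
}

# dh_seq: B x S x U gradient w.r.t. every step's output
lstm_backward <- function(dh_seq, cache) {
  dm <- cache$dims; B <- dm[["B"]]; S <- dm[["S"]]; D <- dm[["D"]]; U <- dm[["U"]]
  p <- cache$p
  dWx <- matrix(0, D, 4L * U); dWh <- matrix(0, U, 4L * U); db <- numeric(4L * U)
  dx <- array(0, c(B, S, D))
  dh_next <- matrix(0, B, U); dc_next <- matrix(0, B, U)
  for (t in rev(seq_len(S))) {
    st <- cache$steps[[t]]
    dh <- dh_seq[, t, , drop = FALSE]
    dim(dh) <- c(B, U)
    dh <- dh + dh_next
    do_ <- dh * st$tc
    dct <- dc_next + dh * st$o * (1 - st$tc^2)
    di <- dct * st$g
    df <- dct * st$c_prev
    dg <- dct * st$i
    dz <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                do_ * st$o * (1 - st$o),
                dg * (1 - st$g^2))
    xt <- cache$x[, t, , drop = FALSE]
    dim(xt) <- c(B, D)
    dWx <- dWx + crossprod(xt, dz)
    dWh <- dWh + crossprod(st$h_prev, dz)
    db <- db + colSums(dz)
    dh_next <- dz %*% t(p$Wh)
    dc_next <- dct * st$f
    dx[, t, ] <- dz %*% t(p$Wx)
  }
  list(dx = dx, grads = list(Wx = dWx, Wh = dWh, b = db))
}

# --- parameter-tree utilities ------------------------------------------------

# flatten a nested list of numeric arrays into a flat named list
flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(p[[nm]])) {
      out <- c(out, flatten_params(p[[nm]], key))
    } else {
      out[[key]] <- p[[nm]]
    }
  }
  out
}

# write flat named values back into the nested structure of `template`
unflatten_params <- function(flat, template, prefix = "") {
  for (nm in names(template)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(template[[nm]])) {
      template[[nm]] <- unflatten_params(flat, template[[nm]], key)
    } else {
      v <- flat[[key]]
      dim(v) <- dim(template[[nm]])
      template[[nm]] <- v
    }
  }
  template
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

adam_step <- function(flat, grads, state, lr = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(flat)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    flat[[k]] <- flat[[k]] - lr * (state$m[[k]] / bc1) /
      (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}
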