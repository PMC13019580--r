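#' Model configuration
#'
#' Defaults reproduce the published layer dimensions: a 256-unit LSTM trunk
#' followed by 128- and 64-unit fully connected layers in the interpretable
#' blocks (the generic blocks use 256 -> 128 -> horizon), degree-3
#' polynomial trend basis, order-3 Fourier seasonal basis with a 90-step
#' period, three attention heads (one per module stream), and 21 features
#' on a 210-day backcast / 30-day horizon window.
#'
#' @param lstm_units LSTM hidden width (default 256).
#' @param fc1_units first fully connected width (default 128).
#' @param fc2_units second fully connected width in the interpretable
#'   blocks (default 64).
#' @param dropout_rate dropout rate after the interpretable blocks' second
#'   FC layer (default 0.2; the published table names the layer but not
#'   the rate).
#' @param poly_degree trend polynomial degree p (default 3).
#' @param fourier_order seasonal Fourier order i (default 3).
#' @param season_period seasonal basis period in steps (default 90).
#' @param n_heads number of attention heads; fixed at 3, one per module.
#' @param n_features number of panel features F (default 21).
#' @param window a [window_spec()] (default 30-step horizon, 7:1 ratio).
#' @param d_attn per-head query/key/value width; defaults to
#'   `horizon / n_heads` (the usual d_model/h split; the published work
#'   leaves these widths unstated).
#' @return a `model_config` list.
#' @export
model_config <- function(lstm_units = 256L, fc1_units = 128L, fc2_units = 64L,
                         dropout_rate = 0.2, poly_degree = 3L,
                         fourier_order = 3L, season_period = 90,
                         n_heads = 3L, n_features = 21L,
                         window = window_spec(),
                         d_attn = NULL) {
  if (n_heads != 3L) stop("the architecture has exactly 3 heads (one per module stream)")
  stopifnot(lstm_units >= 1, fc1_units >= 1, fc2_units >= 1,
            dropout_rate >= 0, dropout_rate < 1, poly_degree >= 0,
            fourier_order >= 1, season_period > 0, n_features >= 1)
  if (is.null(d_attn)) d_attn <- max(1L, window$horizon %/% n_heads)
  structure(list(lstm_units = as.integer(lstm_units),
                 fc1_units = as.integer(fc1_units),
                 fc2_units = as.integer(fc2_units),
                 dropout_rate = dropout_rate,
                 poly_degree = as.integer(poly_degree),
                 fourier_order = as.integer(fourier_order),
                 season_period = season_period,
                 n_heads = 3L,
                 n_features = as.integer(n_features),
                 window = window,
                 d_attn = as.integer(d_attn)),
            class = "model_config")
}

#' Training configuration
#'
#' Defaults follow the published experimental settings: 120 epochs, batch
#' size 64, learning rate 1e-4, mean squared error loss, Adam optimizer.
#'
#' @param epochs number of passes over the training windows.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed RNG seed controlling shuffling and dropout masks.
#' @param decomp_penalty weight of the decomposition-fidelity regularizer:
#'   adds `decomp_penalty * mean(x2^2)` to the loss, where `x2` is the
#'   window residual left after subtracting the trend and seasonal
#'   backcasts. Without it the unconstrained generic blocks can absorb
#'   signal the basis blocks should carry (the fused forecast is
#'   unaffected, but the per-module decomposition becomes arbitrary); a
#'   small positive weight presses the interpretable blocks to explain
#'   what their bases can express. Default 0.1; set 0 for the plain MSE
#'   objective.
#' @param seasonal_center weight of the seasonal-centering regularizer:
#'   adds `seasonal_center * mean(theta_const^2)` for the seasonal block's
#'   constant Fourier coefficient. A seasonal component is mean-zero by
#'   definition, but the Fourier basis carries a constant column whose
#'   span overlaps the trend polynomial, leaving the level split between
#'   the two blocks unidentified; shrinking the seasonal constant places
#'   the level in the trend block. Default 1; set 0 to disable.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 120L, batch_size = 64L,
                         learning_rate = 1e-4, seed = 1L,
                         decomp_penalty = 0.1, seasonal_center = 1) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate >= 0,
            decomp_penalty >= 0, seasonal_center >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 loss = "mse", optimizer = "adam",
                 decomp_penalty = decomp_penalty,
                 seasonal_center = seasonal_center,
                 seed = as.integer(seed)),
            class = "train_config")
}

# trunk = LSTM over the F feature channels (one step per feature, each step
# consuming that feature's full window) + FC head. `head_dims` is the chain
# after the LSTM, last entry is the output width (theta or horizon).
trunk_init <- function(input_dim, cfg, head_dims, dropout = FALSE) {
  U <- cfg$lstm_units
  layers <- list(lstm = lstm_init(input_dim, U))
  dims <- c(U, head_dims)
  for (j in seq_along(head_dims)) {
    layers[[paste0("fc", j)]] <- dense_init(dims[j], dims[j + 1L])
  }
  attr(layers, "n_fc") <- length(head_dims)
  attr(layers, "dropout") <- dropout
  layers
}

#' Build the forecasting network
#'
#' Composes the four-block dual-residual stack (trend, seasonal, two
#' generic residual blocks) and the three-head feature-channel attention
#' fusion, with seeded deterministic weight initialization
#' (Glorot-uniform dense maps, orthogonal recurrent maps). The trend and
#' seasonal basis matrices are fixed, non-trainable.
#'
#' @param cfg a [model_config()].
#' @param seed integer RNG seed; the same seed yields bitwise-identical
#'   initial weights.
#' @return a `pedvol_model`: list with `params`, `cfg`, fixed `bases`.
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  set.seed(seed)
  L <- cfg$window$backcast; H <- cfg$window$horizon
  K_t <- cfg$poly_degree + 1L
  K_s <- 2L * cfg$fourier_order + 1L
  d <- cfg$d_attn
  params <- list(
    trend    = trunk_init(L, cfg, c(cfg$fc1_units, cfg$fc2_units, K_t), dropout = TRUE),
    seasonal = trunk_init(L, cfg, c(cfg$fc1_units, cfg$fc2_units, K_s), dropout = TRUE),
    basic1   = trunk_init(L, cfg, c(cfg$fc1_units, H)),
    basic2   = trunk_init(H, cfg, c(cfg$fc1_units, H)),
    attn = list(
      h1 = list(Wq = glorot_uniform(H, d), Wk = glorot_uniform(H, d),
                Wv = glorot_uniform(H, d)),
      h2 = list(Wq = glorot_uniform(H, d), Wk = glorot_uniform(H, d),
                Wv = glorot_uniform(H, d)),
      h3 = list(Wq = glorot_uniform(H, d), Wk = glorot_uniform(H, d),
                Wv = glorot_uniform(H, d)),
      out = dense_init(3L * d, H),
      fc = dense_init(H, H)))
  bases <- list(trend = make_trend_basis(L, H, cfg$poly_degree),
                seasonal = make_seasonal_basis(L, H, cfg$fourier_order,
                                               cfg$season_period))
  structure(list(params = params, cfg = cfg, bases = bases, seed = seed),
            class = "pedvol_model")
}

#' @export
print.pedvol_model <- function(x, ...) {
  np <- sum(vapply(flatten_params(x$params), length, 0L))
  cat("<pedvol_model> L=", x$cfg$window$backcast, " H=", x$cfg$window$horizon,
      " F=", x$cfg$n_features, " lstm=", x$cfg$lstm_units,
      " params=", np, "\n", sep = "")
  invisible(x)
}

# trunk forward: x (B,F,In) -> list(out (B,F,K), cache)
trunk_forward <- function(x, p, cfg, train = FALSE) {
  d <- dim(x); B <- d[1L]; F_ <- d[2L]
  lst <- lstm_forward(x, p$lstm)
  n_fc <- attr(p, "n_fc")
  h <- matrix(lst$out, B * F_, dim(lst$out)[3L])
  caches <- list(lstm = lst$cache)
  for (j in seq_len(n_fc)) {
    act <- if (j < n_fc) "relu" else "linear"
    dn <- dense_forward(h, p[[paste0("fc", j)]], act)
    h <- dn$out
    caches[[paste0("fc", j)]] <- dn$cache
    if (isTRUE(attr(p, "dropout")) && j == n_fc - 1L) {
      dr <- dropout_forward(h, cfg$dropout_rate, train)
      h <- dr$out
      caches$dropout <- dr$cache
    }
  }
  out <- h
  dim(out) <- c(B, F_, ncol(h))
  caches$dims <- c(B, F_)
  list(out = out, cache = caches)
}

trunk_backward <- function(dout, p, cache) {
  B <- cache$dims[1L]; F_ <- cache$dims[2L]
  n_fc <- attr(p, "n_fc")
  dh <- matrix(dout, B * F_, dim(dout)[3L])
  grads <- list()
  for (j in rev(seq_len(n_fc))) {
    if (isTRUE(attr(p, "dropout")) && j == n_fc) {
      # dropout sits between fc(n_fc-1) and the theta head in forward order;
      # on the way back it is crossed after the head's backward
    }
    bk <- dense_backward(dh, cache[[paste0("fc", j)]])
    grads[[paste0("fc", j)]] <- bk$grads
    dh <- bk$dx
    if (isTRUE(attr(p, "dropout")) && j == n_fc) {
      dh <- dropout_backward(dh, cache$dropout)
    }
  }
  dh_seq <- dh
  dim(dh_seq) <- c(B, F_, ncol(dh))
  lb <- lstm_backward(dh_seq, cache$lstm)
  grads$lstm <- lb$grads
  list(dx = lb$dx, grads = grads)
}

# project theta (B,F,K) through a basis matrix M (len x K) -> (B,F,len)
basis_project <- function(theta, M) {
  d <- dim(theta)
  out <- matrix(theta, d[1L] * d[2L], d[3L]) %*% t(M)
  dim(out) <- c(d[1L], d[2L], nrow(M))
  out
}

basis_project_back <- function(dout, M) {
  d <- dim(dout)
  dth <- matrix(dout, d[1L] * d[2L], d[3L]) %*% M
  dim(dth) <- c(d[1L], d[2L], ncol(M))
  dth
}

#' Run the dual-residual stack
#'
#' Chains trend -> seasonal -> generic block 1 -> generic block 2. Each
#' stage receives the previous stage's residual `x_l = x_{l-1} -
#' backcast_{l-1}` (exactly, no rescaling); the interpretable blocks emit
#' backcast and forecast from one shared theta through their fixed basis
#' pair, so their decomposition is directly readable. Generic block 2
#' consumes generic block 1's horizon-length forecast; the residual stream
#' passed to attention is the sum of the two generic forecasts.
#'
#' @param model a `pedvol_model`.
#' @param x0 input array, batch x features x backcast (B, F, L).
#' @param train logical; enables dropout.
#' @return a `module_streams` list: `trend`, `seasonal` (each with
#'   `backcast`, `forecast`, `theta`), `residual1`, `residual2` (each with
#'   `forecast`), `residual_inputs` (x0..x3), and `cache` when training.
#' @export
stack_forward <- function(model, x0, train = FALSE) {
  p <- model$params; cfg <- model$cfg; bs <- model$bases
  tr <- trunk_forward(x0, p$trend, cfg, train)
  back_t <- basis_project(tr$out, bs$trend$back)
  fore_t <- basis_project(tr$out, bs$trend$fore)
  x1 <- x0 - back_t
  se <- trunk_forward(x1, p$seasonal, cfg, train)
  back_s <- basis_project(se$out, bs$seasonal$back)
  fore_s <- basis_project(se$out, bs$seasonal$fore)
  x2 <- x1 - back_s
  b1 <- trunk_forward(x2, p$basic1, cfg, train)
  b2 <- trunk_forward(b1$out, p$basic2, cfg, train)
  structure(list(
    trend = list(backcast = back_t, forecast = fore_t, theta = tr$out),
    seasonal = list(backcast = back_s, forecast = fore_s, theta = se$out),
    residual1 = list(forecast = b1$out),
    residual2 = list(forecast = b2$out),
    residual_inputs = list(x0 = x0, x1 = x1, x2 = x2, x3 = b1$out),
    cache = list(trend = tr$cache, seasonal = se$cache,
                 basic1 = b1$cache, basic2 = b2$cache)),
    class = "module_streams")
}

# --- attention fusion --------------------------------------------------------

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1L, max))
  e / rowSums(e)
}

#' Fuse module streams with three-head feature-channel attention
#'
#' Head k applies scaled dot-product attention across the F feature
#' channels of module k's horizon-length forecast (head 1 = trend, head 2 =
#' seasonal, head 3 = residual). The concatenated heads are projected by a
#' learned output map and a final linear layer to the fused H-step
#' forecast. The per-head F x F attention matrices (row-stochastic) are
#' returned for heatmap-style inspection.
#'
#' @param model a `pedvol_model`.
#' @param streams list of three forecast arrays (B, F, H): trend, seasonal,
#'   residual. A `module_streams` object is also accepted.
#' @return list with `fused` (B, F, H), `weights` (B x 3 x F x F array),
#'   and `cache`.
#' @export
attention_fuse <- function(model, streams) {
  if (inherits(streams, "module_streams")) {
    streams <- list(streams$trend$forecast, streams$seasonal$forecast,
                    streams$residual1$forecast + streams$residual2$forecast)
  }
  d1 <- dim(streams[[1L]])
  for (k in 2:3) {
    if (!identical(dim(streams[[k]]), d1)) stop("stream shape mismatch")
  }
  B <- d1[1L]; F_ <- d1[2L]; H <- d1[3L]
  p <- model$params$attn
  d <- ncol(p$h1$Wq)
  heads <- list(p$h1, p$h2, p$h3)
  O_cat <- matrix(0, B * F_, 3L * d)
  W_all <- array(0, c(B, 3L, F_, F_))
  hcache <- vector("list", B)
  for (b in seq_len(B)) {
    hc <- vector("list", 3L)
    for (k in 1:3) {
      Z <- matrix(streams[[k]][b, , ], F_, H)
      hp <- heads[[k]]
      Q <- Z %*% hp$Wq; K <- Z %*% hp$Wk; V <- Z %*% hp$Wv
      S_ <- tcrossprod(Q, K) / sqrt(d)
      A <- softmax_rows(S_)
      O <- A %*% V
      # rows b, b+B, ... so that dim<-c(B, F, H) reshapes are batch-major
      O_cat[seq.int(b, by = B, length.out = F_), (k - 1L) * d + seq_len(d)] <- O
      W_all[b, k, , ] <- A
      hc[[k]] <- list(Z = Z, Q = Q, K = K, V = V, A = A)
    }
    hcache[[b]] <- hc
  }
  o1 <- dense_forward(O_cat, p$out, "linear")
  o2 <- dense_forward(o1$out, p$fc, "linear")
  fused <- o2$out
  dim(fused) <- c(B, F_, H)
  list(fused = fused, weights = W_all,
       cache = list(hcache = hcache, out = o1$cache, fc = o2$cache,
                    dims = c(B = B, F_ = F_, H = H, d = d)))
}

attention_backward <- function(dfused, model, cache) {
  dm <- cache$dims; B <- dm[["B"]]; F_ <- dm[["F_"]]; H <- dm[["H"]]; d <- dm[["d"]]
  p <- model$params$attn
  heads <- list(p$h1, p$h2, p$h3)
  b2 <- dense_backward(matrix(dfused, B * F_, H), cache$fc)
  b1 <- dense_backward(b2$dx, cache$out)
  dO_cat <- b1$dx
  dstreams <- list(array(0, c(B, F_, H)), array(0, c(B, F_, H)),
                   array(0, c(B, F_, H)))
  hg <- lapply(1:3, function(k) list(Wq = matrix(0, H, d), Wk = matrix(0, H, d),
                                     Wv = matrix(0, H, d)))
  inv_sqrt_d <- 1 / sqrt(d)
  for (b in seq_len(B)) {
    rows <- seq.int(b, by = B, length.out = F_)
    for (k in 1:3) {
      hc <- cache$hcache[[b]][[k]]
      hp <- heads[[k]]
      dO <- dO_cat[rows, (k - 1L) * d + seq_len(d), drop = FALSE]
      dA <- tcrossprod(dO, hc$V)
      dV <- crossprod(hc$A, dO)
      dS <- hc$A * (dA - rowSums(dA * hc$A))
      dQ <- dS %*% hc$K * inv_sqrt_d
      dK <- crossprod(dS, hc$Q) * inv_sqrt_d
      hg[[k]]$Wq <- hg[[k]]$Wq + crossprod(hc$Z, dQ)
      hg[[k]]$Wk <- hg[[k]]$Wk + crossprod(hc$Z, dK)
      hg[[k]]$Wv <- hg[[k]]$Wv + crossprod(hc$Z, dV)
      dZ <- dQ %*% t(hp$Wq) + dK %*% t(hp$Wk) + dV %*% t(hp$Wv)
      dstreams[[k]][b, , ] <- dZ
    }
  }
  list(dstreams = dstreams,
       grads = list(h1 = hg[[1L]], h2 = hg[[2L]], h3 = hg[[3L]],
                    out = b1$grads, fc = b2$grads))
}

# --- full forward / backward -------------------------------------------------

model_forward <- function(model, x0, train = FALSE) {
  st <- stack_forward(model, x0, train)
  fu <- attention_fuse(model, st)
  list(fused = fu$fused, streams = st, attention = fu)
}

model_backward <- function(model, fwd, dfused, dx2_pen = NULL,
                           dtheta_s_pen = NULL) {
  p <- model$params; bs <- model$bases
  st <- fwd$streams
  ab <- attention_backward(dfused, model, fwd$attention$cache)
  # residual stream gradient reaches both generic forecasts
  d_f2 <- ab$dstreams[[3L]]
  bk2 <- trunk_backward(d_f2, p$basic2, st$cache$basic2)
  d_f1 <- ab$dstreams[[3L]] + bk2$dx
  bk1 <- trunk_backward(d_f1, p$basic1, st$cache$basic1)
  dx2 <- bk1$dx
  if (!is.null(dx2_pen)) dx2 <- dx2 + dx2_pen
  # seasonal: forecast grad from attention, backcast grad from x2 = x1 - back_s
  dtheta_s <- basis_project_back(ab$dstreams[[2L]], bs$seasonal$fore) +
    basis_project_back(-dx2, bs$seasonal$back)
  if (!is.null(dtheta_s_pen)) dtheta_s <- dtheta_s + dtheta_s_pen
  bks <- trunk_backward(dtheta_s, p$seasonal, st$cache$seasonal)
  dx1 <- dx2 + bks$dx
  dtheta_t <- basis_project_back(ab$dstreams[[1L]], bs$trend$fore) +
    basis_project_back(-dx1, bs$trend$back)
  bkt <- trunk_backward(dtheta_t, p$trend, st$cache$trend)
  list(trend = bkt$grads, seasonal = bks$grads,
       basic1 = bk1$grads, basic2 = bk2$grads, attn = ab$grads)
}

#' Forecast a batch of windows
#'
#' Evaluation-mode forward pass (dropout off, deterministic).
#'
#' @param model a `pedvol_model`.
#' @param inputs window inputs, N x L x F (as produced by [make_windows()]).
#' @param chunk batch chunk size for memory control.
#' @return list with `forecast` (N x H x F), module forecast streams
#'   `trend`, `seasonal`, `residual` (each N x H x F), and `attention`
#'   (N x 3 x F x F).
#' @export
model_predict <- function(model, inputs, chunk = 64L) {
  UseMethod("model_predict")
}

#' @rdname model_predict
#' @export
model_predict.pedvol_model <- function(model, inputs, chunk = 64L) {
  d <- dim(inputs); N <- d[1L]; F_ <- d[3L]
  H <- model$cfg$window$horizon
  out <- array(0, c(N, H, F_))
  s_tr <- array(0, c(N, H, F_)); s_se <- array(0, c(N, H, F_))
  s_re <- array(0, c(N, H, F_))
  attw <- array(0, c(N, 3L, F_, F_))
  for (start in seq.int(1L, N, by = chunk)) {
    idx <- start:min(start + chunk - 1L, N)
    x0 <- aperm(inputs[idx, , , drop = FALSE], c(1L, 3L, 2L))
    fw <- model_forward(model, x0, train = FALSE)
    out[idx, , ] <- aperm(fw$fused, c(1L, 3L, 2L))
    s_tr[idx, , ] <- aperm(fw$streams$trend$forecast, c(1L, 3L, 2L))
    s_se[idx, , ] <- aperm(fw$streams$seasonal$forecast, c(1L, 3L, 2L))
    s_re[idx, , ] <- aperm(fw$streams$residual1$forecast +
                             fw$streams$residual2$forecast, c(1L, 3L, 2L))
    attw[idx, , , ] <- fw$attention$weights
  }
  list(forecast = out, trend = s_tr, seasonal = s_se, residual = s_re,
       attention = attw)
}

#' Train the network
#'
#' Minimizes mean squared error between the fused forecast and the window
#' targets with Adam. Dropout is active only during training; shuffling and
#' dropout masks derive from `tc$seed`, so identical seeds and configs give
#' identical loss trajectories in single-threaded BLAS mode.
#'
#' @param model a `pedvol_model`.
#' @param windows a `window_set` of training windows.
#' @param tc a [train_config()].
#' @param val_windows optional `window_set` for per-epoch validation loss.
#' @param verbose print per-epoch losses.
#' @return list with the trained `model` and `history` (data.frame with
#'   epoch, train_loss, val_loss, seconds).
#' @export
train_model <- function(model, windows, tc = train_config(),
                        val_windows = NULL, verbose = FALSE) {
  N <- dim(windows$inputs)[1L]
  if (is.null(N) || N < 1L) stop("empty window set")
  if (dim(windows$targets)[2L] != model$cfg$window$horizon) {
    stop("window horizon does not match model config")
  }
  set.seed(tc$seed)
  flat <- flatten_params(model$params)
  opt <- adam_init(flat)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), seconds = numeric())
  for (ep in seq_len(tc$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    ord <- sample.int(N)
    ep_loss <- 0; n_batch <- 0L
    for (start in seq.int(1L, N, by = tc$batch_size)) {
      idx <- ord[start:min(start + tc$batch_size - 1L, N)]
      x0 <- aperm(windows$inputs[idx, , , drop = FALSE], c(1L, 3L, 2L))
      y <- aperm(windows$targets[idx, , , drop = FALSE], c(1L, 3L, 2L))
      fw <- model_forward(model, x0, train = TRUE)
      err <- fw$fused - y
      loss <- mean(err^2)
      dx2_pen <- NULL
      if (tc$decomp_penalty > 0) {
        x2 <- fw$streams$residual_inputs$x2
        loss <- loss + tc$decomp_penalty * mean(x2^2)
        dx2_pen <- 2 * tc$decomp_penalty * x2 / length(x2)
      }
      dth_pen <- NULL
      if (tc$seasonal_center > 0) {
        th <- fw$streams$seasonal$theta
        dth_pen <- array(0, dim(th))
        th_c <- th[, , 1L, drop = FALSE]
        loss <- loss + tc$seasonal_center * mean(th_c^2)
        dth_pen[, , 1L] <- 2 * tc$seasonal_center * th_c / length(th_c)
      }
      grads <- model_backward(model, fw, 2 * err / length(err), dx2_pen,
                              dth_pen)
      up <- adam_step(flat, flatten_params(grads), opt, lr = tc$learning_rate)
      flat <- up$flat; opt <- up$state
      model$params <- unflatten_params(flat, model$params)
      # window-weighted so the epoch loss is invariant to batch partitioning
      ep_loss <- ep_loss + loss * length(idx); n_batch <- n_batch + length(idx)
    }
    vl <- NA_real_
    if (!is.null(val_windows)) {
      pv <- model_predict(model, val_windows$inputs)
      vl <- mean((pv$forecast - val_windows$targets)^2)
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / n_batch,
                                   val_loss = vl,
                                   seconds = proc.time()[["elapsed"]] - t0))
    if (verbose) {
      message(sprintf("epoch %3d  train %.6f  val %s", ep, ep_loss / n_batch,
                      ifelse(is.na(vl), "-", sprintf("%.6f", vl))))
    }
  }
  list(model = model, history = hist)
}

#' Average attention weights over a window set
#'
#' @param model a `pedvol_model`.
#' @param windows a `window_set`.
#' @param feature_names labels for the F axis (defaults to the window set's).
#' @return array (3, F, F) of mean per-head row-stochastic attention
#'   weights, with head / feature dimnames.
#' @export
export_attention <- function(model, windows,
                             feature_names = windows$feature_names) {
  pr <- model_predict(model, windows$inputs)
  m <- apply(pr$attention, c(2L, 3L, 4L), mean)
  dimnames(m) <- list(head = c("trend", "seasonal", "residual"),
                      query = feature_names, key = feature_names)
  m
}

#' Write attention weight matrices as CSV (one file per head)
#' @param weights array (3, F, F) from [export_attention()].
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
write_attention_csv <- function(weights, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(3L)
  for (k in 1:3) {
    paths[k] <- file.path(dir, paste0("attention_head_",
                                      dimnames(weights)[[1L]][k], ".csv"))
    utils::write.csv(weights[k, , ], paths[k], row.names = TRUE)
  }
  invisible(paths)
}

# --- checkpointing (text-only, self-describing) ------------------------------

#' Save / load a model checkpoint directory
#'
#' The checkpoint is a directory holding `config.json` (all model and
#' window configuration fields plus the package version) and
#' `weights.json` (flat parameter list with dimensions, full precision),
#' so a checkpoint is self-describing and portable.
#'
#' @param model a `pedvol_model`.
#' @param dir checkpoint directory.
#' @return `dir` (save) or a `pedvol_model` (load).
#' @export
save_checkpoint <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfgl <- unclass(model$cfg)
  cfgl$window <- unclass(cfgl$window)
  jsonlite::write_json(list(config = cfgl, seed = model$seed,
                            package_version = as.character(utils::packageVersion("pedvol"))),
                       file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  flat <- flatten_params(model$params)
  # doubles as %.17g strings: exact binary round trip, still plain text
  ser <- lapply(flat, function(x) list(dim = if (is.null(dim(x))) length(x) else dim(x),
                                       data = sprintf("%.17g", as.vector(x))))
  jsonlite::write_json(ser, file.path(dir, "weights.json"))
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  w <- meta$config$window
  cfg <- model_config(lstm_units = meta$config$lstm_units,
                      fc1_units = meta$config$fc1_units,
                      fc2_units = meta$config$fc2_units,
                      dropout_rate = meta$config$dropout_rate,
                      poly_degree = meta$config$poly_degree,
                      fourier_order = meta$config$fourier_order,
                      season_period = meta$config$season_period,
                      n_features = meta$config$n_features,
                      window = window_spec(w$horizon, w$ratio, w$stride),
                      d_attn = meta$config$d_attn)
  model <- build_model(cfg, seed = meta$seed)
  ser <- jsonlite::read_json(file.path(dir, "weights.json"), simplifyVector = TRUE)
  flat <- flatten_params(model$params)
  for (k in names(flat)) {
    v <- as.numeric(ser[[k]]$data)
    dims <- as.integer(ser[[k]]$dim)
    if (length(dims) > 1L) dim(v) <- dims
    flat[[k]] <- v
  }
  model$params <- unflatten_params(flat, model$params)
  model
}
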