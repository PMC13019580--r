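# Shared fixtures: tiny configs, toy panels, oracle stubs.

tiny_window <- function(horizon = 4L, ratio = 2L) window_spec(horizon, ratio)

tiny_config <- function(n_features = 3L, horizon = 4L, ratio = 2L,
                        dropout = 0) {
  model_config(lstm_units = 5L, fc1_units = 6L, fc2_units = 4L,
               dropout_rate = dropout, n_features = n_features,
               window = window_spec(horizon, ratio), season_period = 6)
}

random_panel <- function(T_ = 40L, F_ = 3L, seed = 1L,
                         start = as.Date("2020-01-01")) {
  set.seed(seed)
  panel_series(start + seq_len(T_) - 1L,
               matrix(stats::runif(T_ * F_, 0, 100), T_, F_),
               paste0("f", seq_len(F_)))
}

write_tmp_panel <- function(panel) {
  path <- tempfile(fileext = ".csv")
  write_panel_csv(panel, path)
  path
}

# a stub with the pedvol_model interface whose forecast is the true future:
# panels built from it satisfy zero-error invariants in both modes.
oracle_model <- function(panel, spec) {
  structure(list(panel = panel, cfg = list(window = spec,
                                           n_features = ncol(panel$values))),
            class = c("oracle_model", "pedvol_model"))
}

# model_predict dispatches on the concrete forward; the oracle overrides it
# by looking up true future rows via the window's own input values.
model_predict_oracle <- function(om, inputs) {
  spec <- om$cfg$window
  L <- spec$backcast; H <- spec$horizon
  N <- dim(inputs)[1L]; F_ <- dim(inputs)[3L]
  out <- array(0, c(N, H, F_))
  vals <- om$panel$values
  T_ <- nrow(vals)
  for (k in seq_len(N)) {
    # locate the window by matching its last input row (panels are random,
    # rows unique with probability 1)
    last <- inputs[k, L, ]
    pos <- which(apply(vals, 1L, function(r) isTRUE(all.equal(r, last,
                                                              check.attributes = FALSE))))
    stopifnot(length(pos) == 1L, pos + H <= T_)
    out[k, , ] <- vals[(pos + 1L):(pos + H), ]
  }
  list(forecast = out,
       trend = out * 0, seasonal = out * 0, residual = out * 0,
       attention = array(1 / F_, c(N, 3L, F_, F_)))
}

registerS3method("model_predict", "oracle_model", model_predict_oracle,
                 envir = asNamespace("pedvol"))

# tiny trained-free model for structural tests
tiny_model <- function(seed = 1L, ...) build_model(tiny_config(...), seed = seed)
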