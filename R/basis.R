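#' Polynomial trend basis pair
#'
#' Fixed (non-trainable) power-matrix basis `T = [1, t, ..., t^p]` used by
#' the trend block: the block learns only the coefficient vector theta, and
#' both backcast and forecast are projections of the same theta, so the
#' forecast extrapolates the backcast polynomial smoothly.
#'
#' The time grid is normalized by the backcast length for numerical
#' stability. Two anchor conventions are supported:
#' \describe{
#'   \item{`"forecast_start"`}{(default) backcast grid `t_j = (j - L)/L`,
#'     `j = 0..L-1` (so it covers `[-1, 0)`), forecast grid `t_j = j/L`,
#'     `j = 0..H-1`. Zero sits at the forecast origin.}
#'   \item{`"backcast_start"`}{backcast grid `t_j = j/L`, `j = 0..L-1`,
#'     forecast continuing at `t_j = (L + j)/L`.}
#' }
#'
#' @param L backcast length (rows of `back`).
#' @param H forecast horizon (rows of `fore`).
#' @param p polynomial degree (>= 0); the basis has `K = p + 1` columns.
#' @param anchor `"forecast_start"` or `"backcast_start"`.
#' @return a `basis_pair`: list with `back` (L x K), `fore` (H x K), `K`,
#'   and `kind = "trend"`.
#' @export
make_trend_basis <- function(L, H, p = 3L,
                             anchor = c("forecast_start", "backcast_start")) {
  anchor <- match.arg(anchor)
  if (p < 0L) stop("p must be >= 0")
  g <- switch(anchor,
    forecast_start = list(back = (seq_len(L) - 1 - L) / L,
                          fore = (seq_len(H) - 1) / L),
    backcast_start = list(back = (seq_len(L) - 1) / L,
                          fore = (L + seq_len(H) - 1) / L))
  K <- p + 1L
  pow <- function(t) outer(t, 0:p, `^`)
  structure(list(back = pow(g$back), fore = pow(g$fore), K = K, kind = "trend"),
            class = "basis_pair")
}

#' Truncated Fourier seasonal basis pair
#'
#' Fixed basis `S = [1, cos(2*pi*t), ..., cos(2*pi*i*t), sin(2*pi*t), ...,
#' sin(2*pi*i*t)]` with `t` in units of the seasonal period (90 steps by
#' default), giving `K = 2i + 1` columns. The forecast grid continues the
#' backcast grid, so seasonal patterns extrapolate in phase; rows `period`
#' steps apart are identical.
#'
#' @param L backcast length.
#' @param H forecast horizon.
#' @param i Fourier order (>= 1).
#' @param period seasonal period in steps (default 90).
#' @param anchor grid convention, see [make_trend_basis()].
#' @return a `basis_pair` with `K = 2i + 1` and `kind = "seasonal"`.
#' @export
make_seasonal_basis <- function(L, H, i = 3L, period = 90,
                                anchor = c("forecast_start", "backcast_start")) {
  anchor <- match.arg(anchor)
  if (i < 1L) stop("Fourier order i must be >= 1")
  if (period <= 0) stop("period must be > 0")
  g <- switch(anchor,
    forecast_start = list(back = (seq_len(L) - 1 - L) / period,
                          fore = (seq_len(H) - 1) / period),
    backcast_start = list(back = (seq_len(L) - 1) / period,
                          fore = (L + seq_len(H) - 1) / period))
  four <- function(t) {
    arg <- 2 * pi * outer(t, seq_len(i))  # length(t) x i even when length(t) == 1
    cbind(1, cos(arg), sin(arg))
  }
  structure(list(back = four(g$back), fore = four(g$fore), K = 2L * i + 1L,
                 kind = "seasonal"),
            class = "basis_pair")
}
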