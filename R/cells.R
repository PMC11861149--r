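# Reference (single-sample) implementations of the three recurrent cells.
# These plain-R steps are the readable ground truth for the batched
# RcppArmadillo layer kernels; equivalence is enforced by tests.
#
# Orientation convention (shared with the C++ kernels): inputs are row
# vectors, weights are (fan_in x fan_out), gate blocks packed [i, f, z, o].

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One step of the vanilla LSTM cell-state recurrence
#'
#' `C_t = f_t * C_{t-1} + i_t * z_t`, completed with the standard output
#' `h_t = o_t * tanh(C_t)`. Gate activations are supplied directly, which
#' makes the recurrence itself testable in isolation.
#'
#' @param state list with numeric vectors `c` (cell state) and `h` (hidden
#'   state).
#' @param gates list with vectors `i`, `f`, `o` (gate activations in (0,1))
#'   and `z` (candidate cell state in (-1,1)).
#' @return updated state list.
#' @export
lstm_step <- function(state, gates) {
  stopifnot(is.list(state), is.list(gates))
  v <- c(state$c, gates$i, gates$f, gates$o, gates$z)
  if (!all(is.finite(v))) stop("non-finite state or gate values", call. = FALSE)
  H <- length(state$c)
  stopifnot(lengths(gates[c("i", "f", "o", "z")]) == H)
  c_new <- gates$f * state$c + gates$i * gates$z
  list(c = c_new, h = gates$o * tanh(c_new))
}

#' One step of the sLSTM cell (exponential gating with normalizer state)
#'
#' Pre-activations `[i~, f~, z~, o~] = x W + h_{t-1} U + b`; input and
#' forget gates pass through the exponential (`i_t = exp(i~_t)`,
#' `f_t = exp(f~_t)`), computed in a log-domain stabilized form with the
#' running max-shift `m_t` so that the gates never overflow. The state
#' recurrences are `c_t = f_t c_{t-1} + i_t z_t` and the normalizer
#' `n_t = f_t n_{t-1} + i_t`; the output is `h_t = o_t * (c_t / n_t)` with
#' sigmoid `o_t` and tanh candidate `z_t`. The ratio `c_t / n_t` is
#' invariant to the stabilizer shift, so the stabilized states equal the
#' naive ones up to a common factor `exp(-m_t)`.
#'
#' @param state list with vectors `c`, `n`, `h`, `m` (use
#'   [slstm_init_state()] for the zero state).
#' @param x input vector.
#' @param params list with `W` (`length(x)` x 4H), `U` (H x 4H), `b` (4H).
#' @return updated state list; gate activations `i`, `f`, `o` and candidate
#'   `z` are attached as attribute `gates`.
#' @export
slstm_step <- function(state, x, params) {
  H <- length(state$c)
  a <- drop(x %*% params$W + state$h %*% params$U) + params$b
  stopifnot(length(a) == 4 * H)
  it_ <- a[1:H]; ft_ <- a[H + 1:H]
  z <- tanh(a[2 * H + 1:H]); o <- sigmoid(a[3 * H + 1:H])
  m_new <- pmax(ft_ + state$m, it_)
  i <- exp(it_ - m_new)
  f <- exp(ft_ + state$m - m_new)
  c_new <- f * state$c + i * z
  n_new <- f * state$n + i
  out <- list(c = c_new, n = n_new, h = o * (c_new / n_new), m = m_new)
  attr(out, "gates") <- list(i = i, f = f, o = o, z = z)
  out
}

#' Zero initial state for [slstm_step()]
#' @param hidden_size number of hidden units.
#' @return list with zero vectors `c`, `n`, `h`, `m`.
#' @export
slstm_init_state <- function(hidden_size) {
  z <- numeric(hidden_size)
  list(c = z, n = z, h = z, m = z)
}

#' One step of the mLSTM cell (matrix memory with query readout)
#'
#' The memory is a square `H x H` matrix updated as
#' `C_t = f_t (*) C_{t-1} + i_t (*) tanh(W_c [h_{t-1}, x_t] + b_c)` with
#' sigmoid gates broadcast row-wise, a normalizer
#' `n_t = f_t * n_{t-1} + i_t`, and readout
#' `h_t = C_t q_t / max(n_t' q_t, 1)` where the query `q_t = x_t W_q + b_q`
#' is a learned projection of the input. The denominator clamp at 1 keeps
#' the readout bounded before the normalizer has accumulated gate mass.
#'
#' @param state list with `C` (H x H matrix) and `n` (length-H vector); use
#'   [mlstm_init_state()].
#' @param x input vector.
#' @param h_prev previous hidden output (length H).
#' @param params list with `Wg` (`(H + length(x))` x 2H), `bg`, `Wc`
#'   (`(H + length(x))` x H^2), `bc`, `Wq` (`length(x)` x H), `bq`.
#' @return list with updated `C`, `n` and the hidden readout `h`.
#' @export
mlstm_step <- function(state, x, h_prev, params) {
  H <- length(state$n)
  stopifnot(is.matrix(state$C), nrow(state$C) == H, ncol(state$C) == H,
            length(h_prev) == H)
  q <- drop(x %*% params$Wq) + params$bq
  if (length(q) != ncol(state$C)) {
    stop("query dimension (", length(q), ") does not match memory columns (",
         ncol(state$C), ")", call. = FALSE)
  }
  u <- c(h_prev, x)
  g <- sigmoid(drop(u %*% params$Wg) + params$bg)
  i <- g[1:H]; f <- g[H + 1:H]
  M <- matrix(tanh(drop(u %*% params$Wc) + params$bc), H, H)
  C_new <- state$C * f + M * i        # recycling along rows = row broadcast
  n_new <- f * state$n + i
  den <- max(sum(n_new * q), 1)
  list(C = C_new, n = n_new, h = drop(C_new %*% q) / den)
}

#' Zero initial state for [mlstm_step()]
#' @param hidden_size number of hidden units (memory is hidden x hidden).
#' @return list with zero matrix `C` and zero vector `n`.
#' @export
mlstm_init_state <- function(hidden_size) {
  list(C = matrix(0, hidden_size, hidden_size), n = numeric(hidden_size))
}
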