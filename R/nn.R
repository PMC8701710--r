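# Numerical primitives for the decoder side: masked softmax helpers and an
# LSTM cell with a hand-derived backward pass. The encoder's fused
# transformer layer (attention + feed-forward + layer norms, forward and
# backward) is compiled code in src/enc_layer.cpp; everything here is
# plain matrix algebra on (positions x width) shapes.

#' @keywords internal
nn_softmax <- function(s) {
  m <- max(s)
  e <- exp(s - m)
  e / sum(e)
}

# Row-wise softmax for attention score matrices.
#' @keywords internal
nn_softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

# Masked softmax over a vector; inadmissible entries get exactly 0.
#' @keywords internal
nn_softmax_masked <- function(s, mask) {
  p <- numeric(length(s))
  if (!any(mask)) return(p)
  p[mask] <- nn_softmax(s[mask])
  p
}

#' @keywords internal
nn_sigmoid <- function(x) 1 / (1 + exp(-x))

# LSTM cell ----------------------------------------------------------------

#' @keywords internal
lstm_forward <- function(x, h_prev, c_prev, Wx, Wh, b) {
  H <- length(h_prev)
  z <- as.numeric(Wx %*% x + Wh %*% h_prev + b)
  i <- nn_sigmoid(z[1:H])
  f <- nn_sigmoid(z[(H + 1):(2 * H)])
  o <- nn_sigmoid(z[(2 * H + 1):(3 * H)])
  g <- tanh(z[(3 * H + 1):(4 * H)])
  c_new <- f * c_prev + i * g
  tc <- tanh(c_new)
  h_new <- o * tc
  list(h = h_new, c = c_new, i = i, f = f, o = o, g = g, tc = tc)
}

#' @keywords internal
lstm_backward <- function(dh, dc, cache, x, h_prev, c_prev, Wx, Wh) {
  i <- cache$i; f <- cache$f; o <- cache$o; g <- cache$g; tc <- cache$tc
  do_ <- dh * tc
  dc_total <- dc + dh * o * (1 - tc^2)
  di <- dc_total * g
  df <- dc_total * c_prev
  dg <- dc_total * i
  dzi <- di * i * (1 - i)
  dzf <- df * f * (1 - f)
  dzo <- do_ * o * (1 - o)
  dzg <- dg * (1 - g^2)
  dz <- c(dzi, dzf, dzo, dzg)
  list(dx = as.numeric(crossprod(Wx, dz)),
       dh_prev = as.numeric(crossprod(Wh, dz)),
       dc_prev = dc_total * f,
       dz = dz)
}

# Gradient container helpers ----------------------------------------------

# Accumulates gradients for a named parameter list; missing entries are
# created as zeros of the parameter's shape on first touch.
#' @keywords internal
grad_env <- function() new.env(parent = emptyenv())

#' @keywords internal
g_add <- function(ge, name, value) {
  cur <- ge[[name]]
  ge[[name]] <- if (is.null(cur)) value else cur + value
  invisible(NULL)
}

#' @keywords internal
grads_as_list <- function(ge) as.list(ge)
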