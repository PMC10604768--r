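# Multi-layer unidirectional LSTM with full backpropagation through time.
# Batch-major sequences: X is [N, T, D]; gate order in the packed weight
# matrices is (input, forget, cell, output).

lstm_param_names <- function(prefix, n_layers) {
  unlist(lapply(seq_len(n_layers), function(l)
    paste0(prefix, "_l", l, c("_Wx", "_Wh", "_b"))))
}

lstm_init_params <- function(prefix, input_dim, hidden, n_layers) {
  params <- list()
  for (l in seq_len(n_layers)) {
    d_in <- if (l == 1) input_dim else hidden
    params[[paste0(prefix, "_l", l, "_Wx")]] <- glorot(d_in, hidden,
                                                       c(d_in, 4 * hidden))
    params[[paste0(prefix, "_l", l, "_Wh")]] <- glorot(hidden, hidden,
                                                       c(hidden, 4 * hidden))
    b <- rep(0, 4 * hidden)
    b[(hidden + 1):(2 * hidden)] <- 1   # forget-gate bias at 1
    params[[paste0(prefix, "_l", l, "_b")]] <- b
  }
  params
}

# X: [N, T, D] -> list(h_all [N, T, H] of the top layer, h_last, cache)
lstm_stack_fwd <- function(X, params, prefix, hidden, n_layers) {
  N <- dim(X)[1]; T_len <- dim(X)[2]
  layer_caches <- vector("list", n_layers)
  inp <- X
  for (l in seq_len(n_layers)) {
    Wx <- params[[paste0(prefix, "_l", l, "_Wx")]]
    Wh <- params[[paste0(prefix, "_l", l, "_Wh")]]
    b <- params[[paste0(prefix, "_l", l, "_b")]]
    h <- matrix(0, N, hidden)
    cc <- matrix(0, N, hidden)
    steps <- vector("list", T_len)
    H_all <- array(0, c(N, T_len, hidden))
    for (t in seq_len(T_len)) {
      xt <- inp[, t, , drop = FALSE]
      dim(xt) <- c(N, dim(inp)[3])
      a <- xt %*% Wx + h %*% Wh + rep(b, each = N)
      i <- 1 / (1 + exp(-a[, 1:hidden, drop = FALSE]))
      f <- 1 / (1 + exp(-a[, (hidden + 1):(2 * hidden), drop = FALSE]))
      g <- tanh(a[, (2 * hidden + 1):(3 * hidden), drop = FALSE])
      o <- 1 / (1 + exp(-a[, (3 * hidden + 1):(4 * hidden), drop = FALSE]))
      c_prev <- cc
      cc <- f * c_prev + i * g
      tc <- tanh(cc)
      h <- o * tc
      H_all[, t, ] <- h
      steps[[t]] <- list(xt = xt, i = i, f = f, g = g, o = o,
                         c_prev = c_prev, cc = cc, tc = tc)
    }
    layer_caches[[l]] <- list(steps = steps, H_all = H_all)
    inp <- H_all
  }
  list(h_all = inp, h_last = inp[, T_len, , drop = TRUE],
       cache = list(layers = layer_caches, N = N, T_len = T_len,
                    in_dim = dim(X)[3]))
}

# dH_all: gradient on the top layer's per-step outputs [N, T, H] (may be all
# zero except the last step).  Returns dX and parameter gradients.
lstm_stack_bwd <- function(dH_all, cache, params, prefix, hidden, n_layers) {
  N <- cache$N; T_len <- cache$T_len
  grads <- list()
  dH_top <- dH_all
  for (l in rev(seq_len(n_layers))) {
    Wx <- params[[paste0(prefix, "_l", l, "_Wx")]]
    Wh <- params[[paste0(prefix, "_l", l, "_Wh")]]
    lc <- cache$layers[[l]]
    d_in <- nrow(Wx)
    dWx <- array(0, dim(Wx)); dWh <- array(0, dim(Wh)); db <- rep(0, 4 * hidden)
    dX_l <- array(0, c(N, T_len, d_in))
    dh_next <- matrix(0, N, hidden)
    dc_next <- matrix(0, N, hidden)
    for (t in rev(seq_len(T_len))) {
      st <- lc$steps[[t]]
      dh <- dH_top[, t, , drop = FALSE]
      dim(dh) <- c(N, hidden)
      dh <- dh + dh_next
      do <- dh * st$tc
      dcc <- dh * st$o * (1 - st$tc^2) + dc_next
      di <- dcc * st$g
      dg <- dcc * st$i
      df <- dcc * st$c_prev
      dc_next <- dcc * st$f
      da <- cbind(di * st$i * (1 - st$i),
                  df * st$f * (1 - st$f),
                  dg * (1 - st$g^2),
                  do * st$o * (1 - st$o))
      h_prev <- if (t == 1) matrix(0, N, hidden) else {
        hp <- lc$H_all[, t - 1, , drop = FALSE]; dim(hp) <- c(N, hidden); hp
      }
      dWx <- dWx + crossprod(st$xt, da)
      dWh <- dWh + crossprod(h_prev, da)
      db <- db + colSums(da)
      dh_next <- da %*% t(Wh)
      dX_l[, t, ] <- da %*% t(Wx)
    }
    grads[[paste0(prefix, "_l", l, "_Wx")]] <- dWx
    grads[[paste0(prefix, "_l", l, "_Wh")]] <- dWh
    grads[[paste0(prefix, "_l", l, "_b")]] <- db
    dH_top <- dX_l
  }
  list(dX = dH_top, grads = grads)
}
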