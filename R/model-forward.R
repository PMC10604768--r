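# Batched forward and backward passes for the three autoencoder families.
# Batches are [N, P, W] arrays (samples x parcels x time).  The backward
# passes return named gradient lists aligned with model$params and are
# checked against finite differences in the tests.

# ---- condition embedding ---------------------------------------------------

# raw condition triplet: (min-max age, sex code M=1/F=0, group code ASD=1/TD=0)
cond_raw_matrix <- function(phenotypes, config) {
  a <- config$age_range
  age <- phenotypes$age
  if (any(age < a[1] | age > a[2])) {
    warning("age outside configured bounds [", a[1], ", ", a[2],
            "]; clipping", call. = FALSE)
    age <- pmin(pmax(age, a[1]), a[2])
  }
  cbind(age = (age - a[1]) / (a[2] - a[1]),
        sex = as.numeric(phenotypes$sex == "M"),
        group = as.numeric(phenotypes$group == "ASD"))
}

embed_fwd <- function(params, raw) {
  raw %*% params$embed_W + rep(params$embed_b, each = nrow(raw))
}

#' Map a phenotype to its condition embedding
#'
#' The phenotype record is reduced to a raw triplet (min-max normalized age,
#' sex code, diagnostic-group code) and passed through the model's learned
#' affine embedding map, yielding a vector of length `embedding_dim` that the
#' conditional models stack as an extra parcel row (encoder) and concatenate
#' to the latent vector (decoder).
#'
#' @param phenotype One-row data frame with `age`, `sex` (`"M"`/`"F"`),
#'   `group` (`"TD"`/`"ASD"`).
#' @param model A conditional `fc_vae`.
#' @return A `condition_embedding`: list with `y` (embedding vector) and
#'   `raw` (the normalized triplet).
#' @export
make_condition_embedding <- function(phenotype, model) {
  assert_that(inherits(model, "fc_vae"), "model must be an fc_vae")
  assert_that(isTRUE(model$config$conditional),
              "model is unconditional: it has no embedding map")
  raw <- cond_raw_matrix(phenotype, model$config)
  structure(list(y = drop(embed_fwd(model$params, raw)), raw = drop(raw)),
            class = "condition_embedding")
}

# ---- input assembly --------------------------------------------------------

# stack the embedding as an extra parcel row when conditional
stack_condition <- function(X, Y) {
  d <- dim(X)
  out <- array(0, c(d[1], d[2] + 1L, d[3]))
  out[, seq_len(d[2]), ] <- X
  out[, d[2] + 1L, ] <- Y
  out
}

as_seq <- function(Xenc) aperm(Xenc, c(1, 3, 2))  # [N, R, W] -> [N, T=W, R]

# ---- CNN family ------------------------------------------------------------

cnn_enc_fwd <- function(model, X4, training) {
  p <- model$params; cfg <- model$config
  k <- cfg$kernel; s <- cfg$stride; pd <- cfg$pad; sl <- cfg$leaky_slope
  cache <- list(bn = list())
  h <- X4
  for (l in 1:3) {
    cv <- conv2d_fwd(h, p[[paste0("enc_conv", l, "_W")]],
                     p[[paste0("enc_conv", l, "_b")]], k, s, pd)
    bn <- batchnorm_fwd(cv$y, p[[paste0("enc_bn", l, "_gamma")]],
                        p[[paste0("enc_bn", l, "_beta")]],
                        model$bn[[paste0("enc_bn", l)]], training)
    ac <- leaky_relu_fwd(bn$y, sl)
    cache[[paste0("cv", l)]] <- cv
    cache[[paste0("bnc", l)]] <- bn
    cache[[paste0("ac", l)]] <- ac
    cache$bn[[paste0("enc_bn", l)]] <- bn$running
    h <- ac$y
  }
  N <- dim(h)[1]
  flat <- h; dim(flat) <- c(N, prod(dim(h)[-1]))
  cache$conv_out_dim <- dim(h)
  mu_a <- affine_fwd(flat, p$enc_cnn_mu_W, p$enc_cnn_mu_b)
  lv_a <- affine_fwd(flat, p$enc_cnn_lv_W, p$enc_cnn_lv_b)
  cache$mu_a <- mu_a; cache$lv_a <- lv_a
  list(mu = mu_a$y, logvar = lv_a$y, cache = cache)
}

cnn_enc_bwd <- function(dmu, dlv, cache, model) {
  p <- model$params; cfg <- model$config
  k <- cfg$kernel; s <- cfg$stride; pd <- cfg$pad
  g <- list()
  amu <- affine_bwd(dmu, cache$mu_a, p$enc_cnn_mu_W)
  alv <- affine_bwd(dlv, cache$lv_a, p$enc_cnn_lv_W)
  g$enc_cnn_mu_W <- amu$dW; g$enc_cnn_mu_b <- amu$db
  g$enc_cnn_lv_W <- alv$dW; g$enc_cnn_lv_b <- alv$db
  dflat <- amu$dX + alv$dX
  dh <- dflat; dim(dh) <- cache$conv_out_dim
  for (l in 3:1) {
    dh <- leaky_relu_bwd(dh, cache[[paste0("ac", l)]])
    bb <- batchnorm_bwd(dh, cache[[paste0("bnc", l)]],
                        p[[paste0("enc_bn", l, "_gamma")]])
    g[[paste0("enc_bn", l, "_gamma")]] <- bb$dgamma
    g[[paste0("enc_bn", l, "_beta")]] <- bb$dbeta
    cb <- conv2d_bwd(bb$dX, cache[[paste0("cv", l)]],
                     p[[paste0("enc_conv", l, "_W")]], k, s, pd)
    g[[paste0("enc_conv", l, "_W")]] <- cb$dW
    g[[paste0("enc_conv", l, "_b")]] <- cb$db
    dh <- cb$dX
  }
  list(dX = dh, grads = g)
}

cnn_dec_fwd <- function(model, Zin, training) {
  p <- model$params; cfg <- model$config; shp <- model$shapes
  k <- cfg$kernel; s <- cfg$stride; pd <- cfg$pad; sl <- cfg$leaky_slope
  f <- cfg$conv_filters
  N <- nrow(Zin)
  cache <- list(bn = list())
  fc <- affine_fwd(Zin, p$dec_cnn_fc_W, p$dec_cnn_fc_b)
  a0 <- leaky_relu_fwd(fc$y, sl)
  h <- a0$y; dim(h) <- c(N, f[3], shp$decoder_h[4], shp$decoder_w[4])
  cache$fc <- fc; cache$a0 <- a0
  outch <- c(f[2], f[1], 1L)
  for (l in 1:3) {
    ct <- convT2d_fwd(h, p[[paste0("dec_convT", l, "_W")]],
                      p[[paste0("dec_convT", l, "_b")]],
                      outch[l], shp$decoder_h[4 - l], shp$decoder_w[4 - l],
                      k, s, pd)
    cache[[paste0("ct", l)]] <- ct
    if (l < 3) {
      bn <- batchnorm_fwd(ct$y, p[[paste0("dec_bn", l, "_gamma")]],
                          p[[paste0("dec_bn", l, "_beta")]],
                          model$bn[[paste0("dec_bn", l)]], training)
      ac <- leaky_relu_fwd(bn$y, sl)
      cache[[paste0("bnc", l)]] <- bn
      cache[[paste0("ac", l)]] <- ac
      cache$bn[[paste0("dec_bn", l)]] <- bn$running
      h <- ac$y
    } else {
      sg <- sigmoid_fwd(ct$y)
      cache$sg <- sg
      h <- sg$y
    }
  }
  xh <- h; dim(xh) <- c(N, cfg$n_parcels, cfg$window)
  list(x_hat = xh, cache = cache)
}

cnn_dec_bwd <- function(dxh, cache, model) {
  p <- model$params; cfg <- model$config
  k <- cfg$kernel; s <- cfg$stride; pd <- cfg$pad
  g <- list()
  N <- dim(dxh)[1]
  dh <- dxh; dim(dh) <- c(N, 1L, cfg$n_parcels, cfg$window)
  dh <- sigmoid_bwd(dh, cache$sg)
  for (l in 3:1) {
    if (l < 3) {
      dh <- leaky_relu_bwd(dh, cache[[paste0("ac", l)]])
      bb <- batchnorm_bwd(dh, cache[[paste0("bnc", l)]],
                          p[[paste0("dec_bn", l, "_gamma")]])
      g[[paste0("dec_bn", l, "_gamma")]] <- bb$dgamma
      g[[paste0("dec_bn", l, "_beta")]] <- bb$dbeta
      dh <- bb$dX
    }
    tb <- convT2d_bwd(dh, cache[[paste0("ct", l)]],
                      p[[paste0("dec_convT", l, "_W")]], k, s, pd)
    g[[paste0("dec_convT", l, "_W")]] <- tb$dW
    g[[paste0("dec_convT", l, "_b")]] <- tb$db
    dh <- tb$dX
  }
  da0 <- dh; dim(da0) <- c(N, prod(dim(dh)[-1]))
  da0 <- leaky_relu_bwd(da0, cache$a0)
  ab <- affine_bwd(da0, cache$fc, p$dec_cnn_fc_W)
  g$dec_cnn_fc_W <- ab$dW; g$dec_cnn_fc_b <- ab$db
  list(dZin = ab$dX, grads = g)
}

# ---- RNN family ------------------------------------------------------------

rnn_enc_fwd <- function(model, Xseq) {
  p <- model$params; cfg <- model$config
  hh <- cfg$lstm_hidden
  ls <- lstm_stack_fwd(Xseq, p, "enc_rnn", hh, cfg$lstm_layers)
  N <- dim(Xseq)[1]; T_len <- dim(Xseq)[2]
  hl <- ls$h_all[, T_len, , drop = FALSE]; dim(hl) <- c(N, hh)
  mu_a <- affine_fwd(hl, p$enc_rnn_mu_W, p$enc_rnn_mu_b)
  lv_a <- affine_fwd(hl, p$enc_rnn_lv_W, p$enc_rnn_lv_b)
  list(mu = mu_a$y, logvar = lv_a$y,
       cache = list(ls = ls, mu_a = mu_a, lv_a = lv_a, N = N, T_len = T_len))
}

rnn_enc_bwd <- function(dmu, dlv, cache, model) {
  p <- model$params; cfg <- model$config
  hh <- cfg$lstm_hidden
  g <- list()
  amu <- affine_bwd(dmu, cache$mu_a, p$enc_rnn_mu_W)
  alv <- affine_bwd(dlv, cache$lv_a, p$enc_rnn_lv_W)
  g$enc_rnn_mu_W <- amu$dW; g$enc_rnn_mu_b <- amu$db
  g$enc_rnn_lv_W <- alv$dW; g$enc_rnn_lv_b <- alv$db
  dH <- array(0, c(cache$N, cache$T_len, hh))
  dH[, cache$T_len, ] <- amu$dX + alv$dX
  lb <- lstm_stack_bwd(dH, cache$ls$cache, p, "enc_rnn", hh, cfg$lstm_layers)
  list(dX = lb$dX, grads = c(g, lb$grads))
}

rnn_dec_fwd <- function(model, Zin) {
  p <- model$params; cfg <- model$config
  hh <- cfg$lstm_hidden; T_len <- cfg$window; P <- cfg$n_parcels
  N <- nrow(Zin)
  fc <- affine_fwd(Zin, p$dec_rnn_in_W, p$dec_rnn_in_b)
  a0 <- leaky_relu_fwd(fc$y, cfg$leaky_slope)
  U <- array(0, c(N, T_len, hh))
  for (t in seq_len(T_len)) U[, t, ] <- a0$y   # repeated latent input
  ls <- lstm_stack_fwd(U, p, "dec_rnn", hh, cfg$lstm_layers)
  Hmat <- ls$h_all; dim(Hmat) <- c(N * T_len, hh)
  out <- affine_fwd(Hmat, p$dec_rnn_out_W, p$dec_rnn_out_b)
  sg <- sigmoid_fwd(out$y)                      # [N*T, P]
  xh <- sg$y; dim(xh) <- c(N, T_len, P)
  xh <- aperm(xh, c(1, 3, 2))                   # [N, P, W]
  list(x_hat = xh,
       cache = list(fc = fc, a0 = a0, ls = ls, out = out, sg = sg,
                    N = N, T_len = T_len))
}

rnn_dec_bwd <- function(dxh, cache, model) {
  p <- model$params; cfg <- model$config
  hh <- cfg$lstm_hidden; T_len <- cache$T_len; N <- cache$N
  g <- list()
  dseq <- aperm(dxh, c(1, 3, 2))                # [N, T, P]
  dim(dseq) <- c(N * T_len, cfg$n_parcels)
  dpre <- sigmoid_bwd(dseq, cache$sg)
  ob <- affine_bwd(dpre, cache$out, p$dec_rnn_out_W)
  g$dec_rnn_out_W <- ob$dW; g$dec_rnn_out_b <- ob$db
  dH <- ob$dX; dim(dH) <- c(N, T_len, hh)
  lb <- lstm_stack_bwd(dH, cache$ls$cache, p, "dec_rnn", hh, cfg$lstm_layers)
  g <- c(g, lb$grads)
  du <- apply(lb$dX, c(1, 3), sum)              # collapse the repeat
  du <- leaky_relu_bwd(du, cache$a0)
  ab <- affine_bwd(du, cache$fc, p$dec_rnn_in_W)
  g$dec_rnn_in_W <- ab$dW; g$dec_rnn_in_b <- ab$db
  list(dZin = ab$dX, grads = g)
}

# ---- full model forward / backward ----------------------------------------

# X: [N, P, W]; raw: [N, 3] or NULL; eps: [N, d] standard-normal draws
vae_fwd <- function(model, X, raw = NULL, eps, training = FALSE) {
  cfg <- model$config
  cache <- list()
  Y <- NULL
  if (cfg$conditional) {
    assert_that(!is.null(raw), "conditional model requires phenotype conditions")
    Y <- embed_fwd(model$params, raw)
    Xenc <- stack_condition(X, Y)
  } else {
    Xenc <- X
  }
  if (cfg$family == "CNN") {
    X4 <- Xenc; dim(X4) <- c(dim(Xenc)[1], 1L, dim(Xenc)[2], dim(Xenc)[3])
    enc <- cnn_enc_fwd(model, X4, training)
    mu <- enc$mu; lv <- enc$logvar
  } else if (cfg$family == "RNN") {
    enc <- rnn_enc_fwd(model, as_seq(Xenc))
    mu <- enc$mu; lv <- enc$logvar
  } else {
    X4 <- Xenc; dim(X4) <- c(dim(Xenc)[1], 1L, dim(Xenc)[2], dim(Xenc)[3])
    enc_c <- cnn_enc_fwd(model, X4, training)
    enc_r <- rnn_enc_fwd(model, as_seq(Xenc))
    mu <- enc_c$mu * enc_r$mu          # element-wise latent fusion
    lv <- enc_c$logvar + enc_r$logvar
    enc <- list(c = enc_c, r = enc_r)
  }
  z <- mu + exp(lv / 2) * eps
  Zin <- if (cfg$conditional) cbind(z, Y) else z
  if (cfg$family == "CNN") {
    dec <- cnn_dec_fwd(model, Zin, training)
    x_hat <- dec$x_hat
  } else if (cfg$family == "RNN") {
    dec <- rnn_dec_fwd(model, Zin)
    x_hat <- dec$x_hat
  } else {
    dec_c <- cnn_dec_fwd(model, Zin, training)
    dec_r <- rnn_dec_fwd(model, Zin)
    x_hat <- (dec_c$x_hat + dec_r$x_hat) / 2
    dec <- list(c = dec_c, r = dec_r)
  }
  list(x_hat = x_hat, mu = mu, logvar = lv, z = z, Y = Y, raw = raw,
       eps = eps, enc = enc, dec = dec, X = X)
}

# dxh: gradient wrt x_hat; dmu_extra/dlv_extra: KL contributions.
# Returns gradients for every parameter (missing entries treated as zero).
vae_bwd <- function(model, fwd, dxh, dmu_extra, dlv_extra) {
  cfg <- model$config
  N <- dim(dxh)[1]
  if (cfg$family == "CNN") {
    db <- cnn_dec_bwd(dxh, fwd$dec$cache, model)
    g <- db$grads; dZin <- db$dZin
  } else if (cfg$family == "RNN") {
    db <- rnn_dec_bwd(dxh, fwd$dec$cache, model)
    g <- db$grads; dZin <- db$dZin
  } else {
    db_c <- cnn_dec_bwd(dxh / 2, fwd$dec$c$cache, model)
    db_r <- rnn_dec_bwd(dxh / 2, fwd$dec$r$cache, model)
    g <- c(db_c$grads, db_r$grads)
    dZin <- db_c$dZin + db_r$dZin
  }
  d <- cfg$latent_dim
  dz <- dZin[, seq_len(d), drop = FALSE]
  dY_dec <- if (cfg$conditional) dZin[, (d + 1):ncol(dZin), drop = FALSE]
  dmu <- dz + dmu_extra
  dlv <- dz * fwd$eps * 0.5 * exp(fwd$logvar / 2) + dlv_extra
  if (cfg$family == "CNN") {
    eb <- cnn_enc_bwd(dmu, dlv, fwd$enc$cache, model)
    g <- c(g, eb$grads)
    dXenc <- eb$dX; dim(dXenc) <- dim(dXenc)[c(1, 3, 4)]
  } else if (cfg$family == "RNN") {
    eb <- rnn_enc_bwd(dmu, dlv, fwd$enc$cache, model)
    g <- c(g, eb$grads)
    dXenc <- aperm(eb$dX, c(1, 3, 2))
  } else {
    dmu_c <- dmu * fwd$enc$r$mu
    dmu_r <- dmu * fwd$enc$c$mu
    eb_c <- cnn_enc_bwd(dmu_c, dlv, fwd$enc$c$cache, model)
    eb_r <- rnn_enc_bwd(dmu_r, dlv, fwd$enc$r$cache, model)
    g <- c(g, eb_c$grads, eb_r$grads)
    dX4 <- eb_c$dX; dim(dX4) <- dim(dX4)[c(1, 3, 4)]
    dXenc <- dX4 + aperm(eb_r$dX, c(1, 3, 2))
  }
  if (cfg$conditional) {
    P <- cfg$n_parcels
    dY <- dXenc[, P + 1L, ] + dY_dec
    if (is.null(dim(dY))) dY <- matrix(dY, nrow = N)
    g$embed_W <- crossprod(fwd$raw, dY)
    g$embed_b <- colSums(dY)
  }
  g
}

# pull the batch-norm running statistics updated during a training forward
# pass back into the model object
collect_bn_updates <- function(model, fwd) {
  upd <- list()
  cfg <- model$config
  if (cfg$family == "CNN") {
    upd <- c(fwd$enc$cache$bn, fwd$dec$cache$bn)
  } else if (cfg$family == "HYBRID") {
    upd <- c(fwd$enc$c$cache$bn, fwd$dec$c$cache$bn)
  }
  for (nm in names(upd)) model$bn[[nm]] <- upd[[nm]]
  model
}

# ---- public single-sample API ---------------------------------------------

check_window_matrix <- function(x, cfg) {
  assert_that(is.matrix(x), "x must be a parcels x window matrix")
  if (nrow(x) != cfg$n_parcels || ncol(x) != cfg$window) {
    stop_fc("input shape mismatch: expected ", cfg$n_parcels, "x", cfg$window,
            ", got ", nrow(x), "x", ncol(x))
  }
}

resolve_condition <- function(y, model) {
  if (inherits(y, "condition_embedding")) return(matrix(y$y, nrow = 1))
  if (is.data.frame(y)) return(embed_fwd(model$params,
                                         cond_raw_matrix(y, model$config)))
  assert_that(is.numeric(y) && length(y) == model$config$embedding_dim,
              "condition must have length ", model$config$embedding_dim,
              ", got ", length(y))
  matrix(y, nrow = 1)
}

#' Encode a window into its latent Gaussian parameters
#'
#' @param model An `fc_vae`.
#' @param x `n_parcels x window` matrix with entries in \[0, 1\].
#' @param y Condition ([make_condition_embedding()] result, phenotype row, or
#'   embedding vector); required iff the model is conditional.  The embedding
#'   is stacked as one extra parcel row before encoding.
#' @return List with `mu` and `logvar`, each of length `latent_dim`.
#' @export
encode <- function(model, x, y = NULL) {
  cfg <- model$config
  check_window_matrix(x, cfg)
  if (cfg$conditional && is.null(y)) stop_fc("conditional model needs y")
  X <- array(x, c(1L, nrow(x), ncol(x)))
  Xenc <- if (cfg$conditional) {
    stack_condition(X, resolve_condition(y, model))
  } else X
  if (cfg$family == "CNN") {
    X4 <- Xenc; dim(X4) <- c(1L, 1L, dim(Xenc)[2], dim(Xenc)[3])
    enc <- cnn_enc_fwd(model, X4, training = FALSE)
  } else if (cfg$family == "RNN") {
    enc <- rnn_enc_fwd(model, as_seq(Xenc))
  } else {
    X4 <- Xenc; dim(X4) <- c(1L, 1L, dim(Xenc)[2], dim(Xenc)[3])
    enc_c <- cnn_enc_fwd(model, X4, training = FALSE)
    enc_r <- rnn_enc_fwd(model, as_seq(Xenc))
    return(list(mu = drop(enc_c$mu * enc_r$mu),
                logvar = drop(enc_c$logvar + enc_r$logvar)))
  }
  list(mu = drop(enc$mu), logvar = drop(enc$logvar))
}

#' Sample a latent vector with the reparameterization trick
#'
#' `z = mu + exp(logvar / 2) * eps` with `eps ~ N(0, I)` drawn from the
#' current RNG stream, so a seed set beforehand makes the draw reproducible.
#'
#' @param mu,logvar Numeric vectors of equal length.
#' @return Latent sample `z`.
#' @export
reparameterize <- function(mu, logvar) {
  assert_that(length(mu) == length(logvar),
              "mu and logvar must have the same length")
  mu + exp(logvar / 2) * rnorm(length(mu))
}

#' Decode a latent vector into a reconstructed window
#'
#' @param model An `fc_vae`.
#' @param z Latent vector of length `latent_dim`.
#' @param y Condition, required iff the model is conditional; concatenated to
#'   `z` before decoding.  Only the data rows are reconstructed, never the
#'   embedding row.
#' @return `n_parcels x window` matrix with entries in \[0, 1\].
#' @export
decode <- function(model, z, y = NULL) {
  cfg <- model$config
  assert_that(length(z) == cfg$latent_dim,
              "z must have length ", cfg$latent_dim, ", got ", length(z))
  if (cfg$conditional && is.null(y)) stop_fc("conditional model needs y")
  Zin <- matrix(z, nrow = 1)
  if (cfg$conditional) Zin <- cbind(Zin, resolve_condition(y, model))
  xh <- if (cfg$family == "CNN") {
    cnn_dec_fwd(model, Zin, training = FALSE)$x_hat
  } else if (cfg$family == "RNN") {
    rnn_dec_fwd(model, Zin)$x_hat
  } else {
    (cnn_dec_fwd(model, Zin, training = FALSE)$x_hat +
       rnn_dec_fwd(model, Zin)$x_hat) / 2
  }
  matrix(xh[1, , ], cfg$n_parcels, cfg$window)
}
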