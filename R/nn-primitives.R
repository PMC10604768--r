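# Dense-linear-algebra building blocks for the autoencoder families.
# All layers come as forward/backward pairs operating on plain arrays;
# gradients are analytic and are validated against central finite
# differences in the test suite.

# ---- initialisation --------------------------------------------------------

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dims)
}

# ---- activations -----------------------------------------------------------

leaky_relu_fwd <- function(x, slope = 0.2) {
  neg <- x < 0
  y <- x
  y[neg] <- slope * x[neg]
  list(y = y, neg = neg, slope = slope)
}

leaky_relu_bwd <- function(dy, cache) {
  dx <- dy
  dx[cache$neg] <- cache$slope * dy[cache$neg]
  dx
}

sigmoid_fwd <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(y = y)
}

sigmoid_bwd <- function(dy, cache) dy * cache$y * (1 - cache$y)

tanh_bwd <- function(dy, y) dy * (1 - y * y)

# ---- affine ----------------------------------------------------------------

# X: [N, D]; W: [D, M]; b: length M
affine_fwd <- function(X, W, b) {
  list(y = X %*% W + rep(b, each = nrow(X)), X = X)
}

affine_bwd <- function(dy, cache, W) {
  list(dX = dy %*% t(W),
       dW = crossprod(cache$X, dy),
       db = colSums(dy))
}

# ---- 2D convolution core ---------------------------------------------------

# All convs use square kernels with stride `s` and zero padding `p`.
conv_out_len <- function(n, k, s, p) (n + 2L * p - k) %/% s + 1L

# X: [N, C, H, W] -> matrix [N*Ho*Wo, C*k*k]
im2col <- function(X, k, s, p) {
  d <- dim(X); N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  Ho <- conv_out_len(H, k, s, p); Wo <- conv_out_len(W, k, s, p)
  Xp <- array(0, c(N, C, H + 2L * p, W + 2L * p))
  Xp[, , p + seq_len(H), p + seq_len(W)] <- X
  hi <- (seq_len(Ho) - 1L) * s
  wi <- (seq_len(Wo) - 1L) * s
  cols <- array(0, c(N, Ho, Wo, C, k, k))
  for (kj in seq_len(k)) for (ki in seq_len(k)) {
    blk <- Xp[, , hi + ki, wi + kj, drop = FALSE]       # [N, C, Ho, Wo]
    cols[, , , , ki, kj] <- aperm(blk, c(1, 3, 4, 2))
  }
  dim(cols) <- c(N * Ho * Wo, C * k * k)
  cols
}

# inverse scatter-add of im2col; cols: [N*Ho*Wo, C*k*k] -> X: [N, C, H, W]
col2im <- function(cols, N, C, H, W, k, s, p) {
  Ho <- conv_out_len(H, k, s, p); Wo <- conv_out_len(W, k, s, p)
  dim(cols) <- c(N, Ho, Wo, C, k, k)
  Xp <- array(0, c(N, C, H + 2L * p, W + 2L * p))
  hi <- (seq_len(Ho) - 1L) * s
  wi <- (seq_len(Wo) - 1L) * s
  for (kj in seq_len(k)) for (ki in seq_len(k)) {
    blk <- cols[, , , , ki, kj, drop = FALSE]
    dim(blk) <- c(N, Ho, Wo, C)
    Xp[, , hi + ki, wi + kj] <- Xp[, , hi + ki, wi + kj, drop = FALSE] +
      aperm(blk, c(1, 4, 2, 3))
  }
  Xp[, , p + seq_len(H), p + seq_len(W), drop = FALSE]
}

# weight: [C*k*k, F]; bias: length F
conv2d_fwd <- function(X, W, b, k, s, p) {
  d <- dim(X); N <- d[1]; H <- d[3]; Wd <- d[4]
  Ho <- conv_out_len(H, k, s, p); Wo <- conv_out_len(Wd, k, s, p)
  cols <- im2col(X, k, s, p)
  Ymat <- cols %*% W + rep(b, each = nrow(cols))
  Y <- Ymat
  dim(Y) <- c(N, Ho, Wo, ncol(W))
  Y <- aperm(Y, c(1, 4, 2, 3))                          # [N, F, Ho, Wo]
  list(y = Y, cols = cols, in_dim = d)
}

conv2d_bwd <- function(dY, cache, W, k, s, p) {
  d <- cache$in_dim
  dYmat <- aperm(dY, c(1, 3, 4, 2))
  dim(dYmat) <- c(dim(dY)[1] * dim(dY)[3] * dim(dY)[4], dim(dY)[2])
  dW <- crossprod(cache$cols, dYmat)
  db <- colSums(dYmat)
  dcols <- dYmat %*% t(W)
  dX <- col2im(dcols, d[1], d[2], d[3], d[4], k, s, p)
  list(dX = dX, dW = dW, db = db)
}

# Transposed convolution, defined as the adjoint of the conv that maps the
# *target* shape [N, Fo, H, W] down to the input shape [N, Fi, h, w].
# weight: [Fo*k*k, Fi]; bias: length Fo.  Choosing the geometry this way
# makes the decoder invert the encoder's shape chain exactly (the usual
# "output padding" falls out of the target shape).
convT2d_fwd <- function(X, W, b, out_ch, out_h, out_w, k, s, p) {
  d <- dim(X); N <- d[1]; Fi <- d[2]; h <- d[3]; w <- d[4]
  Xmat <- aperm(X, c(1, 3, 4, 2))
  dim(Xmat) <- c(N * h * w, Fi)
  dcols <- Xmat %*% t(W)
  Y <- col2im(dcols, N, out_ch, out_h, out_w, k, s, p)
  Y <- Y + aperm(array(b, c(out_ch, N, out_h, out_w)), c(2, 1, 3, 4))
  list(y = Y, Xmat = Xmat, in_dim = d)
}

convT2d_bwd <- function(dY, cache, W, k, s, p) {
  d <- cache$in_dim
  cols <- im2col(dY, k, s, p)                           # [N*h*w, Fo*k*k]
  dXmat <- cols %*% W
  dW <- crossprod(cols, cache$Xmat)
  db <- apply(dY, 2, sum)
  dX <- dXmat
  dim(dX) <- c(d[1], d[3], d[4], d[2])
  dX <- aperm(dX, c(1, 4, 2, 3))
  list(dX = dX, dW = dW, db = db)
}

# ---- batch normalisation (per channel over N, H, W) ------------------------

batchnorm_fwd <- function(X, gamma, beta, running, training, eps = 1e-5,
                          momentum = 0.1) {
  d <- dim(X); C <- d[2]
  Xc <- aperm(X, c(1, 3, 4, 2))
  dim(Xc) <- c(d[1] * d[3] * d[4], C)                   # [M, C]
  if (training) {
    mu <- colMeans(Xc)
    xm <- Xc - rep(mu, each = nrow(Xc))
    v <- colMeans(xm * xm)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean
    v <- running$var
    xm <- Xc - rep(mu, each = nrow(Xc))
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xm * rep(inv_sd, each = nrow(Xc))
  Ymat <- xhat * rep(gamma, each = nrow(Xc)) + rep(beta, each = nrow(Xc))
  Y <- Ymat
  dim(Y) <- c(d[1], d[3], d[4], C)
  Y <- aperm(Y, c(1, 4, 2, 3))
  list(y = Y, xhat = xhat, inv_sd = inv_sd, dim = d, running = running,
       training = training)
}

batchnorm_bwd <- function(dY, cache, gamma) {
  d <- cache$dim; C <- d[2]
  dYc <- aperm(dY, c(1, 3, 4, 2))
  dim(dYc) <- c(d[1] * d[3] * d[4], C)
  M <- nrow(dYc)
  dgamma <- colSums(dYc * cache$xhat)
  dbeta <- colSums(dYc)
  dxhat <- dYc * rep(gamma, each = M)
  if (cache$training) {
    dXc <- (dxhat - rep(colMeans(dxhat), each = M) -
              cache$xhat * rep(colMeans(dxhat * cache$xhat), each = M)) *
           rep(cache$inv_sd, each = M)
  } else {
    dXc <- dxhat * rep(cache$inv_sd, each = M)
  }
  dX <- dXc
  dim(dX) <- c(d[1], d[3], d[4], C)
  dX <- aperm(dX, c(1, 4, 2, 3))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
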