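#' Configuration of a (conditional) variational autoencoder
#'
#' Three encoder/decoder families are available: `"CNN"` (three strided
#' convolution layers with `conv_filters` filters, batch normalization and
#' leaky-ReLU, mirrored by transposed convolutions), `"RNN"` (a three-layer
#' unidirectional LSTM over the time axis, each step seeing one
#' parcel-vector), and `"HYBRID"` (CNN and RNN encoders and decoders in
#' parallel; latent Gaussians fused by element-wise multiplication of means
#' and addition of log-variances, decoder outputs averaged).
#'
#' When `conditional = TRUE` the phenotype embedding (length
#' `embedding_dim`, which must equal `window` so it can be stacked as one
#' extra parcel row) is appended to the encoder input and concatenated to the
#' latent vector before decoding.
#'
#' @param family `"CNN"`, `"RNN"` or `"HYBRID"`.
#' @param conditional Use the phenotype-conditioned variant (CVAE)?
#' @param latent_dim Latent dimensionality `d` (2000 at full scale; desk-scale
#'   analyses use 16-128).
#' @param n_parcels Number of parcels per window (rows).
#' @param window Window length in time steps (columns).
#' @param conv_filters Three filter counts for the convolutional family.
#' @param lstm_layers Number of LSTM layers (3).
#' @param lstm_hidden LSTM hidden width.
#' @param embedding_dim Length of the condition embedding; defaults to
#'   `window` (200 at full scale).
#' @param learning_rate Adam learning rate.
#' @param beta Weight of the KL term in the ELBO.
#' @param epochs,batch_size Training schedule.
#' @param seed Seed for weight initialization, shuffling and latent noise.
#' @param recon_likelihood `"gaussian"` (sum-of-squares/2) or `"bernoulli"`
#'   (binary cross-entropy) reconstruction term.
#' @param age_range Age normalization bounds (years) for the condition
#'   embedding; ages outside are clipped with a warning.
#' @param leaky_slope Negative-side slope of the leaky-ReLU.
#' @return An object of class `fc_model_config`.
#' @export
model_config <- function(family = c("CNN", "RNN", "HYBRID"),
                         conditional = FALSE,
                         latent_dim = 2000,
                         n_parcels = 200,
                         window = 200,
                         conv_filters = c(32, 64, 128),
                         lstm_layers = 3,
                         lstm_hidden = 256,
                         embedding_dim = window,
                         learning_rate = 1e-4,
                         beta = 1,
                         epochs = 30,
                         batch_size = 32,
                         seed = 1L,
                         recon_likelihood = c("gaussian", "bernoulli"),
                         age_range = c(5, 40),
                         leaky_slope = 0.2) {
  family <- match.arg(family)
  recon_likelihood <- match.arg(recon_likelihood)
  assert_that(is_count(latent_dim), "latent_dim must be >= 1")
  assert_that(is_count(n_parcels) && is_count(window),
              "n_parcels and window must be >= 1")
  assert_that(length(conv_filters) == 3 && all(conv_filters >= 1),
              "conv_filters must give three filter counts")
  if (conditional) {
    assert_that(embedding_dim == window,
                "embedding_dim must equal window: the condition embedding is ",
                "stacked as one extra parcel row of the window matrix")
  }
  cfg <- structure(list(
    family = family, conditional = conditional,
    latent_dim = as.integer(latent_dim),
    n_parcels = as.integer(n_parcels), window = as.integer(window),
    conv_filters = as.integer(conv_filters),
    lstm_layers = as.integer(lstm_layers),
    lstm_hidden = as.integer(lstm_hidden),
    embedding_dim = as.integer(embedding_dim),
    learning_rate = learning_rate, beta = beta,
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    seed = as.integer(seed), recon_likelihood = recon_likelihood,
    age_range = age_range, leaky_slope = leaky_slope,
    kernel = 3L, stride = 2L, pad = 1L
  ), class = "fc_model_config")
  if (family %in% c("CNN", "HYBRID")) model_shapes(cfg)  # validate geometry
  cfg
}

#' Shape chain of a model configuration
#'
#' Computes, without instantiating any weights, the tensor shapes implied by
#' a configuration: the number of parcel rows consumed by the encoder (one
#' more than `n_parcels` when conditional), the strided-convolution shape
#' chain of encoder and decoder, and the length of the decoder input (latent
#' dimension plus embedding length when conditional; 2200 at full scale with
#' `latent_dim = 2000`).
#'
#' @param config An [model_config()].
#' @return List with `encoder_input_rows`, `decoder_input_len`,
#'   `encoder_h`/`encoder_w` and `decoder_h`/`decoder_w` chains (from input
#'   to innermost), and `encoder_flat` / `decoder_flat` sizes.
#' @examples
#' cfg <- model_config("CNN", conditional = TRUE)  # paper-scale defaults
#' model_shapes(cfg)$encoder_input_rows  # 201
#' model_shapes(cfg)$decoder_input_len   # 2200
#' @export
model_shapes <- function(config) {
  k <- config$kernel; s <- config$stride; p <- config$pad
  rows_in <- config$n_parcels + if (config$conditional) 1L else 0L
  chain <- function(n) {
    out <- n
    for (i in 1:3) out <- c(out, conv_out_len(out[length(out)], k, s, p))
    out
  }
  eh <- chain(rows_in); ew <- chain(config$window)
  dh <- chain(config$n_parcels); dw <- chain(config$window)
  if (config$family %in% c("CNN", "HYBRID") && any(c(eh, ew, dh, dw) < 1)) {
    stop_fc("convolution geometry collapses for input ", rows_in, "x",
            config$window, ": shape chain rows ",
            paste(eh, collapse = " -> "), ", cols ",
            paste(ew, collapse = " -> "))
  }
  f3 <- config$conv_filters[3]
  list(encoder_input_rows = rows_in,
       decoder_input_len = config$latent_dim +
         if (config$conditional) config$embedding_dim else 0L,
       encoder_h = eh, encoder_w = ew, decoder_h = dh, decoder_w = dw,
       encoder_flat = f3 * eh[4] * ew[4],
       decoder_flat = f3 * dh[4] * dw[4])
}

#' Build an untrained model from a configuration
#'
#' Initializes all weights (Glorot-uniform, seeded from `config$seed`),
#' batch-normalization parameters and running statistics for the requested
#' family, plus the learned affine condition-embedding map when conditional.
#'
#' @param config An [model_config()].
#' @return An object of class `fc_vae` with elements `config`, `params`
#'   (named list of arrays), `bn` (running statistics) and `shapes`.
#' @export
build_model <- function(config) {
  assert_that(inherits(config, "fc_model_config"), "config must be fc_model_config")
  shp <- model_shapes(config)
  with_seed(config$seed, {
    params <- list()
    bn <- list()
    k <- config$kernel
    f <- config$conv_filters
    d <- config$latent_dim
    dz <- shp$decoder_input_len
    if (config$family %in% c("CNN", "HYBRID")) {
      chans <- c(1L, f)
      for (l in 1:3) {
        params[[paste0("enc_conv", l, "_W")]] <-
          glorot(chans[l] * k * k, chans[l + 1], c(chans[l] * k * k, chans[l + 1]))
        params[[paste0("enc_conv", l, "_b")]] <- rep(0, chans[l + 1])
        params[[paste0("enc_bn", l, "_gamma")]] <- rep(1, chans[l + 1])
        params[[paste0("enc_bn", l, "_beta")]] <- rep(0, chans[l + 1])
        bn[[paste0("enc_bn", l)]] <- list(mean = rep(0, chans[l + 1]),
                                          var = rep(1, chans[l + 1]))
      }
      params$enc_cnn_mu_W <- glorot(shp$encoder_flat, d)
      params$enc_cnn_mu_b <- rep(0, d)
      params$enc_cnn_lv_W <- glorot(shp$encoder_flat, d)
      params$enc_cnn_lv_b <- rep(0, d)
      params$dec_cnn_fc_W <- glorot(dz, shp$decoder_flat)
      params$dec_cnn_fc_b <- rep(0, shp$decoder_flat)
      # transposed convs are parameterized by their adjoint ("mirror") conv
      outch <- c(f[2], f[1], 1L)
      inch <- c(f[3], f[2], f[1])
      for (l in 1:3) {
        params[[paste0("dec_convT", l, "_W")]] <-
          glorot(outch[l] * k * k, inch[l], c(outch[l] * k * k, inch[l]))
        params[[paste0("dec_convT", l, "_b")]] <- rep(0, outch[l])
        if (l < 3) {
          params[[paste0("dec_bn", l, "_gamma")]] <- rep(1, outch[l])
          params[[paste0("dec_bn", l, "_beta")]] <- rep(0, outch[l])
          bn[[paste0("dec_bn", l)]] <- list(mean = rep(0, outch[l]),
                                            var = rep(1, outch[l]))
        }
      }
    }
    if (config$family %in% c("RNN", "HYBRID")) {
      hh <- config$lstm_hidden
      params <- c(params, lstm_init_params("enc_rnn", shp$encoder_input_rows,
                                           hh, config$lstm_layers))
      params$enc_rnn_mu_W <- glorot(hh, d)
      params$enc_rnn_mu_b <- rep(0, d)
      params$enc_rnn_lv_W <- glorot(hh, d)
      params$enc_rnn_lv_b <- rep(0, d)
      params$dec_rnn_in_W <- glorot(dz, hh)
      params$dec_rnn_in_b <- rep(0, hh)
      params <- c(params, lstm_init_params("dec_rnn", hh, hh,
                                           config$lstm_layers))
      params$dec_rnn_out_W <- glorot(hh, config$n_parcels)
      params$dec_rnn_out_b <- rep(0, config$n_parcels)
    }
    if (config$conditional) {
      params$embed_W <- glorot(3, config$embedding_dim)
      params$embed_b <- rep(0, config$embedding_dim)
    }
    structure(list(config = config, params = params, bn = bn, shapes = shp,
                   trained = FALSE), class = "fc_vae")
  })
}

#' @export
print.fc_vae <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<fc_vae> %s%s, d=%d, input %dx%d, %s parameters%s\n",
              if (x$config$conditional) "conditional " else "",
              x$config$family, x$config$latent_dim, x$config$n_parcels,
              x$config$window, format(n_par, big.mark = ","),
              if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model An `fc_vae`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}
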