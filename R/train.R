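#' Train a (conditional) variational autoencoder on windowed BOLD samples
#'
#' Unconditional models (VAE) are trained on the neurotypical windows only,
#' reflecting the normative-modeling design: the decoder learns the typical
#' population and deviations of atypical inputs from their reconstructions
#' carry the signal.  Conditional models (CVAE) train on both groups with
#' their true phenotype embeddings.  Optimization is Adam at
#' `config$learning_rate` on the negative ELBO; all stochasticity (shuffling,
#' latent noise) is derived from `config$seed`, so a rerun reproduces the
#' loss history exactly.
#'
#' @param model An untrained (or further-trainable) `fc_vae` from
#'   [build_model()].
#' @param window_samples List of `window_sample` objects (see
#'   [sliding_windows()]).
#' @param phenotypes Phenotype data frame covering every window's subject.
#' @param config Optional [model_config()] override; defaults to the model's.
#' @return List with `model` (trained) and `history` (data frame of per-epoch
#'   mean `total`, `recon`, `kl`).
#' @export
train_model <- function(model, window_samples, phenotypes,
                        config = model$config) {
  assert_that(inherits(model, "fc_vae"), "model must be an fc_vae")
  assert_that(length(window_samples) > 0, "no training windows supplied")
  ids <- vapply(window_samples, function(w) w$subject_id, character(1))
  missing_ph <- setdiff(unique(ids), phenotypes$subject_id)
  assert_that(length(missing_ph) == 0,
              "windows without phenotype rows: ",
              paste(missing_ph, collapse = ", "))
  ph <- phenotypes[match(ids, phenotypes$subject_id), , drop = FALSE]
  if (!config$conditional) {
    keep <- ph$group == "TD"
    if (!any(keep)) {
      stop_fc("VAE training set is empty after restricting to the ",
              "neurotypical (TD) group", class = "fcvae_empty_training")
    }
    window_samples <- window_samples[keep]
    ph <- ph[keep, , drop = FALSE]
  }
  n <- length(window_samples)
  P <- config$n_parcels; W <- config$window; d <- config$latent_dim
  X_all <- array(0, c(n, P, W))
  for (i in seq_len(n)) {
    check_window_matrix(window_samples[[i]]$matrix, config)
    X_all[i, , ] <- window_samples[[i]]$matrix
  }
  raw_all <- if (config$conditional) cond_raw_matrix(ph, config)

  opt <- adam_init(model$params)
  history <- matrix(0, config$epochs, 3,
                    dimnames = list(NULL, c("total", "recon", "kl")))
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batch_starts <- seq(1, n, by = config$batch_size)
      ep_loss <- c(total = 0, recon = 0, kl = 0)
      for (b0 in batch_starts) {
        idx <- ord[b0:min(b0 + config$batch_size - 1, n)]
        Xb <- X_all[idx, , , drop = FALSE]
        rawb <- if (config$conditional) raw_all[idx, , drop = FALSE]
        eps <- matrix(rnorm(length(idx) * d), length(idx), d)
        fwd <- vae_fwd(model, Xb, rawb, eps, training = TRUE)
        model <- collect_bn_updates(model, fwd)
        gl <- elbo_grad_batch(Xb, fwd$x_hat, fwd$mu, fwd$logvar,
                              config$beta, config$recon_likelihood)
        grads <- vae_bwd(model, fwd, gl$dxh, gl$dmu, gl$dlv)
        grads <- grads[names(model$params)]
        names(grads) <- names(model$params)
        upd <- adam_step(model$params, grads, opt, config$learning_rate)
        model$params <- upd$params
        opt <- upd$state
        ep_loss <- ep_loss +
          elbo_value_batch(Xb, fwd$x_hat, fwd$mu, fwd$logvar,
                           config$beta, config$recon_likelihood) *
          length(idx)
      }
      history[epoch, ] <- ep_loss / n
    }
  })
  model$trained <- TRUE
  list(model = model,
       history = data.frame(epoch = seq_len(config$epochs), history))
}

#' Save a trained model to disk
#'
#' Writes the serialized weights plus a JSON sidecar holding the full
#' configuration and seed, so a reload reproduces the model bit-exactly.
#'
#' @param model An `fc_vae`.
#' @param path File path for the weights (sidecar gets `.json` appended).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, path)
  cfg <- model$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a model saved by [save_model()]
#' @param path Path given to [save_model()].
#' @return The `fc_vae` object.
#' @export
load_model <- function(path) {
  assert_that(file.exists(path), "no checkpoint at ", path)
  readRDS(path)
}
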