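# shared desk-scale fixtures, built in code

# micro config for shape and gradient tests
micro_model_config <- function(family = "CNN", conditional = FALSE, ...) {
  model_config(family, conditional = conditional, latent_dim = 5,
               n_parcels = 6, window = 8, conv_filters = c(3, 4, 5),
               lstm_hidden = 7, epochs = 1, seed = 42, ...)
}

# small cohort with optional coupling effects
tiny_cohort <- function(seed = 11, n_per_cell = 5, n_parcels = 20,
                        scan_range = c(80, 130), effects = NULL,
                        noise_sd = 1, coupling_base = NULL, sex_ratio = 1) {
  cfg <- fc_sim_config(n_subjects_per_cell = n_per_cell,
                       n_parcels = n_parcels,
                       scan_length_range = scan_range,
                       effect_table = effects, noise_sd = noise_sd,
                       coupling_base = coupling_base,
                       sex_ratio = sex_ratio, seed = seed)
  c(generate_cohort(cfg), list(config = cfg))
}

# strongly coupled neurotypical baseline used by the normative-model checks
coupled_base <- function(r = 0.5, k = 5) {
  m <- matrix(r, k, k); diag(m) <- 1; m
}

# under-connectivity across every network pair for the diagnostic group
broad_underconnectivity <- function(delta = -0.5) {
  nets <- c("DMN", "Limbic", "Visual", "Somatomotor", "Salience")
  prs <- t(utils::combn(nets, 2))
  fc_effect(prs[, 1], prs[, 2], group = "ASD", delta = delta)
}

group_of <- function(windows, phenotypes) {
  vapply(windows, function(w)
    phenotypes$group[match(w$subject_id, phenotypes$subject_id)], character(1))
}

sex_of <- function(windows, phenotypes) {
  vapply(windows, function(w)
    phenotypes$sex[match(w$subject_id, phenotypes$subject_id)], character(1))
}

# training settings used across the desk-scale model checks: KL weight 0.01
# counteracts posterior collapse at this scale (see the methods vignette)
desk_model_config <- function(family = "CNN", conditional = FALSE,
                              latent_dim = 48, seed = 1, epochs = 40, ...) {
  model_config(family, conditional = conditional, latent_dim = latent_dim,
               n_parcels = 20, window = 40, conv_filters = c(8, 16, 32),
               lstm_hidden = 32, learning_rate = 2e-3, beta = 0.01,
               epochs = epochs, batch_size = 32, seed = seed, ...)
}
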