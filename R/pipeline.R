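# latent means of a set of windows, batched (true conditions when CVAE)
encode_mus <- function(model, windows, phenotypes = NULL) {
  cfg <- model$config
  n <- length(windows)
  X <- array(0, c(n, cfg$n_parcels, cfg$window))
  for (i in seq_len(n)) X[i, , ] <- windows[[i]]$matrix
  raw <- NULL
  if (cfg$conditional) {
    ids <- vapply(windows, function(w) w$subject_id, character(1))
    ph <- phenotypes[match(ids, phenotypes$subject_id), , drop = FALSE]
    raw <- cond_raw_matrix(ph, cfg)
  }
  Xenc <- if (cfg$conditional) {
    stack_condition(X, embed_fwd(model$params, raw))
  } else X
  if (cfg$family == "CNN") {
    X4 <- Xenc; dim(X4) <- c(n, 1L, dim(Xenc)[2], dim(Xenc)[3])
    cnn_enc_fwd(model, X4, training = FALSE)$mu
  } else if (cfg$family == "RNN") {
    rnn_enc_fwd(model, as_seq(Xenc))$mu
  } else {
    X4 <- Xenc; dim(X4) <- c(n, 1L, dim(Xenc)[2], dim(Xenc)[3])
    cnn_enc_fwd(model, X4, training = FALSE)$mu *
      rnn_enc_fwd(model, as_seq(Xenc))$mu
  }
}

default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulation = list(n_subjects_per_cell = 5, n_parcels = 20, n_networks = 5,
                      scan_length_range = c(80, 130), noise_sd = 1,
                      ar_coefficient = 0.4, sex_ratio = 1, effects = list()),
    preprocessing = list(test_fraction = 0.25, window = 40, step = 10),
    model = list(family = "CNN", conditional = FALSE, latent_dim = 16,
                 conv_filters = c(8, 16, 32), lstm_hidden = 32),
    training = list(learning_rate = 1e-3, epochs = 15, batch_size = 32,
                    beta = 1),
    fc_analysis = list(alpha = 0.05, by_sex = TRUE)
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    assert_that(file.exists(config), "config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  assert_that(is.list(config), "config must be a list or a YAML path")
  out <- utils::modifyList(default_pipeline_config(), config)
  # modifyList drops unnamed nested entries; effect rows are unnamed
  if (!is.null(config$simulation$effects)) {
    out$simulation$effects <- config$simulation$effects
  }
  out
}

pipeline_log <- function(run_dir, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), paste0(...))
  message(msg)
  cat(msg, "\n", file = file.path(run_dir, "log.txt"), append = TRUE)
}

require_artifact <- function(path, stage_needed) {
  if (!file.exists(path)) {
    stop_fc("missing upstream artifact ", basename(path),
            ": run stage '", stage_needed, "' first",
            class = "fcvae_missing_stage")
  }
  path
}

#' Run the end-to-end analysis pipeline
#'
#' Chains the stages `simulate` (synthetic cohort written as TSV/CSV),
#' `preprocess` (subject split plus sliding-window augmentation), `train`
#' (VAE or CVAE on the training windows), `evaluate` (reconstruction and
#' latent-separation metrics on held-out windows) and `fc` (counterfactual
#' connectivity, Welch-t divergence maps, chord diagrams and, when both
#' sexes are present, the male/female FC-similarity score).  Stages are
#' resumable: each reads the artifacts of its predecessors from the run
#' directory and fails with an actionable error if they are missing.  Every
#' random draw derives from the single `seed`, so a rerun with the same
#' configuration reproduces all metrics exactly.
#'
#' @param config Pipeline configuration: a YAML file path or a nested list
#'   (sections `simulation`, `preprocessing`, `model`, `training`,
#'   `fc_analysis`; missing entries fall back to desk-scale defaults).
#' @param stages Subset of `c("simulate", "preprocess", "train", "evaluate",
#'   "fc")`.
#' @param outdir Parent output directory.
#' @param run_id Run directory name; defaults to a timestamp.
#' @param seed Overrides `config$seed`.
#' @return The run directory path, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "preprocess", "train",
                                    "evaluate", "fc"),
                         outdir = tempdir(), run_id = NULL, seed = NULL) {
  cfg <- read_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  stages <- match.arg(stages, several.ok = TRUE)
  run_dir <- file.path(outdir,
                       run_id %||% format(Sys.time(), "run-%Y%m%d-%H%M%S"))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(run_dir, "config.yaml"))
  seeds <- derive_seeds(cfg$seed, 5)

  if ("simulate" %in% stages) {
    sim <- cfg$simulation
    eff <- if (length(sim$effects)) {
      do.call(rbind, lapply(sim$effects, function(e)
        fc_effect(e$network_i, e$network_j, e$group, e$sex %||% "any",
                  e$delta)))
    }
    simcfg <- fc_sim_config(
      n_subjects_per_cell = sim$n_subjects_per_cell,
      n_parcels = sim$n_parcels, n_networks = sim$n_networks,
      scan_length_range = unlist(sim$scan_length_range),
      noise_sd = sim$noise_sd, ar_coefficient = sim$ar_coefficient,
      sex_ratio = sim$sex_ratio, effect_table = eff, seed = seeds[1])
    cohort <- generate_cohort(simcfg)
    write_cohort(cohort$series, cohort$phenotypes,
                 file.path(run_dir, "cohort"))
    pipeline_log(run_dir, "simulate: ", length(cohort$series), " subjects, ",
                 nrow(simcfg$effect_table), " coupling effect(s)")
  }

  if ("preprocess" %in% stages) {
    require_artifact(file.path(run_dir, "cohort", "phenotypes.csv"), "simulate")
    cohort <- read_cohort(file.path(run_dir, "cohort"))
    pp <- cfg$preprocessing
    split <- subject_split(cohort$phenotypes, pp$test_fraction, seed = seeds[2])
    wtr <- cohort_windows(cohort$series, split$train, pp$window, pp$step)
    wte <- cohort_windows(cohort$series, split$test, pp$window, pp$step)
    assert_that(length(wtr) > 0 && length(wte) > 0,
                "windowing produced an empty train or test set; ",
                "check scan_length_range against the window length")
    saveRDS(list(split = split, train = wtr, test = wte,
                 phenotypes = cohort$phenotypes),
            file.path(run_dir, "preprocessed.rds"))
    jsonlite::write_json(split, file.path(run_dir, "split.json"))
    pipeline_log(run_dir, "preprocess: ", length(wtr), " train / ",
                 length(wte), " test windows from ",
                 length(split$train), "/", length(split$test), " subjects")
  }

  if ("train" %in% stages) {
    pp_path <- require_artifact(file.path(run_dir, "preprocessed.rds"),
                                "preprocess")
    pp <- readRDS(pp_path)
    md <- cfg$model; tr <- cfg$training
    mcfg <- model_config(
      family = md$family, conditional = isTRUE(md$conditional),
      latent_dim = md$latent_dim, n_parcels = cfg$simulation$n_parcels,
      window = cfg$preprocessing$window,
      conv_filters = unlist(md$conv_filters),
      lstm_hidden = md$lstm_hidden, learning_rate = tr$learning_rate,
      beta = tr$beta %||% 1, epochs = tr$epochs, batch_size = tr$batch_size,
      seed = seeds[3])
    fit <- train_model(build_model(mcfg), pp$train, pp$phenotypes)
    save_model(fit$model, file.path(run_dir, "checkpoints", "model.rds"))
    utils::write.csv(fit$history,
                     file.path(run_dir, "checkpoints", "loss_history.csv"),
                     row.names = FALSE)
    pipeline_log(run_dir, "train: ", md$family,
                 if (isTRUE(md$conditional)) " CVAE" else " VAE",
                 ", final loss ",
                 round(fit$history$total[nrow(fit$history)], 3))
  }

  if ("evaluate" %in% stages) {
    pp <- readRDS(require_artifact(file.path(run_dir, "preprocessed.rds"),
                                   "preprocess"))
    model <- load_model(require_artifact(
      file.path(run_dir, "checkpoints", "model.rds"), "train"))
    ph <- pp$phenotypes
    grp_of <- function(w) ph$group[match(w$subject_id, ph$subject_id)]
    td <- pp$test[vapply(pp$test, grp_of, character(1)) == "TD"]
    asd <- pp$test[vapply(pp$test, grp_of, character(1)) == "ASD"]
    m_td <- cohort_reconstruction_metrics(model, td, ph, seed = seeds[4])
    m_asd <- cohort_reconstruction_metrics(model, asd, ph, seed = seeds[4])
    lat <- latent_group_test(encode_mus(model, td, ph),
                             encode_mus(model, asd, ph))
    metrics <- data.frame(
      cohort = c("TD", "ASD"),
      cosine = c(m_td$cosine, m_asd$cosine),
      pcc = c(m_td$pcc, m_asd$pcc),
      l1 = c(m_td$l1, m_asd$l1),
      n_windows = c(m_td$n, m_asd$n))
    dir.create(file.path(run_dir, "metrics"), showWarnings = FALSE)
    utils::write.csv(metrics, file.path(run_dir, "metrics", "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(reconstruction = metrics,
           latent_test = lat[c("t", "p_value", "significant")]),
      file.path(run_dir, "metrics", "metrics.json"),
      auto_unbox = TRUE, digits = NA)
    pipeline_log(run_dir, "evaluate: L1 TD ", signif(m_td$l1, 3), ", ASD ",
                 signif(m_asd$l1, 3), "; latent p ",
                 signif(lat$p_value, 3))
  }

  if ("fc" %in% stages) {
    pp <- readRDS(require_artifact(file.path(run_dir, "preprocessed.rds"),
                                   "preprocess"))
    model <- load_model(require_artifact(
      file.path(run_dir, "checkpoints", "model.rds"), "train"))
    ph <- pp$phenotypes
    atlas <- atlas_from_labels(rownames(pp$test[[1]]$matrix))
    fc_dir <- file.path(run_dir, "fc")
    dir.create(fc_dir, showWarnings = FALSE)
    alpha <- cfg$fc_analysis$alpha
    run_side <- function(windows, tag) {
      conn_in <- connectivity_set(windows, atlas)
      conn_cf <- counterfactual_connectivity(model, windows, ph, atlas,
                                             seed = seeds[5])
      div <- fc_divergence(conn_in, conn_cf, alpha = alpha)
      utils::write.csv(div, file.path(fc_dir, paste0("divergence_", tag, ".csv")),
                       row.names = FALSE)
      chord_diagram(div, file.path(fc_dir, paste0("chord_", tag, ".png")),
                    title = paste0("ASD vs neurotypical-like (", tag, ")"))
      div
    }
    grp_of <- function(w) ph$group[match(w$subject_id, ph$subject_id)]
    sex_of <- function(w) ph$sex[match(w$subject_id, ph$subject_id)]
    asd <- pp$test[vapply(pp$test, grp_of, character(1)) == "ASD"]
    assert_that(length(asd) >= 2, "need at least 2 neurodivergent test windows")
    res <- list(combined = run_side(asd, "combined"))
    if (isTRUE(cfg$fc_analysis$by_sex)) {
      sexes <- vapply(asd, sex_of, character(1))
      if (sum(sexes == "M") >= 2 && sum(sexes == "F") >= 2) {
        res$male <- run_side(asd[sexes == "M"], "male")
        res$female <- run_side(asd[sexes == "F"], "female")
        sim_mf <- fc_similarity(divergence_t_matrix(res$male),
                                divergence_t_matrix(res$female))
        jsonlite::write_json(list(fc_similarity_male_female = sim_mf),
                             file.path(fc_dir, "similarity.json"),
                             auto_unbox = TRUE, digits = NA)
        pipeline_log(run_dir, "fc: male/female t-map similarity ",
                     signif(sim_mf, 3))
      } else {
        pipeline_log(run_dir,
                     "fc: skipped by-sex analysis (fewer than 2 windows ",
                     "for one sex)")
      }
    }
    pipeline_log(run_dir, "fc: ", sum(res$combined$significant),
                 " significant pair(s) of ", nrow(res$combined))
  }
  invisible(run_dir)
}
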