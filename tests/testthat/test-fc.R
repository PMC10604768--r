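# brute-force oracle: explicit double loop over parcel pairs
oracle_connectivity <- function(mat, atlas) {
  nets <- attr(atlas, "networks")
  out <- matrix(NA_real_, length(nets), length(nets),
                dimnames = list(nets, nets))
  for (i in seq_along(nets)) for (j in seq_along(nets)) {
    A <- which(atlas$network == nets[i])
    B <- which(atlas$network == nets[j])
    vals <- c()
    for (a in A) for (b in B) {
      if (a == b) next
      if (i == j && a > b) next    # distinct unordered pairs on the diagonal
      vals <- c(vals, cor(mat[a, ], mat[b, ]))
    }
    out[i, j] <- mean(vals)
  }
  out
}

test_that("network connectivity agrees with trivial one-parcel cases", {
  labels <- c("7Networks_LH_Default_1", "7Networks_LH_Limbic_1")
  atlas <- atlas_from_labels(labels)
  x <- rnorm(30)
  m1 <- rbind(x, x); rownames(m1) <- labels
  expect_equal(network_connectivity(m1, atlas)["DMN", "Limbic"], 1)
  m2 <- rbind(x, -x); rownames(m2) <- labels
  expect_equal(network_connectivity(m2, atlas)["DMN", "Limbic"], -1)
})

test_that("network connectivity equals the brute-force parcel-pair oracle", {
  set.seed(17)
  for (rep in 1:10) {
    n_parcels <- sample(8:14, 1)
    cfg <- fc_sim_config(n_parcels = n_parcels, n_networks = 3,
                         scan_length_range = c(25, 35))
    atlas <- atlas_from_labels(cfg$parcel_labels)
    mat <- matrix(rnorm(n_parcels * 30), n_parcels, 30)
    got <- network_connectivity(mat, atlas)
    want <- oracle_connectivity(mat, atlas)
    expect_lt(max(abs(got - want), na.rm = TRUE), 1e-12)
    expect_equal(got, t(got))
    expect_true(all(abs(got[!is.na(got)]) <= 1 + 1e-12))
  }
})

test_that("excluded and zero-variance parcels are ignored", {
  labels <- c("7Networks_LH_Default_1", "7Networks_LH_Default_2",
              "7Networks_LH_Limbic_1", "7Networks_LH_Cont_Par_1")
  atlas <- atlas_from_labels(labels)
  set.seed(2)
  m <- matrix(rnorm(4 * 40), 4, 40, dimnames = list(labels, NULL))
  base <- network_connectivity(m, atlas)
  # perturbing the excluded control parcel changes nothing
  m2 <- m; m2[4, ] <- rnorm(40) * 100
  expect_equal(network_connectivity(m2, atlas), base)
  m3 <- m; m3[2, ] <- 5
  expect_warning(out <- network_connectivity(m3, atlas), "zero-variance")
  expect_equal(out["DMN", "Limbic"], cor(m3[1, ], m3[3, ]))
})

test_that("Welch divergence matches the hand-evaluated formula", {
  mk <- function(v) {
    m <- matrix(0, 2, 2, dimnames = list(c("DMN", "Limbic"), c("DMN", "Limbic")))
    m[1, 2] <- m[2, 1] <- v
    diag(m) <- NA
    structure(m, class = c("connectivity_matrix", "matrix", "array"))
  }
  a <- lapply(c(1, 2, 3, 4) / 10, mk)
  b <- lapply(c(2, 3, 4, 5) / 10, mk)
  res <- fc_divergence(a, b, include_diagonal = FALSE)
  expect_equal(nrow(res), 1)
  # hand calculation: equal sample variances, n = 4 each, so
  # t = (mean(a) - mean(b)) / sqrt(2 * s^2 / 4) and df = 6
  s2 <- var(c(1, 2, 3, 4) / 10)
  expect_equal(res$welch_t, -0.1 / sqrt(2 * s2 / 4), tolerance = 1e-10)
  expect_equal(res$welch_t, -1.095, tolerance = 1e-3)
  expect_equal(res$df, 6, tolerance = 1e-9)
  expect_equal(res$direction, "under")
})

test_that("identical sides give null divergence everywhere", {
  co <- tiny_cohort(seed = 51, n_per_cell = 2, scan_range = c(60, 70))
  atlas <- atlas_from_labels(co$config$parcel_labels)
  w <- cohort_windows(co$series, NULL, window = 40, step = 10)
  conn <- connectivity_set(w[1:5], atlas)
  res <- fc_divergence(conn, conn)
  expect_true(all(res$welch_t == 0))
  expect_true(all(res$p_value == 1))
  expect_false(any(res$significant))
  expect_error(fc_divergence(conn[1], conn), "at least 2")
})

test_that("BH adjustment is available and never increases significance", {
  set.seed(8)
  co <- tiny_cohort(seed = 52, n_per_cell = 3, scan_range = c(90, 120),
                    effects = fc_effect("DMN", "Limbic", group = "ASD",
                                        delta = -0.4))
  atlas <- atlas_from_labels(co$config$parcel_labels)
  w <- cohort_windows(co$series, NULL, window = 40, step = 10)
  g <- group_of(w, co$phenotypes)
  raw <- fc_divergence(connectivity_set(w[g == "ASD"], atlas),
                       connectivity_set(w[g == "TD"], atlas))
  adj <- fc_divergence(connectivity_set(w[g == "ASD"], atlas),
                       connectivity_set(w[g == "TD"], atlas), adjust = "BH")
  expect_lte(sum(adj$significant), sum(raw$significant))
  expect_true(all(adj$p_value >= raw$p_value - 1e-12))
})

test_that("fc_similarity is cosine on upper triangles", {
  set.seed(3)
  M <- matrix(rnorm(25), 5, 5); M <- M + t(M)
  dimnames(M) <- list(LETTERS[1:5], LETTERS[1:5])
  expect_equal(fc_similarity(M, M), 1)
  expect_equal(fc_similarity(M, -M), -1)
  A <- diag(2); B <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(fc_similarity(A, B), 0)  # orthogonal upper triangles
  expect_error(fc_similarity(M, M * 0), "zero-norm")
  M2 <- M; rownames(M2) <- letters[1:5]
  expect_error(fc_similarity(M, M2), "network order")
})

test_that("counterfactuals have the input shape and honor conditioning", {
  co <- tiny_cohort(seed = 53, n_per_cell = 2, scan_range = c(50, 60))
  w <- cohort_windows(co$series, NULL, window = 40, step = 10)
  ph1 <- co$phenotypes[match(w[[1]]$subject_id, co$phenotypes$subject_id), ]
  vae <- build_model(desk_model_config("CNN", latent_dim = 8, epochs = 1))
  set.seed(2); cf1 <- generate_counterfactual(vae, w[[1]])
  expect_equal(dim(cf1), dim(w[[1]]$matrix))
  set.seed(2); cf2 <- generate_counterfactual(vae, w[[1]])
  expect_identical(cf1, cf2)
  cvae <- build_model(desk_model_config("CNN", conditional = TRUE,
                                        latent_dim = 8, epochs = 1))
  expect_error(generate_counterfactual(cvae, w[[1]]), "phenotype")
  # no-flip identity: a neurotypical input's counterfactual equals its
  # plain reconstruction because the flipped group is already TD
  ph_td <- ph1; ph_td$group <- "TD"
  set.seed(5); cf_td <- generate_counterfactual(cvae, w[[1]], ph_td)
  set.seed(5); rec_td <- fcvae:::reconstruct_window(cvae, w[[1]]$matrix, ph_td)
  expect_identical(cf_td, rec_td)
  # the flip changes the decoder input, so ASD counterfactual differs from
  # plain reconstruction under the same latent draw
  ph_asd <- ph1; ph_asd$group <- "ASD"
  set.seed(5); cf_asd <- generate_counterfactual(cvae, w[[1]], ph_asd)
  set.seed(5); rec_asd <- fcvae:::reconstruct_window(cvae, w[[1]]$matrix, ph_asd)
  expect_false(identical(cf_asd, rec_asd))
})

test_that("injected coupling effects are recovered with the right sign", {
  # one cohort per seed carries both an under- and an over-connectivity
  # effect; the trained normative model must recover both directions
  t_under <- c(); t_over <- c()
  for (sd in 1:5) {
    cfg <- fc_sim_config(
      n_subjects_per_cell = 6, n_parcels = 20,
      scan_length_range = c(120, 160), sex_ratio = 1, noise_sd = 0.5,
      coupling_base = coupled_base(0.4), seed = 600 + sd,
      effect_table = rbind(
        fc_effect("DMN", "Limbic", group = "ASD", delta = -0.35),
        fc_effect("Salience", "Limbic", group = "ASD", delta = 0.35)))
    co <- generate_cohort(cfg)
    ph <- co$phenotypes
    sp <- subject_split(ph, 0.3, seed = sd)
    wtr <- cohort_windows(co$series, sp$train, 40, 10, per_parcel = TRUE)
    wte <- cohort_windows(co$series, sp$test, 40, 40, per_parcel = TRUE)
    atlas <- atlas_from_labels(cfg$parcel_labels)
    fit <- train_model(build_model(desk_model_config("CNN", epochs = 30,
                                                     seed = sd)),
                       wtr, ph)
    asd <- wte[group_of(wte, ph) == "ASD"]
    div <- fc_divergence(connectivity_set(asd, atlas),
                         counterfactual_connectivity(fit$model, asd, ph,
                                                     atlas, seed = 1))
    t_under <- c(t_under, div$welch_t[div$network_a == "DMN" &
                                        div$network_b == "Limbic"])
    t_over <- c(t_over, div$welch_t[div$network_a == "Limbic" &
                                      div$network_b == "Salience"])
  }
  expect_lt(mean(t_under), 0)
  expect_gt(mean(t_over), 0)
  expect_gte(sum(t_under < 0), 4)
  expect_gte(sum(t_over > 0), 4)
})
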