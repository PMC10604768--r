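test_that("shape chain reports the conditional concatenation contracts", {
  cfg <- model_config("CNN", conditional = TRUE)  # full-scale defaults
  shp <- model_shapes(cfg)
  expect_equal(shp$encoder_input_rows, 201)
  expect_equal(shp$decoder_input_len, 2200)
  cfg0 <- model_config("CNN", conditional = FALSE)
  expect_equal(model_shapes(cfg0)$encoder_input_rows, 200)
  expect_equal(model_shapes(cfg0)$decoder_input_len, 2000)
  # embedding must be stackable as a parcel row
  expect_error(model_config("CNN", conditional = TRUE, embedding_dim = 150),
               "embedding_dim")
})

test_that("every family round-trips shapes and stays in [0, 1]", {
  ph <- data.frame(subject_id = "s", age = 12, sex = "F", group = "ASD",
                   site = "x")
  set.seed(5)
  x <- matrix(runif(6 * 8), 6, 8)
  for (family in c("CNN", "RNN", "HYBRID")) {
    for (conditional in c(FALSE, TRUE)) {
      m <- build_model(micro_model_config(family, conditional))
      expect_gt(n_parameters(m), 0)
      y <- if (conditional) make_condition_embedding(ph, m)
      enc <- encode(m, x, y)
      expect_length(enc$mu, 5)
      expect_length(enc$logvar, 5)
      set.seed(1); z <- reparameterize(enc$mu, enc$logvar)
      xh <- decode(m, z, y)
      expect_equal(dim(xh), c(6, 8))
      expect_true(all(xh >= 0 & xh <= 1))
      # deterministic encoder
      expect_identical(enc, encode(m, x, y))
    }
  }
})

test_that("shape mismatches are rejected with expected-vs-got messages", {
  m <- build_model(micro_model_config("CNN"))
  expect_error(encode(m, matrix(0.5, 5, 8)), "expected 6x8.*got 5x8")
  expect_error(decode(m, rep(0, 4)), "length 5.*got 4")
  mc <- build_model(micro_model_config("CNN", conditional = TRUE))
  expect_error(encode(mc, matrix(0.5, 6, 8)), "needs y")
  expect_error(decode(mc, rep(0, 5)), "needs y")
})

test_that("reparameterization has the right moments and limits", {
  # zero-variance limit: z collapses onto mu
  mu <- c(1.5, -2, 0.25)
  expect_equal(reparameterize(mu, rep(-1e10, 3)), mu)
  # standard-normal case: sample moments at Monte-Carlo tolerance 3/sqrt(n)
  set.seed(7)
  n <- 1e4
  z <- replicate(n, reparameterize(0, 0))
  expect_lt(abs(mean(z)), 3 / sqrt(n))
  expect_lt(abs(var(z) - 1), 3 * sqrt(2 / n))
  set.seed(42); a <- reparameterize(mu, c(0, 0, 0))
  set.seed(42); b <- reparameterize(mu, c(0, 0, 0))
  expect_identical(a, b)
})

test_that("condition embedding is deterministic and phenotype-sensitive", {
  m <- build_model(micro_model_config("CNN", conditional = TRUE))
  ph <- data.frame(subject_id = "s", age = 12, sex = "F", group = "ASD",
                   site = "x")
  y1 <- make_condition_embedding(ph, m)
  expect_length(y1$y, 8)   # embedding_dim == window
  expect_identical(y1, make_condition_embedding(ph, m))
  ph_td <- ph; ph_td$group <- "TD"
  y2 <- make_condition_embedding(ph_td, m)
  expect_equal(unname(abs(y1$raw[3] - y2$raw[3])), 1)
  expect_false(isTRUE(all.equal(y1$y, y2$y)))
  ph_m <- ph; ph_m$sex <- "M"
  expect_false(isTRUE(all.equal(make_condition_embedding(ph_m, m)$y, y1$y)))
  # out-of-range age is clipped with a warning
  ph_old <- ph; ph_old$age <- 95
  expect_warning(make_condition_embedding(ph_old, m), "clip")
})

test_that("hybrid latent fusion multiplies means and adds log-variances", {
  m <- build_model(micro_model_config("HYBRID"))
  set.seed(6)
  x <- matrix(runif(48), 6, 8)
  X4 <- array(x, c(1, 1, 6, 8))
  enc_c <- fcvae:::cnn_enc_fwd(m, X4, training = FALSE)
  enc_r <- fcvae:::rnn_enc_fwd(m, fcvae:::as_seq(array(x, c(1, 6, 8))))
  fused <- encode(m, x)
  expect_equal(fused$mu, drop(enc_c$mu * enc_r$mu))
  expect_equal(fused$logvar, drop(enc_c$logvar + enc_r$logvar))
  # multiplicative identity: an all-ones recurrent mean leaves the
  # convolutional mean unchanged
  m1 <- m
  m1$params$enc_rnn_mu_W[] <- 0
  m1$params$enc_rnn_mu_b[] <- 1
  expect_equal(encode(m1, x)$mu, drop(enc_c$mu))
})

test_that("training reduces the loss, is seeded, and enforces TD-only VAEs", {
  co <- tiny_cohort(seed = 41, n_per_cell = 3, scan_range = c(60, 90))
  w <- cohort_windows(co$series, NULL, window = 40, step = 10)
  cfg <- desk_model_config("CNN", latent_dim = 16, epochs = 8, seed = 2)
  fit1 <- train_model(build_model(cfg), w, co$phenotypes)
  expect_lt(fit1$history$total[8], fit1$history$total[1])
  expect_true(all(fit1$history$kl >= -1e-9))
  fit2 <- train_model(build_model(cfg), w, co$phenotypes)
  expect_equal(fit1$history, fit2$history)
  # VAE mode with no neurotypical windows is a precondition failure
  asd_only <- w[group_of(w, co$phenotypes) == "ASD"]
  expect_error(train_model(build_model(cfg), asd_only, co$phenotypes),
               class = "fcvae_empty_training")
})

test_that("checkpoints reload bit-exactly with a config sidecar", {
  co <- tiny_cohort(seed = 43, n_per_cell = 2, scan_range = c(50, 60))
  w <- cohort_windows(co$series, NULL, window = 40, step = 10)
  cfg <- desk_model_config("CNN", latent_dim = 8, epochs = 2, seed = 3)
  fit <- train_model(build_model(cfg), w, co$phenotypes)
  path <- file.path(withr::local_tempdir(), "model.rds")
  save_model(fit$model, path)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$family, "CNN")
  expect_equal(side$seed, 3)
  back <- load_model(path)
  x <- w[[1]]$matrix
  expect_identical(encode(fit$model, x), encode(back, x))
})
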