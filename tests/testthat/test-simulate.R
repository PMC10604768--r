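test_that("coupling matrix applies effects to matching cells only", {
  cfg <- fc_sim_config(effect_table = fc_effect("DMN", "Limbic",
                                                group = "ASD", delta = -0.3))
  td <- build_coupling_matrix(cfg, "TD", "M")
  asd <- build_coupling_matrix(cfg, "ASD", "M")
  expect_equal(td, {
    b <- cfg$coupling_base; dimnames(b) <- dimnames(td); b
  })
  expect_equal(asd["DMN", "Limbic"], cfg$coupling_base[1, 2] - 0.3)
  expect_equal(asd["Limbic", "DMN"], asd["DMN", "Limbic"])
  # untouched entries unchanged
  expect_equal(asd["Visual", "Salience"], td["Visual", "Salience"])
})

test_that("empty effect table leaves the base coupling unchanged", {
  cfg <- fc_sim_config()
  expect_equal(unname(build_coupling_matrix(cfg, "ASD", "F")),
               unname(cfg$coupling_base))
})

test_that("sex- and any-level effects match the right cells", {
  cfg <- fc_sim_config(effect_table = rbind(
    fc_effect("Salience", "Limbic", group = "any", sex = "M", delta = 0.3),
    fc_effect("DMN", "Visual", group = "ASD", sex = "F", delta = -0.2)))
  expect_equal(build_coupling_matrix(cfg, "TD", "M")["Salience", "Limbic"],
               0.2 + 0.3)
  expect_equal(build_coupling_matrix(cfg, "TD", "F")["Salience", "Limbic"],
               0.2)
  expect_equal(build_coupling_matrix(cfg, "ASD", "F")["DMN", "Visual"], 0)
  expect_equal(build_coupling_matrix(cfg, "ASD", "M")["DMN", "Visual"], 0.2)
})

test_that("perturbed coupling is repaired to positive semidefinite", {
  base <- diag(5)
  cfg <- fc_sim_config(coupling_base = base, effect_table = fc_effect(
    "Salience", "Limbic", group = "ASD", sex = "M", delta = 0.5))
  C <- build_coupling_matrix(cfg, "ASD", "M")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-10))
  expect_equal(unname(diag(C)), rep(1, 5))
  # a deliberately inconsistent perturbation is projected, not passed through
  cfg2 <- fc_sim_config(coupling_base = base, effect_table = rbind(
    fc_effect("DMN", "Limbic", group = "ASD", delta = 0.95),
    fc_effect("DMN", "Visual", group = "ASD", delta = 0.95),
    fc_effect("Limbic", "Visual", group = "ASD", delta = -0.95)))
  C2 <- build_coupling_matrix(cfg2, "ASD", "M")
  ev2 <- eigen(C2, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev2 >= -1e-10))
})

test_that("out-of-range coupling raises an invalid-effect error", {
  cfg <- fc_sim_config(effect_table = fc_effect("DMN", "Limbic",
                                                group = "ASD", delta = 0.9))
  expect_error(build_coupling_matrix(cfg, "ASD", "M"),
               class = "fcvae_invalid_effect")
  expect_silent(build_coupling_matrix(cfg, "TD", "M"))
})

test_that("zero noise makes same-network parcel rows identical", {
  cfg <- fc_sim_config(n_parcels = 10, noise_sd = 0,
                       scan_length_range = c(50, 50))
  ph <- data.frame(subject_id = "s1", age = 12, sex = "M", group = "TD",
                   site = "site1")
  ts <- simulate_subject(cfg, ph, seed = 4)
  same_net <- which(cfg$parcel_network == cfg$parcel_network[1])
  expect_equal(ts$matrix[same_net[1], ], ts$matrix[same_net[2], ])
  expect_equal(cor(ts$matrix[same_net[1], ], ts$matrix[same_net[2], ]), 1)
})

test_that("sample cross-network correlation tracks the configured coupling", {
  ph <- data.frame(subject_id = "s1", age = 12, sex = "M", group = "TD",
                   site = "site1")
  # identity coupling: between-network parcel correlation -> 0 as T grows
  cfg0 <- fc_sim_config(n_parcels = 10, noise_sd = 0, coupling_base = diag(5),
                        scan_length_range = c(5000, 5000))
  ts0 <- simulate_subject(cfg0, ph, seed = 9)
  nets <- cfg0$parcel_network
  r0 <- cor(ts0$matrix[which(nets == 1)[1], ], ts0$matrix[which(nets == 2)[1], ])
  expect_lt(abs(r0), 0.05)
  # nonzero coupling: correlation approaches the configured entry
  base <- diag(5); base[1, 2] <- base[2, 1] <- 0.6
  cfg1 <- fc_sim_config(n_parcels = 10, noise_sd = 0, coupling_base = base,
                        scan_length_range = c(5000, 5000))
  ts1 <- simulate_subject(cfg1, ph, seed = 9)
  r1 <- cor(ts1$matrix[which(nets == 1)[1], ], ts1$matrix[which(nets == 2)[1], ])
  expect_lt(abs(r1 - 0.6), 0.05)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- fc_sim_config(n_parcels = 12, scan_length_range = c(60, 90))
  ph <- data.frame(subject_id = "s1", age = 20, sex = "F", group = "ASD",
                   site = "site2")
  a <- simulate_subject(cfg, ph, seed = 123)
  b <- simulate_subject(cfg, ph, seed = 123)
  expect_identical(a$matrix, b$matrix)
  co1 <- generate_cohort(fc_sim_config(n_subjects_per_cell = 2,
                                       n_parcels = 8,
                                       scan_length_range = c(50, 60),
                                       seed = 77))
  co2 <- generate_cohort(fc_sim_config(n_subjects_per_cell = 2,
                                       n_parcels = 8,
                                       scan_length_range = c(50, 60),
                                       seed = 77))
  expect_identical(lapply(co1$series, `[[`, "matrix"),
                   lapply(co2$series, `[[`, "matrix"))
  expect_identical(co1$phenotypes, co2$phenotypes)
})

test_that("cohort counts and sex ratio follow the configuration", {
  co <- generate_cohort(fc_sim_config(n_subjects_per_cell = 10,
                                      n_parcels = 6,
                                      scan_length_range = c(30, 40),
                                      seed = 5))
  expect_length(co$series, 40)
  expect_equal(nrow(co$phenotypes), 40)
  expect_setequal(unique(co$phenotypes$group), c("TD", "ASD"))
  # binomial check of the male fraction at 4:1 over a large phenotype draw
  big <- fc_sim_config(n_subjects_per_cell = 500, n_parcels = 6,
                       scan_length_range = c(30, 40), sex_ratio = 4, seed = 8)
  set.seed(8)
  ph <- sample_phenotypes(big)
  frac_m <- mean(ph$sex == "M")
  tol <- 3 * sqrt(0.8 * 0.2 / nrow(ph))
  expect_lt(abs(frac_m - 0.8), tol)
})

test_that("invalid configurations are rejected", {
  expect_error(fc_sim_config(n_subjects_per_cell = 0), "n_subjects_per_cell")
  expect_error(fc_sim_config(ar_coefficient = 1), "ar_coefficient")
  expect_error(fc_sim_config(coupling_base = matrix(2, 5, 5)), "coupling")
  expect_error(fc_sim_config(effect_table = fc_effect("DMN", "Nope",
                                                      group = "ASD",
                                                      delta = 0.1)),
               "networks")
})
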