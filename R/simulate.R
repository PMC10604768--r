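#' Build the effective network coupling matrix for one (group, sex) cell
#'
#' Starts from `config$coupling_base`, adds every matching `effect_table`
#' delta to the named entry and its mirror, then repairs the result to the
#' nearest valid correlation matrix (eigenvalue clipping at zero followed by
#' rescaling to unit diagonal) if the perturbation broke positive
#' semidefiniteness.
#'
#' @param config An [fc_sim_config()].
#' @param group `"TD"` or `"ASD"`.
#' @param sex `"M"` or `"F"`.
#' @return A symmetric positive semidefinite matrix with unit diagonal.
#' @examples
#' cfg <- fc_sim_config(effect_table =
#'   fc_effect("DMN", "Limbic", group = "ASD", delta = -0.3))
#' build_coupling_matrix(cfg, "ASD", "M")["DMN", "Limbic"]
#' @export
build_coupling_matrix <- function(config, group, sex) {
  assert_that(inherits(config, "fc_sim_config"), "config must be fc_sim_config")
  assert_that(group %in% c("TD", "ASD"), "group must be TD or ASD")
  assert_that(sex %in% c("M", "F"), "sex must be M or F")
  C <- config$coupling_base
  nets <- config$network_names
  dimnames(C) <- list(nets, nets)
  tab <- config$effect_table
  if (nrow(tab)) {
    hit <- (tab$group == group | tab$group == "any") &
           (tab$sex == sex | tab$sex == "any")
    for (r in which(hit)) {
      i <- match(tab$network_i[r], nets)
      j <- match(tab$network_j[r], nets)
      C[i, j] <- C[i, j] + tab$delta[r]
      if (i != j) C[j, i] <- C[i, j]
    }
  }
  tol <- 1e-8
  if (any(C < -1 - tol | C > 1 + tol)) {
    bad <- which(abs(C) > 1 + tol, arr.ind = TRUE)[1, ]
    stop_fc("invalid effect: coupling entry (", nets[bad[1]], ", ",
            nets[bad[2]], ") = ", signif(C[bad[1], bad[2]], 4),
            " outside [-1, 1] after perturbation",
            class = "fcvae_invalid_effect")
  }
  C <- pmin(pmax(C, -1), 1)
  nearest_correlation(C)
}

# nearest-correlation heuristic: clip eigenvalues at 0, rescale unit diagonal
nearest_correlation <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < -1e-10) {
    lam <- pmax(e$values, 0)
    C <- e$vectors %*% (lam * t(e$vectors))
    d <- sqrt(pmax(diag(C), .Machine$double.eps))
    C <- C / (d %o% d)
    C <- (C + t(C)) / 2
  }
  diag(C) <- 1
  C
}

#' Simulate one subject's parcellated BOLD matrix
#'
#' Draws `n_networks` latent signals as a stationary AR(1) process whose
#' innovations have the cross-network correlation produced by
#' [build_coupling_matrix()] for the subject's (group, sex) cell, then
#' observes each parcel as its network's signal plus i.i.d. Gaussian noise.
#' The scan length is drawn uniformly from `config$scan_length_range`.
#'
#' @param config An [fc_sim_config()].
#' @param phenotype A one-row data frame with at least `subject_id`, `sex`,
#'   `group` (see [sample_phenotypes()]).
#' @param seed Optional integer seed; when given the draw is fully
#'   reproducible and the caller's RNG state is untouched.
#' @return A `parcel_ts` object: `subject_id`, `matrix`
#'   (`n_parcels x T`, parcel labels as rownames), `parcel_labels`, `tr_ms`.
#' @export
simulate_subject <- function(config, phenotype, seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed, simulate_subject(config, phenotype)))
  assert_that(inherits(config, "fc_sim_config"), "config must be fc_sim_config")
  assert_that(all(c("subject_id", "sex", "group") %in% names(phenotype)),
              "phenotype needs subject_id, sex, group")
  C <- build_coupling_matrix(config, phenotype$group, phenotype$sex)
  e <- eigen(C, symmetric = TRUE)
  assert_that(min(e$values) > -1e-8,
              "coupling matrix not PSD after projection")
  # matrix square root handles rank-deficient (PSD) couplings that chol cannot
  Csqrt <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))

  T_len <- if (config$scan_length_range[1] == config$scan_length_range[2]) {
    config$scan_length_range[1]
  } else sample(seq(config$scan_length_range[1], config$scan_length_range[2]), 1)

  K <- config$n_networks
  phi <- config$ar_coefficient
  innov <- Csqrt %*% matrix(rnorm(K * T_len), K, T_len)
  S <- matrix(0, K, T_len)
  S[, 1] <- innov[, 1]
  if (T_len > 1) {
    scale_innov <- sqrt(1 - phi^2)   # keeps marginal variance at 1
    for (t in 2:T_len) S[, t] <- phi * S[, t - 1] + scale_innov * innov[, t]
  }
  X <- S[config$parcel_network, , drop = FALSE]
  if (config$noise_sd > 0) {
    X <- X + matrix(rnorm(length(X), sd = config$noise_sd), nrow(X), ncol(X))
  }
  rownames(X) <- config$parcel_labels
  parcel_ts(phenotype$subject_id, X, config$parcel_labels)
}

#' Construct a parcel-by-time BOLD container
#'
#' @param subject_id Subject identifier.
#' @param matrix `n_parcels x T` numeric matrix of BOLD values.
#' @param parcel_labels Atlas-style parcel names, one per row.
#' @param tr_ms Repetition time in milliseconds.
#' @return An object of class `parcel_ts`.
#' @export
parcel_ts <- function(subject_id, matrix, parcel_labels = rownames(matrix),
                      tr_ms = 2000) {
  assert_that(is.matrix(matrix) && is.numeric(matrix), "matrix must be numeric")
  assert_that(!anyNA(matrix) && all(is.finite(matrix)),
              "BOLD matrix must be finite with no missing values")
  assert_that(length(parcel_labels) == nrow(matrix),
              "parcel_labels length must equal the number of rows")
  rownames(matrix) <- parcel_labels
  structure(list(subject_id = as.character(subject_id), matrix = matrix,
                 parcel_labels = as.character(parcel_labels),
                 tr_ms = tr_ms), class = "parcel_ts")
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("<parcel_ts> %s: %d parcels x %d time steps (TR %d ms)\n",
              x$subject_id, nrow(x$matrix), ncol(x$matrix), x$tr_ms))
  invisible(x)
}

#' Sample a phenotype table for a simulated cohort
#'
#' Each diagnostic group receives `2 * n_subjects_per_cell` subjects; sex is
#' Bernoulli with male probability `sex_ratio / (1 + sex_ratio)`, age is
#' uniform over `age_range`, and subjects are spread over three nominal
#' acquisition sites.
#'
#' @param config An [fc_sim_config()].
#' @return Data frame with columns `subject_id`, `age`, `sex`, `group`, `site`.
#' @export
sample_phenotypes <- function(config) {
  assert_that(inherits(config, "fc_sim_config"), "config must be fc_sim_config")
  n_group <- 2L * config$n_subjects_per_cell
  groups <- rep(c("TD", "ASD"), each = n_group)
  n <- length(groups)
  p_male <- config$sex_ratio / (1 + config$sex_ratio)
  data.frame(
    subject_id = sprintf("sub-%04d", seq_len(n)),
    age = round(runif(n, config$age_range[1], config$age_range[2]), 1),
    sex = ifelse(rbinom(n, 1, p_male) == 1, "M", "F"),
    group = groups,
    site = paste0("site", (seq_len(n) - 1L) %% 3L + 1L),
    stringsAsFactors = FALSE
  )
}

#' Generate a full synthetic cohort
#'
#' Samples phenotypes and one parcellated BOLD series per subject, fully
#' reproducible from `config$seed`.
#'
#' @param config An [fc_sim_config()].
#' @return A list with `series` (list of [parcel_ts()]) and `phenotypes`
#'   (data frame, one row per subject, same order).
#' @export
generate_cohort <- function(config) {
  assert_that(inherits(config, "fc_sim_config"), "config must be fc_sim_config")
  assert_that(config$n_subjects_per_cell >= 1, "n_subjects_per_cell must be >= 1")
  with_seed(config$seed, {
    phen <- sample_phenotypes(config)
    series <- lapply(seq_len(nrow(phen)), function(i)
      simulate_subject(config, phen[i, ]))
    list(series = series, phenotypes = phen)
  })
}
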