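#' Generate a neurotypical-like counterfactual reconstruction
#'
#' For an unconditional model (trained on neurotypical windows only) the
#' counterfactual is the plain reconstruction: the decoder can only express
#' patterns of the typical population, so the output of an atypical input
#' drifts toward them.  For a conditional model the window is encoded with
#' its TRUE phenotype embedding and decoded with the embedding whose
#' diagnostic group is flipped to neurotypical, age and sex unchanged —
#' input-versus-output differences are then attributable to the flipped
#' condition alone.
#'
#' @param model A trained `fc_vae`.
#' @param window A `window_sample` or a `n_parcels x window` matrix.
#' @param phenotype One-row phenotype data frame; required for conditional
#'   models.
#' @return Matrix of the same shape as the input window.
#' @export
generate_counterfactual <- function(model, window, phenotype = NULL) {
  x <- if (inherits(window, "window_sample")) window$matrix else window
  cfg <- model$config
  if (!cfg$conditional) {
    enc <- encode(model, x)
    z <- reparameterize(enc$mu, enc$logvar)
    return(decode(model, z))
  }
  if (is.null(phenotype)) {
    stop_fc("conditional counterfactual requires the window's phenotype")
  }
  y_true <- make_condition_embedding(phenotype, model)
  target <- phenotype
  target$group <- "TD"
  y_target <- make_condition_embedding(target, model)
  enc <- encode(model, x, y_true)
  z <- reparameterize(enc$mu, enc$logvar)
  decode(model, z, y_target)
}

#' Network-pair functional connectivity of one window
#'
#' For every unordered pair of retained networks (A, B), the connectivity is
#' the mean Pearson correlation over all parcel pairs (a in A, b in B,
#' a != b); the diagonal holds the within-network mean over distinct parcel
#' pairs.  Parcels marked `EXCLUDED` by the atlas are ignored; parcel rows
#' with zero variance are dropped with a warning.  Averaging the parcel-pair
#' correlations (rather than correlating network-mean signals) keeps the
#' estimate insensitive to network size; the alternative is available via
#' `method = "mean_signal"`.
#'
#' @param matrix `n_parcels x T` matrix (a window or a full scan).
#' @param atlas A `network_atlas` covering every row.
#' @param method `"parcel_pairs"` (default) or `"mean_signal"`.
#' @return A `connectivity_matrix`: symmetric `K x K` matrix over the
#'   retained networks, entries in \[-1, 1\].
#' @export
network_connectivity <- function(matrix, atlas,
                                 method = c("parcel_pairs", "mean_signal")) {
  method <- match.arg(method)
  assert_that(ncol(matrix) >= 2, "need at least 2 time points")
  assert_that(nrow(matrix) == nrow(atlas),
              "atlas covers ", nrow(atlas), " parcels but matrix has ",
              nrow(matrix), " rows")
  nets <- attr(atlas, "networks")
  keep <- atlas$network != "EXCLUDED"
  sds <- apply(matrix, 1, stats::sd)
  flat <- keep & sds == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance parcel(s) dropped from connectivity",
            call. = FALSE)
    keep <- keep & !flat
  }
  X <- matrix[keep, , drop = FALSE]
  grp <- atlas$network[keep]
  K <- length(nets)
  out <- base::matrix(NA_real_, K, K, dimnames = list(nets, nets))
  if (method == "parcel_pairs") {
    R <- stats::cor(t(X))
    for (i in seq_len(K)) for (j in i:K) {
      ai <- which(grp == nets[i]); aj <- which(grp == nets[j])
      if (i == j) {
        if (length(ai) < 2) { out[i, i] <- NA_real_; next }
        v <- R[ai, ai][upper.tri(R[ai, ai])]
      } else {
        v <- R[ai, aj, drop = FALSE]
      }
      out[i, j] <- out[j, i] <- mean(v)
    }
  } else {
    M <- t(vapply(nets, function(nm)
      colMeans(X[grp == nm, , drop = FALSE]), numeric(ncol(X))))
    out <- stats::cor(t(M))
    dimnames(out) <- list(nets, nets)
  }
  structure(out, class = c("connectivity_matrix", "matrix", "array"))
}

#' Welch-t divergence map between two sets of connectivity matrices
#'
#' For each unordered network pair, compares the entries of the input-group
#' connectivity matrices against the synthetic (counterfactual) group with
#' an unpaired two-sided Welch t test (unequal variances,
#' Welch-Satterthwaite degrees of freedom).  A negative t means the input
#' group's connectivity is below the neurotypical-like reference
#' (under-connectivity); positive means above (over-connectivity).  Raw
#' p-values are thresholded at `alpha` by default; Benjamini-Hochberg
#' adjustment and a paired variant are available behind flags.
#'
#' @param conn_input,conn_synthetic Lists of `connectivity_matrix` objects
#'   (at least 2 per side).
#' @param alpha Significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param paired Use a paired t test (sides matched 1:1).
#' @param fisher_z Apply Fisher's z transform to the correlations before
#'   testing.
#' @param include_diagonal Also test within-network (diagonal) entries.
#' @return An `fc_divergence` data frame: `network_a`, `network_b`,
#'   `welch_t`, `df`, `p_value`, `significant`, `direction`.
#' @export
fc_divergence <- function(conn_input, conn_synthetic, alpha = 0.05,
                          adjust = c("none", "BH"), paired = FALSE,
                          fisher_z = FALSE, include_diagonal = TRUE) {
  adjust <- match.arg(adjust)
  assert_that(length(conn_input) >= 2 && length(conn_synthetic) >= 2,
              "need at least 2 connectivity matrices per side")
  nets <- rownames(conn_input[[1]])
  K <- length(nets)
  pairs <- which(upper.tri(diag(K), diag = include_diagonal), arr.ind = TRUE)
  res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    a <- vapply(conn_input, function(m) m[i, j], numeric(1))
    b <- vapply(conn_synthetic, function(m) m[i, j], numeric(1))
    if (fisher_z) { a <- atanh(pmin(pmax(a, -1 + 1e-12), 1 - 1e-12))
                    b <- atanh(pmin(pmax(b, -1 + 1e-12), 1 - 1e-12)) }
    if (all(a == a[1]) && all(b == b[1]) && a[1] == b[1]) {
      return(data.frame(network_a = nets[i], network_b = nets[j],
                        welch_t = 0, df = length(a) + length(b) - 2,
                        p_value = 1, stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(a, b, paired = paired, var.equal = FALSE)
    data.frame(network_a = nets[i], network_b = nets[j],
               welch_t = unname(tt$statistic),
               df = unname(tt$parameter), p_value = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  if (adjust == "BH") res$p_value <- stats::p.adjust(res$p_value, "BH")
  res$significant <- res$p_value < alpha
  res$direction <- ifelse(res$welch_t < 0, "under", "over")
  class(res) <- c("fc_divergence", "data.frame")
  res
}

#' Cosine similarity of two functional-connectivity result matrices
#'
#' Vectorizes the upper triangles (diagonal included) of two matrices on the
#' same network order — e.g. the male and female Welch-t maps, or mean
#' connectivity-difference matrices — and returns their cosine similarity.
#' Comparing male against female results per model quantifies how sex-biased
#' the detected divergence pattern is: higher similarity means the pattern is
#' shared across sexes.
#'
#' @param result_male,result_female Square matrices with identical network
#'   order (connectivity differences or t-value maps).
#' @return Cosine similarity in \[-1, 1\].
#' @export
fc_similarity <- function(result_male, result_female) {
  assert_that(all(dim(result_male) == dim(result_female)),
              "matrices must have the same dimensions")
  if (!is.null(rownames(result_male)) && !is.null(rownames(result_female))) {
    assert_that(identical(rownames(result_male), rownames(result_female)),
                "network order differs between the two matrices")
  }
  ut <- upper.tri(result_male, diag = TRUE)
  a <- result_male[ut]; b <- result_female[ut]
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop_fc("cosine undefined for zero-norm input")
  sum(a * b) / (na * nb)
}

#' Turn an fc_divergence result into a t-value matrix
#'
#' @param result An `fc_divergence` data frame.
#' @param networks Network order (defaults to the canonical five).
#' @return Symmetric matrix of Welch t values (0 where untested).
#' @export
divergence_t_matrix <- function(result, networks = NULL) {
  networks <- networks %||% unique(c(result$network_a, result$network_b))
  M <- base::matrix(0, length(networks), length(networks),
                    dimnames = list(networks, networks))
  for (r in seq_len(nrow(result))) {
    i <- match(result$network_a[r], networks)
    j <- match(result$network_b[r], networks)
    M[i, j] <- M[j, i] <- result$welch_t[r]
  }
  M
}

#' Connectivity matrices of a list of windows
#'
#' @param windows List of `window_sample` objects or matrices.
#' @param atlas A `network_atlas`.
#' @param ... Passed to [network_connectivity()].
#' @return List of `connectivity_matrix` objects.
#' @export
connectivity_set <- function(windows, atlas, ...) {
  lapply(windows, function(w) {
    m <- if (inherits(w, "window_sample")) w$matrix else w
    network_connectivity(m, atlas, ...)
  })
}

#' Counterfactual connectivity for a set of windows
#'
#' Generates the neurotypical-like counterfactual of every window (see
#' [generate_counterfactual()]) and computes its network connectivity.
#'
#' @param model A trained `fc_vae`.
#' @param windows List of `window_sample` objects.
#' @param phenotypes Phenotype data frame (required for conditional models).
#' @param atlas A `network_atlas`.
#' @param seed Seed for the latent draws.
#' @param ... Passed to [network_connectivity()].
#' @return List of `connectivity_matrix` objects.
#' @export
counterfactual_connectivity <- function(model, windows, phenotypes, atlas,
                                        seed = 1L, ...) {
  Xh <- with_seed(seed, counterfactual_batch(model, windows, phenotypes))
  lapply(seq_len(dim(Xh)[1]), function(i) {
    network_connectivity(matrix(Xh[i, , ], dim(Xh)[2], dim(Xh)[3]),
                         atlas, ...)
  })
}

# batched counterfactual generation: encode with true conditions, decode with
# the group flipped to TD (unconditional models: plain reconstruction)
counterfactual_batch <- function(model, windows, phenotypes = NULL) {
  cfg <- model$config
  n <- length(windows)
  X <- array(0, c(n, cfg$n_parcels, cfg$window))
  for (i in seq_len(n)) X[i, , ] <- windows[[i]]$matrix
  raw_true <- raw_tgt <- NULL
  if (cfg$conditional) {
    ids <- vapply(windows, function(w) w$subject_id, character(1))
    ph <- phenotypes[match(ids, phenotypes$subject_id), , drop = FALSE]
    assert_that(!anyNA(ph$group), "phenotype rows missing for some windows")
    raw_true <- cond_raw_matrix(ph, cfg)
    ph_tgt <- ph; ph_tgt$group <- "TD"
    raw_tgt <- cond_raw_matrix(ph_tgt, cfg)
  }
  Y_true <- if (cfg$conditional) embed_fwd(model$params, raw_true)
  Y_tgt <- if (cfg$conditional) embed_fwd(model$params, raw_tgt)
  Xenc <- if (cfg$conditional) stack_condition(X, Y_true) else X
  if (cfg$family == "CNN") {
    X4 <- Xenc; dim(X4) <- c(n, 1L, dim(Xenc)[2], dim(Xenc)[3])
    enc <- cnn_enc_fwd(model, X4, training = FALSE)
    mu <- enc$mu; lv <- enc$logvar
  } else if (cfg$family == "RNN") {
    enc <- rnn_enc_fwd(model, as_seq(Xenc))
    mu <- enc$mu; lv <- enc$logvar
  } else {
    X4 <- Xenc; dim(X4) <- c(n, 1L, dim(Xenc)[2], dim(Xenc)[3])
    enc_c <- cnn_enc_fwd(model, X4, training = FALSE)
    enc_r <- rnn_enc_fwd(model, as_seq(Xenc))
    mu <- enc_c$mu * enc_r$mu; lv <- enc_c$logvar + enc_r$logvar
  }
  z <- mu + exp(lv / 2) * matrix(rnorm(n * cfg$latent_dim), n, cfg$latent_dim)
  Zin <- if (cfg$conditional) cbind(z, Y_tgt) else z
  if (cfg$family == "CNN") {
    cnn_dec_fwd(model, Zin, training = FALSE)$x_hat
  } else if (cfg$family == "RNN") {
    rnn_dec_fwd(model, Zin)$x_hat
  } else {
    (cnn_dec_fwd(model, Zin, training = FALSE)$x_hat +
       rnn_dec_fwd(model, Zin)$x_hat) / 2
  }
}
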