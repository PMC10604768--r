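#' Reconstruction quality metrics
#'
#' Flattens input and reconstruction and reports cosine similarity
#' (`dot / (|x| |x_hat|)`), Pearson correlation, and L1 (mean absolute error
#' per matrix element, in normalized BOLD units).  Cohort-level values are
#' conventionally means of these per-sample metrics (see
#' [cohort_reconstruction_metrics()]).
#'
#' @param x,x_hat Matrices of the same shape.
#' @return List with `cosine`, `pcc`, `l1`.
#' @examples
#' x <- matrix(runif(20), 4, 5)
#' reconstruction_metrics(x, x)  # (1, 1, 0)
#' @export
reconstruction_metrics <- function(x, x_hat) {
  assert_that(all(dim(as.matrix(x)) == dim(as.matrix(x_hat))),
              "x and x_hat must have the same shape")
  a <- as.numeric(x); b <- as.numeric(x_hat)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop_fc("cosine undefined for zero-norm input")
  list(cosine = sum(a * b) / (na * nb),
       pcc = stats::cor(a, b),
       l1 = mean(abs(a - b)))
}

#' Mean reconstruction metrics over a set of windows
#'
#' Runs each window through the model (encode, reparameterize, decode; the
#' conditional path uses the window's true phenotype) and averages the
#' per-sample [reconstruction_metrics()].
#'
#' @param model A trained `fc_vae`.
#' @param windows List of `window_sample` objects.
#' @param phenotypes Phenotype data frame (required for conditional models).
#' @param seed Seed for the latent draws.
#' @return List with mean `cosine`, `pcc`, `l1` and `n` windows.
#' @export
cohort_reconstruction_metrics <- function(model, windows, phenotypes = NULL,
                                          seed = 1L) {
  assert_that(length(windows) > 0, "no windows supplied")
  with_seed(seed, {
    vals <- vapply(windows, function(w) {
      ph <- if (model$config$conditional) {
        phenotypes[phenotypes$subject_id == w$subject_id, , drop = FALSE]
      }
      xh <- reconstruct_window(model, w$matrix, ph)
      m <- reconstruction_metrics(w$matrix, xh)
      c(m$cosine, m$pcc, m$l1)
    }, numeric(3))
  })
  list(cosine = mean(vals[1, ]), pcc = mean(vals[2, ]), l1 = mean(vals[3, ]),
       n = length(windows))
}

# encode -> sample -> decode with the true condition (no flipping)
reconstruct_window <- function(model, x, phenotype = NULL) {
  y <- if (model$config$conditional) {
    make_condition_embedding(phenotype, model)
  }
  enc <- encode(model, x, y)
  z <- reparameterize(enc$mu, enc$logvar)
  decode(model, z, y)
}

#' Latent-space group separation test
#'
#' Reduces each sample's latent mean vector to its scalar average and runs a
#' two-sided two-sample t test (pooled variance) of neurotypical versus
#' neurodivergent scalars; a significant result indicates the encoder
#' separates the groups in latent space.  A per-dimension variant with
#' Benjamini-Hochberg correction is available via `per_dimension`.
#'
#' @param latents_td,latents_asd Matrices of latent `mu` vectors, one row per
#'   sample.
#' @param alpha Significance level.
#' @param per_dimension Test each latent dimension separately (BH-adjusted)
#'   and report the most significant dimension.
#' @return List with `t`, `p_value`, `significant` (plus `dimension` in the
#'   per-dimension variant).
#' @export
latent_group_test <- function(latents_td, latents_asd, alpha = 0.05,
                              per_dimension = FALSE) {
  latents_td <- as.matrix(latents_td)
  latents_asd <- as.matrix(latents_asd)
  assert_that(nrow(latents_td) >= 2 && nrow(latents_asd) >= 2,
              "need at least 2 samples per group")
  if (per_dimension) {
    ps <- vapply(seq_len(ncol(latents_td)), function(j)
      stats::t.test(latents_td[, j], latents_asd[, j],
                    var.equal = TRUE)$p.value, numeric(1))
    padj <- stats::p.adjust(ps, method = "BH")
    j <- which.min(padj)
    return(list(t = NA_real_, p_value = padj[j],
                significant = padj[j] < alpha, dimension = j))
  }
  a <- rowMeans(latents_td)
  b <- rowMeans(latents_asd)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, p_value = 1, significant = FALSE))
    }
    stop_fc("zero within-group variance in both groups")
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       significant = tt$p.value < alpha)
}

#' Percent change between two metric values
#'
#' `100 * (after - before) / before`, the convention used to report e.g. the
#' PCC gain from adding phenotype conditioning to a model.
#'
#' @param metric_before,metric_after Scalar metric values; `metric_before`
#'   must be nonzero.
#' @param digits Decimal places for the returned value (2 by default).
#' @return Percent change, rounded to `digits`.
#' @examples
#' relative_change(0.6551, 0.7165)  # 9.37
#' @export
relative_change <- function(metric_before, metric_after, digits = 2) {
  assert_that(is.numeric(metric_before) && metric_before != 0,
              "metric_before must be nonzero")
  round(100 * (metric_after - metric_before) / metric_before, digits)
}
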