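#' Subject-level train/test split, stratified by (group, sex)
#'
#' Splits subjects (never windows) so that augmented training and testing
#' windows come from disjoint subjects.  Within each (group, sex) stratum the
#' requested test fraction is applied with rounding; strata with fewer than
#' two subjects are assigned best-effort with a warning.
#'
#' @param phenotypes Phenotype data frame (`subject_id`, `group`, `sex`).
#' @param test_fraction Fraction of subjects per stratum held out, in (0, 1).
#' @param seed Integer seed; the split is deterministic given it.
#' @return List with character vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
subject_split <- function(phenotypes, test_fraction = 0.2, seed = 1L) {
  assert_that(test_fraction > 0 && test_fraction < 1,
              "test_fraction must be in (0, 1)")
  strata <- interaction(phenotypes$group, phenotypes$sex, drop = TRUE)
  test_ids <- with_seed(seed, {
    unlist(lapply(levels(strata), function(s) {
      ids <- phenotypes$subject_id[strata == s]
      if (length(ids) < 2) {
        warning("stratum ", s, " has fewer than 2 subjects; ",
                "assigning all of it to the training set", call. = FALSE)
        return(character())
      }
      n_test <- max(1L, round(test_fraction * length(ids)))
      sample(ids, n_test)
    }), use.names = FALSE)
  })
  list(train = setdiff(phenotypes$subject_id, test_ids),
       test = sort(test_ids))
}

#' Min-max normalize a matrix to \[0, 1\]
#'
#' Uses the global minimum and maximum of the whole matrix, preserving
#' relative amplitudes across parcels (which connectivity estimates rely on).
#' A constant matrix maps to all 0.5 by convention.
#'
#' @param matrix Numeric matrix with finite entries.
#' @param per_parcel If `TRUE`, normalize each row independently instead.
#' @return Matrix of the same shape with entries in \[0, 1\].
#' @export
minmax_normalize <- function(matrix, per_parcel = FALSE) {
  if (anyNA(matrix)) stop_fc("matrix contains NA/NaN values")
  assert_that(all(is.finite(matrix)), "matrix must be finite")
  norm1 <- function(m) {
    rng <- range(m)
    if (rng[1] == rng[2]) return(array(0.5, dim(m)))
    (m - rng[1]) / (rng[2] - rng[1])
  }
  if (!per_parcel) {
    out <- norm1(matrix)
  } else {
    out <- t(apply(matrix, 1, function(r) {
      if (min(r) == max(r)) rep(0.5, length(r))
      else (r - min(r)) / (max(r) - min(r))
    }))
  }
  dimnames(out) <- dimnames(matrix)
  out
}

#' Sliding-window augmentation of one subject's scan
#'
#' Cuts the parcel-by-time matrix into windows of `window` time steps
#' starting at 0, `step`, `2*step`, ... (0-based, half-open), yielding
#' `floor((T - window)/step) + 1` windows when `T >= window` and none
#' otherwise (with a warning).  Each window is min-max normalized to
#' \[0, 1\] by default.
#'
#' @param series A [parcel_ts()].
#' @param window Window length in time steps.
#' @param step Step size in time steps.
#' @param normalize Normalize each window with [minmax_normalize()].
#' @param per_parcel Passed to [minmax_normalize()].
#' @return List of `window_sample` objects (`subject_id`, `window_start`,
#'   `matrix`).
#' @export
sliding_windows <- function(series, window = 200, step = 10,
                            normalize = TRUE, per_parcel = FALSE) {
  assert_that(is_count(window) && is_count(step), "window and step must be >= 1")
  T_len <- ncol(series$matrix)
  if (T_len < window) {
    warning("scan ", series$subject_id, " has ", T_len,
            " time steps (< window ", window, "); no windows produced",
            call. = FALSE)
    return(list())
  }
  starts <- seq(0L, T_len - window, by = step)
  lapply(starts, function(s0) {
    m <- series$matrix[, (s0 + 1):(s0 + window), drop = FALSE]
    if (normalize) m <- minmax_normalize(m, per_parcel = per_parcel)
    structure(list(subject_id = series$subject_id,
                   window_start = as.integer(s0),
                   matrix = m), class = "window_sample")
  })
}

#' Window an entire cohort after a subject split
#'
#' Applies [sliding_windows()] to every subject in `ids`, guaranteeing that
#' windows never mix subjects across the split.
#'
#' @param series List of [parcel_ts()].
#' @param ids Subject ids to keep (e.g. the `train` side of
#'   [subject_split()]); `NULL` keeps all.
#' @inheritParams sliding_windows
#' @return Flat list of `window_sample` objects.
#' @export
cohort_windows <- function(series, ids = NULL, window = 200, step = 10,
                           normalize = TRUE, per_parcel = FALSE) {
  keep <- if (is.null(ids)) series
          else Filter(function(s) s$subject_id %in% ids, series)
  out <- lapply(keep, sliding_windows, window = window, step = step,
                normalize = normalize, per_parcel = per_parcel)
  do.call(c, out) %||% list()
}
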