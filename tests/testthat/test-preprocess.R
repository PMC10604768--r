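test_that("subject split is stratified, disjoint, exhaustive, deterministic", {
  set.seed(1)
  ph <- data.frame(subject_id = sprintf("s%03d", 1:100),
                   group = rep(c("TD", "ASD"), each = 50),
                   sex = rep(c("M", "F"), 50),
                   stringsAsFactors = FALSE)
  sp <- subject_split(ph, 0.2, seed = 3)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ph$subject_id)
  expect_equal(length(sp$test), 20)
  # per-stratum proportions within one subject of the target
  strata <- interaction(ph$group, ph$sex)
  for (s in levels(strata)) {
    ids <- ph$subject_id[strata == s]
    expect_lt(abs(sum(ids %in% sp$test) - 0.2 * length(ids)), 1 + 1e-9)
  }
  expect_identical(sp, subject_split(ph, 0.2, seed = 3))
  expect_false(identical(sp$test, subject_split(ph, 0.2, seed = 4)$test))
})

test_that("a tiny stratum is assigned best-effort with a warning", {
  ph <- data.frame(subject_id = c("a", "b", "c", "d", "e"),
                   group = c("TD", "TD", "TD", "ASD", "ASD"),
                   sex = c("M", "M", "M", "M", "F"),
                   stringsAsFactors = FALSE)
  w <- capture_warnings(sp <- subject_split(ph, 0.4, seed = 1))
  expect_true(any(grepl("fewer than 2", w)))
  expect_setequal(c(sp$train, sp$test), ph$subject_id)
})

test_that("window counts follow the closed form and the boundary cases", {
  mk <- function(T_len) parcel_ts("s", matrix(rnorm(4 * T_len), 4, T_len),
                                  sprintf("7Networks_LH_Vis_%d", 1:4))
  expect_length(sliding_windows(mk(200), window = 200, step = 10), 1)
  w <- sliding_windows(mk(290), window = 200, step = 10)
  expect_length(w, 10)
  expect_equal(vapply(w, `[[`, integer(1), "window_start"), seq(0L, 90L, 10L))
  expect_warning(w0 <- sliding_windows(mk(150), window = 200, step = 10),
                 "no windows")
  expect_length(w0, 0)
})

test_that("window count matches a brute-force enumeration oracle", {
  set.seed(42)
  for (i in 1:100) {
    T_len <- sample(5:400, 1)
    win <- sample(2:250, 1)
    step <- sample(1:40, 1)
    # oracle: enumerate every start position explicitly
    starts <- c()
    s0 <- 0
    while (s0 + win <= T_len) { starts <- c(starts, s0); s0 <- s0 + step }
    ts <- parcel_ts("s", matrix(rnorm(2 * T_len), 2, T_len),
                    c("7Networks_LH_Vis_1", "7Networks_LH_Vis_2"))
    got <- suppressWarnings(
      sliding_windows(ts, window = win, step = step, normalize = FALSE))
    expect_length(got, length(starts))
    if (length(starts)) {
      expect_equal(vapply(got, `[[`, integer(1), "window_start"),
                   as.integer(starts))
    }
  }
})

test_that("min-max normalization maps to [0, 1] with the stated conventions", {
  expect_equal(minmax_normalize(matrix(c(0, 5, 10, 10), 2, 2)),
               matrix(c(0, 0.5, 1, 1), 2, 2))
  expect_equal(minmax_normalize(matrix(3, 4, 4)), matrix(0.5, 4, 4))
  set.seed(2)
  for (i in 1:20) {
    m <- matrix(rnorm(30, sd = sample(1:10, 1)), 5, 6)
    n <- minmax_normalize(m)
    expect_equal(range(n), c(0, 1))
    np <- minmax_normalize(m, per_parcel = TRUE)
    expect_true(all(apply(np, 1, min) == 0) && all(apply(np, 1, max) == 1))
  }
  expect_error(minmax_normalize(matrix(c(1, NA), 1, 2)), "NA")
})

test_that("windows never mix subjects across a split", {
  co <- tiny_cohort(seed = 31, n_per_cell = 3, n_parcels = 8,
                    scan_range = c(60, 90))
  sp <- suppressWarnings(subject_split(co$phenotypes, 0.3, seed = 5))
  wtr <- cohort_windows(co$series, sp$train, window = 40, step = 10)
  wte <- cohort_windows(co$series, sp$test, window = 40, step = 10)
  expect_true(all(vapply(wtr, `[[`, character(1), "subject_id") %in% sp$train))
  expect_true(all(vapply(wte, `[[`, character(1), "subject_id") %in% sp$test))
  expect_length(intersect(vapply(wtr, `[[`, character(1), "subject_id"),
                          vapply(wte, `[[`, character(1), "subject_id")), 0)
  # every window is normalized and full width
  expect_true(all(vapply(wtr, function(w)
    ncol(w$matrix) == 40 && min(w$matrix) >= 0 && max(w$matrix) <= 1,
    logical(1))))
})
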