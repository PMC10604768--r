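#' Write a cohort to disk
#'
#' One TSV per subject (parcels as rows, row names = parcel labels, columns
#' `t0, t1, ...`) plus a `phenotypes.csv` with columns
#' `subject_id, age, sex, group, site`.  [read_cohort()] inverts this up to
#' floating-point round-trip.
#'
#' @param series List of [parcel_ts()] objects.
#' @param phenotypes Phenotype data frame (one row per subject).
#' @param directory Output directory (created if missing).
#' @return `directory`, invisibly.
#' @export
write_cohort <- function(series, phenotypes, directory) {
  assert_that(length(series) == nrow(phenotypes),
              "one phenotype row per series is required")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (s in series) {
    m <- s$matrix
    colnames(m) <- paste0("t", seq_len(ncol(m)) - 1L)
    utils::write.table(m, file.path(directory, paste0(s$subject_id, ".tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  utils::write.csv(phenotypes, file.path(directory, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(directory)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory Directory containing per-subject TSV matrices and a
#'   `phenotypes.csv`.
#' @param tr_ms Repetition time to stamp on the series.
#' @return A list with `series` and `phenotypes`, as [generate_cohort()].
#' @export
read_cohort <- function(directory, tr_ms = 2000) {
  assert_that(dir.exists(directory), "directory does not exist: ", directory)
  phen_path <- file.path(directory, "phenotypes.csv")
  mats <- list.files(directory, pattern = "\\.tsv$", full.names = TRUE)
  if (!file.exists(phen_path) || length(mats) == 0) {
    stop_fc("empty cohort: no phenotypes.csv and/or subject TSV files in ",
            directory, class = "fcvae_empty_cohort")
  }
  phen <- utils::read.csv(phen_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex", "group", "site")
  missing_cols <- setdiff(need, names(phen))
  if (length(missing_cols)) {
    stop_fc("phenotype table is missing column(s): ",
            paste(missing_cols, collapse = ", "), class = "fcvae_schema_error")
  }
  ids <- sub("\\.tsv$", "", basename(mats))
  orphan <- setdiff(ids, phen$subject_id)
  if (length(orphan)) {
    stop_fc("matrix files without a phenotype row: ",
            paste(orphan, collapse = ", "), class = "fcvae_schema_error")
  }
  phen <- phen[phen$subject_id %in% ids, , drop = FALSE]
  series <- lapply(phen$subject_id, function(id) {
    m <- as.matrix(utils::read.delim(file.path(directory, paste0(id, ".tsv")),
                                     row.names = 1, check.names = FALSE))
    parcel_ts(id, m, rownames(m), tr_ms = tr_ms)
  })
  list(series = series, phenotypes = phen)
}
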