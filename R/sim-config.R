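#' Simulation configuration for synthetic parcellated BOLD cohorts
#'
#' Describes a cohort generator that emulates the statistical structure of a
#' parcellated resting-state fMRI study: a small number of latent network
#' signals with a controllable cross-network coupling (correlation) matrix,
#' parcel-level observation noise, AR(1) temporal smoothness, variable scan
#' lengths across subjects, and group- or sex-dependent perturbations of the
#' coupling matrix.  Every downstream stage of the package can be exercised
#' against cohorts with *known* connectivity effects.
#'
#' @param n_subjects_per_cell Subjects per (group, sex) cell; each diagnostic
#'   group receives `2 * n_subjects_per_cell` subjects whose sex is drawn with
#'   probability implied by `sex_ratio`.
#' @param n_parcels Number of cortical parcels (rows of each BOLD matrix).
#' @param n_networks Number of latent network signals.  The default 5 matches
#'   the canonical resting-state networks analyzed downstream (DMN, Limbic,
#'   Visual, Somatomotor, Salience).
#' @param scan_length_range Inclusive integer range of scan lengths (time
#'   steps); each subject's length is drawn uniformly from it.
#' @param coupling_base Symmetric `n_networks x n_networks` correlation matrix
#'   of the latent innovations (unit diagonal, entries in \[-1, 1\]).
#' @param effect_table Data frame of coupling perturbations, see [fc_effect()].
#' @param noise_sd Standard deviation of i.i.d. Gaussian parcel noise added on
#'   top of the (unit-variance) latent network signal.  `noise_sd = 1` gives a
#'   within-network parcel-pair correlation of 0.5, a realistic magnitude for
#'   parcel-level resting-state data.
#' @param ar_coefficient AR(1) coefficient of the latent signals in \[0, 1);
#'   0.4 approximates the temporal autocorrelation of BOLD sampled at
#'   TR = 2000 ms.
#' @param sex_ratio Male:female ratio expressed as a single number `r`
#'   meaning `r:1` (males are drawn with probability `r / (1 + r)`).  The
#'   default 4 mirrors the strong male skew of public autism cohorts.
#' @param age_range Uniform age range (years) for simulated phenotypes.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class `fc_sim_config`.
#' @seealso [generate_cohort()], [build_coupling_matrix()], [fc_effect()]
#' @examples
#' cfg <- fc_sim_config(n_subjects_per_cell = 2, n_parcels = 10,
#'                      scan_length_range = c(60, 80), seed = 1)
#' cohort <- generate_cohort(cfg)
#' length(cohort$series)
#' @export
fc_sim_config <- function(n_subjects_per_cell = 20,
                          n_parcels = 200,
                          n_networks = 5,
                          scan_length_range = c(200, 300),
                          coupling_base = NULL,
                          effect_table = NULL,
                          noise_sd = 1,
                          ar_coefficient = 0.4,
                          sex_ratio = 4,
                          age_range = c(8, 30),
                          seed = 1L) {
  assert_that(is_count(n_subjects_per_cell), "n_subjects_per_cell must be >= 1")
  assert_that(is_count(n_parcels) && n_parcels >= 2, "n_parcels must be >= 2")
  assert_that(is_count(n_networks) && n_networks >= 2 &&
                n_networks <= n_parcels,
              "n_networks must be in [2, n_parcels]")
  assert_that(length(scan_length_range) == 2 &&
                scan_length_range[1] <= scan_length_range[2] &&
                scan_length_range[1] >= 2,
              "scan_length_range must be an increasing pair of lengths >= 2")
  assert_that(ar_coefficient >= 0 && ar_coefficient < 1,
              "ar_coefficient must lie in [0, 1)")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(sex_ratio > 0, "sex_ratio must be > 0")

  if (is.null(coupling_base)) {
    coupling_base <- matrix(0.2, n_networks, n_networks)
    diag(coupling_base) <- 1
  }
  validate_coupling(coupling_base, n_networks)
  if (is.null(effect_table)) {
    effect_table <- fc_effect()[0, ]  # empty, right schema
  }
  validate_effect_table(effect_table, n_networks)

  structure(list(
    n_subjects_per_cell = as.integer(n_subjects_per_cell),
    n_parcels = as.integer(n_parcels),
    n_networks = as.integer(n_networks),
    scan_length_range = as.integer(scan_length_range),
    coupling_base = coupling_base,
    effect_table = effect_table,
    noise_sd = noise_sd,
    ar_coefficient = ar_coefficient,
    sex_ratio = sex_ratio,
    age_range = age_range,
    seed = as.integer(seed),
    network_names = sim_network_names(n_networks),
    parcel_network = parcel_network_assignment(n_parcels, n_networks),
    parcel_labels = NULL
  ), class = "fc_sim_config") -> cfg
  cfg$parcel_labels <- schaefer_style_labels(cfg)
  cfg
}

#' Declare a coupling perturbation for the simulator
#'
#' Each row adds `delta` to the (network_i, network_j) entry (and its mirror)
#' of the base coupling matrix for every subject whose group and sex match.
#' `"any"` matches both levels of a factor, so a shared diagnostic effect or a
#' sex-linked baseline difference can be expressed with one row.
#'
#' @param network_i,network_j Network names (see `network_names` of the
#'   configuration; defaults are DMN, Limbic, Visual, Somatomotor, Salience).
#' @param group `"TD"`, `"ASD"` or `"any"`.
#' @param sex `"M"`, `"F"` or `"any"`.
#' @param delta Additive change of the latent coupling correlation.
#' @return A one-row data frame; rows can be `rbind`ed into an effect table.
#' @examples
#' fc_effect("DMN", "Limbic", group = "ASD", delta = -0.3)
#' @export
fc_effect <- function(network_i = character(), network_j = character(),
                      group = character(), sex = "any", delta = numeric()) {
  n <- max(length(network_i), length(network_j), length(group), length(delta))
  if (n == 0) {
    return(data.frame(network_i = character(), network_j = character(),
                      group = character(), sex = character(),
                      delta = numeric(), stringsAsFactors = FALSE))
  }
  data.frame(network_i = network_i, network_j = network_j, group = group,
             sex = sex, delta = delta, stringsAsFactors = FALSE)
}

validate_coupling <- function(C, n_networks) {
  assert_that(is.matrix(C) && all(dim(C) == n_networks),
              "coupling_base must be ", n_networks, "x", n_networks)
  assert_that(max(abs(C - t(C))) < 1e-10, "coupling_base must be symmetric")
  assert_that(all(abs(diag(C) - 1) < 1e-10),
              "coupling_base must have unit diagonal")
  assert_that(all(C >= -1 - 1e-10 & C <= 1 + 1e-10),
              "coupling_base entries must lie in [-1, 1]")
  invisible(C)
}

validate_effect_table <- function(tab, n_networks) {
  need <- c("network_i", "network_j", "group", "sex", "delta")
  assert_that(is.data.frame(tab) && all(need %in% names(tab)),
              "effect_table needs columns ", paste(need, collapse = ", "))
  nets <- sim_network_names(n_networks)
  assert_that(all(tab$network_i %in% nets) && all(tab$network_j %in% nets),
              "effect_table networks must be among: ",
              paste(nets, collapse = ", "))
  assert_that(all(tab$group %in% c("TD", "ASD", "any")),
              "effect_table group must be TD, ASD or any")
  assert_that(all(tab$sex %in% c("M", "F", "any")),
              "effect_table sex must be M, F or any")
  invisible(tab)
}

sim_network_names <- function(n_networks) {
  if (n_networks <= length(FC_NETWORKS)) FC_NETWORKS[seq_len(n_networks)]
  else c(FC_NETWORKS, paste0("Net", seq_len(n_networks - length(FC_NETWORKS))))
}

# contiguous, near-equal blocks of parcels per network
parcel_network_assignment <- function(n_parcels, n_networks) {
  sort(rep_len(seq_len(n_networks), n_parcels))
}

# Schaefer-convention label per parcel (7Networks_<hemi>_<abbrev>_<k>);
# first half of each network's parcels LH, the rest RH
schaefer_style_labels <- function(cfg) {
  abbrev <- c(DMN = "Default", Limbic = "Limbic", Visual = "Vis",
              Somatomotor = "SomMot", Salience = "SalVentAttn")
  vapply(seq_len(cfg$n_parcels), function(p) {
    net <- cfg$network_names[cfg$parcel_network[p]]
    tok <- if (net %in% names(abbrev)) abbrev[[net]] else net
    members <- which(cfg$parcel_network == cfg$parcel_network[p])
    k <- match(p, members)
    hemi <- if (k <= ceiling(length(members) / 2)) "LH" else "RH"
    sprintf("7Networks_%s_%s_%d", hemi, tok, k)
  }, character(1))
}

#' @export
print.fc_sim_config <- function(x, ...) {
  cat("<fc_sim_config>\n")
  cat(sprintf("  %d parcels, %d networks, %d subjects/(group,sex) cell\n",
              x$n_parcels, x$n_networks, x$n_subjects_per_cell))
  cat(sprintf("  scan length %d-%d, AR(1) phi=%.2f, noise sd=%.2f\n",
              x$scan_length_range[1], x$scan_length_range[2],
              x$ar_coefficient, x$noise_sd))
  cat(sprintf("  sex ratio %.1f:1 (M:F), %d coupling effect(s), seed %d\n",
              x$sex_ratio, nrow(x$effect_table), x$seed))
  invisible(x)
}
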