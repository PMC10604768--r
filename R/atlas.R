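#' Parse Schaefer-convention parcel labels into a five-network atlas
#'
#' Labels follow the Schaefer 7-network naming scheme
#' (`7Networks_<LH|RH>_<Network>_<region...>`).  Five networks are retained
#' and renamed to the canonical order used throughout the package
#' (`Vis` -> Visual, `SomMot` -> Somatomotor, `SalVentAttn` -> Salience,
#' `Limbic` -> Limbic, `Default` -> DMN); control (`Cont`) and dorsal
#' attention (`DorsAttn`) parcels are marked `EXCLUDED` and ignored by the
#' connectivity stage.
#'
#' @param labels Character vector of parcel labels (one per parcel row).
#' @return A `network_atlas`: data frame with `parcel`, `label`, `network`,
#'   `hemisphere`, plus attribute `networks` (retained network names).
#' @export
atlas_from_labels <- function(labels) {
  m <- regmatches(labels, regexec(
    "^7Networks_(LH|RH)_(Vis|SomMot|SalVentAttn|Limbic|Default|Cont|DorsAttn)([_A-Za-z0-9]*)$",
    labels))
  bad <- which(vapply(m, length, integer(1)) == 0)
  if (length(bad)) {
    stop_fc("unparseable parcel label at row ", bad[1], ": '",
            labels[bad[1]], "'", class = "fcvae_atlas_error")
  }
  map <- c(Vis = "Visual", SomMot = "Somatomotor", SalVentAttn = "Salience",
           Limbic = "Limbic", Default = "DMN",
           Cont = "EXCLUDED", DorsAttn = "EXCLUDED")
  hemi <- vapply(m, `[`, character(1), 2)
  net <- unname(map[vapply(m, `[`, character(1), 3)])
  atlas <- data.frame(parcel = seq_along(labels), label = labels,
                      network = net, hemisphere = hemi,
                      stringsAsFactors = FALSE)
  retained <- FC_NETWORKS[FC_NETWORKS %in% unique(net)]
  assert_that(length(retained) >= 1, "no retained network has any parcel")
  structure(atlas, networks = retained, class = c("network_atlas", "data.frame"))
}

#' Load a network atlas from a parcel label file
#'
#' Reads a plain-text file with one Schaefer-convention label per line (the
#' standard label-list format of the Schaefer 200-parcel release) and builds
#' the five-network grouping with [atlas_from_labels()].
#'
#' @param label_file Path to the label file.
#' @return A `network_atlas` (see [atlas_from_labels()]).
#' @examples
#' f <- system.file("extdata", "schaefer200_labels_synthetic.txt",
#'                  package = "fcvae")
#' atlas <- load_network_atlas(f)
#' table(atlas$network)
#' @export
load_network_atlas <- function(label_file) {
  assert_that(file.exists(label_file), "label file not found: ", label_file)
  labels <- readLines(label_file, warn = FALSE)
  labels <- labels[nzchar(trimws(labels))]
  atlas_from_labels(trimws(labels))
}
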