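#' Load a network atlas
#'
#' An atlas maps ROI identifiers to one of the three networks under study
#' (`language`, `dmn`, `md`), a hemisphere, and MNI coordinates in mm. The
#' packaged atlas contains 8 left-hemisphere language ROIs, 11 bilateral
#' default-mode ROIs, and 20 bilateral multiple-demand ROIs.
#'
#' @param path Path to an atlas CSV with columns `roi_id`, `network`,
#'   `hemisphere`, `x`, `y`, `z`. Defaults to the packaged atlas.
#' @return A tibble of class `segspeech_atlas`.
#' @export
#' @examples
#' atlas <- network_atlas()
#' table(atlas$network)
network_atlas <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "network_atlas.csv", package = "segspeech")
  }
  if (!file.exists(path)) {
    stop_segspeech(sprintf("atlas file not found: %s", path), "segspeech_io_error")
  }
  atlas <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  validate_atlas(atlas)
}

#' @rdname network_atlas
#' @param atlas A data frame to validate as an atlas.
#' @export
validate_atlas <- function(atlas) {
  required <- c("roi_id", "network", "hemisphere", "x", "y", "z")
  missing <- setdiff(required, names(atlas))
  if (length(missing)) {
    stop_segspeech(
      sprintf("atlas is missing columns: %s", paste(missing, collapse = ", ")),
      "segspeech_schema_error"
    )
  }
  if (anyDuplicated(atlas$roi_id)) {
    stop_segspeech("atlas roi_id values must be unique", "segspeech_schema_error")
  }
  bad <- setdiff(unique(atlas$network), c("language", "dmn", "md"))
  if (length(bad)) {
    stop_segspeech(
      sprintf("unknown network labels: %s", paste(bad, collapse = ", ")),
      "segspeech_schema_error"
    )
  }
  if (!all(atlas$hemisphere %in% c("L", "R"))) {
    stop_segspeech("hemisphere must be 'L' or 'R'", "segspeech_schema_error")
  }
  structure(tibble::as_tibble(atlas), class = c("segspeech_atlas", class(tibble::tibble())))
}

atlas_rois <- function(atlas, network) {
  if (!network %in% atlas$network) {
    stop_segspeech(sprintf("unknown network label: %s", network), "segspeech_usage_error")
  }
  atlas$roi_id[atlas$network == network]
}
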