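#' Packaged immune cell-type marker collection
#'
#' A curated GMT of marker gene sets for 24 immune cell types (adaptive and
#' innate lineages, including the suppressive Treg and Th17 compartments),
#' for scoring real expression cohorts with [score_matrix()]. Synthetic
#' cohorts from [simulate_cohort()] carry their own marker sets over the
#' simulated gene universe (same 24 cell-type names).
#'
#' @param path Optional path to a user GMT to load instead.
#' @return Named list of character vectors (24 sets by default).
#' @export
immune_marker_sets <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "immune_cell_sets.gmt",
                        package = "timephen")
  read_gmt(path)
}
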