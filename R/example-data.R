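#' Published per-reader AUC example table
#'
#' A published 4-reader x 4-mode grid of breast-level empirical AUCs (POM
#' and forced-BI-RADS score types) from a sequential 2D / 2D + DBT reader
#' study, shipped as a worked example for the reporting arithmetic: the
#' reader-averaged cells and modality contrasts recomputed from these
#' per-reader values reproduce the published summary row at 3-dp half-up
#' rounding.
#'
#' @return Data frame with a `reader` column and one numeric column per
#'   score type x mode (`pom_DM`, ..., `birads_AICAD_SM_DBT`).
#' @export
#' @examples
#' aucs <- example_reader_aucs()
#' round_half_up(colMeans(aucs[-1]), 3)
example_reader_aucs <- function() {
  path <- system.file("extdata", "example_reader_aucs.csv",
                      package = "mrmcboot", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
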