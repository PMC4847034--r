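#' Published external-validation calls for the rat AFP binder model
#'
#' The 22 literature-curated external-validation chemicals for the rat
#' alpha-fetoprotein (AFP) binding model, with their experimental binding
#' activity (`experiment`) and the Decision Forest model's published call
#' (`prediction`); 1 marks a binder, 0 a non-binder. Feeding the two columns
#' to [score_predictions()] reproduces the external-validation performance
#' of the model (17 binders of which 7 were recovered, all 5 non-binders
#' recognised).
#'
#' @return A 22-row data frame with columns `chemical`, `experiment`,
#'   `prediction`.
#' @examples
#' calls <- afp_external_calls()
#' score_predictions(calls$experiment, calls$prediction)
#' @export
afp_external_calls <- function() {
  path <- system.file("extdata", "afp_external_calls.csv", package = "dfqsar")
  read.csv(path, stringsAsFactors = FALSE)
}
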