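#' Load a bundled placeholder risk model
#'
#' The package ships two *synthetic placeholder* model configurations,
#' `"m6np"` and `"m4"`, with the basis-function structure of the published
#' two-hCG PUL triage model family but made-up coefficients. They exist so
#' that the validation machinery can be exercised and tested end to end;
#' they are **not** the published M4/M6NP models. To validate the real
#' models, transcribe the published coefficients into a JSON configuration
#' (see [read_model_spec()]) and load that instead.
#'
#' The two placeholders are deliberately different: the `"m4"` variant has
#' sharper logits and a lower EP intercept, so that on cohorts generated
#' from the `"m6np"` variant it shows the classic signature of a
#' transported, less well calibrated model (calibration slope below 1,
#' positive calibration-in-the-large, lower AUC).
#'
#' @param which `"m6np"` or `"m4"`.
#' @return A `pul_model`.
#' @examples
#' example_model("m6np")
#' @export
example_model <- function(which = c("m6np", "m4")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0(which, "_placeholder_synthetic.json"),
                      package = "pulvalidate", mustWork = TRUE)
  read_model_spec(path)
}
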