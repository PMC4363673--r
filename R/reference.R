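#' Packaged reference normalization models
#'
#' Loads the coefficient sets of the reference normalization models
#' shipped with the package (fitted on a 32-subject healthy-control
#' calibration cohort) together with that cohort's covariate means, as
#' ready-to-apply `"norm_model"` objects.  Use them with
#' [apply_normalization()] to normalize measurements from a new cohort
#' without refitting, optionally overriding the reference means.
#'
#' Model naming: `model1` = TICV + sagittal_vertebra_area, `model2` =
#' age + TICV + ap_vertebra_diameter, `model2a` = TICV +
#' ap_vertebra_diameter (the GM variant of model 2, age dropped as
#' non-significant), `model3` = age + TICV + sagittal_vertebra_area.
#'
#' @param path YAML file to read; defaults to the packaged file.
#' @return Named list of `"norm_model"` objects.  Models whose
#'   reported adjusted R-squared is missing (below the 0.35 gate and
#'   not reported) carry `adj_r2 = NA` and `passes_gate = FALSE`.
#' @examples
#' m <- reference_models()[["model3_tca_c2c3"]]
#' # a 58.84-year-old at the reference head size, measured 75 mm^2:
#' apply_normalization(m, 75, list(age = 58.84, ticv = 1434165.26,
#'                                 sagittal_vertebra_area = 199.93))
#' @export
reference_models <- function(path = system.file("extdata",
                                                "reference_models.yaml",
                                                package = "cordnorm")) {
  raw <- yaml::read_yaml(path)
  means <- unlist(raw$reference_means)
  out <- lapply(raw$models, function(m) {
    coefs <- unlist(m$coefficients)
    adj <- if (is.null(m$adj_r2)) NA_real_ else m$adj_r2
    structure(list(
      outcome = m$outcome,
      covariates = names(coefs),
      coefficients = coefs,
      coefficient_p = setNames(rep(NA_real_, length(coefs)), names(coefs)),
      means = means[names(coefs)],
      outcome_mean = NA_real_,
      intercept = NA_real_,
      r2 = NA_real_,
      adj_r2 = adj,
      sigma = NA_real_,
      n = m$n,
      gate = 0.35,
      passes_gate = !is.na(adj) && adj > 0.35
    ), class = "norm_model")
  })
  names(out) <- vapply(raw$models, `[[`, character(1), "name")
  out
}
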