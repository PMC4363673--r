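#' Construct a generator configuration
#'
#' Full parametrization of the synthetic cohort: demographics, the
#' sex-conditional joint distribution of the core covariates (age,
#' TICV, ap_vertebra_diameter, sagittal_vertebra_area), the per-(level,
#' measure) linear area models with their residual SDs, the cross-level
#' residual correlation matrix, auxiliary covariates, the missingness
#' pattern and the seed.  Most users want [default_config()], the
#' packaged calibration.
#'
#' @param n_subjects default cohort size.
#' @param female_fraction proportion of women.
#' @param age_distribution list(mean, sd, min, max) of the pooled age
#'   distribution (years); generation is truncated to `[min, max]` by
#'   resampling.
#' @param sex_age list with `M` and `F` entries, each list(mean, sd):
#'   the per-sex age moments (post-truncation targets).
#' @param sex_covariate_means 3 x 2 matrix (rows `ticv`,
#'   `ap_vertebra_diameter`, `sagittal_vertebra_area`; cols `M`, `F`).
#' @param covariate_sds named within-sex SDs for the same three
#'   covariates.
#' @param covariate_correlations 4 x 4 within-sex correlation matrix
#'   over the core covariates (must be symmetric, unit-diagonal,
#'   positive semi-definite; eigenvalues above `-1e-8` are repaired,
#'   anything lower is an error).
#' @param area_models named list (keys `"C2-C3:TCA"`, ...), each
#'   list(level, measure, coefficients (named over core covariates),
#'   sex_offset, intercept, residual_sd).
#' @param cross_level_residual_correlations 8 x 8 residual correlation
#'   matrix over the outcomes in level-major order (same PSD rule).
#' @param missingness list(thoracic, covariates, shared): numbers of
#'   subjects lacking the thoracic cord levels and lacking the
#'   brain/skeletal covariate record, and whether they are the same
#'   subjects.
#' @param extra_covariates data.frame(name, mean_M, mean_F, sd,
#'   r_ticv) of auxiliary metrics generated as noisy regressions on
#'   TICV (cosmetic realism; no pathway to the areas).
#' @param height_weight list of per-sex height mean/sd (cm), weight
#'   residual sd (kg) and height-weight correlation.
#' @param seed default integer seed.
#' @return object of class `"generator_config"`.
#' @export
generator_config <- function(n_subjects, female_fraction, age_distribution,
                             sex_age, sex_covariate_means, covariate_sds,
                             covariate_correlations, area_models,
                             cross_level_residual_correlations,
                             missingness = list(thoracic = 0L,
                                                covariates = 0L,
                                                shared = TRUE),
                             extra_covariates = NULL,
                             height_weight = NULL,
                             seed = 1L) {
  if (female_fraction < 0 || female_fraction > 1)
    stop("female_fraction must be in [0, 1]", call. = FALSE)
  covariate_correlations <- check_corr(covariate_correlations,
                                       "covariate_correlations")
  cross_level_residual_correlations <-
    check_corr(cross_level_residual_correlations,
               "cross_level_residual_correlations")
  for (key in names(area_models)) {
    am <- area_models[[key]]
    if (!is.finite(am$residual_sd) || am$residual_sd <= 0)
      stop("residual_sd must be > 0 for ", key, call. = FALSE)
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    female_fraction = female_fraction,
    age_distribution = age_distribution,
    sex_age = sex_age,
    sex_covariate_means = sex_covariate_means,
    covariate_sds = covariate_sds,
    covariate_correlations = covariate_correlations,
    area_models = area_models,
    cross_level_residual_correlations = cross_level_residual_correlations,
    missingness = missingness,
    extra_covariates = extra_covariates,
    height_weight = height_weight,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# symmetric / unit-diagonal / PSD validation with repair of numerical
# negatives only (eigenvalues in (-1e-8, 0))
check_corr <- function(R, what, tol = 1e-8) {
  if (!isSymmetric(unname(R), tol = 1e-10))
    stop(what, " must be symmetric", call. = FALSE)
  if (any(abs(diag(R) - 1) > 1e-12))
    stop(what, " must have unit diagonal", call. = FALSE)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol)
    stop(sprintf("%s is not positive semi-definite (min eigenvalue %.3g)",
                 what, min(ev)), call. = FALSE)
  if (min(ev) < 0) {
    # numerically negative only: lift to PSD
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
  }
  R
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("generator_config: n = %d (%.0f%% F), age %g +/- %g in [%g, %g]\n",
              x$n_subjects, 100 * x$female_fraction,
              x$age_distribution$mean, x$age_distribution$sd,
              x$age_distribution$min, x$age_distribution$max))
  cat(sprintf("  %d area models, seed %d\n", length(x$area_models), x$seed))
  invisible(x)
}

# core-covariate moment struct (target scale) for a config; the
# within-sex age SD is the one achieved under the range truncation
config_core_moments <- function(config) {
  lo <- config$age_distribution$min
  hi <- config$age_distribution$max
  sd_age <- vapply(c("M", "F"), function(s)
    age_truncation_params(config$sex_age[[s]]$mean, config$sex_age[[s]]$sd,
                          lo, hi)$sd_achieved, numeric(1))
  mu <- rbind(
    age = c(M = config$sex_age$M$mean, F = config$sex_age$F$mean),
    config$sex_covariate_means)
  sds <- rbind(
    age = sd_age,
    matrix(rep(config$covariate_sds, 2), ncol = 2,
           dimnames = list(names(config$covariate_sds), c("M", "F"))))
  rownames(mu) <- rownames(sds) <- CORE_COVARIATES
  core_moments(1 - config$female_fraction, mu, sds,
               config$covariate_correlations)
}

# beta vector (over core covariates) of one area model
config_area_beta <- function(config, key) {
  am <- config$area_models[[key]]
  beta <- setNames(numeric(length(CORE_COVARIATES)), CORE_COVARIATES)
  beta[names(am$coefficients)] <- am$coefficients
  beta
}

#' Population statistics implied by a configuration
#'
#' Closed-form means, SDs, covariate correlations, age slopes,
#' age-adjusted sex differences and model R-squared values of the
#' generative distribution -- the quantities the calibration targets
#' and large-sample checks compare against.
#'
#' @param config a [generator_config()].
#' @return data.frame with one row per (level, measure).
#' @export
config_population_summary <- function(config) {
  M <- config_core_moments(config)
  keys <- names(config$area_models)
  rows <- lapply(keys, function(key) {
    am <- config$area_models[[key]]
    beta <- config_area_beta(config, key)
    pm <- area_pop_moments(M, beta, am$sex_offset, am$residual_sd,
                           am$intercept)
    pr <- pop_age_sex_projection(M, pm)
    data.frame(
      outcome = key, mean = pm$mean, sd = sqrt(pm$var),
      sex_diff_age_adj = pr$sex_diff,
      age_slope = pr$age_slope,
      r_ticv = pop_cor_x(M, pm, "ticv"),
      r_sagittal_vertebra_area = pop_cor_x(M, pm, "sagittal_vertebra_area"),
      r_ap_vertebra_diameter = pop_cor_x(M, pm, "ap_vertebra_diameter"),
      r2_age_ticv_apvd = pop_r2(M, pm, c("age", "ticv",
                                         "ap_vertebra_diameter")),
      r2_age_ticv_sva = pop_r2(M, pm, c("age", "ticv",
                                        "sagittal_vertebra_area")),
      r2_ticv_apvd = pop_r2(M, pm, c("ticv", "ap_vertebra_diameter")))
  })
  do.call(rbind, rows)
}

#' Solve residual SDs for target adjusted R-squared values
#'
#' For each named outcome, converts the target adjusted R-squared to an
#' (unadjusted) population R-squared at the stated `n` and `p`, then
#' solves the closed form `R^2 = captured / (var_struct + sigma^2)` for
#' the residual SD, where `captured` is the variance of the outcome
#' explained by the OLS projection on the model's covariates.  Returns
#' the updated configuration.  Note the packaged [default_config()]
#' instead pins the residual SD from the target total SD; this operation
#' is the alternative calibration that sacrifices the total SD to hit an
#' R-squared exactly.
#'
#' @param config a [generator_config()].
#' @param target_adj_r2 named numeric vector (names are outcome keys
#'   like `"C2-C3:TCA"`), entries in (0, 1).
#' @param covariates covariate set defining the R-squared (default: the
#'   model's own generative covariates).
#' @param n,p sample size and predictor count used to de-adjust.
#' @return the updated [generator_config()].
#' @export
calibrate_residuals <- function(config, target_adj_r2, covariates = NULL,
                                n = 30, p = NULL) {
  M <- config_core_moments(config)
  for (key in names(target_adj_r2)) {
    if (is.null(config$area_models[[key]]))
      stop("no area model for ", key, call. = FALSE)
    am <- config$area_models[[key]]
    covs <- if (is.null(covariates)) names(am$coefficients) else covariates
    pp <- if (is.null(p)) length(covs) else p
    adj <- target_adj_r2[[key]]
    if (!is.finite(adj) || adj <= 0 || adj >= 1)
      stop("target adjusted R^2 must be in (0, 1)", call. = FALSE)
    r2 <- 1 - (1 - adj) * (n - pp - 1) / (n - 1)
    if (r2 <= 0 || r2 >= 1)
      stop("implied R^2 outside (0, 1) for ", key, call. = FALSE)
    beta <- config_area_beta(config, key)
    pm <- area_pop_moments(M, beta, am$sex_offset, 0, am$intercept)
    cv <- pm$cov_x[covs]
    captured <- drop(crossprod(cv, solve(M$mix_cov[covs, covs], cv)))
    if (captured <= 0)
      stop("covariate pathway captures no variance for ", key, call. = FALSE)
    # captured / (var_struct + sigma^2) = r2
    sig2 <- captured / r2 - pm$var_struct
    if (sig2 <= 0)
      stop("target R^2 not reachable (residual variance would be <= 0) for ",
           key, call. = FALSE)
    config$area_models[[key]]$residual_sd <- sqrt(sig2)
  }
  config
}

#' Write / read a generator configuration as YAML
#'
#' @param config a [generator_config()].
#' @param path YAML file path.
#' @return `read_config()` returns the validated [generator_config()].
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$sex_covariate_means <- mat_to_list(x$sex_covariate_means)
  x$covariate_correlations <- mat_to_list(x$covariate_correlations)
  x$cross_level_residual_correlations <-
    mat_to_list(x$cross_level_residual_correlations)
  x$covariate_sds <- as.list(x$covariate_sds)
  x$area_models <- lapply(x$area_models, function(am) {
    am$coefficients <- as.list(am$coefficients)
    am
  })
  if (!is.null(x$extra_covariates))
    x$extra_covariates <- lapply(
      seq_len(nrow(x$extra_covariates)),
      function(i) as.list(x$extra_covariates[i, ]))
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$sex_covariate_means <- list_to_mat(x$sex_covariate_means)
  x$covariate_correlations <- list_to_mat(x$covariate_correlations)
  x$cross_level_residual_correlations <-
    list_to_mat(x$cross_level_residual_correlations)
  x$covariate_sds <- unlist(x$covariate_sds)
  x$area_models <- lapply(x$area_models, function(am) {
    am$coefficients <- unlist(am$coefficients)
    am
  })
  if (!is.null(x$extra_covariates))
    x$extra_covariates <- do.call(
      rbind, lapply(x$extra_covariates, as.data.frame))
  generator_config(
    n_subjects = x$n_subjects, female_fraction = x$female_fraction,
    age_distribution = x$age_distribution, sex_age = x$sex_age,
    sex_covariate_means = x$sex_covariate_means,
    covariate_sds = x$covariate_sds,
    covariate_correlations = x$covariate_correlations,
    area_models = x$area_models,
    cross_level_residual_correlations = x$cross_level_residual_correlations,
    missingness = x$missingness, extra_covariates = x$extra_covariates,
    height_weight = x$height_weight, seed = x$seed)
}

mat_to_list <- function(m) {
  list(rows = rownames(m), cols = colnames(m),
       values = lapply(seq_len(nrow(m)), function(i) as.list(m[i, ])))
}

list_to_mat <- function(l) {
  m <- do.call(rbind, lapply(l$values, function(r) unlist(r)))
  rownames(m) <- l$rows
  colnames(m) <- l$cols
  m
}
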