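# The packaged calibration behind default_config().
#
# The cohort it emulates: 32 healthy adults (14 M, 18 F), ages 28-78,
# TCA and GM areas at C2-C3, C3-C4, T8-T9 and T9-T10, TICV and C3
# vertebra metrics; two subjects lack the thoracic acquisitions and the
# same two lack the brain/skeletal covariate record, so covariate
# models fit on n = 30 complete cases.
#
# Calibration targets (study summary statistics):
#   * per-level area means/SDs;
#   * age-adjusted male-female differences (4.60 / 3.05 mm^2 TCA at the
#     two reference levels, 1.51 / 1.26 mm^2 GM);
#   * sex-adjusted marginal age slopes (about -2 mm^2/decade cervically
#     and -1.3 mm^2/decade thoracically for TCA);
#   * population R^2 of the reported covariate models (the printed
#     adjusted R^2 values, which estimate population R^2);
#   * the full 8 x 8 cross-level area correlation matrix;
#   * covariate-area correlations (TCA-TICV about 0.63 at C2-C3).
#
# Mechanics per outcome: the head-size covariate coefficients keep the
# ratios of the reported regression coefficients but are scaled by a
# solved factor so the population R^2 of the reported model matches its
# target; the age coefficient and the sex offset are then solved
# linearly for the marginal age slope and the adjusted sex difference;
# the intercept matches the mean; and the residual SD absorbs whatever
# variance the pathways leave, pinning the total SD.  Residual
# correlations across the eight (level, measure) outcomes are solved
# from the target area correlations after subtracting the structural
# (shared-covariate) covariance, then projected to the nearest positive
# semi-definite correlation matrix.

calib_outcome_targets <- function() {
  # order: level-major, TCA then GM
  data.frame(
    level   = rep(CORD_LEVELS, each = 2),
    measure = rep(c("TCA", "GM"), 4),
    mean    = c(79.7, 19.4, 84.1, 21.9, 44.3, 10.3, 45.3, 11.1),
    sd      = c(7.0, 1.9, 7.1, 1.9, 3.1, 1.6, 3.5, 1.3),
    # age-adjusted M-F difference; non-reference levels borrow the
    # adjacent reference level's value
    sex_diff = c(4.60, 1.51, 4.60, 1.51, 3.05, 1.26, 3.05, 1.26),
    # sex-adjusted marginal age slope (mm^2 / year); NA = emergent
    age_slope = c(-0.20, NA, -0.20, NA, -0.13, NA, -0.13, NA),
    # generative covariate pathway and its target population R^2
    pathway = c("sva", "apvd", "sva", "apvd",
                "apvd", "apvd", "apvd", "apvd"),
    r2      = c(0.47, 0.40, 0.44, 0.37, 0.56, 0.20, 0.53, 0.33),
    # reported coefficient ratios for (ticv, head-size metric)
    b_ticv  = c(1.89e-5, 7.19e-6, 1.17e-5, 7.70e-6,
                6.52e-6, 1.84e-6, 6.80e-6, 4.77e-6),
    b_head  = c(0.063, 0.466, 0.080, 0.172,
                0.709, 0.143, 0.854, 0.191),
    stringsAsFactors = FALSE)
}

# target area correlation matrix across the eight outcomes
calib_area_correlations <- function() {
  keys <- as.vector(t(outer(CORD_LEVELS, CORD_MEASURES, outcome_key)))
  R <- diag(8)
  upper <- c(
    0.65, 0.89, 0.76, 0.74, 0.55, 0.65, 0.63,
          0.51, 0.58, 0.68, 0.38, 0.59, 0.52,
                0.85, 0.63, 0.55, 0.57, 0.62,
                      0.62, 0.30, 0.54, 0.57,
                            0.49, 0.89, 0.76,
                                  0.49, 0.63,
                                        0.74)
  # `upper` is listed row by row; lower.tri() indexes column-major,
  # which enumerates exactly those positions, so fill and reflect
  R[lower.tri(R)] <- upper
  R <- R + t(R) - diag(8)
  dimnames(R) <- list(keys, keys)
  R
}

solve_area_model <- function(M, tgt) {
  head_cov <- if (tgt$pathway == "sva") "sagittal_vertebra_area" else
    "ap_vertebra_diameter"
  model_covs <- if (tgt$measure == "TCA")
    c("age", "ticv", head_cov) else c("ticv", head_cov)

  make_beta <- function(s, b_age) {
    beta <- setNames(numeric(4), CORE_COVARIATES)
    beta["ticv"] <- s * tgt$b_ticv
    beta[head_cov] <- s * tgt$b_head
    beta["age"] <- b_age
    beta
  }

  # for a given pathway scale, solve (b_age, g) -- both enter the
  # age-slope and adjusted-sex-difference projections affinely
  solve_linear <- function(s) {
    if (tgt$measure == "TCA") {
      f <- function(b_age, g) {
        pm <- area_pop_moments(M, make_beta(s, b_age), g, 0)
        pr <- pop_age_sex_projection(M, pm)
        c(pr$age_slope, pr$sex_diff)
      }
      f00 <- f(0, 0)
      A <- cbind(f(1, 0) - f00, f(0, 1) - f00)
      sol <- solve(A, c(tgt$age_slope, tgt$sex_diff) - f00)
      list(b_age = sol[1], g = sol[2])
    } else {
      f <- function(g) {
        pm <- area_pop_moments(M, make_beta(s, 0), g, 0)
        pop_age_sex_projection(M, pm)$sex_diff
      }
      f0 <- f(0)
      list(b_age = 0, g = (tgt$sex_diff - f0) / (f(1) - f0))
    }
  }

  # population R^2 of the reported model with total variance pinned at
  # the target SD
  r2_at <- function(s) {
    lin <- solve_linear(s)
    pm <- area_pop_moments(M, make_beta(s, lin$b_age), lin$g, 0)
    cv <- pm$cov_x[model_covs]
    captured <- drop(crossprod(cv, solve(M$mix_cov[model_covs, model_covs],
                                         cv)))
    list(r2 = captured / tgt$sd^2, lin = lin, pm = pm)
  }

  # bracket: pathway variance must leave room for a positive residual
  s_hi <- 1
  while (r2_at(s_hi)$pm$var_struct < 0.95 * tgt$sd^2 && s_hi < 64)
    s_hi <- s_hi * 2
  root <- uniroot(function(s) r2_at(s)$r2 - tgt$r2,
                  lower = 1e-3, upper = s_hi, tol = 1e-10)
  sol <- r2_at(root$root)
  beta <- make_beta(root$root, sol$lin$b_age)
  sigma2 <- tgt$sd^2 - sol$pm$var_struct
  if (sigma2 <= 0)
    stop("calibration infeasible for ", outcome_key(tgt$level, tgt$measure),
         call. = FALSE)
  pm <- area_pop_moments(M, beta, sol$lin$g, sqrt(sigma2))
  alpha <- tgt$mean - pm$mean
  list(level = tgt$level, measure = tgt$measure,
       coefficients = beta[beta != 0],
       sex_offset = sol$lin$g, intercept = alpha,
       residual_sd = sqrt(sigma2))
}

#' The packaged default configuration
#'
#' Returns the calibrated generator configuration emulating the
#' 32-subject healthy-control study: 14 men / 18 women, ages 28-78
#' (pooled mean 48.8, SD 14.3), TICV mean 1,434,165 mm^3,
#' ap_vertebra_diameter mean 15.63 mm, sagittal_vertebra_area mean
#' 199.93 mm^2, per-level area means/SDs, sex and age effects, reported
#' model R^2 values, and the cross-level area correlation structure
#' (adjacent-level TCA correlation 0.89).  The calibration is computed,
#' not hard-coded: see the source of `solve_area_model()` and the
#' methods vignette.
#'
#' @param seed default seed stored in the config.
#' @return a [generator_config()].
#' @export
default_config <- function(seed = 1L) {
  cached <- get0(".default_config_cache", envir = cordnorm_cache)
  if (!is.null(cached)) {
    cached$seed <- as.integer(seed)
    return(cached)
  }

  p_female <- 18 / 32
  sex_age <- list(M = list(mean = 46.8, sd = 13.4),
                  F = list(mean = 50.4, sd = 15.1))
  # per-sex covariate means; weighted means reproduce the cohort means
  # (TICV 1434165.26, apvd 15.63, sva 199.93)
  d_ticv <- 150000; d_apvd <- 0.8; d_sva <- 15
  means <- c(ticv = 1434165.26, ap_vertebra_diameter = 15.63,
             sagittal_vertebra_area = 199.93)
  gaps <- c(ticv = d_ticv, ap_vertebra_diameter = d_apvd,
            sagittal_vertebra_area = d_sva)
  mu_M <- means + p_female * gaps
  mu_F <- means - (1 - p_female) * gaps
  sex_covariate_means <- cbind(M = mu_M, F = mu_F)

  covariate_sds <- c(ticv = 110000, ap_vertebra_diameter = 1.0,
                     sagittal_vertebra_area = 20)

  # within-sex correlations: a common head-size factor links TICV and
  # the vertebra metrics; the negative age rows reconcile the marginal
  # (about -2 mm^2/decade) with the conditional (about -0.1 mm^2/year)
  # age effects of the cervical TCA models
  Rw <- matrix(c(
    1.00, -0.40, -0.40, -0.40,
   -0.40,  1.00,  0.30,  0.40,
   -0.40,  0.30,  1.00,  0.40,
   -0.40,  0.40,  0.40,  1.00), 4, 4,
    dimnames = list(CORE_COVARIATES, CORE_COVARIATES))

  # within-sex age SDs as achieved under the [28, 78] range truncation
  sd_age <- vapply(sex_age, function(s)
    age_truncation_params(s$mean, s$sd, 28, 78)$sd_achieved, numeric(1))
  M <- core_moments(1 - p_female,
                    rbind(age = c(M = 46.8, F = 50.4), sex_covariate_means),
                    rbind(age = sd_age,
                          matrix(rep(covariate_sds, 2), ncol = 2,
                                 dimnames = list(names(covariate_sds),
                                                 c("M", "F")))),
                    Rw)

  tgts <- calib_outcome_targets()
  area_models <- list()
  for (i in seq_len(nrow(tgts))) {
    tgt <- as.list(tgts[i, ])
    area_models[[outcome_key(tgt$level, tgt$measure)]] <-
      solve_area_model(M, tgt)
  }

  # residual correlations from the target area correlations
  keys <- names(area_models)
  sds <- tgts$sd
  Rtar <- calib_area_correlations()
  Re <- diag(8)
  for (i in 1:7) for (j in (i + 1):8) {
    bi <- setNames(numeric(4), CORE_COVARIATES)
    bi[names(area_models[[i]]$coefficients)] <- area_models[[i]]$coefficients
    bj <- setNames(numeric(4), CORE_COVARIATES)
    bj[names(area_models[[j]]$coefficients)] <- area_models[[j]]$coefficients
    sc <- area_struct_cov(M, bi, area_models[[i]]$sex_offset,
                          bj, area_models[[j]]$sex_offset)
    rho <- (Rtar[i, j] * sds[i] * sds[j] - sc) /
      (area_models[[i]]$residual_sd * area_models[[j]]$residual_sd)
    Re[i, j] <- Re[j, i] <- max(-0.95, min(0.95, rho))
  }
  dimnames(Re) <- list(keys, keys)
  ev <- eigen(Re, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0)
    Re <- as.matrix(Matrix::nearPD(Re, corr = TRUE)$mat)
  dimnames(Re) <- list(keys, keys)

  extras <- data.frame(
    name = c("total_cortex", "subcortical_gm", "total_wm", "thalamus",
             "cerebellum", "brainstem", "foramen_magnum_area",
             "nasion_inion", "mcrae_line", "mcraes_to_c4",
             "ap_canal_diameter"),
    mean_M = c(490000, 62000, 480000, 15800, 145000, 23000,
               870, 192, 36.5, 80, 14.6),
    mean_F = c(440000, 56000, 420000, 14400, 131000, 20500,
               810, 182, 34.5, 74, 13.9),
    sd = c(38000, 5200, 42000, 1300, 12500, 2100, 75, 7.5, 2.6, 5.5, 1.1),
    r_ticv = c(0.75, 0.70, 0.78, 0.60, 0.55, 0.55, 0.45, 0.40, 0.30,
               0.35, 0.25),
    stringsAsFactors = FALSE)

  height_weight <- list(
    height = list(M = list(mean = 177.5, sd = 7.0),
                  F = list(mean = 164.5, sd = 6.5)),
    weight_sd = 9.5, bmi_mean = 24.5, height_weight_cor = 0.45)

  config <- generator_config(
    n_subjects = 32L, female_fraction = p_female,
    age_distribution = list(mean = 48.8, sd = 14.3, min = 28, max = 78),
    sex_age = sex_age,
    sex_covariate_means = sex_covariate_means,
    covariate_sds = covariate_sds,
    covariate_correlations = Rw,
    area_models = area_models,
    cross_level_residual_correlations = Re,
    missingness = list(thoracic = 2L, covariates = 2L, shared = TRUE),
    extra_covariates = extras,
    height_weight = height_weight,
    seed = as.integer(seed))
  assign(".default_config_cache", config, envir = cordnorm_cache)
  config
}

cordnorm_cache <- new.env(parent = emptyenv())
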