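# Population moment algebra for the generative cohort model.
#
# The generator draws sex ~ Bernoulli, then (age, ticv,
# ap_vertebra_diameter, sagittal_vertebra_area) from a sex-conditional
# multivariate normal (age truncated by resampling), then each cord
# area as a linear predictor in those covariates plus a sex offset plus
# a correlated Gaussian residual.  Everything the calibration needs --
# means, SDs, correlations, projection (OLS) coefficients and
# population R-squared of any covariate subset -- is a closed-form
# function of the configured first and second moments, computed here.
# Moments are on the post-truncation ("target") scale throughout.

# first/second moments of the sex mixture over the core covariates
core_moments <- function(p_male, mu, sds_by_sex, corr) {
  # mu: 4 x 2 matrix (rows CORE_COVARIATES, cols M, F), target scale
  # sds_by_sex: 4 x 2 matrix of within-sex SDs
  # corr: shared 4 x 4 within-sex correlation matrix
  q <- p_male * (1 - p_male)
  dmu <- mu[, "M"] - mu[, "F"]
  S_M <- diag(sds_by_sex[, "M"]) %*% corr %*% diag(sds_by_sex[, "M"])
  S_F <- diag(sds_by_sex[, "F"]) %*% corr %*% diag(sds_by_sex[, "F"])
  Sbar <- p_male * S_M + (1 - p_male) * S_F
  dimnames(Sbar) <- dimnames(S_M) <- dimnames(S_F) <-
    list(CORE_COVARIATES, CORE_COVARIATES)
  mix_mean <- drop(mu %*% c(p_male, 1 - p_male))
  mix_cov <- Sbar + q * tcrossprod(dmu)
  list(p = p_male, q = q, mu = mu, dmu = dmu,
       S_M = S_M, S_F = S_F, Sbar = Sbar,
       mix_mean = mix_mean, mix_cov = mix_cov)
}

# population moments of one area outcome: A = alpha + beta'X + g*M + eps
area_pop_moments <- function(M, beta, g, sigma, alpha = 0) {
  sex_eff <- drop(crossprod(beta, M$dmu)) + g   # E[A|M] - E[A|F]
  cov_x <- drop(M$Sbar %*% beta) + M$q * sex_eff * M$dmu
  names(cov_x) <- CORE_COVARIATES
  var_struct <- drop(crossprod(beta, M$Sbar %*% beta)) + M$q * sex_eff^2
  list(mean = alpha + drop(crossprod(beta, M$mix_mean)) + g * M$p,
       var = var_struct + sigma^2,
       var_struct = var_struct,
       cov_x = cov_x,
       cov_sex = M$q * sex_eff,
       sex_eff = sex_eff)
}

# structural (pre-residual) covariance between two outcomes
area_struct_cov <- function(M, beta1, g1, beta2, g2) {
  s1 <- drop(crossprod(beta1, M$dmu)) + g1
  s2 <- drop(crossprod(beta2, M$dmu)) + g2
  drop(crossprod(beta1, M$Sbar %*% beta2)) + M$q * s1 * s2
}

# population R^2 of the OLS projection of the outcome on a subset of
# the core covariates
pop_r2 <- function(M, pm, covariates) {
  S <- M$mix_cov[covariates, covariates, drop = FALSE]
  cv <- pm$cov_x[covariates]
  drop(crossprod(cv, solve(S, cv))) / pm$var
}

# projection of the outcome on (age, male): returns the age slope and
# the male-minus-female difference adjusted for age -- the population
# counterparts of lm(A ~ age + sex) and of the age-adjusted
# least-square-means sex comparison
pop_age_sex_projection <- function(M, pm) {
  v_age <- M$mix_cov["age", "age"]
  c_am <- M$q * M$dmu["age"]
  S <- matrix(c(v_age, c_am, c_am, M$q), 2, 2)
  b <- solve(S, c(pm$cov_x["age"], pm$cov_sex))
  list(age_slope = b[1], sex_diff = b[2])
}

# population correlation of an outcome with one core covariate
pop_cor_x <- function(M, pm, covariate) {
  pm$cov_x[covariate] / sqrt(pm$var * M$mix_cov[covariate, covariate])
}
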