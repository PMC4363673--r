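truncnorm_moments <- function(m, s, lo, hi) {
  a <- (lo - m) / s; b <- (hi - m) / s
  Z <- pnorm(b) - pnorm(a)
  d <- (dnorm(a) - dnorm(b)) / Z
  c(mean = m + s * d,
    var = s^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z - d^2))
}

# Latent age parameters for generation under hard range truncation.
# The truncation window is narrow relative to the nominal SD, so no
# latent normal attains the nominal SD inside it; the latent SD is
# fixed at 1.3x nominal and the latent mean solved so the truncated
# MEAN is exact.  The achieved truncated SD is what the calibration
# engine uses as the within-sex age SD, keeping downstream moments
# exact with respect to the actual generative distribution.
age_truncation_params <- function(mean_t, sd_nominal, lo, hi) {
  s_lat <- 1.3 * sd_nominal
  m_lat <- uniroot(function(m)
    truncnorm_moments(m, s_lat, lo, hi)[["mean"]] - mean_t,
    lower = lo - 3 * s_lat, upper = hi + 3 * s_lat, tol = 1e-12)$root
  tm <- truncnorm_moments(m_lat, s_lat, lo, hi)
  list(m_lat = m_lat, s_lat = s_lat, sd_achieved = sqrt(tm[["var"]]))
}

# Latent (pre-truncation) per-sex parameters reproducing the target
# covariate moments after age is truncated to [lo, hi] by resampling.
# With (age, C) jointly normal and the whole vector redrawn whenever
# age falls outside the range, the observed distribution is the
# age-slab-truncated normal, whose moments are closed-form; this
# inverts them so the post-truncation moments equal the targets.
# `S` is the target within-sex covariance on the truncated scale (its
# age variance being the achieved truncated variance).
latent_sex_params <- function(mean_t, sd_nominal, lo, hi, mu_c, S) {
  ap <- age_truncation_params(mean_t, sd_nominal, lo, hi)
  m_a <- ap$m_lat; s_a <- ap$s_lat
  mean_tr <- mean_t
  var_tr <- ap$sd_achieved^2
  v_lat <- s_a^2
  shrink <- var_tr / v_lat          # variance retained after truncation

  # invert the truncation maps for the covariate block
  # cov_tr(age, C) = cov_lat * shrink
  c_tr <- S[1, -1]
  c_lat <- c_tr / shrink
  # var/cov of C: cov_tr(Ci, Cj) = cov_lat - c_i c_j / v_lat * (1 - shrink)
  S_cc_lat <- S[-1, -1] + tcrossprod(c_lat) / v_lat * (1 - shrink)
  # E_tr[C] = mean_lat(C) + c_lat / v_lat * (mean_tr - m_a)
  mu_c_lat <- mu_c - c_lat / v_lat * (mean_tr - m_a)

  S_lat <- rbind(c(v_lat, c_lat), cbind(c_lat, S_cc_lat))
  list(mean = c(m_a, mu_c_lat), chol = t(chol(S_lat)),
       age_mean_latent = m_a)
}

# everything generate_cohort() needs, precomputed once per config
generator_internals <- function(config) {
  M <- config_core_moments(config)
  lo <- config$age_distribution$min
  hi <- config$age_distribution$max
  lat <- list(
    M = latent_sex_params(config$sex_age$M$mean, config$sex_age$M$sd,
                          lo, hi, M$mu[-1, "M"], M$S_M),
    F = latent_sex_params(config$sex_age$F$mean, config$sex_age$F$sd,
                          lo, hi, M$mu[-1, "F"], M$S_F))
  keys <- names(config$area_models)
  betas <- sapply(keys, function(k) config_area_beta(config, k))
  res_sd <- vapply(config$area_models, `[[`, numeric(1), "residual_sd")
  g <- vapply(config$area_models, `[[`, numeric(1), "sex_offset")
  alpha <- vapply(config$area_models, `[[`, numeric(1), "intercept")
  Lres <- t(chol(config$cross_level_residual_correlations))
  list(M = M, lat = lat, keys = keys, betas = betas, res_sd = res_sd,
       g = g, alpha = alpha, Lres = Lres, lo = lo, hi = hi)
}

subject_seed <- function(seed, i) {
  (as.numeric(seed) %% 97911) * 21001 + i * 7 + 11
}

#' Generate a synthetic cohort
#'
#' Draws, per subject: sex; then age and the core covariates (TICV,
#' ap_vertebra_diameter, sagittal_vertebra_area) from the
#' sex-conditional joint normal, resampling the whole vector until age
#' falls inside the configured range; then auxiliary brain/skeletal
#' metrics, height and weight; then the eight cord areas as linear
#' predictors plus a cross-level correlated Gaussian residual vector,
#' redrawing the residuals in the rare case a GM area does not satisfy
#' `0 < gm < tca`.  The configured missingness pattern (subjects
#' lacking the thoracic levels / the covariate record) is applied last.
#'
#' Each subject consumes an independent RNG stream derived from `seed`
#' and the subject index, so enlarging the cohort does not perturb
#' earlier subjects.  Identical `(config, n, seed)` yield identical
#' cohorts.
#'
#' @param config a [generator_config()], typically [default_config()].
#' @param n number of subjects (default `config$n_subjects`).
#' @param seed integer seed (default `config$seed`).
#' @return a [cohort()] with derived metrics populated.
#' @export
generate_cohort <- function(config, n = config$n_subjects,
                            seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (n < 4) stop("n must be at least 4", call. = FALSE)
  gi <- generator_internals(config)
  extras <- config$extra_covariates
  hw <- config$height_weight
  n_out <- length(gi$keys)
  sigma_ticv <- config$covariate_sds[["ticv"]]

  ids <- sprintf("S%05d", seq_len(n))
  sex <- character(n)
  core <- matrix(NA_real_, n, 4, dimnames = list(NULL, CORE_COVARIATES))
  areas <- matrix(NA_real_, n, n_out, dimnames = list(NULL, gi$keys))
  height <- weight <- dh <- middle_dev <- numeric(n)
  n_extra <- if (is.null(extras)) 0L else nrow(extras)
  extra_vals <- matrix(NA_real_, n, n_extra)
  resample_total <- 0L

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))

  for (i in seq_len(n)) {
    set.seed(subject_seed(seed, i))
    s <- if (runif(1) < 1 - config$female_fraction) "M" else "F"
    sex[i] <- s
    lat <- gi$lat[[s]]
    for (try in 1:1000) {
      x <- lat$mean + drop(lat$chol %*% rnorm(4))
      if (x[1] >= gi$lo && x[1] <= gi$hi) break
      if (try == 1000) stop("age truncation failed to converge",
                            call. = FALSE)
    }
    core[i, ] <- x

    # auxiliary metrics: noisy regressions on standardized TICV
    if (n_extra) {
      ticv_z <- (x[2] - gi$M$mu["ticv", s]) / sigma_ticv
      z <- rnorm(n_extra)
      mu_e <- if (s == "M") extras$mean_M else extras$mean_F
      extra_vals[i, ] <- mu_e + extras$sd *
        (extras$r_ticv * ticv_z + sqrt(1 - extras$r_ticv^2) * z)
    }

    hs <- hw$height[[s]]
    hz <- rnorm(1)
    height[i] <- hs$mean + hs$sd * hz
    weight[i] <- hw$bmi_mean * (height[i] / 100)^2 +
      hw$weight_sd * (hw$height_weight_cor * hz +
                      sqrt(1 - hw$height_weight_cor^2) * rnorm(1))

    # areas with cross-level correlated residuals; redraw residuals if
    # a GM/TCA ordering constraint is violated
    base <- gi$alpha + drop(crossprod(gi$betas, x)) + gi$g * (s == "M")
    for (try in 1:100) {
      eps <- gi$res_sd * drop(gi$Lres %*% rnorm(n_out))
      a <- base + eps
      tca <- a[seq(1, n_out, by = 2)]
      gm <- a[seq(2, n_out, by = 2)]
      if (all(gm > 0) && all(gm < tca)) break
      resample_total <- resample_total + 1L
      if (try == 100) stop("area constraints unreachable; check config",
                           call. = FALSE)
    }
    areas[i, ] <- a

    # per-subject vertebra height split (see covariates block below)
    dh[i] <- rnorm(1, 0, 0.35)
    middle_dev[i] <- rnorm(1, 0, 0.045)
  }
  if (resample_total > 0.1 * n)
    stop(sprintf("excessive residual resampling (%d redraws for %d subjects)",
                 resample_total, n), call. = FALSE)

  # missingness: which subjects lack thoracic levels / covariates
  set.seed(subject_seed(seed, 0))
  n_thor <- min(config$missingness$thoracic, n)
  n_cov <- min(config$missingness$covariates, n)
  miss_thor <- sort(sample.int(n, n_thor))
  miss_cov <- if (isTRUE(config$missingness$shared)) {
    if (n_cov <= n_thor) miss_thor[seq_len(n_cov)] else
      sort(c(miss_thor, sample(setdiff(seq_len(n), miss_thor),
                               n_cov - n_thor)))
  } else sort(sample(setdiff(seq_len(n), miss_thor), n_cov))

  subjects <- data.frame(id = ids, sex = sex, age = core[, "age"],
                         height = height, weight = weight,
                         stringsAsFactors = FALSE)

  cord_rows <- list()
  for (k in seq_along(gi$keys)) {
    parts <- strsplit(gi$keys[k], ":", fixed = TRUE)[[1]]
    lv <- parts[1]
    keep <- if (lv %in% c("T8-T9", "T9-T10"))
      setdiff(seq_len(n), miss_thor) else seq_len(n)
    if (parts[2] == "TCA")
      cord_rows[[lv]] <- data.frame(
        id = ids[keep], level = lv,
        tca = areas[keep, outcome_key(lv, "TCA")],
        gm = areas[keep, outcome_key(lv, "GM")],
        stringsAsFactors = FALSE)
  }
  cord <- do.call(rbind, cord_rows)
  rownames(cord) <- NULL

  keep_cov <- setdiff(seq_len(n), miss_cov)
  mvh <- core[, "sagittal_vertebra_area"] / core[, "ap_vertebra_diameter"]
  # vertebra heights consistent with the drawn sagittal area:
  # anterior/posterior average to mvh exactly; the middle height gets
  # its own small deviation so the two area proxies stay distinct
  middle <- mvh * (1 + middle_dev)
  covariates <- data.frame(
    id = ids[keep_cov],
    ticv = core[keep_cov, "ticv"],
    ap_vertebra_diameter = core[keep_cov, "ap_vertebra_diameter"],
    anterior_height = mvh[keep_cov] + dh[keep_cov],
    posterior_height = mvh[keep_cov] - dh[keep_cov],
    middle_vertebra_height = middle[keep_cov],
    stringsAsFactors = FALSE)
  if (n_extra)
    for (j in seq_len(n_extra))
      covariates[[extras$name[j]]] <- extra_vals[keep_cov, j]
  if (all(c("total_cortex", "subcortical_gm", "total_wm") %in%
          names(covariates))) {
    covariates$total_gm <- covariates$total_cortex +
      covariates$subcortical_gm
    covariates$brain <- covariates$total_gm + covariates$total_wm
  }

  derive_metrics(cohort(subjects, cord, covariates,
                        age_range = c(gi$lo - 10, gi$hi + 22)))
}
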