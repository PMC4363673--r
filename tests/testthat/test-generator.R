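test_that("the packaged configuration carries the study conditions", {
  cfg <- default_config()
  expect_identical(cfg$n_subjects, 32L)
  expect_equal(cfg$female_fraction, 18 / 32)
  expect_equal(cfg$age_distribution$mean, 48.8)
  expect_equal(cfg$age_distribution$sd, 14.3)
  expect_equal(c(cfg$age_distribution$min, cfg$age_distribution$max),
               c(28, 78))
  expect_equal(cfg$sex_age$M$mean, 46.8)
  expect_equal(cfg$sex_age$F$mean, 50.4)
  # cohort-level covariate means recombine from the per-sex means
  p <- 1 - cfg$female_fraction
  mix <- cfg$sex_covariate_means %*% c(p, 1 - p)
  expect_equal(unname(mix["ticv", 1]), 1434165.26)
  expect_equal(unname(mix["ap_vertebra_diameter", 1]), 15.63)
  expect_equal(unname(mix["sagittal_vertebra_area", 1]), 199.93)
  expect_identical(cfg$missingness$thoracic, 2L)
  expect_identical(cfg$missingness$covariates, 2L)
})

test_that("the calibrated population matches its analytic targets", {
  s <- config_population_summary(default_config())
  expect_equal(s$mean, c(79.7, 19.4, 84.1, 21.9, 44.3, 10.3, 45.3, 11.1),
               tolerance = 1e-6)
  expect_equal(s$sd, c(7.0, 1.9, 7.1, 1.9, 3.1, 1.6, 3.5, 1.3),
               tolerance = 1e-6)
  expect_equal(s$sex_diff_age_adj,
               c(4.60, 1.51, 4.60, 1.51, 3.05, 1.26, 3.05, 1.26),
               tolerance = 1e-6)
  tca <- s$outcome %in% paste0(c("C2-C3", "C3-C4", "T8-T9", "T9-T10"),
                               ":TCA")
  expect_equal(s$age_slope[tca], c(-0.20, -0.20, -0.13, -0.13),
               tolerance = 1e-6)
  # targeted model R^2 values
  expect_equal(s$r2_age_ticv_sva[s$outcome == "C2-C3:TCA"], 0.47,
               tolerance = 1e-6)
  expect_equal(s$r2_ticv_apvd[s$outcome == "C2-C3:GM"], 0.40,
               tolerance = 1e-6)
  expect_equal(s$r2_age_ticv_apvd[s$outcome == "T9-T10:TCA"], 0.53,
               tolerance = 1e-6)
})

test_that("generation is reproducible and stream-stable", {
  cfg <- default_config()
  a <- generate_cohort(cfg, n = 32, seed = 123)
  b <- generate_cohort(cfg, n = 32, seed = 123)
  expect_identical(a, b)
  other <- generate_cohort(cfg, n = 32, seed = 124)
  expect_false(identical(a$cord$tca, other$cord$tca))
  # enlarging the cohort leaves earlier subjects untouched
  big <- generate_cohort(cfg, n = 48, seed = 123)
  expect_identical(big$subjects[1:32, c("id", "sex", "age", "height")],
                   a$subjects[, c("id", "sex", "age", "height")])
  shared <- intersect(a$cord$id, big$cord$id)
  ka <- a$cord[a$cord$id %in% shared & a$cord$level == "C2-C3", "tca"]
  kb <- big$cord[big$cord$id %in% shared & big$cord$level == "C2-C3", "tca"]
  expect_identical(ka, kb)
})

test_that("missingness counts match the configuration exactly", {
  co <- generate_cohort(default_config(), n = 32, seed = 77)
  w <- cohort_wide(co)
  expect_identical(sum(is.na(w$tca_T8.T9)), 2L)
  expect_identical(sum(is.na(w$tca_T9.T10)), 2L)
  expect_identical(sum(is.na(w$ticv)), 2L)
  # the same two subjects lack both (thoracic n stays 30)
  expect_identical(which(is.na(w$tca_T8.T9)), which(is.na(w$ticv)))
  expect_identical(nrow(co$covariates), 30L)
})

test_that("a degenerate configuration is deterministic", {
  cfg <- default_config()
  for (k in names(cfg$area_models)) {
    cfg$area_models[[k]]$coefficients[] <- 0
    cfg$area_models[[k]]$sex_offset <- 0
    cfg$area_models[[k]]$residual_sd <- 1e-9
    cfg$area_models[[k]]$intercept <- if (grepl("TCA", k)) 80 else 20
  }
  co <- generate_cohort(cfg, n = 10, seed = 5)
  expect_equal(co$cord$tca, rep(80, nrow(co$cord)), tolerance = 1e-6)
  expect_equal(co$cord$gm, rep(20, nrow(co$cord)), tolerance = 1e-6)
})

test_that("generated data recover the configured coefficients", {
  cfg <- default_config()
  co <- generate_cohort(cfg, n = 20000, seed = 99)
  w <- cohort_wide(co)
  w$male <- as.numeric(w$sex == "M")
  fit <- lm(tca_C2.C3 ~ age + ticv + sagittal_vertebra_area + male,
            data = w)
  am <- cfg$area_models[["C2-C3:TCA"]]
  expect_lt(abs(coef(fit)[["age"]] - am$coefficients[["age"]]), 0.015)
  expect_lt(abs(coef(fit)[["ticv"]] - am$coefficients[["ticv"]]) /
              am$coefficients[["ticv"]], 0.15)
  expect_lt(abs(coef(fit)[["sagittal_vertebra_area"]] -
                  am$coefficients[["sagittal_vertebra_area"]]) /
              am$coefficients[["sagittal_vertebra_area"]], 0.15)
  expect_lt(abs(coef(fit)[["male"]] - am$sex_offset), 0.35)
})

test_that("large samples converge to the configured moments", {
  co <- generate_cohort(default_config(), n = 8000, seed = 55)
  w <- cohort_wide(co)
  expect_equal(mean(w$gm_C2.C3), 19.4, tolerance = 0.1)
  expect_equal(sd(w$tca_T9.T10, na.rm = TRUE), 3.5, tolerance = 0.15)
  expect_equal(mean(w$ticv, na.rm = TRUE), 1434165.26,
               tolerance = 5000 / 1434165)
  expect_equal(cor(w$gm_T8.T9, w$gm_T9.T10, use = "complete.obs"), 0.63,
               tolerance = 0.05)
  expect_true(all(w$age >= 28 & w$age <= 78))
  expect_true(all(co$cord$gm > 0 & co$cord$gm < co$cord$tca))
})

test_that("derived vertebra metrics stay internally consistent", {
  co <- generate_cohort(default_config(), n = 200, seed = 61)
  cv <- co$covariates
  expect_equal(cv$sagittal_vertebra_area,
               (cv$anterior_height + cv$posterior_height) / 2 *
                 cv$ap_vertebra_diameter, tolerance = 1e-9)
  # the trapezoid proxy is correlated with, but distinct from, the
  # rectangle proxy
  r <- cor(cv$sagittal_area_trapez, cv$sagittal_vertebra_area)
  expect_gt(r, 0.9)
  expect_lt(r, 0.9999)
})

test_that("calibrate_residuals hits a requested adjusted R-squared", {
  cfg <- default_config()
  cfg2 <- calibrate_residuals(cfg, c("C2-C3:TCA" = 0.47), n = 30)
  # implied population R^2 equals the de-adjusted target
  r2_expect <- 1 - (1 - 0.47) * (30 - 3 - 1) / (30 - 1)
  s <- config_population_summary(cfg2)
  expect_equal(s$r2_age_ticv_sva[s$outcome == "C2-C3:TCA"], r2_expect,
               tolerance = 1e-8)
  # brute-force check: a large simulated regression reproduces it
  co <- generate_cohort(cfg2, n = 20000, seed = 8)
  fit <- summary(lm(tca_C2.C3 ~ age + ticv + sagittal_vertebra_area,
                    data = cohort_wide(co)))
  expect_equal(fit$r.squared, r2_expect, tolerance = 0.02)
  # boundary targets are rejected
  expect_error(calibrate_residuals(cfg, c("C2-C3:TCA" = 0)), "in \\(0, 1\\)")
  expect_error(calibrate_residuals(cfg, c("C2-C3:TCA" = 1)), "in \\(0, 1\\)")
  # a weak pathway cannot reach a high R^2 for any residual SD
  expect_error(calibrate_residuals(cfg, c("C2-C3:GM" = 0.9),
                                   covariates = "age", n = 30, p = 1),
               "not reachable")
})

test_that("the closed form behind calibrate_residuals is correct", {
  # one covariate capturing all structural variance: var(pred) = 1 and
  # target R^2 = 0.5 force sigma^2 = 1
  cfg <- default_config()
  key <- "C2-C3:TCA"
  am <- cfg$area_models[[key]]
  sd_age <- cordnorm:::age_truncation_params(46.8, 13.4, 28, 78)$sd_achieved
  cfg$area_models[[key]]$coefficients <-
    c(age = 0, ticv = 0, sagittal_vertebra_area = 0)
  cfg$area_models[[key]]$sex_offset <- 0
  # give the model a pure age pathway with unit predictor variance
  M <- cordnorm:::config_core_moments(cfg)
  v_age <- M$mix_cov["age", "age"]
  cfg$area_models[[key]]$coefficients["age"] <- 1 / sqrt(v_age)
  r2 <- 0.5
  adj <- 1 - (1 - r2) * (30 - 1) / (30 - 1 - 1)
  out <- calibrate_residuals(cfg, setNames(adj, key),
                             covariates = "age", n = 30, p = 1)
  expect_equal(out$area_models[[key]]$residual_sd, 1, tolerance = 1e-8)
})

test_that("invalid correlation inputs are rejected or repaired", {
  cfg <- default_config()
  bad <- cfg$covariate_correlations
  bad[1, 2] <- bad[2, 1] <- 0.999
  bad[1, 3] <- bad[3, 1] <- -0.999
  bad[2, 3] <- bad[3, 2] <- 0.999
  expect_error(generator_config(
    n_subjects = 32, female_fraction = 0.5,
    age_distribution = cfg$age_distribution, sex_age = cfg$sex_age,
    sex_covariate_means = cfg$sex_covariate_means,
    covariate_sds = cfg$covariate_sds,
    covariate_correlations = bad,
    area_models = cfg$area_models,
    cross_level_residual_correlations =
      cfg$cross_level_residual_correlations),
    "positive semi-definite")
  expect_error(generator_config(
    n_subjects = 32, female_fraction = 1.5,
    age_distribution = cfg$age_distribution, sex_age = cfg$sex_age,
    sex_covariate_means = cfg$sex_covariate_means,
    covariate_sds = cfg$covariate_sds,
    covariate_correlations = cfg$covariate_correlations,
    area_models = cfg$area_models,
    cross_level_residual_correlations =
      cfg$cross_level_residual_correlations),
    "female_fraction")
})

test_that("configurations round-trip through YAML", {
  cfg <- default_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$sex_covariate_means, cfg$sex_covariate_means)
  expect_equal(back$covariate_correlations, cfg$covariate_correlations,
               tolerance = 1e-12)
  expect_equal(back$area_models[["C2-C3:TCA"]]$coefficients,
               cfg$area_models[["C2-C3:TCA"]]$coefficients)
  expect_identical(back$n_subjects, cfg$n_subjects)
  # and generates an equivalent cohort (YAML serialization keeps 17
  # significant digits)
  ca <- generate_cohort(back, n = 16, seed = 2)
  cb <- generate_cohort(cfg, n = 16, seed = 2)
  expect_equal(ca$cord$tca, cb$cord$tca, tolerance = 1e-9)
  expect_identical(ca$subjects$sex, cb$subjects$sex)
})
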