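toy_corr_table <- function(r_tca, r_gm, metrics) {
  rows <- c("C2-C3:TCA", "C2-C3:GM")
  rmat <- rbind(r_tca, r_gm)
  dimnames(rmat) <- list(rows, metrics)
  structure(list(r = rmat, p = rmat * 0, n = rmat * 0 + 30,
                 row_vars = rows, col_vars = metrics),
            class = "correlation_table")
}

test_that("screen_predictors keeps metrics with r above the threshold", {
  metrics <- c("ticv", "sagittal_vertebra_area", "sagittal_area_trapez",
               "ap_vertebra_diameter", "mean_vertebra_height",
               "mcraes_to_c4", "nasion_inion", "mcrae_line")
  # the reported screening pattern at the cervical reference level
  ct <- toy_corr_table(
    r_tca = c(0.63, 0.53, 0.42, 0.37, 0.46, 0.45, 0.45, 0.20),
    r_gm  = c(0.62, 0.52, 0.50, 0.57, 0.25, 0.22, 0.26, 0.15),
    metrics)
  kept <- screen_predictors(ct)
  expect_setequal(kept, c("ticv", "sagittal_vertebra_area",
                          "sagittal_area_trapez", "ap_vertebra_diameter",
                          "mean_vertebra_height"))
  # r exactly at the threshold is excluded (strict inequality):
  # mcraes_to_c4 and nasion_inion peak at exactly 0.45 above
  expect_false("mcraes_to_c4" %in% kept)
  # all-zero correlations retain nothing
  ct0 <- toy_corr_table(rep(0, 8), rep(0, 8), metrics)
  expect_length(screen_predictors(ct0), 0)
  # missing reference rows are an error
  ct$row_vars <- rownames(ct$r) <- c("C3-C4:TCA", "C3-C4:GM")
  expect_error(screen_predictors(ct), "lacks row")
})

test_that("a noiseless linear outcome is fitted exactly", {
  set.seed(6)
  d <- data.frame(x1 = rnorm(20), x2 = rnorm(20))
  d$y <- 3 + 1.5 * d$x1 - 2 * d$x2
  # lm warns about the (intentionally) perfect fit
  m <- suppressWarnings(fit_norm_model(d, "y", c("x1", "x2")))
  expect_equal(m$r2, 1)
  expect_equal(m$adj_r2, 1)
  expect_equal(unname(m$coefficients), c(1.5, -2), tolerance = 1e-10)
  expect_equal(m$intercept, 3, tolerance = 1e-10)
  expect_true(m$passes_gate)
})

test_that("coefficients match the explicit normal equations", {
  for (s in 1:5) {
    set.seed(s)
    p <- 3
    n <- p + 3
    d <- as.data.frame(matrix(rnorm(n * p), n, p,
                              dimnames = list(NULL, c("u", "v", "w"))))
    d$y <- rnorm(n)
    m <- fit_norm_model(d, "y", c("u", "v", "w"))
    X <- cbind(1, as.matrix(d[c("u", "v", "w")]))
    bhat <- solve(crossprod(X), crossprod(X, d$y))
    expect_equal(unname(m$coefficients), unname(bhat[-1, 1]),
                 tolerance = 1e-9)
    expect_equal(unname(m$intercept), unname(bhat[1, 1]), tolerance = 1e-9)
  }
})

test_that("adjusted R-squared follows its definition", {
  co <- generate_cohort(default_config(), n = 32, seed = 14)
  m <- fit_norm_model(co, "C2-C3:TCA",
                      c("age", "ticv", "sagittal_vertebra_area"))
  expect_equal(m$adj_r2,
               1 - (1 - m$r2) * (m$n - 1) / (m$n - 3 - 1),
               tolerance = 1e-12)
  expect_lte(m$adj_r2, m$r2)
  expect_identical(m$n, 30L)  # two subjects lack the covariate record
})

test_that("fit_norm_model validates cases and rank", {
  d <- data.frame(x1 = 1:4, y = c(2, 4, 6, 8))
  expect_error(fit_norm_model(d[1:3, ], "y", "x1"), "too few")
  d2 <- data.frame(x1 = c(1, 2, 3, 4, 5, 6))
  d2$x2 <- 2 * d2$x1              # exactly collinear
  d2$y <- c(2.1, 3.9, 6.2, 8.0, 9.8, 12.1)
  expect_error(fit_norm_model(d2, "y", c("x1", "x2")), "rank-deficient")
})

test_that("normalization is the identity at the covariate centroid", {
  co <- generate_cohort(default_config(), n = 32, seed = 16)
  m <- fit_norm_model(co, "C2-C3:TCA",
                      c("age", "ticv", "ap_vertebra_diameter"))
  expect_equal(apply_normalization(m, 81.25, as.list(m$means)), 81.25,
               tolerance = 1e-12)
})

test_that("the residual formula reproduces hand arithmetic", {
  m <- reference_models()[["model3_tca_c2c3"]]
  # only age deviates from the reference means: 10 years above adds
  # -0.105 * (48.84 - 58.84) = +1.05
  out <- apply_normalization(m, 75, list(age = 58.84, ticv = 1434165.26,
                                         sagittal_vertebra_area = 199.93))
  expect_equal(out, 76.05, tolerance = 1e-10)
})

test_that("each normalization term is linear in its coefficient", {
  m <- reference_models()[["model3_tca_c2c3"]]
  vals <- list(age = 60, ticv = 1500000, sagittal_vertebra_area = 210)
  base <- apply_normalization(m, 80, vals)
  m2 <- m
  m2$coefficients["age"] <- 2 * m2$coefficients["age"]
  doubled <- apply_normalization(m2, 80, vals)
  age_term <- m$coefficients[["age"]] * (m$means[["age"]] - vals$age)
  expect_equal(doubled - base, age_term, tolerance = 1e-12)
})

test_that("covariate mismatches are rejected", {
  m <- reference_models()[["model2a_gm_c2c3"]]
  expect_error(apply_normalization(m, 20, list(ticv = 1.4e6)),
               "missing covariate")
  expect_error(apply_normalization(m, 20,
                                   list(ticv = 1.4e6,
                                        ap_vertebra_diameter = 15,
                                        age = 50)),
               "not in model")
  expect_error(apply_normalization(m, 20,
                                   list(ticv = NA,
                                        ap_vertebra_diameter = 15)),
               "missing covariate value")
})

test_that("in-sample normalization obeys the exact %RSD identity", {
  co <- generate_cohort(default_config(), n = 32, seed = 18)
  w <- cohort_wide(co)
  m <- fit_norm_model(w, "C2-C3:TCA",
                      c("age", "ticv", "sagittal_vertebra_area"))
  ev <- evaluate_model(m, w)
  expect_equal(ev$rsd_norm, ev$rsd_meas * sqrt(1 - m$r2),
               tolerance = 1e-10)
  # and the normalized values preserve the outcome mean exactly
  keep <- !is.na(w$tca_C2.C3) & !is.na(w$ticv)
  y <- w$tca_C2.C3[keep]
  y_norm <- apply_normalization(m, y, list(
    age = w$age[keep], ticv = w$ticv[keep],
    sagittal_vertebra_area = w$sagittal_vertebra_area[keep]))
  expect_equal(mean(y_norm), mean(y), tolerance = 1e-12)
})

test_that("an all-zero model changes nothing", {
  m <- reference_models()[["model2a_gm_c2c3"]]
  m$coefficients[] <- 0
  co <- generate_cohort(default_config(), n = 32, seed = 20)
  ev <- evaluate_model(m, co)
  expect_equal(ev$reduction, 0, tolerance = 1e-12)
})

test_that("normalized values are invariant to affine covariate rescaling", {
  co <- generate_cohort(default_config(), n = 32, seed = 22)
  w <- cohort_wide(co)
  m1 <- fit_norm_model(w, "C2-C3:TCA", c("age", "ticv"))
  w2 <- w
  w2$ticv <- w2$ticv / 1000 + 7   # litres-with-offset, say
  m2 <- fit_norm_model(w2, "C2-C3:TCA", c("age", "ticv"))
  keep <- !is.na(w$tca_C2.C3) & !is.na(w$ticv)
  n1 <- apply_normalization(m1, w$tca_C2.C3[keep],
                            list(age = w$age[keep], ticv = w$ticv[keep]))
  n2 <- apply_normalization(m2, w2$tca_C2.C3[keep],
                            list(age = w2$age[keep], ticv = w2$ticv[keep]))
  expect_equal(n1, n2, tolerance = 1e-9)
})

test_that("transfer to the source level is idempotent", {
  co <- generate_cohort(default_config(), n = 32, seed = 24)
  covs <- c("age", "ticv", "ap_vertebra_diameter")
  direct <- fit_norm_model(co, "C2-C3:TCA", covs)
  tr <- transfer_model(co, covs, "C2-C3", "TCA")
  expect_equal(tr$model$coefficients, direct$coefficients)
  expect_equal(tr$model$adj_r2, direct$adj_r2)
})

test_that("transfer refits level-specific coefficients", {
  co <- generate_cohort(default_config(), n = 32, seed = 26)
  covs <- c("age", "ticv", "ap_vertebra_diameter")
  src <- fit_norm_model(co, "C2-C3:TCA", covs)
  tr <- transfer_model(co, covs, "T9-T10", "TCA")
  expect_identical(tr$model$covariates, covs)
  expect_false(isTRUE(all.equal(tr$model$coefficients, src$coefficients)))
  # the two thoracic-missing subjects are the covariate-missing ones,
  # so thoracic complete cases stay at 30
  expect_identical(tr$model$n, 30L)
})

test_that("non-significant covariates are dropped on request", {
  set.seed(33)
  n <- 200
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$tca_C2.C3 <- 50 + 3 * d$x1 + rnorm(n, 0, 1)
  tr <- transfer_model(d, c("x1", "x2"), "C2-C3", "TCA",
                       drop_nonsignificant = TRUE)
  expect_identical(tr$model$covariates, "x1")
})

test_that("norm model YAML round-trips", {
  co <- generate_cohort(default_config(), n = 32, seed = 28)
  m <- fit_norm_model(co, "C2-C3:GM", c("ticv", "ap_vertebra_diameter"))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_norm_model(m, path)
  back <- read_norm_model(path)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$means, m$means)
  expect_equal(back$adj_r2, m$adj_r2)
  expect_identical(back$covariates, m$covariates)
})

test_that("packaged reference models load with gates evaluated", {
  mods <- reference_models()
  expect_length(mods, 14)
  expect_true(mods$model3_tca_c2c3$passes_gate)
  expect_false(mods$model2a_gm_t8t9$passes_gate)  # unreported adj R^2
  expect_true(is.na(mods$model2a_gm_t8t9$adj_r2))
  expect_equal(mods$model2_tca_c2c3$means[["age"]], 48.84)
  expect_equal(mods$model2a_gm_t9t10$adj_r2, 0.33)
})
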