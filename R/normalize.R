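# skull/vertebra-derived candidate normalization metrics: covariates not
# expected to be altered by neurological disease (brain tissue volumes
# are excluded from screening by design)
SKELETAL_METRICS <- c(
  "ticv", "nasion_inion", "foramen_magnum_area", "mcrae_line",
  "mcraes_to_c4", "ap_canal_diameter", "ap_vertebra_diameter",
  "middle_vertebra_height", "mean_vertebra_height",
  "sagittal_vertebra_area", "sagittal_area_trapez")

#' Screen normalization candidates by correlation strength
#'
#' Retains the metrics whose Pearson correlation with the reference
#' level's TCA or GM area is strictly greater than the threshold.
#' Screening is restricted to skull- and vertebra-derived metrics,
#' which are unlikely to be altered by diseases that affect brain and
#' cord tissue.
#'
#' @param corr a [correlation_table()] whose rows contain the TCA and
#'   GM outcomes of the reference level and whose columns are candidate
#'   metrics.
#' @param threshold retention threshold on `r` (strict inequality).
#' @param level reference disc level used to locate the TCA/GM rows.
#' @param candidates metrics eligible for retention.
#' @return character vector of retained metric names (column order).
#' @export
screen_predictors <- function(corr, threshold = 0.45, level = "C2-C3",
                              candidates = SKELETAL_METRICS) {
  stopifnot(inherits(corr, "correlation_table"))
  rows <- paste0(level, ":", c("TCA", "GM"))
  miss <- setdiff(rows, rownames(corr$r))
  if (length(miss))
    stop("correlation table lacks row(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cols <- intersect(colnames(corr$r), candidates)
  best <- apply(corr$r[rows, cols, drop = FALSE], 2, max)
  names(best)[best > threshold]
}

#' Fit a multi-linear normalization model
#'
#' Ordinary least squares of the outcome on the covariates over
#' complete cases.  The fitted object freezes everything the residual
#' normalization needs: the coefficients, the complete-case covariate
#' means of the fitting sample, R-squared, adjusted R-squared and the
#' retention gate `adj_r2 > 0.35`.
#'
#' @param x a [cohort()] object or wide data.frame.
#' @param outcome outcome key, e.g. `"C2-C3:TCA"`.
#' @param covariates character vector of covariate names.
#' @param gate adjusted R-squared retention threshold.
#' @return An object of class `"norm_model"`.
#' @export
fit_norm_model <- function(x, outcome, covariates, gate = 0.35) {
  wide <- if (inherits(x, "cohort")) cohort_wide(x) else x
  y <- resolve_var(wide, outcome)
  covs <- lapply(covariates, function(v) resolve_var(wide, v))
  names(covs) <- covariates
  keep <- !is.na(y)
  for (v in covs) keep <- keep & !is.na(v)
  y <- y[keep]
  dat <- as.data.frame(lapply(covs, `[`, keep))
  n <- length(y)
  p <- length(covariates)
  if (n < p + 3) stop("too few complete cases (", n, ")", call. = FALSE)
  dat$.y <- y
  fit <- lm(reformulate(covariates, ".y"), data = dat)
  if (fit$rank < p + 1) stop("rank-deficient design", call. = FALSE)
  sm <- summary(fit)
  coefs <- coef(fit)[covariates]
  coef_p <- sm$coefficients[covariates, 4]
  structure(list(
    outcome = outcome,
    covariates = covariates,
    coefficients = coefs,
    coefficient_p = coef_p,
    means = vapply(dat[covariates], mean, numeric(1)),
    outcome_mean = mean(y),
    intercept = unname(coef(fit)[1]),
    r2 = sm$r.squared,
    adj_r2 = sm$adj.r.squared,
    sigma = sm$sigma,
    n = n,
    gate = gate,
    passes_gate = sm$adj.r.squared > gate
  ), class = "norm_model")
}

#' @export
print.norm_model <- function(x, ...) {
  cat(sprintf("normalization model for %s (n = %d)\n", x$outcome, x$n))
  cat(sprintf("  R2 = %.3f, adj R2 = %.3f (%s gate > %.2f)\n", x$r2, x$adj_r2,
              if (x$passes_gate) "passes" else "fails", x$gate))
  for (v in x$covariates)
    cat(sprintf("  %-24s coef %12.6g  mean %12.6g\n", v,
                x$coefficients[v], x$means[v]))
  invisible(x)
}

#' Apply the residual normalization
#'
#' Maps a measured area to its value at the model's reference covariate
#' means:
#' `A_pred = A_meas + a (X_mean - X_meas) + b (Y_mean - Y_meas) + ...`
#' where `a, b, ...` are the fitted coefficients and `X_mean, ...` the
#' covariate means frozen into the model at fit time (or externally
#' supplied reference means).  Pure function: no refitting.
#'
#' @param model a `"norm_model"` (from [fit_norm_model()] or
#'   [reference_models()]).
#' @param a_meas measured area value(s), mm^2.
#' @param covariate_values named list/data.frame of the subject's
#'   covariate values; names must match the model's covariates exactly
#'   (no extras, no omissions).
#' @param reference_means optional named vector overriding the model's
#'   stored covariate means (e.g. when applying a packaged model to a
#'   new cohort with its own reference population).
#' @return normalized area value(s), mm^2.
#' @export
apply_normalization <- function(model, a_meas, covariate_values,
                                reference_means = NULL) {
  stopifnot(inherits(model, "norm_model"))
  covariate_values <- as.list(covariate_values)
  extra <- setdiff(names(covariate_values), model$covariates)
  miss <- setdiff(model$covariates, names(covariate_values))
  if (length(extra))
    stop("covariate(s) not in model: ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (length(miss))
    stop("missing covariate value(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  means <- if (is.null(reference_means)) model$means else {
    if (!all(model$covariates %in% names(reference_means)))
      stop("reference_means must name every model covariate", call. = FALSE)
    reference_means[model$covariates]
  }
  adj <- 0
  for (v in model$covariates) {
    xv <- covariate_values[[v]]
    if (anyNA(xv)) stop("missing covariate value for ", v, call. = FALSE)
    adj <- adj + model$coefficients[[v]] * (means[[v]] - xv)
  }
  a_meas + adj
}

#' Evaluate a normalization model by %RSD reduction
#'
#' Applies the model to its outcome over the model's complete-case
#' sample and compares the percent relative standard deviation of the
#' measured and the normalized values.  The relative reduction is
#' `100 * (1 - %RSD_norm / %RSD_meas)`.
#'
#' @param model a `"norm_model"`.
#' @param x a [cohort()] object or wide data.frame.
#' @return list with `rsd_meas`, `rsd_norm`, `reduction` (all percent)
#'   and `n`.
#' @export
evaluate_model <- function(model, x) {
  wide <- if (inherits(x, "cohort")) cohort_wide(x) else x
  y <- resolve_var(wide, model$outcome)
  covs <- lapply(model$covariates, function(v) resolve_var(wide, v))
  names(covs) <- model$covariates
  keep <- !is.na(y)
  for (v in covs) keep <- keep & !is.na(v)
  y <- y[keep]
  covs <- lapply(covs, `[`, keep)
  y_norm <- apply_normalization(model, y, covs)
  r_meas <- rsd(y)
  r_norm <- rsd(y_norm)
  list(rsd_meas = r_meas, rsd_norm = r_norm,
       reduction = 100 * (1 - r_norm / r_meas), n = length(y))
}

#' Transfer a covariate model to another disc level
#'
#' Refits the source model's covariate set on the target level's
#' outcome (coefficients are level-specific) and evaluates the %RSD
#' reduction there.  When `drop_nonsignificant` is `TRUE`, covariates
#' whose refitted coefficient is not significant (two-sided p >= 0.05)
#' are dropped and the model refitted once -- the mechanism by which an
#' age + head-size TCA model collapses to a head-size-only GM model.
#'
#' @param x a [cohort()] object or wide data.frame.
#' @param covariates covariate set selected at the source level.
#' @param target_level disc level to refit on.
#' @param measure `"TCA"` or `"GM"`.
#' @param drop_nonsignificant drop covariates with p >= `alpha` and
#'   refit (single pass, weakest first).
#' @param alpha significance threshold for coefficient retention.
#' @return list with the refitted `model` and its `evaluation`.
#' @export
transfer_model <- function(x, covariates, target_level,
                           measure = "TCA", drop_nonsignificant = FALSE,
                           alpha = 0.05) {
  outcome <- outcome_key(target_level, measure)
  model <- fit_norm_model(x, outcome, covariates)
  if (drop_nonsignificant) {
    repeat {
      ns <- model$coefficient_p[model$coefficient_p >= alpha]
      if (!length(ns) || length(model$covariates) <= 1) break
      drop <- names(which.max(ns))
      model <- fit_norm_model(x, outcome, setdiff(model$covariates, drop))
    }
  }
  list(model = model, evaluation = evaluate_model(model, x))
}
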