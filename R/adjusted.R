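#' Covariate-adjusted (least-square) means for a two-level factor
#'
#' Fits `outcome ~ factor + covariates` by ordinary least squares on
#' complete cases and reports each factor level's model prediction with
#' every covariate held at its grand (complete-case) mean -- the
#' classical least-square-means convention.  The group difference is
#' tested two-sided on the residual degrees of freedom, with a matching
#' 95% t confidence interval.  An equal-slopes model is used (no
#' factor-by-covariate interaction).
#'
#' @param x a [cohort()] object or wide data.frame.
#' @param outcome outcome variable name (e.g. `"C2-C3:TCA"`).
#' @param factor_var grouping variable with exactly two observed levels
#'   (e.g. `"sex"`), or a factor/character vector aligned with the
#'   subjects (e.g. from [median_split()]).
#' @param covariates character vector of adjustment covariates (may be
#'   empty, in which case the comparison reduces to the equal-variance
#'   two-sample t test of raw means).
#' @return An object of class `"adjusted_comparison"`: a list with the
#'   adjusted means, their SEs, the difference (first level minus
#'   second), its SE, `t`, two-sided `p`, `ci` (95%), `df`, `n` and the
#'   levels compared.
#' @export
ls_means <- function(x, outcome, factor_var, covariates = character()) {
  wide <- if (inherits(x, "cohort")) cohort_wide(x) else x
  y <- resolve_var(wide, outcome)
  f <- if (length(factor_var) == 1 && is.character(factor_var)) {
    v <- wide[[factor_var]]
    if (is.null(v)) stop("unknown factor variable: ", factor_var, call. = FALSE)
    v
  } else factor_var
  f <- if (is.factor(f)) f else as.factor(f)  # keep a supplied level order
  covs <- lapply(covariates, function(v) resolve_var(wide, v))
  names(covs) <- covariates

  keep <- !is.na(y) & !is.na(f)
  for (v in covs) keep <- keep & !is.na(v)
  y <- y[keep]; f <- droplevels(f[keep])
  covs <- lapply(covs, `[`, keep)
  if (nlevels(f) != 2)
    stop("factor must have exactly 2 observed levels, got ", nlevels(f),
         call. = FALSE)
  n <- length(y)
  if (n < length(covariates) + 3)
    stop("too few complete cases (", n, ")", call. = FALSE)

  dat <- data.frame(.y = y, .f = f)
  for (nm in names(covs)) dat[[nm]] <- covs[[nm]]
  fml <- if (length(covariates))
    reformulate(c(".f", names(covs)), ".y") else .y ~ .f
  fit <- lm(fml, data = dat)
  if (fit$rank < ncol(model.matrix(fit)))
    stop("rank-deficient design", call. = FALSE)

  # predictions at each factor level with covariates at their grand means
  newd <- data.frame(.f = factor(levels(f), levels = levels(f)))
  for (nm in names(covs)) newd[[nm]] <- mean(covs[[nm]])
  X <- model.matrix(delete.response(terms(fit)), newd)
  est <- drop(X %*% coef(fit))
  V <- vcov(fit)
  se <- sqrt(diag(X %*% V %*% t(X)))
  cvec <- X[1, ] - X[2, ]
  diff <- sum(cvec * coef(fit))
  se_diff <- sqrt(drop(t(cvec) %*% V %*% cvec))
  df <- fit$df.residual
  tval <- diff / se_diff
  p <- 2 * pt(-abs(tval), df)
  ci <- diff + qt(c(0.025, 0.975), df) * se_diff

  structure(list(outcome = outcome, factor = levels(f),
                 adj_mean = setNames(est, levels(f)),
                 se_mean = setNames(se, levels(f)),
                 diff = diff, se_diff = se_diff, t = tval, p = p,
                 ci = ci, df = df, covariates = covariates, n = n),
            class = "adjusted_comparison")
}

#' @export
print.adjusted_comparison <- function(x, ...) {
  cat(sprintf("%s adjusted for {%s} (n = %d)\n", x$outcome,
              paste(x$factor, collapse = " vs "),
              x$n))
  for (lv in names(x$adj_mean))
    cat(sprintf("  %-10s adj. mean %7.2f (SE %.2f)\n", lv,
                x$adj_mean[lv], x$se_mean[lv]))
  cat(sprintf("  difference %.2f (SE %.2f), t(%d) = %.2f, p = %.4f, 95%% CI [%.2f, %.2f]\n",
              x$diff, x$se_diff, x$df, x$t, x$p, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Median split of a continuous variable
#'
#' Divides subjects at the sample median; subjects exactly at the
#' median join the upper (`">="`) group.
#'
#' @param x a [cohort()] object, wide data.frame, or numeric vector.
#' @param variable variable name when `x` is a cohort (default `"age"`).
#' @return list with `cutoff` and `labels`, a factor with levels
#'   `"< cutoff"` and `">= cutoff"` (in that order).
#' @export
median_split <- function(x, variable = "age") {
  v <- if (is.numeric(x)) x else {
    wide <- if (inherits(x, "cohort")) cohort_wide(x) else x
    resolve_var(wide, variable)
  }
  if (anyNA(v)) stop("variable must be present for all subjects", call. = FALSE)
  if (length(unique(v)) < 2) stop("all values identical", call. = FALSE)
  cutoff <- median(v)
  lab <- c(sprintf("< %g", cutoff), sprintf(">= %g", cutoff))
  labels <- factor(ifelse(v >= cutoff, lab[2], lab[1]), levels = lab)
  list(cutoff = cutoff, labels = labels)
}

#' Multivariate screen of demographic covariates
#'
#' One multiple linear regression of the outcome on age, sex, height
#' and weight (by default) over complete cases, reporting per-covariate
#' coefficients and two-sided p-values, and flagging covariates at the
#' exploratory p < 0.1 threshold.  Optionally applies a Bonferroni
#' correction across the screened covariates before flagging.
#'
#' @param x a [cohort()] object or wide data.frame.
#' @param outcome outcome variable name.
#' @param covariates covariates to screen (sex enters coded F=0, M=1).
#' @param flag_threshold reporting threshold for the `flagged` column.
#' @param bonferroni multiply p-values by the number of screened
#'   covariates (capped at 1) before flagging.
#' @return data.frame with columns `covariate`, `coefficient`, `se`,
#'   `p`, `flagged`, plus attribute `n`.
#' @export
covariate_screen <- function(x, outcome,
                             covariates = c("age", "sex", "height", "weight"),
                             flag_threshold = 0.1, bonferroni = FALSE) {
  wide <- if (inherits(x, "cohort")) cohort_wide(x) else x
  y <- resolve_var(wide, outcome)
  mats <- lapply(covariates, function(v) resolve_var(wide, v))
  names(mats) <- covariates
  keep <- !is.na(y)
  for (v in mats) keep <- keep & !is.na(v)
  y <- y[keep]
  dat <- as.data.frame(lapply(mats, `[`, keep))
  n <- length(y)
  if (n < length(covariates) + 3)
    stop("too few complete cases (", n, ")", call. = FALSE)
  dat$.y <- y
  fit <- lm(reformulate(covariates, ".y"), data = dat)
  if (fit$rank < ncol(model.matrix(fit)))
    stop("rank-deficient design", call. = FALSE)
  sm <- summary(fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  p <- sm[, 4]
  if (bonferroni) p <- pmin(1, p * length(p))
  out <- data.frame(covariate = rownames(sm),
                    coefficient = sm[, 1], se = sm[, 2], p = p,
                    flagged = p < flag_threshold, row.names = NULL)
  attr(out, "n") <- n
  out
}
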