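#' Pearson product-moment correlation with two-sided p-value
#'
#' Pairwise-complete Pearson correlation; the p-value comes from the t
#' transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom, two-sided.
#'
#' @param x,y numeric vectors of equal length; pairs with a missing
#'   value in either are dropped.
#' @return A list with elements `r`, `p` and `n` (complete pairs used).
#' @export
pearson_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in input series", call. = FALSE)
  r <- cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Cell-wise Pearson correlation table
#'
#' Computes `r`, two-sided `p` and per-cell complete-pair `n` for every
#' (row variable, column variable) pair, with pairwise deletion so each
#' cell uses all subjects observed for that pair.  No multiple-testing
#' correction is applied; the table is exploratory.
#'
#' @param x a [cohort()] object (or a wide data.frame from
#'   [cohort_wide()]).
#' @param row_vars,col_vars character vectors of variable names; cord
#'   outcomes may be given as `"C2-C3:TCA"` style keys.
#' @return An object of class `"correlation_table"`: list of matrices
#'   `r`, `p`, `n` with the requested dimnames.
#' @export
correlation_table <- function(x, row_vars, col_vars = row_vars) {
  wide <- if (inherits(x, "cohort")) cohort_wide(x) else x
  get <- function(v) resolve_var(wide, v)
  rmat <- matrix(NA_real_, length(row_vars), length(col_vars),
                 dimnames = list(row_vars, col_vars))
  pmat <- rmat
  nmat <- matrix(NA_integer_, length(row_vars), length(col_vars),
                 dimnames = list(row_vars, col_vars))
  for (i in seq_along(row_vars)) {
    xi <- get(row_vars[i])
    for (j in seq_along(col_vars)) {
      res <- pearson_cor(xi, get(col_vars[j]))
      rmat[i, j] <- res$r
      pmat[i, j] <- res$p
      nmat[i, j] <- res$n
    }
  }
  structure(list(r = rmat, p = pmat, n = nmat,
                 row_vars = row_vars, col_vars = col_vars),
            class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, digits = 2, ...) {
  cat("Pearson correlation table (pairwise complete cases)\n")
  print(round(x$r, digits))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over [stats::shapiro.test()] with the usual sample-size
#' contract (3 to 5000 observations) and an explicit error on constant
#' input.
#'
#' @param values numeric vector; `NA`s are dropped.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000, got ", n, call. = FALSE)
  if (sd(values) == 0) stop("constant input", call. = FALSE)
  st <- shapiro.test(values)
  list(W = unname(st$statistic), p = st$p.value)
}

#' Percent relative standard deviation
#'
#' `%RSD = 100 * sd(values) / mean(values)` with the n-1 SD denominator;
#' the group-variability metric used throughout the normalization
#' evaluation.
#'
#' @param values numeric vector; `NA`s are dropped.
#' @return percent value.
#' @export
rsd <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("mean is zero; %RSD undefined", call. = FALSE)
  100 * sd(values) / m
}

#' Pool group moments exactly
#'
#' Combines per-group `(n, mean, sd)` summaries into the overall mean
#' and SD via the total sum-of-squares decomposition (within + between),
#' with the `N - 1` denominator.  Equivalent to computing the moments of
#' the concatenated raw data.
#'
#' @param groups list of numeric vectors `c(n, mean, sd)` (or a
#'   data.frame with columns `n`, `mean`, `sd`).
#' @return list with pooled `n`, `mean`, `sd`.
#' @examples
#' pooled_moments(list(c(14, 46.8, 13.4), c(18, 50.4, 15.1)))
#' @export
pooled_moments <- function(groups) {
  if (is.data.frame(groups))
    groups <- lapply(seq_len(nrow(groups)),
                     function(i) c(groups$n[i], groups$mean[i], groups$sd[i]))
  if (!length(groups)) stop("empty group list", call. = FALSE)
  n <- vapply(groups, `[`, numeric(1), 1)
  m <- vapply(groups, `[`, numeric(1), 2)
  s <- vapply(groups, `[`, numeric(1), 3)
  if (any(n < 2)) stop("each group needs n >= 2", call. = FALSE)
  N <- sum(n)
  grand <- sum(n * m) / N
  ss_within <- sum((n - 1) * s^2)
  ss_between <- sum(n * (m - grand)^2)
  list(n = N, mean = grand, sd = sqrt((ss_within + ss_between) / (N - 1)))
}
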