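#' Assemble a cohort object
#'
#' A cohort bundles three tables keyed by subject id: demographics
#' (`subjects`), per-level cord areas (`cord`) and head/vertebra
#' covariates (`covariates`).  Missing data are represented by absent
#' rows (a subject without a thoracic acquisition simply has no
#' `T8-T9` / `T9-T10` rows) or `NA` cells, never by zeros.
#'
#' @param subjects data.frame with columns `id`, `sex` (`"M"`/`"F"`),
#'   `age` (years) and optionally `height` (cm), `weight` (kg).
#' @param cord data.frame with columns `id`, `level` (one of `"C2-C3"`,
#'   `"C3-C4"`, `"T8-T9"`, `"T9-T10"`), `tca` and `gm` (mm^2); derived
#'   columns `wm` and `gm_fraction` are added by [derive_metrics()].
#' @param covariates data.frame with column `id` plus any of the
#'   measured metric columns (`ticv`, `ap_vertebra_diameter`,
#'   `anterior_height`, ...; volumes mm^3, lengths mm, areas mm^2).
#' @param age_range plausible age bounds; ages outside raise an error.
#' @return An object of class `"cohort"` (a list of the three
#'   data.frames) with validated referential integrity.
#' @examples
#' co <- cohort(
#'   subjects = data.frame(id = "s1", sex = "F", age = 52),
#'   cord = data.frame(id = "s1", level = "C2-C3", tca = 79.7, gm = 19.4))
#' derive_metrics(co)$cord$wm
#' @export
cohort <- function(subjects,
                   cord = empty_cord(),
                   covariates = empty_covariates(),
                   age_range = c(18, 100)) {
  subjects <- as.data.frame(subjects)
  cord <- as.data.frame(cord)
  covariates <- as.data.frame(covariates)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s table lacks column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  need(subjects, c("id", "sex", "age"), "subjects")
  if (nrow(cord)) need(cord, c("id", "level", "tca", "gm"), "cord")
  if (nrow(covariates)) need(covariates, "id", "covariates")

  subjects$id <- as.character(subjects$id)
  if (anyDuplicated(subjects$id))
    stop("duplicate subject id(s): ",
         paste(unique(subjects$id[duplicated(subjects$id)]), collapse = ", "),
         call. = FALSE)
  if (!all(subjects$sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'", call. = FALSE)
  bad_age <- which(!is.na(subjects$age) &
                   (subjects$age < age_range[1] | subjects$age > age_range[2]))
  if (length(bad_age))
    stop(sprintf("age outside plausible range [%g, %g] for subject(s): %s",
                 age_range[1], age_range[2],
                 paste(subjects$id[bad_age], collapse = ", ")), call. = FALSE)

  if (nrow(cord)) {
    cord$id <- as.character(cord$id)
    bad_lvl <- which(!(cord$level %in% CORD_LEVELS))
    if (length(bad_lvl))
      stop(sprintf("unknown disc level label in cord row(s) %s: %s",
                   paste(bad_lvl, collapse = ", "),
                   paste(unique(cord$level[bad_lvl]), collapse = ", ")),
           call. = FALSE)
    key <- paste(cord$id, cord$level)
    if (anyDuplicated(key))
      stop("duplicate (subject, level) pair(s) in cord table: ",
           paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
    orphan <- setdiff(cord$id, subjects$id)
    if (length(orphan))
      stop("cord rows reference unknown subject(s): ",
           paste(orphan, collapse = ", "), call. = FALSE)
    ok <- !is.na(cord$tca) & !is.na(cord$gm)
    if (any(ok & (cord$tca <= 0 | cord$gm <= 0)))
      stop("cord areas must be strictly positive", call. = FALSE)
    if (any(ok & cord$gm >= cord$tca))
      stop("gm area must be strictly smaller than tca", call. = FALSE)
  }
  if (nrow(covariates)) {
    covariates$id <- as.character(covariates$id)
    orphan <- setdiff(covariates$id, subjects$id)
    if (length(orphan))
      stop("covariate rows reference unknown subject(s): ",
           paste(orphan, collapse = ", "), call. = FALSE)
    if (anyDuplicated(covariates$id))
      stop("duplicate covariate row(s) for subject(s): ",
           paste(unique(covariates$id[duplicated(covariates$id)]),
                 collapse = ", "), call. = FALSE)
    num <- covariates[setdiff(names(covariates), "id")]
    if (length(num) && any(vapply(num, function(x) any(!is.na(x) & x <= 0),
                                  logical(1))))
      stop("covariate metrics must be strictly positive when present",
           call. = FALSE)
  }

  structure(list(subjects = subjects, cord = cord, covariates = covariates),
            class = "cohort")
}

empty_cord <- function() {
  data.frame(id = character(), level = character(),
             tca = numeric(), gm = numeric())
}

empty_covariates <- function() {
  data.frame(id = character())
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d subjects (%d M / %d F), %d cord records, %d covariate records\n",
              nrow(x$subjects), sum(x$subjects$sex == "M"),
              sum(x$subjects$sex == "F"), nrow(x$cord), nrow(x$covariates)))
  lv <- table(factor(x$cord$level, levels = CORD_LEVELS))
  cat("cord records per level:",
      paste(sprintf("%s=%d", names(lv), lv), collapse = ", "), "\n")
  invisible(x)
}

#' Compute derived cord and vertebra metrics
#'
#' Populates the derived columns from their measured inputs:
#' * `wm = tca - gm` and `gm_fraction = 100 * gm / tca` per cord record;
#' * `mean_vertebra_height = (anterior_height + posterior_height) / 2`;
#' * `sagittal_vertebra_area = mean_vertebra_height * ap_vertebra_diameter`;
#' * `sagittal_area_trapez = 2 * ((mean_vertebra_height +
#'   middle_vertebra_height) / 2 * ap_vertebra_diameter / 2)`, the
#'   bi-trapezoidal approximation of the sagittal C3 vertebra area.
#'
#' Raw columns are never modified and the operation is idempotent.
#' Records whose inputs are missing keep `NA` in the derived columns.
#'
#' @param x a [cohort()] object.
#' @return The cohort with derived columns filled in.
#' @export
derive_metrics <- function(x) {
  stopifnot(inherits(x, "cohort"))
  cd <- x$cord
  if (nrow(cd)) {
    ok <- !is.na(cd$tca) & !is.na(cd$gm)
    if (any(ok & (cd$tca <= 0 | cd$gm <= 0)))
      stop("cord areas must be strictly positive", call. = FALSE)
    if (any(ok & cd$gm >= cd$tca))
      stop("gm area must be strictly smaller than tca", call. = FALSE)
    cd$wm <- cd$tca - cd$gm
    cd$gm_fraction <- 100 * cd$gm / cd$tca
    x$cord <- cd
  }
  cv <- x$covariates
  if (nrow(cv)) {
    has <- function(nm) nm %in% names(cv)
    if (has("anterior_height") && has("posterior_height")) {
      mvh <- (cv$anterior_height + cv$posterior_height) / 2
      cv$mean_vertebra_height <- mvh
      if (has("ap_vertebra_diameter")) {
        cv$sagittal_vertebra_area <- mvh * cv$ap_vertebra_diameter
        if (has("middle_vertebra_height"))
          cv$sagittal_area_trapez <-
            2 * ((mvh + cv$middle_vertebra_height) / 2 *
                 cv$ap_vertebra_diameter / 2)
      }
    }
    x$covariates <- cv
  }
  x
}

#' Read / write a cohort as CSV tables
#'
#' A cohort directory holds `subjects.csv` (id, sex, age, height,
#' weight), `cord.csv` (id, level, tca_mm2, gm_mm2) and optionally
#' `covariates.csv` (id plus one column per metric).  Empty cells are
#' missing values; numbers use the `.` decimal separator.  Writing then
#' reading reproduces all values exactly (numbers are serialized with
#' 17 significant digits).
#'
#' @param path directory containing (or to receive) the CSV files.
#' @param x a [cohort()] object.
#' @param age_range passed on to [cohort()] validation.
#' @return `read_cohort()` returns a validated [cohort()];
#'   `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path, age_range = c(18, 100)) {
  fp <- function(f) file.path(path, f)
  if (!file.exists(fp("subjects.csv")))
    stop("no subjects.csv under ", path, call. = FALSE)
  # sex must be read as character ("F" would otherwise parse as FALSE)
  subjects <- read.csv(fp("subjects.csv"), stringsAsFactors = FALSE,
                       colClasses = c(id = "character", sex = "character"))
  for (col in intersect(c("age", "height", "weight"), names(subjects)))
    subjects[[col]] <- parse_numeric(subjects[[col]], "subjects.csv", col)

  cord <- empty_cord()
  if (file.exists(fp("cord.csv"))) {
    raw <- read.csv(fp("cord.csv"), stringsAsFactors = FALSE,
                    colClasses = c(id = "character"))
    miss <- setdiff(c("id", "level", "tca_mm2", "gm_mm2"), names(raw))
    if (length(miss))
      stop("cord.csv lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    bad <- which(!(raw$level %in% CORD_LEVELS))
    if (length(bad))
      stop(sprintf("cord.csv row(s) %s: unknown disc level label %s",
                   paste(bad + 1L, collapse = ", "),  # +1: header line
                   paste(unique(raw$level[bad]), collapse = ", ")),
           call. = FALSE)
    cord <- data.frame(id = raw$id, level = raw$level,
                       tca = parse_numeric(raw$tca_mm2, "cord.csv", "tca_mm2"),
                       gm = parse_numeric(raw$gm_mm2, "cord.csv", "gm_mm2"),
                       stringsAsFactors = FALSE)
    for (col in setdiff(names(raw), c("id", "level", "tca_mm2", "gm_mm2")))
      cord[[sub("_mm2$", "", col)]] <- parse_numeric(raw[[col]], "cord.csv", col)
  }

  covariates <- empty_covariates()
  if (file.exists(fp("covariates.csv"))) {
    covariates <- read.csv(fp("covariates.csv"), stringsAsFactors = FALSE,
                           colClasses = c(id = "character"))
    for (col in setdiff(names(covariates), "id"))
      covariates[[col]] <- parse_numeric(covariates[[col]],
                                         "covariates.csv", col)
  }
  cohort(subjects, cord, covariates, age_range = age_range)
}

parse_numeric <- function(x, file, col) {
  if (is.numeric(x)) return(x)
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop(sprintf("%s row(s) %s: non-numeric value in column '%s'",
                 file, paste(bad + 1L, collapse = ", "), col), call. = FALSE)
  out
}

#' @rdname read_cohort
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) {
    for (col in names(df))
      if (is.numeric(df[[col]])) {
        v <- sprintf("%.17g", df[[col]])
        v[is.na(df[[col]])] <- ""
        df[[col]] <- v
      }
    df
  }
  write.csv(fmt(x$subjects), file.path(path, "subjects.csv"),
            row.names = FALSE, quote = FALSE, na = "")
  cd <- x$cord
  names(cd)[names(cd) == "tca"] <- "tca_mm2"
  names(cd)[names(cd) == "gm"] <- "gm_mm2"
  names(cd)[names(cd) == "wm"] <- "wm_mm2"
  write.csv(fmt(cd), file.path(path, "cord.csv"),
            row.names = FALSE, quote = FALSE, na = "")
  write.csv(fmt(x$covariates), file.path(path, "covariates.csv"),
            row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Flatten a cohort to one row per subject
#'
#' Produces the wide analysis table used by the modelling functions:
#' demographics, covariate columns, and one column per (level, measure)
#' named e.g. `tca_C2.C3`, `gm_T9.T10` plus `wm_*` and `gmf_*` when
#' derived.  Subjects without a record at a level carry `NA` there.
#'
#' @param x a [cohort()] object.
#' @return A data.frame with `nrow(x$subjects)` rows.
#' @export
cohort_wide <- function(x) {
  stopifnot(inherits(x, "cohort"))
  out <- x$subjects
  if (nrow(x$covariates))
    out <- merge(out, x$covariates, by = "id", all.x = TRUE, sort = FALSE)
  cd <- x$cord
  measures <- intersect(c("tca", "gm", "wm", "gm_fraction"), names(cd))
  for (lv in CORD_LEVELS) {
    sub <- cd[cd$level == lv, , drop = FALSE]
    for (m in measures) {
      nm <- paste0(switch(m, gm_fraction = "gmf", m), "_", gsub("-", ".", lv))
      out[[nm]] <- sub[[m]][match(out$id, sub$id)]
    }
  }
  out[match(x$subjects$id, out$id), , drop = FALSE]
}

# resolve a variable name ("age", "ticv", "tca_C2.C3", or (level, measure)
# shorthand like "C2-C3:TCA") to a numeric vector over subjects
resolve_var <- function(wide, var) {
  if (grepl(":", var, fixed = TRUE)) {
    parts <- strsplit(var, ":", fixed = TRUE)[[1]]
    col <- paste0(tolower(parts[2]), "_", gsub("-", ".", parts[1]))
    if (!col %in% names(wide))
      stop("unknown outcome: ", var, call. = FALSE)
    return(wide[[col]])
  }
  if (!var %in% names(wide))
    stop("unknown variable: ", var, call. = FALSE)
  v <- wide[[var]]
  if (var == "sex") v <- as.numeric(v == "M")  # numeric coding F=0, M=1
  v
}
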