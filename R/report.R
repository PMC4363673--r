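#' Write / read a fitted normalization model as YAML
#'
#' Serializes covariates, coefficients, covariate means, sample size
#' and fit statistics with full precision, so a model fitted on one
#' cohort can be applied to another.
#'
#' @param model a `"norm_model"`.
#' @param path YAML file path.
#' @return `read_norm_model()` returns the `"norm_model"`.
#' @export
write_norm_model <- function(model, path) {
  stopifnot(inherits(model, "norm_model"))
  x <- unclass(model)
  for (nm in c("coefficients", "coefficient_p", "means"))
    x[[nm]] <- as.list(x[[nm]])
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname write_norm_model
#' @export
read_norm_model <- function(path) {
  x <- yaml::read_yaml(path)
  for (nm in c("coefficients", "coefficient_p", "means"))
    x[[nm]] <- unlist(x[[nm]])
  x$covariates <- as.character(x$covariates)
  structure(x, class = "norm_model")
}

corr_table_df <- function(ct) {
  data.frame(
    row = rep(rownames(ct$r), times = ncol(ct$r)),
    col = rep(colnames(ct$r), each = nrow(ct$r)),
    r = as.vector(ct$r), p = as.vector(ct$p), n = as.vector(ct$n))
}

#' Run the full analysis pipeline
#'
#' One seeded, reproducible run of simulate (or load), describe,
#' adjusted-means, screen, normalize and transfer, writing CSV tables,
#' model YAMLs and a JSON run manifest under `outdir`:
#'
#' * `cohort/` -- the three cohort CSVs (when simulated);
#' * `cross_level_correlations.csv`, `brain_correlations.csv`,
#'   `skeletal_correlations.csv`, `normality.csv` -- descriptive tables;
#' * `sex_comparisons.csv`, `age_comparisons.csv`,
#'   `demographic_screen.csv` -- adjusted-mean comparisons at the two
#'   reference levels and the age/sex/height/weight screen;
#' * `normalization_models.csv`, `model_*.yaml`, `transfer.csv` --
#'   fitted C2-C3 models, their serializations, and the transfer of the
#'   selected covariate sets to the other levels;
#' * `summary.csv` -- computed headline numbers next to the packaged
#'   reference values;
#' * `manifest.json` -- seed, package version, per-file MD5 hashes.
#'
#' @param config a [generator_config()]; ignored when `cohort_dir`
#'   points at an existing cohort.
#' @param seed integer seed for the simulation.
#' @param outdir output directory (created if needed).
#' @param cohort_dir optional directory of cohort CSVs to analyze
#'   instead of simulating.
#' @return the manifest, invisibly.
#' @export
run_full_analysis <- function(config = default_config(), seed = config$seed,
                              outdir, cohort_dir = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("stage '%s' failed: %s", what, conditionMessage(e)),
           call. = FALSE)
    })
  }

  co <- stage("simulate", {
    if (is.null(cohort_dir)) {
      co <- generate_cohort(config, seed = seed)
      cdir <- file.path(outdir, "cohort")
      write_cohort(co, cdir)
      written <- c(written, list.files(cdir, full.names = TRUE))
      co
    } else read_cohort(cohort_dir)
  })
  message(sprintf("cohort: %d subjects, %d cord records",
                  nrow(co$subjects), nrow(co$cord)))

  area_keys <- as.vector(t(outer(CORD_LEVELS, CORD_MEASURES, outcome_key)))
  ref_keys <- c("C2-C3:TCA", "C2-C3:GM", "T9-T10:TCA", "T9-T10:GM")
  wide <- cohort_wide(co)

  stage("describe", {
    emit(corr_table_df(correlation_table(wide, area_keys)),
         "cross_level_correlations.csv")
    brain <- intersect(c("total_cortex", "subcortical_gm", "total_gm",
                         "total_wm", "brain"), names(wide))
    if (length(brain))
      emit(corr_table_df(correlation_table(wide, ref_keys, brain)),
           "brain_correlations.csv")
    skel <- intersect(SKELETAL_METRICS, names(wide))
    emit(corr_table_df(correlation_table(wide, ref_keys, skel)),
         "skeletal_correlations.csv")
    norm <- do.call(rbind, lapply(area_keys, function(k) {
      v <- resolve_var(wide, k)
      sw <- shapiro_wilk(v)
      data.frame(outcome = k, W = sw$W, p = sw$p,
                 n = sum(!is.na(v)), rsd = rsd(v))
    }))
    emit(norm, "normality.csv")
  })

  stage("adjust", {
    cmp_df <- function(cmp) data.frame(
      outcome = cmp$outcome,
      group1 = cmp$factor[1], group2 = cmp$factor[2],
      adj_mean1 = cmp$adj_mean[1], se1 = cmp$se_mean[1],
      adj_mean2 = cmp$adj_mean[2], se2 = cmp$se_mean[2],
      diff = cmp$diff, se_diff = cmp$se_diff, p = cmp$p,
      ci_lo = cmp$ci[1], ci_hi = cmp$ci[2], n = cmp$n)
    emit(do.call(rbind, lapply(ref_keys, function(k)
      cmp_df(ls_means(wide, k, "sex", "age")))), "sex_comparisons.csv")
    ms <- median_split(wide$age)
    message(sprintf("age median split at %g years", ms$cutoff))
    emit(do.call(rbind, lapply(ref_keys, function(k)
      cmp_df(ls_means(wide, k, ms$labels, "sex")))), "age_comparisons.csv")
    emit(do.call(rbind, lapply(ref_keys, function(k) {
      sc <- covariate_screen(wide, k)
      sc$outcome <- k
      sc
    })), "demographic_screen.csv")
  })

  models <- stage("normalize", {
    skel <- intersect(SKELETAL_METRICS, names(wide))
    ct <- correlation_table(wide, paste0("C2-C3:", c("TCA", "GM")), skel)
    retained <- screen_predictors(ct)
    message("retained covariates (r > 0.45): ",
            paste(retained, collapse = ", "))
    sets <- list(
      model1 = c("ticv", "sagittal_vertebra_area"),
      model2 = c("age", "ticv", "ap_vertebra_diameter"),
      model3 = c("age", "ticv", "sagittal_vertebra_area"),
      model2a = c("ticv", "ap_vertebra_diameter"))
    rows <- list(); fitted <- list()
    for (ok in c("C2-C3:TCA", "C2-C3:GM")) for (nm in names(sets)) {
      if (ok == "C2-C3:GM" && nm %in% c("model2", "model3")) next
      if (ok == "C2-C3:TCA" && nm == "model2a") next
      m <- fit_norm_model(wide, ok, sets[[nm]])
      ev <- evaluate_model(m, wide)
      fitted[[paste(nm, ok, sep = "/")]] <- m
      mp <- file.path(outdir, sprintf("model_%s_%s.yaml", nm,
                                      gsub("[^A-Za-z0-9]", "", ok)))
      write_norm_model(m, mp)
      written <- c(written, mp)
      rows[[length(rows) + 1]] <- data.frame(
        outcome = ok, model = nm,
        covariates = paste(sets[[nm]], collapse = "+"),
        adj_r2 = m$adj_r2, passes_gate = m$passes_gate, n = m$n,
        rsd_meas = ev$rsd_meas, rsd_norm = ev$rsd_norm,
        reduction = ev$reduction)
    }
    emit(do.call(rbind, rows), "normalization_models.csv")
    list(sets = sets, fitted = fitted)
  })

  stage("transfer", {
    rows <- list()
    for (lv in c("C3-C4", "T8-T9", "T9-T10")) {
      tr <- transfer_model(wide, models$sets$model2, lv, "TCA")
      rows[[length(rows) + 1]] <- data.frame(
        level = lv, measure = "TCA", model = "model2",
        adj_r2 = tr$model$adj_r2, passes_gate = tr$model$passes_gate,
        rsd_meas = tr$evaluation$rsd_meas,
        rsd_norm = tr$evaluation$rsd_norm,
        reduction = tr$evaluation$reduction, n = tr$model$n)
      trg <- transfer_model(wide, models$sets$model2a, lv, "GM")
      rows[[length(rows) + 1]] <- data.frame(
        level = lv, measure = "GM", model = "model2a",
        adj_r2 = trg$model$adj_r2, passes_gate = trg$model$passes_gate,
        rsd_meas = trg$evaluation$rsd_meas,
        rsd_norm = trg$evaluation$rsd_norm,
        reduction = trg$evaluation$reduction, n = trg$model$n)
    }
    emit(do.call(rbind, rows), "transfer.csv")
  })

  stage("summary", {
    ref <- reference_models()
    m2 <- models$fitted[["model2/C2-C3:TCA"]]
    m2a <- models$fitted[["model2a/C2-C3:GM"]]
    m3 <- models$fitted[["model3/C2-C3:TCA"]]
    tr_red <- vapply(c("C3-C4", "T8-T9", "T9-T10"), function(lv)
      transfer_model(wide, models$sets$model2, lv,
                     "TCA")$evaluation$reduction, numeric(1))
    sm <- data.frame(
      quantity = c("mean TCA C2-C3 (mm^2)",
                   "TCA C2-C3 %RSD reduction, model2 (%)",
                   "GM C2-C3 %RSD reduction, model2a (%)",
                   "mean transfer %RSD reduction, TCA (%)",
                   "adj R2 model3 TCA C2-C3",
                   "adj R2 model2a GM C2-C3"),
      computed = c(mean(wide$tca_C2.C3, na.rm = TRUE),
                   evaluate_model(m2, wide)$reduction,
                   evaluate_model(m2a, wide)$reduction,
                   mean(tr_red), m3$adj_r2, m2a$adj_r2),
      reference = c(79.7, 27, 25, 32,
                    ref$model3_tca_c2c3$adj_r2,
                    ref$model2a_gm_c2c3$adj_r2))
    emit(sm, "summary.csv")
  })

  manifest <- list(
    seed = seed,
    package_version = as.character(packageVersion("cordnorm")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    simulated = is.null(cohort_dir),
    files = lapply(sort(unique(written)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
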