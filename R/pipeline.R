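#' Table of SHD rules and quality (one row per stratification)
#'
#' @param fit a [dose_strat()] fit.
#' @param symptom label for the row.
#' @return data.frame shaped like a per-symptom rule report: rule text,
#'   cluster sizes, precision, recall, MI.
#' @export
rule_report <- function(fit, symptom = "symptom") {
  rs <- fit$rule_set
  rule_txt <- if (is.null(rs) || !nrow(rs$rules)) ""
    else paste(sprintf("%s > %.6g", rs$rules$feature, rs$rules$threshold),
               collapse = " AND ")
  data.frame(symptom = symptom, rules = rule_txt,
             n_hd = sum(fit$hd),
             n_shd = if (is.null(fit$shd)) NA_integer_ else sum(fit$shd),
             precision = if (is.null(rs)) NA_real_ else rs$precision,
             recall = if (is.null(rs)) NA_real_ else rs$recall,
             mi_bits = if (is.null(rs)) NA_real_ else rs$mi_bits,
             stringsAsFactors = FALSE)
}

#' Assemble an analysis bundle from generator output
#'
#' Lateralizes the cohort, builds the feature and mean-dose matrices for a
#' symptom configuration, applies the eligibility filter, optionally
#' imputes baselines, and derives endpoints — the aligned inputs every
#' downstream stage consumes.
#'
#' @param gen a [generate_cohort()] result (or an equivalent list with
#'   `cohort`, `covariates`, `symptoms`).
#' @param spec a [feature_spec()]; default drymouth.
#' @param impute run [impute_baseline()] (needed only for change-from-
#'   baseline endpoints).
#' @param seed seed for the imputer.
#' @param endpoint_threshold severity cut for [derive_endpoints()].
#' @return a list with `features`, `organ_means`, `ntcp_design`,
#'   `covariate_design`, `endpoints`, `patients`, `cohort` (lateralized),
#'   `spec`.
#' @export
build_bundle <- function(gen, spec = default_feature_specs()$drymouth,
                         impute = FALSE, seed = NULL,
                         endpoint_threshold = 4) {
  cohort <- lateralize_cohort(gen$cohort)
  st <- gen$symptoms
  elig <- eligibility_filter(st, spec$symptom)
  if (impute) st <- impute_baseline(st, seed = seed)
  ep <- derive_endpoints(st, spec$symptom, threshold = endpoint_threshold,
                         patients = elig$retained)
  features <- build_feature_matrix(cohort, spec)
  pats <- intersect(rownames(features), ep$patient)
  features <- features[pats, , drop = FALSE]
  ep <- ep[match(pats, ep$patient), , drop = FALSE]
  cov_raw <- gen$covariates[match(pats, gen$covariates$patient), ,
                            drop = FALSE]
  cov <- encode_covariates(cov_raw, cohort[pats])
  cov_design <- as.matrix(cov[, covariate_names()])
  rownames(cov_design) <- pats
  organ_means <- organ_mean_doses(cohort[pats], spec$organs)
  ntcp_organs <- intersect(spec$ntcp_organs,
                           Reduce(union, lapply(cohort[pats], function(p)
                             names(p$curves))))
  ntcp_means <- organ_mean_doses(cohort[pats], ntcp_organs)
  ntcp_design <- cbind(cov_design, ntcp_means)
  list(features = features, organ_means = organ_means,
       ntcp_design = ntcp_design, covariate_design = cov_design,
       endpoints = ep, patients = pats, cohort = cohort[pats],
       spec = spec, exclusions = elig$exclusions)
}

#' Run the full stratification pipeline and write report CSVs
#'
#' simulate -> lateralize -> features -> cluster -> mine rules -> LRT
#' -> cross-validate, writing `features.csv`, `labels.csv`, `rules.csv`,
#' `lrt.csv` and `cv.csv` into `outdir`.  Byte-identical outputs are
#' produced for identical seeds.
#'
#' @param outdir output directory (created if needed).
#' @param seed master seed: drives the generator, the mixture fit and the
#'   cross-validation folds.
#' @param n_patients cohort size.
#' @param spec a [feature_spec()].
#' @param cv_folds folds for [cross_validate()].
#' @param impute impute baselines before deriving endpoints.
#' @param ... overrides passed to [cohort_config()].
#' @return invisibly, a list with the fitted objects and report paths.
#' @export
run_pipeline <- function(outdir, seed = 1L, n_patients = 300,
                         spec = default_feature_specs()$drymouth,
                         cv_folds = 5, impute = FALSE, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- cohort_config(n_patients = n_patients, seed = seed, ...)
  gen <- generate_cohort(cfg)
  bundle <- build_bundle(gen, spec, impute = impute, seed = seed + 1L)
  fit <- dose_strat(bundle$features, bundle$organ_means, seed = seed + 2L)
  y <- bundle$endpoints$late_severe
  lrt <- lrt_report(y, bundle$covariate_design, fit$labels, fit$hd_cluster,
                    fit$shd)
  cv <- cross_validate(bundle$features, y, bundle$organ_means,
                       bundle$ntcp_design, k = cv_folds, seed = seed + 3L)
  paths <- c(features = file.path(outdir, "features.csv"),
             labels = file.path(outdir, "labels.csv"),
             rules = file.path(outdir, "rules.csv"),
             lrt = file.path(outdir, "lrt.csv"),
             cv = file.path(outdir, "cv.csv"))
  write_feature_matrix(bundle$features, paths["features"])
  utils::write.csv(data.frame(patient = names(fit$labels),
                              cluster = unname(fit$labels),
                              hd = unname(fit$hd),
                              shd = if (is.null(fit$shd)) NA
                                    else unname(fit$shd)),
                   paths["labels"], row.names = FALSE)
  utils::write.csv(rule_report(fit, spec$symptom), paths["rules"],
                   row.names = FALSE)
  utils::write.csv(lrt, paths["lrt"], row.names = FALSE)
  write_cv_report(cv, paths["cv"],
                  endpoint = paste0(spec$symptom, ":late_severe"))
  invisible(list(fit = fit, lrt = lrt, cv = cv, bundle = bundle,
                 paths = paths))
}
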