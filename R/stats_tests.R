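#' Encode the clinical covariate table
#'
#' Builds the binary confounder indicators used throughout the likelihood
#' -ratio and NTCP analyses: T-stage > 2, N-stage > 1, HPV/p16 positivity,
#' base-of-tongue and tonsil subsites, age >= 65, ECOG performance score 1
#' and 2 (unknown scores are the reference level), and the parotid dose
#' limit (mean dose > 20 Gy to both parotids or > 25 Gy to one).
#'
#' @param raw data.frame with columns `patient`, `t_stage` (0-4), `n_stage`
#'   (0-3), `hpv` ("positive"/"negative"/"unknown"), `subsite`
#'   ("BOT"/"Tonsil"/"other"), `age`, `ecog` (0/1/2 or NA = unknown), plus
#'   any extra columns carried through for reporting.
#' @param cohort optional named list of [patient_dose()] objects (matching
#'   `raw$patient`) from which the parotid limit is computed; otherwise the
#'   `parotid_limit` column must already be present.
#' @return a data.frame of 0/1 indicators with `patient` and raw columns
#'   retained, class `"covariate_table"`.
#' @export
encode_covariates <- function(raw, cohort = NULL) {
  stopifnot(is.data.frame(raw), "patient" %in% names(raw))
  out <- raw
  out$t34 <- as.integer(raw$t_stage > 2)
  out$n2plus <- as.integer(raw$n_stage > 1)
  out$hpv_pos <- as.integer(raw$hpv == "positive")
  out$subsite_bot <- as.integer(raw$subsite == "BOT")
  out$subsite_tonsil <- as.integer(raw$subsite == "Tonsil")
  out$age_ge65 <- as.integer(raw$age >= 65)
  out$ecog_1 <- as.integer(!is.na(raw$ecog) & raw$ecog == 1)
  out$ecog_2 <- as.integer(!is.na(raw$ecog) & raw$ecog == 2)
  if (!is.null(cohort)) {
    flags <- vapply(raw$patient, function(p)
      dose_limit_flags(cohort[[as.character(p)]])[["parotid"]], logical(1))
    out$parotid_limit <- as.integer(flags)
  } else if (!"parotid_limit" %in% names(out)) {
    stop("supply `cohort` or a precomputed parotid_limit column",
         call. = FALSE)
  }
  class(out) <- c("covariate_table", class(out))
  out
}

#' Names of the standard clinical confounder indicators
#' @return character vector of design-matrix column names.
#' @export
covariate_names <- function() {
  c("t34", "n2plus", "hpv_pos", "subsite_bot", "subsite_tonsil",
    "age_ge65", "ecog_1", "ecog_2", "parotid_limit")
}

#' Maximum-likelihood logistic fit with separation fallback
#'
#' Logistic regression through `stats::glm` with an always-included
#' intercept.  Rank-deficient designs drop aliased columns with a warning;
#' (quasi-)separation — non-convergence or runaway coefficients — triggers
#' a ridge-penalized Newton refit (penalty 1e-6 on non-intercept terms)
#' with a warning.
#'
#' @param design numeric matrix of predictors (no intercept column), or
#'   `NULL`/0-column for an intercept-only model.
#' @param y binary outcome vector.
#' @return an object of class `"dose_logit"`: coefficients, `log_lik`,
#'   `k` (parameter count), `n`, `fitted`, `converged`, `ridged`.
#' @export
fit_logistic_mle <- function(design, y) {
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  n <- length(y)
  if (is.null(design) || NCOL(design) == 0L) {
    X <- matrix(numeric(0), n, 0)
  } else {
    X <- as.matrix(design)
    stopifnot(nrow(X) == n)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  Xi <- cbind(`(Intercept)` = 1, X)
  k_declared <- ncol(Xi)
  qrx <- qr(Xi)
  if (qrx$rank < ncol(Xi)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    dropped <- colnames(Xi)[-keep]
    warning("dropping aliased column(s): ", paste(dropped, collapse = ", "))
    Xi <- Xi[, sort(keep), drop = FALSE]
  }
  fit <- suppressWarnings(
    stats::glm.fit(Xi, y, family = stats::binomial()))
  beta <- fit$coefficients
  ridged <- FALSE
  if (!fit$converged || any(!is.finite(beta)) || any(abs(beta) > 15)) {
    warning("separation suspected; ridge-penalized refit (lambda = 1e-6)")
    beta <- ridge_logit(Xi, y, lambda = 1e-6)
    ridged <- TRUE
  }
  eta <- drop(Xi %*% beta)
  p <- stats::plogis(eta)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ll <- sum(y * log(p) + (1 - y) * log(1 - p))
  # the parameter count reflects the declared design: aliased columns are
  # dropped for estimation but still counted, so an uninformative added
  # indicator costs the full AIC/BIC penalty
  structure(list(coefficients = beta, log_lik = ll, k = k_declared, n = n,
                 fitted = p, design_names = colnames(Xi),
                 converged = fit$converged, ridged = ridged,
                 family = "binomial"),
            class = "dose_logit")
}

# Newton-Raphson logistic with a small ridge on non-intercept coefficients
ridge_logit <- function(Xi, y, lambda = 1e-6, max_iter = 100) {
  p <- ncol(Xi)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  for (i in seq_len(max_iter)) {
    mu <- stats::plogis(drop(Xi %*% beta))
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xi * w, Xi) + pen
    g <- crossprod(Xi, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-10) break
  }
  names(beta) <- colnames(Xi)
  beta
}

#' @export
print.dose_logit <- function(x, ...) {
  cat(sprintf("<dose_logit> n=%d, k=%d, logLik=%.3f%s\n", x$n, x$k,
              x$log_lik, if (x$ridged) " (ridged)" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.dose_logit <- function(object, ...) object$coefficients

#' @export
logLik.dose_logit <- function(object, ...) {
  structure(object$log_lik, df = object$k, class = "logLik")
}

#' Ordinary least-squares fit with the same report surface
#'
#' The linear-model variant (0-10 rating modelled directly); nested models
#' are compared with an F-test by [lrt_nested()].
#'
#' @inheritParams fit_logistic_mle
#' @param y numeric outcome (0-10 ratings).
#' @return an object of class `"dose_lm"`.
#' @export
fit_linear_mle <- function(design, y) {
  y <- as.numeric(y)
  n <- length(y)
  X <- if (is.null(design) || NCOL(design) == 0L) matrix(numeric(0), n, 0)
       else as.matrix(design)
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(Xi, y)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  structure(list(coefficients = fit$coefficients, log_lik = ll,
                 k = fit$rank + 1L, n = n, rss = rss, rank = fit$rank,
                 fitted = fit$fitted.values, family = "gaussian"),
            class = "dose_lm")
}

#' Likelihood-ratio test of nested models
#'
#' For logistic fits: statistic `2 (lnL_ext - lnL_base)` against a
#' chi-squared with df = added parameters; for linear fits the F-test on
#' residual sums of squares is used.  Reports the p-value, the odds ratio
#' of the added indicator (exponentiated coefficient; `NA` when more than
#' one column was added), and the AIC / BIC changes of the extension
#' (`AIC = 2k - 2 lnL`, `BIC = k ln n - 2 lnL`; negative deltas favour the
#' extended model, with a BIC drop of 6 or more conventionally read as
#' strong evidence).
#'
#' @param base,extended fits from [fit_logistic_mle()] (or
#'   [fit_linear_mle()]); `base`'s design columns must be a subset of
#'   `extended`'s and both must use the same outcomes.
#' @return an object of class `"lrt_result"`: `statistic`, `df`, `p_value`,
#'   `odds_ratio`, `delta_aic`, `delta_bic`, `strong_bic`.
#' @export
lrt_nested <- function(base, extended) {
  if (!identical(class(base), class(extended)))
    stop("base and extended fits must be of the same family", call. = FALSE)
  if (base$n != extended$n)
    stop("models fitted to different numbers of observations",
         call. = FALSE)
  bn <- names(base$coefficients)
  en <- names(extended$coefficients)
  if (!all(bn %in% en))
    stop("models are not nested (base columns not a subset)", call. = FALSE)
  df <- extended$k - base$k
  if (df < 0) stop("extended model has fewer parameters", call. = FALSE)
  if (inherits(base, "dose_lm")) {
    df2 <- extended$n - extended$rank
    fstat <- if (df == 0) 0
             else ((base$rss - extended$rss) / df) / (extended$rss / df2)
    p <- if (df == 0) 1 else stats::pf(fstat, df, df2, lower.tail = FALSE)
    stat <- fstat
  } else {
    stat <- max(0, 2 * (extended$log_lik - base$log_lik))
    p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  }
  added <- setdiff(en, bn)
  or <- if (length(added) == 1L && inherits(base, "dose_logit"))
    exp(unname(extended$coefficients[added])) else NA_real_
  aic <- function(f) 2 * f$k - 2 * f$log_lik
  bic <- function(f) f$k * log(f$n) - 2 * f$log_lik
  res <- list(statistic = stat, df = df, p_value = p, odds_ratio = or,
              delta_aic = aic(extended) - aic(base),
              delta_bic = bic(extended) - bic(base),
              added = added)
  res$strong_bic <- res$delta_bic <= -6
  class(res) <- "lrt_result"
  res
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: stat=%.3f, df=%d, p=%.4g, OR=%s, dAIC=%+.1f, dBIC=%+.1f%s\n",
              x$statistic, x$df, x$p_value,
              if (is.na(x$odds_ratio)) "N/A" else sprintf("%.3f",
                                                          x$odds_ratio),
              x$delta_aic, x$delta_bic,
              if (isTRUE(x$strong_bic)) " [strong]" else ""))
  invisible(x)
}

#' Chi-squared tests of cluster membership against covariates
#'
#' Pearson chi-squared (without continuity correction) of each covariate
#' against cluster / SHD membership; cells with expected count below 1 are
#' flagged in the output.
#'
#' @param membership cluster labels or logical SHD membership.
#' @param covariates data.frame of covariates (factors or 0/1 indicators).
#' @param columns covariate columns to test (default: the standard
#'   indicators present).
#' @return data.frame with `covariate`, `statistic`, `df`, `p_value`,
#'   `low_expected`.
#' @export
chi2_cluster_covariates <- function(membership, covariates,
                                    columns = NULL) {
  if (is.null(columns))
    columns <- intersect(covariate_names(), names(covariates))
  rows <- lapply(columns, function(cl) {
    tab <- table(membership, covariates[[cl]])
    if (nrow(tab) < 2L || ncol(tab) < 2L)
      return(data.frame(covariate = cl, statistic = NA_real_,
                        df = NA_integer_, p_value = NA_real_,
                        low_expected = NA))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(covariate = cl, statistic = unname(ct$statistic),
               df = unname(ct$parameter), p_value = ct$p.value,
               low_expected = any(ct$expected < 1))
  })
  do.call(rbind, rows)
}

#' Odds ratio and Fisher exact p for a 2x2 table
#'
#' The odds ratio is the cross-product `ad/bc`, with a 0.5 Haldane
#' correction added to every cell when any cell is zero; the two-sided
#' p-value comes from Fisher's exact test on the uncorrected counts.
#'
#' @param table 2x2 matrix of non-negative counts `rbind(c(a, b), c(c, d))`.
#' @return list with `odds_ratio`, `p_value`, `corrected` (Haldane flag),
#'   `undefined` (an entire margin is empty).
#' @export
fisher_or <- function(table) {
  tab <- as.matrix(table)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(odds_ratio = NA_real_, p_value = NA_real_,
                corrected = FALSE, undefined = TRUE))
  corrected <- any(tab == 0)
  tt <- if (corrected) tab + 0.5 else tab
  or <- (tt[1, 1] * tt[2, 2]) / (tt[1, 2] * tt[2, 1])
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = or, p_value = p, corrected = corrected,
       undefined = FALSE)
}

#' Published organ dose-limit flags for one patient
#'
#' Evaluates the standard head-and-neck planning limits on the patient's
#' DVHs: spinal cord max > 50 Gy; parotid mean > 25 Gy for one gland or
#' > 20 Gy for both; pharyngeal constrictor means (> 50 / > 60 Gy for IPC,
#' MPC, SPC); mandible max > 70 Gy; larynx V50 > 27% (percent volume at
#' 50 Gy); brachial plexus max > 60 Gy; and the esophagus composite
#' V35 > 50% OR V50 > 40% OR V70 > 20% OR V60 > 30%.  Flags whose ROIs are
#' absent are `NA` and listed in the `"missing"` attribute.
#'
#' @param pd a [patient_dose()]; parotids may be stored under lateralized
#'   or left/right names.
#' @return named logical vector of limit flags.
#' @export
dose_limit_flags <- function(pd) {
  stopifnot(inherits(pd, "patient_dose"))
  cv <- pd$curves
  get <- function(nm) if (nm %in% names(cv)) cv[[nm]] else NULL
  pair <- function(a, b) {
    out <- list(get(a), get(b))
    out[!vapply(out, is.null, logical(1))]
  }
  flags <- c()
  missing <- character()
  flag <- function(name, value) flags[[name]] <<- value
  # spinal cord
  sc <- get("spinal_cord")
  flag("spinal_cord", if (is.null(sc)) NA else max_dose(sc) > 50)
  # parotid: >25 for one OR >20 for both
  par <- pair("ipsilateral_parotid", "contralateral_parotid")
  if (!length(par)) par <- pair("left_parotid", "right_parotid")
  if (length(par) < 2L) {
    flag("parotid", NA)
  } else {
    md <- vapply(par, mean_dose, numeric(1))
    flag("parotid", any(md > 25) || all(md > 20))
  }
  for (org in c("ipc", "mpc", "spc")) {
    o <- get(org)
    flag(org, if (is.null(o)) NA else mean_dose(o) > 50)
    flag(paste0(org, "_2"), if (is.null(o)) NA else mean_dose(o) > 60)
  }
  mand <- get("mandible")
  flag("mandible", if (is.null(mand)) NA else max_dose(mand) > 70)
  lar <- get("larynx")
  flag("larynx", if (is.null(lar)) NA else volume_at_dose(lar, 50) > 27)
  bp <- get("brachial_plexus")
  flag("brachial_plexus", if (is.null(bp)) NA else max_dose(bp) > 60)
  eso <- get("esophagus")
  flag("esophagus", if (is.null(eso)) NA else
    volume_at_dose(eso, 35) > 50 || volume_at_dose(eso, 50) > 40 ||
    volume_at_dose(eso, 70) > 20 || volume_at_dose(eso, 60) > 30)
  out <- unlist(flags)
  attr(out, "missing") <- names(out)[is.na(out)]
  out
}

#' Table of LRT comparisons for one endpoint
#'
#' Fits the covariate-only baseline, then baseline + all-cluster indicators
#' ("All", two indicators against the low-dose reference), baseline + HD
#' indicator, and baseline + SHD indicator, and reports p, OR, dAIC, dBIC
#' for each extension.
#'
#' @param outcome binary endpoint vector.
#' @param covariates design matrix (patients x clinical indicators).
#' @param labels cluster labels (1..k).
#' @param hd_cluster HD component id.
#' @param shd logical SHD membership (or `NULL` to skip).
#' @return data.frame with one row per model ("All", "HD", "SHD").
#' @export
lrt_report <- function(outcome, covariates, labels, hd_cluster,
                       shd = NULL) {
  keep <- !is.na(outcome)
  y <- as.numeric(outcome[keep])
  X <- as.matrix(covariates)[keep, , drop = FALSE]
  labels <- labels[keep]
  base <- fit_logistic_mle(X, y)
  # dose-ordered cluster indicators vs the lowest-dose reference
  lev <- sort(unique(labels))
  rows <- list()
  if (length(lev) > 1L) {
    ind <- sapply(setdiff(lev, min(lev)), function(l)
      as.integer(labels == l))
    colnames(ind) <- paste0("cluster", setdiff(lev, min(lev)))
    ext <- fit_logistic_mle(cbind(X, ind), y)
    r <- lrt_nested(base, ext)
    rows[["All"]] <- data.frame(model = "All", p_value = r$p_value,
                                odds_ratio = NA_real_,
                                delta_aic = r$delta_aic,
                                delta_bic = r$delta_bic)
  }
  hd_ind <- as.integer(labels == hd_cluster)
  ext <- fit_logistic_mle(cbind(X, hd = hd_ind), y)
  r <- lrt_nested(base, ext)
  rows[["HD"]] <- data.frame(model = "HD", p_value = r$p_value,
                             odds_ratio = r$odds_ratio,
                             delta_aic = r$delta_aic,
                             delta_bic = r$delta_bic)
  if (!is.null(shd)) {
    ext <- fit_logistic_mle(cbind(X, shd = as.integer(shd[keep])), y)
    r <- lrt_nested(base, ext)
    rows[["SHD"]] <- data.frame(model = "SHD", p_value = r$p_value,
                                odds_ratio = r$odds_ratio,
                                delta_aic = r$delta_aic,
                                delta_bic = r$delta_bic)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
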