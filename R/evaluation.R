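#' Rank-based cluster risk scores
#'
#' Clusters are ranked by the count of positive outcomes among their
#' training-fold members (descending); test patients receive risk 1 for the
#' top-ranked cluster, 0.5 for the second, 0 for the third (and equally
#' spaced values for other k).  Ties in outcome counts are broken by the
#' cluster's mean dose (higher dose = riskier).
#'
#' @param train_labels,train_outcomes training-fold cluster labels and
#'   binary outcomes.
#' @param test_labels labels of the test-fold patients; every level must
#'   have been seen in training.
#' @param cluster_dose per-cluster average summed mean dose (tie-break),
#'   named or ordered by cluster id.
#' @return numeric risk scores for the test patients.
#' @export
rank_risk_scores <- function(train_labels, train_outcomes, test_labels,
                             cluster_dose) {
  lev <- sort(unique(train_labels))
  if (!all(test_labels %in% lev))
    stop("test labels contain clusters unseen in training", call. = FALSE)
  pos <- vapply(lev, function(l)
    sum(train_outcomes[train_labels == l]), numeric(1))
  dose <- cluster_dose[lev]
  ord <- order(-pos, -dose)              # rank 1 = most positives
  risk_levels <- if (length(lev) == 1L) 1
                 else seq(1, 0, length.out = length(lev))
  risk <- numeric(length(lev))
  risk[ord] <- risk_levels
  risk[match(test_labels, lev)]
}

#' Recalibrated NTCP logistic model
#'
#' The comparison model: logistic regression of the endpoint on the
#' clinical covariates plus the mean doses (Gy) to the symptom's NTCP organ
#' list, refit on each training fold.
#'
#' @param train_design,train_y training covariate+dose design and outcomes.
#' @param test_design test design matrix (same columns).
#' @return predicted probabilities for the test rows, with the fitted
#'   `"dose_logit"` model as an attribute.
#' @export
fit_ntcp <- function(train_design, train_y, test_design) {
  fit <- fit_logistic_mle(train_design, train_y)
  Xi <- cbind(1, as.matrix(test_design))
  colnames(Xi) <- c("(Intercept)", colnames(test_design))
  Xi <- Xi[, fit$design_names, drop = FALSE]
  p <- stats::plogis(drop(Xi %*% fit$coefficients))
  attr(p, "model") <- fit
  p
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with ties counted 0.5.
#'
#' @param scores numeric risk scores.
#' @param outcomes binary outcomes.
#' @return AUC in \[0, 1\]; `NA` with a warning when only one class is
#'   present.
#' @export
auc_roc <- function(scores, outcomes) {
  y <- as.logical(outcomes)
  if (!any(y) || all(y)) {
    warning("AUC undefined: only one outcome class present")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  n1 <- sum(y); n0 <- sum(!y)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as 0
#' when any margin of the confusion matrix is empty.  Multi-level risk
#' scores are binarized at risk >= 1 (i.e. membership in the highest-risk
#' cluster) before computing the coefficient.
#'
#' @param pred binary predictions, or numeric risk scores (binarized at
#'   `>= 1`).
#' @param outcomes binary outcomes.
#' @return value in \[-1, 1\].
#' @export
mcc <- function(pred, outcomes) {
  y <- as.logical(outcomes)
  p <- if (is.logical(pred)) pred else as.numeric(pred) >= 1
  tp <- as.numeric(sum(p & y)); fp <- as.numeric(sum(p & !y))
  fn <- as.numeric(sum(!p & y)); tn <- as.numeric(sum(!p & !y))
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

# stratified fold assignment: fold sizes differ by <= 1 overall and within
# each outcome class (each class is dealt round-robin starting from the
# currently least-filled folds)
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  counts <- rep(0L, k)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    ord <- order(counts, sample.int(k))      # least-filled first
    assignment <- rep_len(ord, length(idx))
    fold[idx] <- assignment
    counts <- counts + tabulate(assignment, k)
  }
  fold
}

#' Cross-validated comparison of stratifications and NTCP models
#'
#' Stratified k-fold cross-validation of up to four risk models for one
#' binary endpoint: `"All"` (3-level rank risk from the cluster
#' stratification), `"HD"` (high-dose cluster membership), `"SHD"`
#' (rule-based simplified membership) and `"NTCP"` (recalibrated logistic
#' model on covariates + organ mean doses).  Clustering and rule mining are
#' refit inside each training fold so no test information leaks; test-fold
#' scores are pooled across folds before computing AUC and MCC.  A fold
#' lacking positives triggers a re-draw with a new sub-seed (up to 10
#' attempts).
#'
#' @param features dose feature matrix (patients x features).
#' @param outcome binary endpoint, aligned with `features` rows.
#' @param organ_means patients x organs mean-dose matrix for HD
#'   identification (defaults to per-organ Vx means).
#' @param ntcp_design covariates + NTCP organ mean doses matrix; `NTCP` is
#'   skipped when `NULL`.
#' @param models subset of `c("All", "HD", "SHD", "NTCP")`.
#' @param k number of folds.
#' @param seed RNG seed (folds and mixture fits).
#' @param k_clusters mixture components per fold.
#' @param frozen_clusters fit the mixture and rules once on the full cohort
#'   instead of per fold (the leakage-prone variant, for comparison).
#' @param ... passed to [fit_bgmm()].
#' @return an object of class `"cv_result"`: pooled `auc` and `mcc` per
#'   model, per-fold values, `folds`, `seed`.
#' @export
cross_validate <- function(features, outcome, organ_means = NULL,
                           ntcp_design = NULL,
                           models = c("All", "HD", "SHD", "NTCP"),
                           k = 5, seed = NULL, k_clusters = 3,
                           frozen_clusters = FALSE, ...) {
  X <- as.matrix(features)
  y <- as.numeric(outcome)
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (!is.null(organ_means))
    organ_means <- as.matrix(organ_means)[keep, , drop = FALSE]
  else organ_means <- feature_organ_means(X)
  if (!is.null(ntcp_design))
    ntcp_design <- as.matrix(ntcp_design)[keep, , drop = FALSE]
  else models <- setdiff(models, "NTCP")
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  n <- length(y)
  with_seed(seed, {
    fold <- NULL
    for (try in 1:10) {
      f <- stratified_folds(y, k)
      ok <- all(vapply(seq_len(k), function(i)
        sum(y[f != i]) > 0 && sum(y[f != i]) < sum(f != i), logical(1)))
      if (ok) { fold <- f; break }
    }
    if (is.null(fold))
      stop("could not draw folds with positives in every training fold",
           call. = FALSE)
    full_fit <- if (frozen_clusters)
      dose_strat(X, organ_means, k = k_clusters,
                 seed = sample.int(2^31 - 1, 1), ...) else NULL
    scores <- lapply(models, function(m) rep(NA_real_, n))
    names(scores) <- models
    for (i in seq_len(k)) {
      tr <- fold != i; te <- !tr
      if (frozen_clusters) {
        fit <- full_fit
        lab_tr <- fit$labels[tr]; lab_te <- fit$labels[te]
        shd_te <- if (!is.null(fit$shd)) fit$shd[te]
      } else {
        fit <- dose_strat(X[tr, , drop = FALSE],
                          organ_means[tr, , drop = FALSE],
                          k = k_clusters, seed = sample.int(2^31 - 1, 1),
                          ...)
        lab_tr <- fit$labels
        lab_te <- assign_cluster(fit$model, X[te, , drop = FALSE])
        shd_te <- if (!is.null(fit$rule_set))
          shd_membership(fit$rule_set, X[te, , drop = FALSE])
      }
      dose_rank <- fit$cluster_mean_dose_sum
      dose_rank[is.na(dose_rank)] <- -Inf
      if ("All" %in% models)
        scores$All[te] <- rank_risk_scores(lab_tr, y[tr], lab_te, dose_rank)
      if ("HD" %in% models)
        scores$HD[te] <- as.numeric(lab_te == fit$hd_cluster)
      if ("SHD" %in% models) {
        # when a training fold admits no rules (degenerate HD split) the
        # simplified group falls back to plain HD membership
        if (is.null(shd_te)) shd_te <- lab_te == fit$hd_cluster
        scores$SHD[te] <- as.numeric(shd_te)
      }
      if ("NTCP" %in% models)
        scores$NTCP[te] <- fit_ntcp(ntcp_design[tr, , drop = FALSE], y[tr],
                                    ntcp_design[te, , drop = FALSE])
    }
    per_fold <- lapply(models, function(m)
      vapply(seq_len(k), function(i) {
        te <- fold == i
        if (length(unique(y[te])) < 2L) return(NA_real_)
        auc_roc(scores[[m]][te], y[te])
      }, numeric(1)))
    names(per_fold) <- models
    pooled_auc <- vapply(models, function(m)
      auc_roc(scores[[m]], y), numeric(1))
    # NTCP probabilities are binarized at 0.5 for MCC; rank risks at >= 1
    pooled_mcc <- vapply(models, function(m) {
      s <- scores[[m]]
      if (m == "NTCP") mcc(s >= 0.5, y) else mcc(s, y)
    }, numeric(1))
    structure(list(auc = pooled_auc, mcc = pooled_mcc,
                   per_fold_auc = per_fold, scores = scores,
                   outcome = y, folds = fold, n_folds = k, seed = seed,
                   models = models),
              class = "cv_result")
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold stratified CV, n=%d (%.1f%% positive)\n",
              x$n_folds, length(x$outcome), 100 * mean(x$outcome)))
  df <- data.frame(model = x$models, auc = round(x$auc, 3),
                   mcc = round(x$mcc, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a cross-validation report CSV (rows = metric, columns = models)
#'
#' @param cv a [cross_validate()] result.
#' @param path output path.
#' @param endpoint label written into the table.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(cv, path, endpoint = "late_severe") {
  df <- data.frame(endpoint = endpoint,
                   metric = c("AUC", "MCC"),
                   rbind(cv$auc, cv$mcc), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
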