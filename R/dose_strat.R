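#' Identify the high-dose cluster
#'
#' For every patient, sums the mean dose over the configuration organs; the
#' high-dose (HD) cluster is the component whose members have the highest
#' average of that per-patient sum (averaging makes the choice invariant to
#' cluster size).  Empty clusters are excluded from the argmax with a
#' warning.
#'
#' @param model a fitted [fit_bgmm()] object with labels.
#' @param organ_means patients x organs matrix of mean doses in Gy (rows in
#'   the order of `model$labels`), e.g. from [organ_mean_doses()]; or a
#'   cohort list plus `spec` from which it is computed.
#' @param spec optional [feature_spec()] when `organ_means` is a cohort.
#' @return integer HD component id, with attribute
#'   `"cluster_mean_dose_sum"` (per-component average summed mean dose, Gy).
#' @export
identify_hd <- function(model, organ_means, spec = NULL) {
  stopifnot(inherits(model, "bgmm"))
  if (is.list(organ_means) && !is.data.frame(organ_means)) {
    stopifnot(inherits(spec, "feature_spec"))
    organ_means <- organ_mean_doses(organ_means, spec$organs)
  }
  organ_means <- as.matrix(organ_means)
  stopifnot(nrow(organ_means) == length(model$labels))
  if (anyNA(organ_means))
    stop("mean doses not computable for all configuration organs",
         call. = FALSE)
  patient_sum <- rowSums(organ_means)
  sums <- rep(NA_real_, model$k)
  for (j in seq_len(model$k)) {
    members <- model$labels == j
    if (!any(members)) {
      warning("component ", j, " is empty; excluded from HD identification")
      next
    }
    sums[j] <- mean(patient_sum[members])
  }
  hd <- which.max(sums)
  attr(hd, "cluster_mean_dose_sum") <- sums
  hd
}

#' Check that the HD cluster has the highest severe-symptom incidence
#'
#' Report-only sanity check: computes the per-cluster incidence of a severe
#' late endpoint and reports whether the HD cluster attains the (strict)
#' maximum.
#'
#' @param labels integer cluster labels (1..k).
#' @param hd_cluster HD component id.
#' @param outcome logical endpoint vector aligned with `labels`.
#' @return a list with `hd_is_max` (logical), `tie` (logical) and
#'   `incidence` (per-cluster rates).
#' @export
verify_hd_incidence <- function(labels, hd_cluster, outcome) {
  stopifnot(length(labels) == length(outcome))
  outcome <- as.logical(outcome)
  inc <- tapply(outcome, factor(labels, levels = sort(unique(labels))),
                mean)
  mx <- max(inc, na.rm = TRUE)
  tie <- sum(abs(inc - mx) < 1e-12, na.rm = TRUE) > 1L
  list(hd_is_max = isTRUE(abs(inc[as.character(hd_cluster)] - mx) < 1e-12) &&
         !tie,
       tie = tie, incidence = inc)
}

#' Fit a dose-pattern stratification model
#'
#' The package's central fit: clusters patients on their multi-organ dose
#' features with a 3-component variational Bayesian Gaussian mixture,
#' identifies the high-dose (HD) cluster as the component with the highest
#' average summed organ mean dose, and (optionally) distills HD membership
#' into a minimal conjunction of dose-threshold rules — the simplified
#' high-dose (SHD) group — by mutual-information beam search.
#'
#' @param features a [build_feature_matrix()] result (or plain numeric
#'   matrix with column names).
#' @param organ_means patients x organs mean-dose matrix used to rank the
#'   clusters by dose (see [identify_hd()]).  Defaults to the per-organ mean
#'   of the Vx feature columns when omitted, which preserves the dose
#'   ordering on cumulative-DVH features.
#' @param k number of mixture components.
#' @param seed integer seed (mandatory for a reproducible fit).
#' @param rules mine SHD threshold rules from the HD labels.
#' @param beam_width,max_depth beam-search parameters, see
#'   [beam_search_rules()].
#' @param ... further arguments passed to [fit_bgmm()].
#' @return an object of class `"dose_strat"` with elements `model`
#'   ([fit_bgmm()] fit), `hd_cluster`, `cluster_mean_dose_sum`, `labels`,
#'   `hd` (logical HD membership), `rule_set`, `shd` (logical SHD
#'   membership) and `features_used`.
#' @seealso [predict.dose_strat()], [summary.dose_strat()]
#' @export
dose_strat <- function(features, organ_means = NULL, k = 3, seed = NULL,
                       rules = TRUE, beam_width = 25, max_depth = 2, ...) {
  X <- as.matrix(features)
  if (is.null(organ_means)) organ_means <- feature_organ_means(X)
  model <- fit_bgmm(X, k = k, seed = seed, ...)
  hd <- identify_hd(model, organ_means)
  is_hd <- model$labels == as.integer(hd)
  rs <- NULL; shd <- NULL
  if (isTRUE(rules) && any(is_hd) && !all(is_hd)) {
    rs <- beam_search_rules(X, is_hd, beam_width = beam_width,
                            max_depth = max_depth)
    shd <- shd_membership(rs, X)
  }
  structure(list(model = model, hd_cluster = as.integer(hd),
                 cluster_mean_dose_sum = attr(hd, "cluster_mean_dose_sum"),
                 labels = model$labels, hd = is_hd, rule_set = rs,
                 shd = shd, features_used = colnames(X), seed = seed),
            class = "dose_strat")
}

# per-organ average of Vx columns: a dose-ordering surrogate when organ
# mean doses are not supplied separately
feature_organ_means <- function(X) {
  org <- sub(":[^:]+$", "", colnames(X))
  sapply(unique(org), function(o)
    rowMeans(X[, org == o, drop = FALSE]))
}

#' @export
print.dose_strat <- function(x, ...) {
  cat(sprintf("<dose_strat> %d patients, %d clusters; HD = component %d (n=%d)\n",
              length(x$labels), x$model$k, x$hd_cluster, sum(x$hd)))
  cat("cluster avg summed mean dose (Gy):",
      paste(sprintf("%.1f", x$cluster_mean_dose_sum), collapse = " "), "\n")
  if (!is.null(x$rule_set)) print(x$rule_set)
  invisible(x)
}

#' @export
summary.dose_strat <- function(object, ...) {
  sizes <- tabulate(object$labels, object$model$k)
  out <- list(n = length(object$labels), k = object$model$k,
              sizes = sizes, weights = object$model$weights,
              hd_cluster = object$hd_cluster,
              cluster_mean_dose_sum = object$cluster_mean_dose_sum,
              n_hd = sum(object$hd),
              n_shd = if (is.null(object$shd)) NA_integer_
                      else sum(object$shd),
              rule_set = object$rule_set)
  class(out) <- "summary.dose_strat"
  out
}

#' @export
print.summary.dose_strat <- function(x, ...) {
  cat("Dose-pattern stratification\n")
  cat(sprintf("  patients: %d, components: %d\n", x$n, x$k))
  df <- data.frame(component = seq_len(x$k), size = x$sizes,
                   weight = round(x$weights, 3),
                   avg_sum_mean_dose_gy = round(x$cluster_mean_dose_sum, 1))
  df$role <- ifelse(df$component == x$hd_cluster, "HD", "")
  print(df, row.names = FALSE)
  if (!is.null(x$rule_set)) {
    cat(sprintf("SHD group: %d patients\n", x$n_shd))
    print(x$rule_set)
  }
  invisible(x)
}

#' @export
coef.dose_strat <- function(object, ...) object$model$means

#' Predict stratification for new patients
#'
#' @param object a [dose_strat()] fit.
#' @param newdata feature matrix with the training feature columns.
#' @param type `"cluster"` for component ids, `"hd"` for logical HD
#'   membership, `"shd"` for rule-based membership, `"risk"` for the
#'   3-level risk score used in evaluation (1 = HD, 0.5 = middle, 0 = low,
#'   ordered by cluster dose).
#' @param ... unused.
#' @export
predict.dose_strat <- function(object, newdata,
                               type = c("cluster", "hd", "shd", "risk"),
                               ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (type == "shd") {
    if (is.null(object$rule_set)) stop("no rule set fitted", call. = FALSE)
    return(shd_membership(object$rule_set, X))
  }
  lab <- assign_cluster(object$model, X)
  if (type == "cluster") return(lab)
  if (type == "hd") return(lab == object$hd_cluster)
  # dose-ordered risk: highest avg summed mean dose -> 1, next -> .5, ...
  ord <- order(-object$cluster_mean_dose_sum)
  risk_levels <- seq(1, 0, length.out = object$model$k)
  risk_map <- numeric(object$model$k)
  risk_map[ord] <- risk_levels
  risk_map[lab]
}

#' @export
plot.dose_strat <- function(x, ...) {
  means <- x$model$means
  matplot(t(means), type = "l", lty = 1, lwd = 2,
          xlab = "feature index", ylab = "component mean (Gy)",
          main = "Dose-pattern cluster profiles", xaxt = "n", ...)
  axis(1, at = seq_len(ncol(means)), labels = FALSE)
  legend("topright", bty = "n", lwd = 2, col = seq_len(nrow(means)),
         legend = paste0("component ", seq_len(nrow(means)),
                         ifelse(seq_len(nrow(means)) == x$hd_cluster,
                                " (HD)", "")))
  invisible(x)
}
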