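# interpolate the cumulative volume fraction at dose d (0 beyond the grid)
vf_at <- function(curve, d) {
  stats::approx(curve$dose_grid, curve$volume_fraction, xout = d,
                method = "linear", yleft = 1, yright = 0, ties = "ordered")$y
}

#' Dose delivered to at least x% of the organ volume
#'
#' Inverts the cumulative DVH: the largest dose d with
#' `volume_fraction(d) >= x/100`, by linear interpolation.  When less than
#' x% of the organ receives any dose at all the result is 0 Gy — this is the
#' convention that makes threshold rules such as "contralateral parotid
#' V45 > 0" meaningful.
#'
#' @param curve a [dvh_curve()].
#' @param x_percent volume percentage in (0, 100].
#' @return dose in Gy.
#' @export
dose_at_volume <- function(curve, x_percent) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (!is.finite(x_percent) || x_percent <= 0 || x_percent > 100)
    stop("x_percent must be in (0, 100]", call. = FALSE)
  v <- x_percent / 100
  vf <- curve$volume_fraction
  d <- curve$dose_grid
  if (vf[length(vf)] >= v) return(d[length(d)])  # whole support above v
  # first index where vf drops below v; invert linearly on [i-1, i]
  i <- which(vf < v)[1L]
  if (i == 1L) return(0)
  d0 <- d[i - 1L]; d1 <- d[i]
  v0 <- vf[i - 1L]; v1 <- vf[i]
  if (v0 == v1) return(d0)
  d0 + (v0 - v) / (v0 - v1) * (d1 - d0)
}

#' Percent of organ volume receiving at least d Gy
#'
#' The conventional published-limit reading of "VxGy" (e.g. the larynx edema
#' limit "V50 > 27" means more than 27% of the larynx receives >= 50 Gy).
#'
#' @param curve a [dvh_curve()].
#' @param d dose in Gy, >= 0.
#' @return volume percentage in \[0, 100\].
#' @export
volume_at_dose <- function(curve, d) {
  stopifnot(inherits(curve, "dvh_curve"), is.finite(d), d >= 0)
  100 * vf_at(curve, d)
}

#' Volume-weighted mean dose of a DVH curve
#'
#' The integral of the cumulative volume fraction over dose (trapezoidal on
#' the stored grid), which equals the mean dose over the organ volume.
#'
#' @param curve a [dvh_curve()].
#' @return mean dose in Gy.
#' @export
mean_dose <- function(curve) {
  stopifnot(inherits(curve, "dvh_curve"))
  d <- curve$dose_grid
  v <- curve$volume_fraction
  if (length(d) == 1L) return(0)
  sum(diff(d) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' Maximum dose of a DVH curve
#'
#' Largest dose with volume fraction above `eps_volume` (the end of the
#' curve's support for the default `eps_volume = 0`), linearly interpolated.
#'
#' @param curve a [dvh_curve()].
#' @param eps_volume volume-fraction floor in \[0, 1).
#' @return dose in Gy.
#' @export
max_dose <- function(curve, eps_volume = 0) {
  stopifnot(inherits(curve, "dvh_curve"), eps_volume >= 0, eps_volume < 1)
  v <- curve$volume_fraction
  d <- curve$dose_grid
  above <- which(v > eps_volume)
  if (!length(above)) return(0)
  i <- max(above)
  if (i == length(d)) return(d[i])
  # interpolate where the curve crosses eps_volume on [i, i+1]
  v0 <- v[i]; v1 <- v[i + 1L]
  if (v0 == v1) return(d[i + 1L])
  d[i] + (v0 - eps_volume) / (v0 - v1) * (d[i + 1L] - d[i])
}

#' Per-symptom clustering configuration
#'
#' Defines which lateralized organs and which dose-at-volume percentages
#' feed the feature matrix for one symptom, mirroring the shipped defaults
#' of [default_feature_specs()].
#'
#' @param symptom symptom label.
#' @param organs ordered character vector of lateralized ROI names.
#' @param vx_lo,vx_hi,vx_step volume percentages: the Vx window lower and
#'   upper bound and its step; `(vx_hi - vx_lo) / vx_step` must be integral.
#' @param include_max also add an `organ:max` (maximum dose) column per
#'   organ, used e.g. for voice where the larynx maximum dose carries the
#'   signal.
#' @param ntcp_organs organs whose mean doses enter the recalibrated NTCP
#'   comparison model.
#' @return an object of class `"feature_spec"`.
#' @export
feature_spec <- function(symptom, organs, vx_lo, vx_hi, vx_step = 5,
                         include_max = FALSE, ntcp_organs = organs) {
  stopifnot(length(organs) >= 1L, vx_step > 0, vx_lo <= vx_hi)
  if (abs((vx_hi - vx_lo) / vx_step - round((vx_hi - vx_lo) / vx_step)) >
      1e-9)
    stop("(vx_hi - vx_lo) must be a multiple of vx_step", call. = FALSE)
  structure(list(symptom = symptom, organs = organs,
                 vx = seq(vx_lo, vx_hi, by = vx_step),
                 include_max = isTRUE(include_max),
                 ntcp_organs = ntcp_organs),
            class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("<feature_spec> %s: %d organs, V%g-V%g (%d Vx values%s)\n",
              x$symptom, length(x$organs), min(x$vx), max(x$vx),
              length(x$vx), if (x$include_max) " + max" else ""))
  invisible(x)
}

#' Shipped per-symptom configurations
#'
#' The default organ sets and Vx windows for the four analyzed symptoms
#' (drymouth, swallow, mucus, voice), together with the organ lists whose
#' mean doses define each symptom's NTCP comparison model.  The drymouth
#' configuration encodes each patient as 5 organs x 8 Vx values = 40
#' features.
#'
#' @return named list of [feature_spec()] objects.
#' @export
default_feature_specs <- function() {
  list(
    drymouth = feature_spec(
      "drymouth",
      organs = c("ipsilateral_parotid", "contralateral_parotid",
                 "ipsilateral_submandibular", "contralateral_submandibular",
                 "hard_palate"),
      vx_lo = 25, vx_hi = 60,
      ntcp_organs = c("ipsilateral_parotid", "contralateral_parotid",
                      "ipsilateral_submandibular",
                      "contralateral_submandibular", "soft_palate",
                      "upper_lip", "lower_lip", "oral_cavity",
                      "mylogeniohyoid")),
    swallow = feature_spec(
      "swallow",
      organs = c("ipc", "mpc", "supraglottic_larynx", "esophagus",
                 "mylogeniohyoid"),
      vx_lo = 30, vx_hi = 65,
      ntcp_organs = c("ipc", "spc", "supraglottic_larynx",
                      "ipsilateral_parotid", "contralateral_parotid",
                      "cricopharyngeal")),
    mucus = feature_spec(
      "mucus",
      organs = c("ipsilateral_parotid", "contralateral_parotid",
                 "ipsilateral_submandibular", "contralateral_submandibular"),
      vx_lo = 25, vx_hi = 65,
      ntcp_organs = c("soft_palate", "hard_palate", "oral_cavity",
                      "mandible", "tongue", "ipsilateral_parotid",
                      "contralateral_parotid")),
    voice = feature_spec(
      "voice",
      organs = c("tongue", "ipc", "larynx", "supraglottic_larynx",
                 "contralateral_submandibular"),
      vx_lo = 45, vx_hi = 65, include_max = TRUE,
      ntcp_organs = c("larynx", "supraglottic_larynx", "tongue",
                      "genioglossus", "mylogeniohyoid")))
}

#' Build the patients x dose-features matrix
#'
#' Columns are ordered organ-major, then ascending Vx (`organ:Vxx`), with an
#' `organ:max` column per organ appended when the spec asks for it.  Row
#' values for a fixed organ are non-increasing in x by construction of the
#' cumulative DVH.  Patients missing a required organ are dropped with a
#' logged reason (or rejected under `strict`).
#'
#' @param cohort named list of lateralized [patient_dose()] objects.
#' @param spec a [feature_spec()].
#' @param strict error (instead of exclude) on patients missing an organ.
#' @return a numeric matrix (class `"dose_feature_matrix"`) with patient ids
#'   as rownames and an `"exclusions"` attribute naming dropped patients.
#' @export
build_feature_matrix <- function(cohort, spec, strict = FALSE) {
  stopifnot(inherits(spec, "feature_spec"))
  cols <- feature_names(spec)
  excl <- character()
  rows <- list()
  for (pd in cohort) {
    if (!all(spec$organs %in% names(pd$curves))) {
      msg <- paste0(pd$patient_id, ": missing ",
                    paste(setdiff(spec$organs, names(pd$curves)),
                          collapse = ", "))
      if (strict) stop(msg, call. = FALSE)
      excl <- c(excl, msg)
      next
    }
    v <- numeric(0)
    for (org in spec$organs) {
      cv <- pd$curves[[org]]
      vals <- vapply(spec$vx, function(x) dose_at_volume(cv, x), numeric(1))
      if (spec$include_max) vals <- c(vals, max_dose(cv))
      v <- c(v, vals)
    }
    rows[[pd$patient_id]] <- v
  }
  if (!length(rows))
    stop("no patients retained for spec '", spec$symptom, "'", call. = FALSE)
  m <- do.call(rbind, rows)
  colnames(m) <- cols
  class(m) <- c("dose_feature_matrix", class(m))
  attr(m, "spec") <- spec
  attr(m, "exclusions") <- excl
  m
}

feature_names <- function(spec) {
  unlist(lapply(spec$organs, function(org) {
    n <- paste0(org, ":V", spec$vx)
    if (spec$include_max) n <- c(n, paste0(org, ":max"))
    n
  }))
}

#' Per-patient organ mean doses
#'
#' @param cohort named list of [patient_dose()] objects.
#' @param organs ROI names; patients missing one get `NA` for it.
#' @return patients x organs matrix of mean doses in Gy.
#' @export
organ_mean_doses <- function(cohort, organs) {
  m <- t(vapply(cohort, function(pd)
    vapply(organs, function(o)
      if (o %in% names(pd$curves)) mean_dose(pd$curves[[o]]) else NA_real_,
      numeric(1)),
    numeric(length(organs))))
  rownames(m) <- vapply(cohort, `[[`, character(1), "patient_id")
  colnames(m) <- organs
  m
}

#' Select the Vx window most informative about late symptoms
#'
#' Scores every contiguous Vx window on the supplied wide grid by the mean
#' (per feature column) empirical mutual information between the
#' median-dichotomized dose feature and each late severe endpoint, summed
#' over endpoints, and returns the best-scoring window.  Ties prefer wider
#' windows, then lower starting percentages.  Exposed for reproducibility;
#' the shipped defaults are [default_feature_specs()].
#'
#' @param features a wide-grid [build_feature_matrix()] result.
#' @param endpoints logical matrix or data.frame, patients x endpoints, with
#'   rownames matching the feature matrix.
#' @return a list with `vx_lo`, `vx_hi`, `score` (bits per feature) and the
#'   full `window_scores` table.
#' @export
screen_vx_range <- function(features, endpoints) {
  spec <- attr(features, "spec")
  stopifnot(!is.null(spec))
  ep <- as.matrix(endpoints)
  ep <- ep[rownames(features), , drop = FALSE]
  storage.mode(ep) <- "logical"
  vx <- spec$vx
  # per-column MI summed over endpoints, median split of the dose feature
  is_vx <- grepl(":V[0-9]+$", colnames(features))
  col_vx <- as.integer(sub("^.*:V", "", colnames(features)[is_vx]))
  col_mi <- vapply(which(is_vx), function(j) {
    x <- features[, j]
    split <- x > stats::median(x)
    if (!any(split) || all(split)) return(0)
    sum(vapply(seq_len(ncol(ep)), function(e)
      mutual_information(split, ep[, e]), numeric(1)))
  }, numeric(1))
  wins <- expand.grid(lo = vx, hi = vx)
  wins <- wins[wins$lo <= wins$hi, , drop = FALSE]
  wins$score <- vapply(seq_len(nrow(wins)), function(i) {
    keep <- col_vx >= wins$lo[i] & col_vx <= wins$hi[i]
    mean(col_mi[keep])
  }, numeric(1))
  ord <- order(-wins$score, -(wins$hi - wins$lo), wins$lo)
  best <- wins[ord[1L], ]
  list(vx_lo = best$lo, vx_hi = best$hi, score = best$score,
       window_scores = wins[order(wins$lo, wins$hi), ])
}

#' Write a feature matrix as CSV (patients x features)
#'
#' @param features a [build_feature_matrix()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  df <- data.frame(patient = rownames(features),
                   as.data.frame(unclass(features)[, , drop = FALSE],
                                 check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
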