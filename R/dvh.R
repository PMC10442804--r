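#' Cumulative dose-volume histogram for one organ
#'
#' A cumulative DVH gives, for each dose level d, the fraction of the organ's
#' volume receiving at least d Gy.  Curves are stored on an arbitrary
#' strictly-increasing dose grid starting at 0 Gy with volume fractions in
#' \[0, 1\]; values between grid points are linearly interpolated and the
#' curve is 0 beyond the last grid point.
#'
#' @param roi_name organ (region of interest) name.
#' @param dose_grid ascending dose grid in Gy; a leading (0, 1) point is
#'   prepended when absent so the whole organ is counted at dose 0.
#' @param volume_fraction cumulative volume fractions, same length as
#'   `dose_grid`, non-increasing.
#' @param repair if `TRUE`, small increases in `volume_fraction` are clipped
#'   to restore monotonicity (isotonic from the left); otherwise they are an
#'   error.
#' @return an object of class `"dvh_curve"`.
#' @export
dvh_curve <- function(roi_name, dose_grid, volume_fraction, repair = FALSE) {
  stopifnot(is.character(roi_name), length(roi_name) == 1L)
  dose_grid <- as.numeric(dose_grid)
  volume_fraction <- as.numeric(volume_fraction)
  if (length(dose_grid) == 0L)
    stop("empty DVH curve for ROI '", roi_name, "'", call. = FALSE)
  if (length(dose_grid) != length(volume_fraction))
    stop("dose_grid and volume_fraction lengths differ for ROI '", roi_name,
         "'", call. = FALSE)
  if (!all(is.finite(dose_grid)) || !all(is.finite(volume_fraction)))
    stop("non-finite values in DVH for ROI '", roi_name, "'", call. = FALSE)
  ord <- order(dose_grid)
  dose_grid <- dose_grid[ord]
  volume_fraction <- volume_fraction[ord]
  if (any(diff(dose_grid) <= 0))
    stop("dose_grid must be strictly increasing for ROI '", roi_name, "'",
         call. = FALSE)
  if (min(dose_grid) < 0)
    stop("negative doses in DVH for ROI '", roi_name, "'", call. = FALSE)
  if (any(volume_fraction < -1e-9) || any(volume_fraction > 1 + 1e-9))
    stop("volume fractions outside [0, 1] for ROI '", roi_name, "'",
         call. = FALSE)
  volume_fraction <- pmin(pmax(volume_fraction, 0), 1)
  if (any(diff(volume_fraction) > 1e-9)) {
    if (!repair)
      stop("non-monotone cumulative volume for ROI '", roi_name, "'",
           call. = FALSE)
    volume_fraction <- rev(cummax(rev(volume_fraction)))
  }
  # clip any residual wiggle below tolerance
  volume_fraction <- rev(cummax(rev(volume_fraction)))
  if (dose_grid[1L] > 0) {
    dose_grid <- c(0, dose_grid)
    volume_fraction <- c(1, volume_fraction)
  }
  volume_fraction[1L] <- 1
  structure(list(roi_name = roi_name, dose_grid = dose_grid,
                 volume_fraction = volume_fraction),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %s: %d points, mean %.1f Gy, max %.1f Gy\n",
              x$roi_name, length(x$dose_grid), mean_dose(x), max_dose(x)))
  invisible(x)
}

#' Per-patient DVH collection
#'
#' @param patient_id patient identifier.
#' @param curves named list of [dvh_curve()] objects, names = ROI names.
#' @return an object of class `"patient_dose"`.
#' @export
patient_dose <- function(patient_id, curves) {
  stopifnot(length(patient_id) == 1L)
  stopifnot(is.list(curves), length(names(curves)) == length(curves))
  for (cv in curves) stopifnot(inherits(cv, "dvh_curve"))
  structure(list(patient_id = as.character(patient_id), curves = curves),
            class = "patient_dose")
}

#' @export
print.patient_dose <- function(x, ...) {
  cat(sprintf("<patient_dose> %s: %d ROIs (%s)\n", x$patient_id,
              length(x$curves),
              paste(utils::head(names(x$curves), 6), collapse = ", ")))
  invisible(x)
}

#' Read a long-format DVH table
#'
#' Expects columns `patient`, `roi`, `dose_gy`, `volume_fraction` (volume may
#' be in percent; it is rescaled to fractions when its maximum exceeds 1.5).
#' ROI names are normalized through an alias map, lower-cased with spaces
#' and punctuation collapsed to underscores.
#'
#' @param path CSV file path.
#' @param roi_aliases named character vector mapping raw (normalized) names
#'   to canonical ROI names, e.g. `c(lt_parotid = "left_parotid")`.
#' @param repair pass non-monotone curves through isotonic clipping instead
#'   of rejecting them.
#' @return a named list of [patient_dose()] objects.
#' @export
read_dvh_table <- function(path, roi_aliases = NULL, repair = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient", "roi", "dose_gy", "volume_fraction")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("DVH table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (max(df$volume_fraction, na.rm = TRUE) > 1.5)
    df$volume_fraction <- df$volume_fraction / 100
  df$roi <- normalize_roi(df$roi, roi_aliases)
  out <- list()
  for (pid in unique(df$patient)) {
    sub <- df[df$patient == pid, , drop = FALSE]
    curves <- list()
    for (r in unique(sub$roi)) {
      rs <- sub[sub$roi == r, , drop = FALSE]
      ord <- order(rs$dose_gy)
      curves[[r]] <- tryCatch(
        dvh_curve(r, rs$dose_gy[ord], rs$volume_fraction[ord],
                  repair = repair),
        error = function(e) stop("patient '", pid, "', ROI '", r, "': ",
                                 conditionMessage(e), call. = FALSE))
    }
    out[[as.character(pid)]] <- patient_dose(pid, curves)
  }
  out
}

#' Write a cohort of DVH curves as a long-format CSV
#'
#' Inverse of [read_dvh_table()]; a read of the written file reproduces all
#' doses and volume fractions.
#'
#' @param cohort named list of [patient_dose()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dvh_table <- function(cohort, path) {
  rows <- lapply(cohort, function(pd) {
    do.call(rbind, lapply(names(pd$curves), function(nm) {
      cv <- pd$curves[[nm]]
      data.frame(patient = pd$patient_id, roi = nm,
                 dose_gy = cv$dose_grid,
                 volume_fraction = cv$volume_fraction,
                 stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# lower-case, collapse runs of non-alphanumerics to "_", apply alias map
normalize_roi <- function(x, roi_aliases = NULL) {
  norm <- gsub("^_+|_+$", "", gsub("[^a-z0-9]+", "_", tolower(x)))
  if (!is.null(roi_aliases)) {
    names(roi_aliases) <- gsub("^_+|_+$", "",
                               gsub("[^a-z0-9]+", "_",
                                    tolower(names(roi_aliases))))
    hit <- norm %in% names(roi_aliases)
    norm[hit] <- unname(roi_aliases[norm[hit]])
  }
  norm
}

#' Default paired-organ table
#'
#' Left/right organ families that are re-encoded as ipsilateral /
#' contralateral after the primary (higher-dose) side is chosen.
#'
#' @return a data.frame with columns `family`, `left`, `right`.
#' @export
default_paired_organs <- function() {
  data.frame(
    family = c("parotid", "submandibular"),
    left = c("left_parotid", "left_submandibular"),
    right = c("right_parotid", "right_submandibular"),
    stringsAsFactors = FALSE)
}

#' Assign ipsilateral / contralateral labels to paired organs
#'
#' The head is bilateral: the side with the higher total mean dose, summed
#' over all paired organ families, is the patient's primary ("ipsilateral")
#' side; every paired organ on that side is renamed
#' `ipsilateral_<family>` and its partner `contralateral_<family>`.  One
#' global primary side is used per patient; exact ties go to the left side.
#' Unpaired midline organs keep their names.  The operation is idempotent.
#'
#' @param pd a [patient_dose()] object.
#' @param pairs a data.frame as from [default_paired_organs()].
#' @param allow_missing with one pair member absent, the present side alone
#'   determines labelling for that family; otherwise an error.
#' @return a relabelled [patient_dose()].
#' @export
lateralize <- function(pd, pairs = default_paired_organs(),
                       allow_missing = FALSE) {
  stopifnot(inherits(pd, "patient_dose"))
  have <- names(pd$curves)
  already <- grepl("^(ipsilateral|contralateral)_", have)
  if (any(already) && !any(pairs$left %in% have | pairs$right %in% have))
    return(pd)  # idempotent: nothing left to relabel
  known <- c(pairs$left, pairs$right)
  left_sum <- 0
  right_sum <- 0
  for (i in seq_len(nrow(pairs))) {
    l <- pairs$left[i]; r <- pairs$right[i]
    if (!(l %in% have) || !(r %in% have)) {
      if (!allow_missing)
        stop("patient '", pd$patient_id, "': paired organ missing (",
             l, " / ", r, ")", call. = FALSE)
      if (l %in% have) left_sum <- left_sum + mean_dose(pd$curves[[l]])
      if (r %in% have) right_sum <- right_sum + mean_dose(pd$curves[[r]])
      next
    }
    left_sum <- left_sum + mean_dose(pd$curves[[l]])
    right_sum <- right_sum + mean_dose(pd$curves[[r]])
  }
  primary_left <- left_sum >= right_sum   # tie -> left
  curves <- pd$curves
  for (i in seq_len(nrow(pairs))) {
    l <- pairs$left[i]; r <- pairs$right[i]; fam <- pairs$family[i]
    ipsi <- if (primary_left) l else r
    contra <- if (primary_left) r else l
    if (ipsi %in% have) {
      cv <- curves[[ipsi]]
      cv$roi_name <- paste0("ipsilateral_", fam)
      curves[[cv$roi_name]] <- cv
    }
    if (contra %in% have) {
      cv <- curves[[contra]]
      cv$roi_name <- paste0("contralateral_", fam)
      curves[[cv$roi_name]] <- cv
    }
    curves[c(l, r)] <- NULL
  }
  patient_dose(pd$patient_id, curves)
}

#' Lateralize every patient in a cohort
#'
#' @param cohort named list of [patient_dose()] objects.
#' @inheritParams lateralize
#' @return the relabelled cohort.
#' @export
lateralize_cohort <- function(cohort, pairs = default_paired_organs(),
                              allow_missing = FALSE) {
  lapply(cohort, lateralize, pairs = pairs, allow_missing = allow_missing)
}
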