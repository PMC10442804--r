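#' Timepoint labels of the longitudinal symptom table
#'
#' Baseline, seven weekly during-treatment ratings, a 6-week and a 6-month
#' follow-up: 10 slots in total.  During-treatment values are used only as
#' imputer inputs, never as endpoints.
#'
#' @return character vector of length 10.
#' @export
symptom_timepoints <- function() {
  c("baseline", paste0("week", 1:7), "followup_6wk", "followup_6mo")
}

#' Longitudinal patient-reported symptom ratings
#'
#' A patients x timepoints x symptoms array of integer severity ratings on
#' the 0-10 scale (0 = none, 10 = worst imaginable), `NA` for missing.
#'
#' @param ratings 3-d array with dimnames (patient, timepoint, symptom);
#'   timepoints must match [symptom_timepoints()].
#' @return an object of class `"symptom_table"`.
#' @export
symptom_table <- function(ratings) {
  stopifnot(is.array(ratings), length(dim(ratings)) == 3L)
  dn <- dimnames(ratings)
  stopifnot(!is.null(dn), identical(dn[[2L]], symptom_timepoints()))
  ok <- is.na(ratings) | (ratings >= 0 & ratings <= 10 &
                            abs(ratings - round(ratings)) < 1e-9)
  if (!all(ok))
    stop("ratings must be integers in 0..10 or NA", call. = FALSE)
  storage.mode(ratings) <- "integer"
  structure(list(ratings = ratings), class = "symptom_table")
}

#' @export
print.symptom_table <- function(x, ...) {
  d <- dim(x$ratings)
  cat(sprintf("<symptom_table> %d patients x %d timepoints x %d symptoms, %.1f%% missing\n",
              d[1], d[2], d[3], 100 * mean(is.na(x$ratings))))
  invisible(x)
}

#' Read a long-format symptom CSV
#'
#' Columns `patient`, `timepoint`, `symptom`, `rating`.
#'
#' @param path CSV path.
#' @param symptoms symptom universe (defaults to those present).
#' @return a [symptom_table()].
#' @export
read_symptom_table <- function(path, symptoms = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient", "timepoint", "symptom", "rating")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("symptom table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  pats <- unique(as.character(df$patient))
  if (is.null(symptoms)) symptoms <- sort(unique(df$symptom))
  arr <- array(NA_integer_,
               dim = c(length(pats), length(symptom_timepoints()),
                       length(symptoms)),
               dimnames = list(pats, symptom_timepoints(), symptoms))
  arr[cbind(match(as.character(df$patient), pats),
            match(df$timepoint, symptom_timepoints()),
            match(df$symptom, symptoms))] <- as.integer(df$rating)
  symptom_table(arr)
}

#' Write a symptom table as long-format CSV (non-missing cells only)
#'
#' @param st a [symptom_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_symptom_table <- function(st, path) {
  stopifnot(inherits(st, "symptom_table"))
  idx <- which(!is.na(st$ratings), arr.ind = TRUE)
  dn <- dimnames(st$ratings)
  df <- data.frame(patient = dn[[1L]][idx[, 1L]],
                   timepoint = dn[[2L]][idx[, 2L]],
                   symptom = dn[[3L]][idx[, 3L]],
                   rating = st$ratings[idx], stringsAsFactors = FALSE)
  df <- df[order(df$patient, match(df$timepoint, symptom_timepoints()),
                 df$symptom), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Apply the cohort eligibility filters
#'
#' Retains patients whose overall item completeness across the whole
#' observation window (all symptoms, all timepoints) is at least
#' `min_completeness`, and who have a non-missing 6-month rating for the
#' analyzed symptom.  Exclusions are logged with reasons.
#'
#' @param st a [symptom_table()].
#' @param symptom analyzed symptom name.
#' @param min_completeness minimum fraction of available items (default
#'   0.7).
#' @return a list with `retained` (patient ids) and `exclusions`
#'   (data.frame patient/reason).
#' @export
eligibility_filter <- function(st, symptom, min_completeness = 0.7) {
  stopifnot(inherits(st, "symptom_table"))
  r <- st$ratings
  stopifnot(symptom %in% dimnames(r)[[3L]])
  pats <- dimnames(r)[[1L]]
  completeness <- apply(!is.na(r), 1L, mean)
  has_6mo <- !is.na(r[, "followup_6mo", symptom])
  reason <- rep(NA_character_, length(pats))
  reason[completeness < min_completeness] <- "completeness"
  reason[is.na(reason) & !has_6mo] <- "no 6-month rating"
  keep <- is.na(reason)
  list(retained = pats[keep],
       exclusions = data.frame(patient = pats[!keep],
                               reason = reason[!keep],
                               stringsAsFactors = FALSE))
}

#' Derive binary symptom endpoints
#'
#' `late_severe` is a 6-month rating strictly above `threshold` (default 4,
#' the "severe" tier; 0 and 2 give the "any" and "moderate" tiers);
#' `change_severe` is a 6-month minus baseline change strictly above the
#' threshold and is `NA` when the baseline is missing (such patients are
#' excluded from change analyses).
#'
#' @param st a [symptom_table()], typically after [eligibility_filter()]
#'   and [impute_baseline()].
#' @param symptom symptom name.
#' @param threshold severity cut (strict inequality).
#' @param patients optional patient subset (e.g. the retained ids).
#' @return a data.frame with columns `patient`, `late_severe`,
#'   `change_severe`, `baseline_imputed`.
#' @export
derive_endpoints <- function(st, symptom, threshold = 4, patients = NULL) {
  stopifnot(inherits(st, "symptom_table"))
  r <- st$ratings
  stopifnot(symptom %in% dimnames(r)[[3L]])
  if (is.null(patients)) patients <- dimnames(r)[[1L]]
  late <- r[patients, "followup_6mo", symptom]
  base <- r[patients, "baseline", symptom]
  imputed <- attr(st, "imputed_baseline")
  imp_flag <- if (is.null(imputed)) rep(FALSE, length(patients))
              else patients %in% imputed[imputed[, "symptom"] == symptom,
                                         "patient"]
  data.frame(patient = patients,
             late_severe = late > threshold,
             change_severe = ifelse(is.na(base), NA, late - base > threshold),
             baseline_imputed = imp_flag,
             stringsAsFactors = FALSE, row.names = NULL)
}
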