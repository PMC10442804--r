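#' Configuration for the synthetic cohort generator
#'
#' The generator emulates an oropharyngeal radiotherapy cohort with three
#' latent dose groups (low / mid / high), spatially correlated organ doses,
#' asymmetric paired organs, clinical covariates enriched in the high-dose
#' group (advanced T/N stage, base-of-tongue subsite, more modulated
#' treatment, less prior surgery), and 0-10 symptom ratings whose severe
#' 6-month endpoint follows a logistic model on dose features and
#' covariates.
#'
#' @param n_patients cohort size.
#' @param group_weights probabilities of the low/mid/high dose groups.
#' @param group_mean_dose per-group target organ mean dose (Gy).
#' @param organ_sd between-patient sd of organ mean doses (Gy).
#' @param correlation shared-latent loading in \[0, 1\]: the fraction of
#'   organ-dose variance common to all of a patient's organs.
#' @param pair_asymmetry_gy range of the left/right mean-dose offset for
#'   paired organs.
#' @param steepness_range logistic DVH falloff steepness range (1/Gy).
#' @param outcome_intercept,outcome_dose_coef logistic endpoint model:
#'   intercept and per-Gy coefficient on the patient's average organ mean
#'   dose centred at 45 Gy.
#' @param outcome_covariate_coef named coefficients on covariate indicator
#'   columns (e.g. `c(t34 = 0.4)`).
#' @param t4_prob,n3_prob,bot_prob per-group probabilities of T4 stage,
#'   N2c/N3 stage and base-of-tongue subsite.
#' @param baseline_missing fraction of patients with a missing baseline
#'   questionnaire.
#' @param n_symptoms number of rated symptoms (first four are drymouth,
#'   swallow, mucus, voice).
#' @param seed RNG seed; the whole cohort is deterministic given it.
#' @return a list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_patients = 300,
                          group_weights = c(0.40, 0.35, 0.25),
                          group_mean_dose = c(20, 45, 70),
                          organ_sd = 3,
                          correlation = 0.5,
                          pair_asymmetry_gy = c(2, 8),
                          steepness_range = c(0.15, 0.35),
                          outcome_intercept = -0.85,
                          outcome_dose_coef = 0.06,
                          outcome_covariate_coef = c(t34 = 0.4,
                                                     age_ge65 = 0.3),
                          t4_prob = c(0.05, 0.08, 0.20),
                          n3_prob = c(0.10, 0.13, 0.22),
                          bot_prob = c(0.35, 0.45, 0.65),
                          baseline_missing = 0.17,
                          n_symptoms = 28,
                          seed = 1L) {
  stopifnot(n_patients >= 0, length(group_weights) == 3L,
            abs(sum(group_weights) - 1) < 1e-9,
            correlation >= 0, correlation <= 1,
            all(group_mean_dose >= 0), organ_sd >= 0,
            baseline_missing >= 0, baseline_missing <= 1)
  for (p in list(t4_prob, n3_prob, bot_prob))
    if (any(p < 0 | p > 1))
      stop("enrichment probabilities must lie in [0, 1]", call. = FALSE)
  structure(as.list(environment()), class = "cohort_config")
}

#' ROIs produced by the synthetic generator
#' @return character vector of organ names (left/right pairs unresolved).
#' @export
synthetic_organs <- function() {
  c("left_parotid", "right_parotid", "left_submandibular",
    "right_submandibular", "hard_palate", "soft_palate", "oral_cavity",
    "tongue", "larynx", "supraglottic_larynx", "ipc", "mpc", "spc",
    "esophagus", "mylogeniohyoid", "mandible", "spinal_cord",
    "upper_lip", "lower_lip", "cricopharyngeal", "genioglossus")
}

#' Generate one synthetic cumulative DVH curve
#'
#' Logistic-tail curve `v(d) = 1 / (1 + exp(s (d - d50)))` on a 1-Gy grid,
#' with `d50` solved by bisection so the trapezoidal mean dose matches
#' `mean_target` to within 0.5 Gy.  A zero target yields the all-zero-dose
#' curve.
#'
#' @param mean_target target mean dose (Gy), `< 0.95 * grid_max`.
#' @param steepness falloff steepness s (1/Gy).
#' @param roi_name ROI label for the curve.
#' @param grid_max top of the dose grid (Gy).
#' @return a [dvh_curve()].
#' @export
generate_dvh <- function(mean_target, steepness = 0.25,
                         roi_name = "organ", grid_max = 90) {
  stopifnot(mean_target >= 0, steepness > 0)
  if (mean_target > 0.95 * grid_max)
    stop("mean_target infeasible on the dose grid", call. = FALSE)
  grid <- seq(0, grid_max, by = 1)
  if (mean_target == 0)
    return(dvh_curve(roi_name, c(0, 1e-6), c(1, 0)))
  d50 <- solve_d50(mean_target, steepness, grid)
  v <- 1 / (1 + exp(steepness * (grid - d50)))
  v[1] <- 1
  dvh_curve(roi_name, grid, v, repair = TRUE)
}

# vectorized bisection for the logistic-tail midpoint: finds d50 per
# (target, steepness) pair so the trapezoidal mean on the unit grid equals
# the target
solve_d50 <- function(target, steepness, grid) {
  m <- length(target)
  ng <- length(grid)
  lo <- rep(-max(grid), m); hi <- rep(max(grid), m)
  sg <- outer(steepness, grid)                  # s_i * g_j
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    # element (i, j) = s_i * (g_j - mid_i); column-wise recycling of s*mid
    V <- 1 / (1 + exp(sg - (steepness * mid)))
    V[, 1] <- 1
    mean_i <- rowSums(V) - (V[, 1] + V[, ng]) / 2
    lower <- mean_i < target
    lo[lower] <- mid[lower]
    hi[!lower] <- mid[!lower]
  }
  (lo + hi) / 2
}

# invert P(Binomial(10, q) >= 5) = p by interpolation on a fine q grid, so
# that dichotomizing the 0-10 rating at > 4 matches the target probability
binom_q_for_p <- function(p) {
  qs <- seq(0, 1, length.out = 2001)
  ps <- stats::pbinom(4, 10, qs, lower.tail = FALSE)
  stats::approx(ps, qs, xout = pmin(pmax(p, min(ps)), max(ps)),
                ties = "ordered")$y
}

#' Generate a synthetic cohort with planted structure
#'
#' Draws latent dose groups, per-organ mean doses (group target + shared
#' patient latent + independent organ noise, paired organs offset
#' asymmetrically), logistic-tail DVHs realizing those means, covariates
#' with group enrichment, and longitudinal 0-10 symptom ratings whose
#' severe 6-month endpoint follows the configured logistic model.  Fully
#' deterministic given `cfg$seed`.
#'
#' @param cfg a [cohort_config()].
#' @return a list with `cohort` (named list of [patient_dose()], not yet
#'   lateralized), `covariates` (raw clinical data.frame), `symptoms`
#'   (a [symptom_table()]), and `truth` (planted group, per-organ true
#'   mean doses, outcome probabilities, baseline-missing mask).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- cfg$n_patients
  organs <- synthetic_organs()
  if (n == 0)
    return(list(cohort = list(),
                covariates = data.frame(patient = character()),
                symptoms = NULL,
                truth = data.frame(patient = character(),
                                   group = integer())))
  with_seed(cfg$seed, {
    ids <- sprintf("P%04d", seq_len(n))
    group <- sample.int(3L, n, replace = TRUE, prob = cfg$group_weights)
    rho <- cfg$correlation
    shared <- stats::rnorm(n)
    target <- cfg$group_mean_dose[group]
    organ_means <- matrix(0, n, length(organs),
                          dimnames = list(ids, organs))
    # fixed anatomical offsets: cord/plexus-like organs run cooler
    offset <- stats::setNames(rep(0, length(organs)), organs)
    offset[c("spinal_cord", "mandible")] <- -12
    offset[c("upper_lip", "lower_lip")] <- -8
    for (j in seq_along(organs)) {
      eps <- stats::rnorm(n)
      organ_means[, j] <- pmax(0.5, target + offset[organs[j]] +
        cfg$organ_sd * (sqrt(rho) * shared + sqrt(1 - rho) * eps))
    }
    # asymmetric paired organs: a random primary side gets +delta, the
    # other -delta, so lateralization is non-trivial
    primary_left <- stats::runif(n) < 0.5
    for (fam in c("parotid", "submandibular")) {
      delta <- stats::runif(n, cfg$pair_asymmetry_gy[1],
                            cfg$pair_asymmetry_gy[2])
      l <- paste0("left_", fam); r <- paste0("right_", fam)
      organ_means[, l] <- pmax(0.5, organ_means[, l] +
                                 ifelse(primary_left, delta, -delta))
      organ_means[, r] <- pmax(0.5, organ_means[, r] +
                                 ifelse(primary_left, -delta, delta))
    }
    steep <- matrix(stats::runif(n * length(organs),
                                 cfg$steepness_range[1],
                                 cfg$steepness_range[2]),
                    n, length(organs))
    # one vectorized bisection for every (patient, organ) curve
    grid <- seq(0, 90, by = 1)
    d50 <- matrix(solve_d50(as.vector(organ_means), as.vector(steep), grid),
                  n, length(organs))
    cohort <- vector("list", n)
    names(cohort) <- ids
    for (i in seq_len(n)) {
      curves <- lapply(seq_along(organs), function(j) {
        v <- 1 / (1 + exp(steep[i, j] * (grid - d50[i, j])))
        v[1] <- 1
        dvh_curve(organs[j], grid, v, repair = TRUE)
      })
      names(curves) <- organs
      cohort[[i]] <- patient_dose(ids[i], curves)
    }
    # covariates with group enrichment
    t4 <- stats::runif(n) < cfg$t4_prob[group]
    t3 <- !t4 & stats::runif(n) < 0.15
    t_stage <- ifelse(t4, 4L, ifelse(t3, 3L, sample(1:2, n, TRUE)))
    n3 <- stats::runif(n) < cfg$n3_prob[group]
    n2 <- !n3 & stats::runif(n) < 0.5
    n_stage <- ifelse(n3, 3L, ifelse(n2, 2L, sample(0:1, n, TRUE)))
    hpv <- sample(c("positive", "negative", "unknown"), n, TRUE,
                  prob = c(0.81, 0.07, 0.12))
    bot <- stats::runif(n) < cfg$bot_prob[group]
    subsite <- ifelse(bot, "BOT",
                      ifelse(stats::runif(n) < 0.7, "Tonsil", "other"))
    age <- round(stats::rnorm(n, 59, 9))
    ecog <- sample(c(0L, 1L, 2L, NA), n, TRUE,
                   prob = c(0.70, 0.20, 0.03, 0.07))
    modality <- sample(c("VMAT/IMPT", "IMRT", "3DCRT"), n, TRUE,
                       prob = c(0.66, 0.30, 0.04))
    surgery <- stats::runif(n) < c(0.14, 0.09, 0.04)[group]
    covars <- data.frame(patient = ids, t_stage = t_stage,
                         n_stage = n_stage, hpv = hpv, subsite = subsite,
                         age = age, ecog = ecog, modality = modality,
                         prior_surgery = surgery,
                         stringsAsFactors = FALSE)
    # outcome model: logistic on centred average organ mean dose + covariates
    avg_dose <- rowMeans(organ_means)
    eta <- cfg$outcome_intercept +
      cfg$outcome_dose_coef * (avg_dose - 45)
    cov_ind <- data.frame(t34 = as.integer(t_stage > 2),
                          n2plus = as.integer(n_stage > 1),
                          age_ge65 = as.integer(age >= 65),
                          subsite_bot = as.integer(subsite == "BOT"))
    for (nm in names(cfg$outcome_covariate_coef)) {
      if (!nm %in% names(cov_ind)) next
      eta <- eta + cfg$outcome_covariate_coef[[nm]] * cov_ind[[nm]]
    }
    p_outcome <- stats::plogis(eta)
    # longitudinal ratings: patient latent severity * symptom loading *
    # time profile, with the 6-month drymouth-like rating drawn so the
    # severe endpoint matches p_outcome
    S <- cfg$n_symptoms
    tp <- symptom_timepoints()
    sym_names <- c("drymouth", "swallow", "mucus", "voice",
                   if (S > 4) paste0("symptom", seq_len(S - 4)))
    loading <- stats::runif(S, 0.4, 1)
    profile <- c(0.15, seq(0.3, 0.9, length.out = 7), 0.7, 0.5)
    latent <- stats::plogis(eta + stats::rnorm(n, 0, 0.5))
    arr <- array(NA_integer_, dim = c(n, length(tp), S),
                 dimnames = list(ids, tp, sym_names))
    for (s in seq_len(S)) {
      q <- outer(latent * loading[s], profile)
      arr[, , s] <- matrix(stats::rbinom(length(q), 10, pmin(q, 1)),
                           n, length(tp))
    }
    # overwrite the four analyzed symptoms' 6-month column so the severe
    # endpoint follows the configured probability exactly
    for (s in seq_len(min(4L, S))) {
      q6 <- binom_q_for_p(p_outcome)
      arr[, "followup_6mo", s] <- stats::rbinom(n, 10, q6)
    }
    base_missing <- stats::runif(n) < cfg$baseline_missing
    arr[base_missing, "baseline", ] <- NA_integer_
    symptoms <- symptom_table(arr)
    truth <- data.frame(patient = ids, group = group,
                        p_outcome = p_outcome,
                        avg_mean_dose = avg_dose,
                        baseline_missing = base_missing,
                        stringsAsFactors = FALSE)
    truth_doses <- as.data.frame(organ_means)
    list(cohort = cohort, covariates = covars, symptoms = symptoms,
         truth = cbind(truth, truth_doses))
  })
}
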