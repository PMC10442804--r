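test_that("logistic MLE matches closed forms", {
  # intercept-only: logit of the prevalence
  y <- rep(c(1, 0), c(2, 6))
  f <- fit_logistic_mle(NULL, y)
  expect_equal(unname(coef(f)), log(0.25 / 0.75), tolerance = 1e-8)
  # single binary predictor from 2x2 counts (40,10;20,30): log cross-product
  x <- rep(c(1, 1, 0, 0), c(40, 10, 20, 30))
  y2 <- rep(c(1, 0, 1, 0), c(40, 10, 20, 30))
  f2 <- fit_logistic_mle(cbind(x = x), y2)
  expect_equal(unname(coef(f2)["x"]), log(6), tolerance = 1e-6)
  # duplicated predictor: one dropped, identical fit
  expect_warning(f3 <- fit_logistic_mle(cbind(x = x, x2 = x), y2),
                 "aliased")
  expect_equal(unname(coef(f3)["x"]), unname(coef(f2)["x"]),
               tolerance = 1e-8)
  expect_equal(f3$log_lik, f2$log_lik, tolerance = 1e-10)
  # separation triggers the ridge fallback, not an error
  ys <- as.numeric(x == 1)
  expect_warning(f4 <- fit_logistic_mle(cbind(x = x), ys), "ridge")
  expect_true(f4$ridged)
})

test_that("nested LRT has its closed-form behaviour", {
  set.seed(20)
  n <- 200
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.5 + x))
  base <- fit_logistic_mle(cbind(x = x), y)
  # an all-zeros added column: statistic 0, p 1, dAIC exactly +2
  expect_warning(
    ext0 <- fit_logistic_mle(cbind(x = x, z = rep(0, n)), y), "aliased")
  r0 <- lrt_nested(base, ext0)
  expect_equal(r0$statistic, 0, tolerance = 1e-9)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$delta_aic, 2, tolerance = 1e-7)
  expect_equal(r0$delta_bic, log(n), tolerance = 1e-7)
  # statistic equals 2 * logLik difference, p from the chi-squared tail
  z <- rbinom(n, 1, 0.5)
  ext <- fit_logistic_mle(cbind(x = x, z = z), y)
  r <- lrt_nested(base, ext)
  expect_equal(r$statistic, 2 * (ext$log_lik - base$log_lik),
               tolerance = 1e-10)
  expect_equal(r$p_value, pchisq(r$statistic, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(r$odds_ratio, exp(unname(coef(ext)["z"])),
               tolerance = 1e-10)
  # AIC/BIC recomputed from (k, lnL, n)
  expect_equal(r$delta_aic,
               (2 * ext$k - 2 * ext$log_lik) -
                 (2 * base$k - 2 * base$log_lik), tolerance = 1e-12)
  expect_equal(r$delta_bic,
               (ext$k * log(n) - 2 * ext$log_lik) -
                 (base$k * log(n) - 2 * base$log_lik), tolerance = 1e-12)
  # strong-evidence flag at dBIC <= -6
  fake <- r; fake$delta_bic <- -6.2; fake$strong_bic <- fake$delta_bic <= -6
  expect_true(fake$strong_bic)
  expect_false(r0$strong_bic)
  # non-nested designs rejected
  other <- fit_logistic_mle(cbind(w = z), y)
  expect_error(lrt_nested(other, ext0), "not nested")
})

test_that("LRT statistic is invariant to affine recoding of base covariates", {
  set.seed(21)
  n <- 150
  a <- rnorm(n); z <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.3 + 0.5 * a + 0.7 * z))
  r1 <- lrt_nested(fit_logistic_mle(cbind(a = a), y),
                   fit_logistic_mle(cbind(a = a, z = z), y))
  a2 <- 3 * a - 10
  r2 <- lrt_nested(fit_logistic_mle(cbind(a = a2), y),
                   fit_logistic_mle(cbind(a = a2, z = z), y))
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-6)
})

test_that("type-I error of the LRT is calibrated under the null", {
  set.seed(22)
  n <- 300; reps <- 300
  rej <- 0
  for (i in seq_len(reps)) {
    x <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, plogis(-0.5 + 0.4 * x))
    z <- rbinom(n, 1, 0.5)               # independent of y
    r <- lrt_nested(fit_logistic_mle(cbind(x = x), y),
                    fit_logistic_mle(cbind(x = x, z = z), y))
    rej <- rej + (r$p_value < 0.05)
  }
  expect_gt(rej / reps, 0.02)
  expect_lt(rej / reps, 0.09)
})

test_that("linear-model variant tests nested fits by F-statistic", {
  set.seed(23)
  n <- 120
  x <- rnorm(n); z <- rnorm(n)
  y <- 2 + x + 0.5 * z + rnorm(n)
  base <- fit_linear_mle(cbind(x = x), y)
  ext <- fit_linear_mle(cbind(x = x, z = z), y)
  r <- lrt_nested(base, ext)
  ref <- anova(lm(y ~ x), lm(y ~ x + z))
  expect_equal(r$statistic, ref$F[2], tolerance = 1e-8)
  expect_equal(r$p_value, ref$`Pr(>F)`[2], tolerance = 1e-8)
})

test_that("chi-squared covariate screening matches the closed form", {
  # counts (30,10;10,30): statistic n(ad-bc)^2/(r1 r2 c1 c2) = 20
  m <- rep(c(1, 1, 0, 0), c(30, 10, 10, 30))
  cv <- data.frame(t34 = rep(c(1, 0, 1, 0), c(30, 10, 10, 30)))
  res <- chi2_cluster_covariates(m, cv, columns = "t34")
  expect_equal(res$statistic, 20, tolerance = 1e-10)
  expect_equal(res$df, 1L)
  expect_equal(res$p_value, pchisq(20, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # covariate identical to membership: p ~ 0
  res2 <- chi2_cluster_covariates(cv$t34, cv, columns = "t34")
  expect_lt(res2$p_value, 1e-10)
  # independent covariate: near-nominal rejection rates over replicates
  set.seed(24)
  ps <- replicate(300, {
    mm <- rbinom(100, 1, 0.5)
    chi2_cluster_covariates(mm, data.frame(t34 = rbinom(100, 1, 0.5)),
                            columns = "t34")$p_value
  })
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.11)
  expect_gt(mean(ps < 0.5), 0.35)
  expect_lt(mean(ps < 0.5), 0.65)
})

test_that("Fisher odds ratios use the cross-product with Haldane correction", {
  r <- fisher_or(rbind(c(10, 10), c(10, 10)))
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_value, 1)
  r2 <- fisher_or(rbind(c(40, 10), c(20, 30)))
  expect_equal(r2$odds_ratio, 6)
  expect_equal(r2$p_value,
               fisher.test(rbind(c(40, 10), c(20, 30)))$p.value,
               tolerance = 1e-12)
  # zero cell: 0.5 added everywhere
  r3 <- fisher_or(rbind(c(0, 10), c(10, 10)))
  expect_true(r3$corrected)
  expect_equal(r3$odds_ratio, (0.5 * 10.5) / (10.5 * 10.5))
  # empty margin flagged undefined
  r4 <- fisher_or(rbind(c(0, 0), c(10, 10)))
  expect_true(r4$undefined)
  # single-predictor logistic OR equals the cross-product ratio
  x <- rep(c(1, 1, 0, 0), c(40, 10, 20, 30))
  y <- rep(c(1, 0, 1, 0), c(40, 10, 20, 30))
  f <- fit_logistic_mle(cbind(x = x), y)
  expect_equal(exp(unname(coef(f)["x"])), r2$odds_ratio, tolerance = 1e-6)
})

test_that("published dose limits are evaluated with the right semantics", {
  mk_pd <- function(parotid_means = c(10, 10), larynx = NULL,
                    extra = list()) {
    curves <- list(
      ipsilateral_parotid = uniform_curve(parotid_means[1]),
      contralateral_parotid = uniform_curve(parotid_means[2]))
    if (!is.null(larynx)) curves$larynx <- larynx
    curves <- c(curves, extra)
    patient_dose("A", curves)
  }
  # parotid: > 25 for one OR > 20 for both
  expect_true(dose_limit_flags(mk_pd(c(26, 10)))[["parotid"]])
  expect_false(dose_limit_flags(mk_pd(c(21, 19)))[["parotid"]])
  expect_true(dose_limit_flags(mk_pd(c(21, 22)))[["parotid"]])
  # larynx V50 > 27 (percent volume at 50 Gy)
  expect_true(dose_limit_flags(mk_pd(larynx = uniform_curve(55)))[["larynx"]])
  expect_false(dose_limit_flags(mk_pd(larynx = uniform_curve(45)))[["larynx"]])
  # zero dose everywhere: all computable flags FALSE
  zero <- patient_dose("Z", list(
    ipsilateral_parotid = uniform_curve(0),
    contralateral_parotid = uniform_curve(0),
    larynx = uniform_curve(0), spinal_cord = uniform_curve(0),
    mandible = uniform_curve(0), esophagus = uniform_curve(0),
    ipc = uniform_curve(0), mpc = uniform_curve(0),
    spc = uniform_curve(0), brachial_plexus = uniform_curve(0)))
  fz <- dose_limit_flags(zero)
  expect_false(any(fz, na.rm = TRUE))
  expect_length(attr(fz, "missing"), 0L)
  # esophagus composite: uniform 55 Gy -> V35 = 100 > 50 -> flagged
  fe <- dose_limit_flags(mk_pd(extra = list(esophagus = uniform_curve(55))))
  expect_true(fe[["esophagus"]])
  # missing ROIs are NA and listed
  fm <- dose_limit_flags(mk_pd())
  expect_true(is.na(fm[["spinal_cord"]]))
  expect_true("spinal_cord" %in% attr(fm, "missing"))
})

test_that("covariate encoding matches the confounder definitions", {
  raw <- data.frame(
    patient = c("A", "B", "C"),
    t_stage = c(4L, 2L, 3L), n_stage = c(3L, 1L, 2L),
    hpv = c("positive", "unknown", "negative"),
    subsite = c("BOT", "Tonsil", "other"),
    age = c(70, 64, 65), ecog = c(1L, NA, 2L),
    parotid_limit = c(1L, 0L, 0L))
  cv <- encode_covariates(raw)
  expect_equal(cv$t34, c(1L, 0L, 1L))
  expect_equal(cv$n2plus, c(1L, 0L, 1L))
  expect_equal(cv$hpv_pos, c(1L, 0L, 0L))
  expect_equal(cv$subsite_bot, c(1L, 0L, 0L))
  expect_equal(cv$subsite_tonsil, c(0L, 1L, 0L))
  expect_equal(cv$age_ge65, c(1L, 0L, 1L))
  expect_equal(cv$ecog_1, c(1L, 0L, 0L))     # unknown ECOG = reference
  expect_equal(cv$ecog_2, c(0L, 0L, 1L))
  expect_true(all(cv$ecog_1 + cv$ecog_2 <= 1))
  # parotid_limit indicator must agree with dose_limit_flags per patient
  cohort <- list(
    A = patient_dose("A", list(
      ipsilateral_parotid = uniform_curve(30),
      contralateral_parotid = uniform_curve(10))),
    B = patient_dose("B", list(
      ipsilateral_parotid = uniform_curve(15),
      contralateral_parotid = uniform_curve(10))),
    C = patient_dose("C", list(
      ipsilateral_parotid = uniform_curve(22),
      contralateral_parotid = uniform_curve(21))))
  cv2 <- encode_covariates(raw[, setdiff(names(raw), "parotid_limit")],
                           cohort)
  for (i in 1:3)
    expect_equal(cv2$parotid_limit[i],
                 as.integer(dose_limit_flags(cohort[[i]])[["parotid"]]))
})

test_that("the LRT report covers All / HD / SHD extensions", {
  set.seed(25)
  n <- 240
  lab <- sample(1:3, n, TRUE)
  X <- cbind(t34 = rbinom(n, 1, 0.2))
  y <- rbinom(n, 1, plogis(-1 + 1.2 * (lab == 3)))
  shd <- lab == 3
  rep_ <- lrt_report(y, X, lab, hd_cluster = 3, shd = shd)
  expect_setequal(rep_$model, c("All", "HD", "SHD"))
  expect_true(is.na(rep_$odds_ratio[rep_$model == "All"]))
  expect_false(anyNA(rep_$odds_ratio[rep_$model != "All"]))
  expect_lt(rep_$p_value[rep_$model == "HD"], 0.01)
  # HD and SHD identical here -> identical rows
  expect_equal(rep_$delta_aic[rep_$model == "HD"],
               rep_$delta_aic[rep_$model == "SHD"], tolerance = 1e-9)
})
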