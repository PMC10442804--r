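mk_table <- function(ratings) symptom_table(ratings)

# tiny 3-patient table for filter/endpoint edge cases
tiny_table <- function() {
  tp <- symptom_timepoints()
  arr <- array(3L, c(3, length(tp), 2),
               dimnames = list(c("A", "B", "C"), tp, c("drymouth", "mucus")))
  arr["A", , ] <- 5L                          # fully complete
  arr["B", sample(seq_along(tp), 1), ] <- 3L
  arr["B", , ] <- NA                          # 100% missing except below
  arr["B", c("baseline", "followup_6mo"), ] <- 4L   # 20% completeness
  arr["C", "followup_6mo", "drymouth"] <- NA  # complete except 6-month
  mk_table(arr)
}

test_that("eligibility applies completeness and 6-month filters", {
  st <- tiny_table()
  res <- eligibility_filter(st, "drymouth")
  expect_identical(res$retained, "A")
  expect_setequal(res$exclusions$patient, c("B", "C"))
  expect_identical(res$exclusions$reason[res$exclusions$patient == "B"],
                   "completeness")
  expect_identical(res$exclusions$reason[res$exclusions$patient == "C"],
                   "no 6-month rating")
  # threshold is inclusive at exactly 70%
  tp <- symptom_timepoints()
  arr <- array(NA_integer_, c(1, length(tp), 1),
               dimnames = list("D", tp, "drymouth"))
  arr[1, 1:7, 1] <- 2L                       # exactly 7/10 complete
  arr[1, "followup_6mo", 1] <- 6L            # 8/10 with the 6-month value
  expect_identical(eligibility_filter(mk_table(arr), "drymouth")$retained,
                   "D")
})

test_that("endpoints use strict > thresholds and severity tiers", {
  tp <- symptom_timepoints()
  arr <- array(0L, c(4, length(tp), 1),
               dimnames = list(paste0("P", 1:4), tp, "drymouth"))
  arr[, "baseline", 1] <- c(2L, 2L, 0L, NA)
  arr[, "followup_6mo", 1] <- c(5L, 4L, 7L, 6L)
  st <- mk_table(arr)
  ep <- derive_endpoints(st, "drymouth")
  expect_identical(ep$late_severe, c(TRUE, FALSE, TRUE, TRUE))
  # change: 3, 2, 7, NA-baseline
  expect_identical(ep$change_severe, c(FALSE, FALSE, TRUE, NA))
  # severity tiers "any" / "moderate" / "severe" are nested downward
  n_any <- sum(derive_endpoints(st, "drymouth", 0)$late_severe)
  n_mod <- sum(derive_endpoints(st, "drymouth", 2)$late_severe)
  n_sev <- sum(derive_endpoints(st, "drymouth", 4)$late_severe)
  expect_true(n_any >= n_mod && n_mod >= n_sev)
  # monotone: raising a 6-month rating never un-flags a patient
  arr2 <- arr
  arr2[, "followup_6mo", 1] <- arr[, "followup_6mo", 1] + 2L
  ep2 <- derive_endpoints(mk_table(arr2), "drymouth")
  expect_true(all(ep2$late_severe >= ep$late_severe))
  # invariance to patient order
  ep_rev <- derive_endpoints(st, "drymouth",
                             patients = rev(dimnames(arr)[[1]]))
  expect_equal(sum(ep_rev$late_severe), sum(ep$late_severe))
})

test_that("imputation fills only missing baselines, deterministically", {
  set.seed(8)
  st <- lowrank_symptoms(n = 120, n_symptoms = 8)
  # no missing baselines: unchanged
  expect_identical(impute_baseline(st, seed = 1), st)
  r <- st$ratings
  masked <- sample(dim(r)[1], 20)
  r[masked, "baseline", ] <- NA_integer_
  stm <- mk_table(r)
  out <- impute_baseline(stm, seed = 1, epochs = 200)
  expect_s3_class(out, "symptom_table")
  # observed cells never touched
  obs <- !is.na(r)
  expect_identical(out$ratings[obs], r[obs])
  # all baselines now present, integer, in range
  base <- out$ratings[, "baseline", ]
  expect_false(anyNA(base))
  expect_true(all(base >= 0 & base <= 10))
  # deterministic given the seed
  out2 <- impute_baseline(stm, seed = 1, epochs = 200)
  expect_identical(out$ratings, out2$ratings)
  out3 <- impute_baseline(stm, seed = 2, epochs = 200)
  expect_s3_class(out3, "symptom_table")
})

test_that("denoiser beats median imputation on masked low-rank baselines", {
  set.seed(9)
  st <- lowrank_symptoms(n = 150, n_symptoms = 12)
  truth <- st$ratings
  r <- truth
  masked <- sample(dim(r)[1], 30)       # 20% of patients lose baseline
  r[masked, "baseline", ] <- NA_integer_
  stm <- mk_table(r)
  out <- impute_baseline(stm, seed = 3)
  imp <- out$ratings[masked, "baseline", ]
  tru <- truth[masked, "baseline", ]
  rmse_net <- sqrt(mean((imp - tru)^2))
  med <- apply(r[-masked, "baseline", ], 2, median)
  med_mat <- matrix(med, length(masked), length(med), byrow = TRUE)
  rmse_med <- sqrt(mean((med_mat - tru)^2))
  expect_lt(rmse_net, rmse_med)
})

test_that("median fallback engages below the training minimum", {
  set.seed(10)
  st <- lowrank_symptoms(n = 25, n_symptoms = 4)
  r <- st$ratings
  r[1:5, "baseline", ] <- NA_integer_
  expect_warning(out <- impute_baseline(mk_table(r), seed = 1),
                 "median")
  expect_false(anyNA(out$ratings[, "baseline", ]))
})

test_that("symptom tables round-trip through CSV", {
  set.seed(11)
  st <- lowrank_symptoms(n = 10, n_symptoms = 3)
  r <- st$ratings
  r[2, "baseline", ] <- NA_integer_
  st <- mk_table(r)
  path <- withr::local_tempfile(fileext = ".csv")
  write_symptom_table(st, path)
  back <- read_symptom_table(path)
  expect_identical(back$ratings[dimnames(r)[[1]], , dimnames(r)[[3]]], r)
})

test_that("masked reconstruction of trained inputs beats the corruption level", {
  set.seed(12)
  st <- lowrank_symptoms(n = 120, n_symptoms = 10)
  X <- matrix(as.numeric(st$ratings), 120) / 10
  obs <- matrix(TRUE, nrow(X), ncol(X))
  net <- train_denoiser(X, obs, seed = 4, epochs = 400)
  # mask half of the inputs of held-back rows and reconstruct them
  mask <- matrix(runif(length(X)) < 0.5, nrow(X), ncol(X))
  pred <- net$predict(X * mask)
  masked_cells <- !mask
  err_net <- mean(abs(pred[masked_cells] - X[masked_cells]))
  err_zero <- mean(abs(X[masked_cells]))   # all-zeros corruption level
  expect_lt(err_net, err_zero * 0.8)
})
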