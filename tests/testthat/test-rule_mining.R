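test_that("candidate thresholds are midpoints, thinned at quantiles", {
  expect_equal(candidate_thresholds(c(0, 10, 20)), c(5, 15))
  expect_equal(candidate_thresholds(c(20, 0, 10, 10)), c(5, 15))
  expect_length(candidate_thresholds(rep(7, 50)), 0)
  expect_length(candidate_thresholds(numeric(0)), 0)
  set.seed(1)
  v <- runif(1000, 0, 80)
  th <- candidate_thresholds(v)
  expect_length(th, 64)
  u <- sort(unique(v))
  mids <- (u[-1] + u[-length(u)]) / 2
  expect_equal(th, unname(quantile(mids, seq(0, 1, length.out = 64),
                                   type = 7)))
  # thresholds split the data non-trivially
  expect_true(all(vapply(th, function(t) any(v > t) && any(v <= t),
                         logical(1))))
})

test_that("mutual information matches its closed forms", {
  y <- rep(c(TRUE, FALSE), each = 20)
  expect_equal(mutual_information(y, y), 1)          # identical, 50/50
  # exactly independent product-form table (2x2 counts 10 each)
  s <- rep(c(TRUE, FALSE, TRUE, FALSE), each = 10)
  t2 <- rep(c(TRUE, TRUE, FALSE, FALSE), each = 10)
  expect_equal(mutual_information(s, t2), 0)
  # plug-in value for counts (30,10;10,30), n = 80
  s3 <- rep(c(TRUE, TRUE, FALSE, FALSE), c(30, 10, 10, 30))
  t3 <- rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 10, 10, 30))
  expect_equal(mutual_information(s3, t3), 0.75 * log2(1.5) - 0.25,
               tolerance = 1e-12)
  expect_equal(mutual_information(s3, t3), oracle_mi(s3, t3),
               tolerance = 1e-12)
  expect_error(mutual_information(c(TRUE, FALSE), TRUE), "lengths differ")
})

test_that("random splits match the MI oracle", {
  set.seed(2)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    s <- runif(n) < runif(1, 0.1, 0.9)
    y <- runif(n) < runif(1, 0.1, 0.9)
    expect_lt(abs(mutual_information(s, y) - oracle_mi(s, y)), 1e-12)
  }
})

test_that("depth-1 beam equals exhaustive single-split search", {
  set.seed(3)
  for (i in 1:6) {
    X <- make_features(120, 8)
    y <- X[, 1] * runif(1, 0.5, 2) + X[, 2] + rnorm(120, 0, 20) > 100
    if (!any(y) || all(y)) next
    rs <- beam_search_rules(X, y, beam_width = 25, max_depth = 1)
    ex <- exhaustive_rules(X, y, depth = 1)
    expect_equal(rs$mi_bits, ex$mi, tolerance = 1e-12)
    expect_identical(unname(shd_membership(rs, X)),
                     unname(ex$member))
  }
})

test_that("full-width depth-2 beam equals exhaustive depth-2 search", {
  set.seed(4)
  for (i in 1:3) {
    X <- make_features(80, 5)
    y <- (X[, 1] > 45) & (X[, 2] > 25)
    y <- xor(y, runif(80) < 0.08)      # label noise
    if (sum(y) < 3 || sum(!y) < 3) next
    n_splits <- sum(vapply(seq_len(ncol(X)), function(j)
      length(candidate_thresholds(X[, j])), integer(1)))
    rs <- beam_search_rules(X, y, beam_width = n_splits, max_depth = 2)
    ex <- exhaustive_rules(X, y, depth = 2)
    expect_equal(rs$mi_bits, ex$mi, tolerance = 1e-12)
    expect_identical(unname(shd_membership(rs, X)),
                     unname(ex$member))
  }
})

test_that("planted conjunctions are recovered exactly", {
  set.seed(5)
  X <- make_features(500, 6, round_gy = 2)
  y <- (X[, 1] > 50) & (X[, 2] > 30)
  rs <- beam_search_rules(X, y)
  expect_equal(rs$precision, 1)
  expect_equal(rs$recall, 1)
  expect_equal(nrow(rs$rules), 2L)
  expect_setequal(rs$rules$feature, colnames(X)[1:2])
  # single planted threshold: a depth-1 rule comes back, nothing extra
  y1 <- X[, 1] > 50
  rs1 <- beam_search_rules(X, y1)
  expect_equal(nrow(rs1$rules), 1L)
  expect_identical(rs1$rules$feature, colnames(X)[1])
  expect_equal(rs1$precision, 1)
  expect_equal(rs1$recall, 1)
})

test_that("conjunction MI never falls below its depth-1 prefix", {
  set.seed(6)
  for (i in 1:5) {
    X <- make_features(150, 6)
    y <- X[, 1] + X[, 2] + rnorm(150, 0, 30) > 80
    if (!any(y) || all(y)) next
    rs2 <- beam_search_rules(X, y, max_depth = 2)
    rs1 <- beam_search_rules(X, y, max_depth = 1)
    expect_gte(rs2$mi_bits, rs1$mi_bits - 1e-12)
  }
})

test_that("rule quality metrics are consistent with membership", {
  set.seed(7)
  X <- make_features(200, 4)
  y <- X[, 1] > 40
  rs <- beam_search_rules(X, y)
  q <- rule_quality(rs, X, y)
  expect_equal(q$precision, rs$precision)
  expect_equal(q$recall, rs$recall)
  expect_equal(q$mi_bits, rs$mi_bits)
  member <- shd_membership(rs, X)
  tp <- sum(member & y)
  expect_equal(rs$precision, tp / sum(member))
  expect_equal(rs$recall, tp / sum(y))
  # SHD identical to HD: precision = recall = 1, MI = H(HD)
  rs_hd <- rs; rs_hd$rules <- data.frame(
    feature = colnames(X)[1], threshold = 40, direction = ">")
  q2 <- rule_quality(rs_hd, X, y)
  p <- mean(y)
  expect_equal(q2$precision, 1)
  expect_equal(q2$recall, 1)
  expect_equal(q2$mi_bits, -p * log2(p) - (1 - p) * log2(1 - p))
  # empty SHD group: precision reported 0 and flagged
  rs_empty <- rs; rs_empty$rules <- data.frame(
    feature = colnames(X)[1], threshold = 1e6, direction = ">")
  q3 <- rule_quality(rs_empty, X, y)
  expect_true(q3$undefined)
  expect_equal(q3$precision, 0)
  # complement of HD at 50/50 prevalence: precision = recall = 0, MI = 1
  yb <- X[, 2] > median(X[, 2])
  rs_c <- rs; rs_c$rules <- data.frame(
    feature = colnames(X)[2], threshold = unname(median(X[, 2])),
    direction = ">")
  q4 <- rule_quality(rs_c, X, !yb)
  expect_equal(q4$precision, 0)
  expect_equal(q4$recall, 0)
  expect_equal(q4$mi_bits, 1, tolerance = 1e-12)
})

test_that("degenerate inputs are handled", {
  X <- matrix(5, 30, 2, dimnames = list(NULL, c("a:V50", "b:V50")))
  y <- rep(c(TRUE, FALSE), 15)
  expect_warning(rs <- beam_search_rules(X, y), "constant")
  expect_equal(nrow(rs$rules), 0L)
  expect_error(beam_search_rules(make_features(10, 2), rep(TRUE, 10)),
               "positive and one negative")
})
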