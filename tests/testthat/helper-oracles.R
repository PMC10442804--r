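# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately use brute force / dense grids, never the package's
# own interpolation code paths.

# random piecewise-linear cumulative DVH: sorted dose knots, non-increasing
# volume fractions starting at 1
rand_curve <- function(n_knots = NULL) {
  if (is.null(n_knots)) n_knots <- sample(4:12, 1)
  doses <- sort(c(0, runif(n_knots - 1, 0, 80)))
  vf <- c(1, sort(runif(n_knots - 1, 0, 1), decreasing = TRUE))
  dvh_curve("organ", doses, vf)
}

# the curve as a plain function: linear between knots, 0 beyond, 1 before
curve_fun <- function(curve) {
  function(d) approx(curve$dose_grid, curve$volume_fraction, xout = d,
                     yleft = 1, yright = 0, ties = "ordered")$y
}

# dense grid including the knots (exact for piecewise-linear curves)
dense_vf <- function(curve, step = 1e-3) {
  d <- sort(unique(c(curve$dose_grid,
                     seq(0, max(curve$dose_grid), by = step))))
  list(d = d, v = curve_fun(curve)(d))
}

# numeric inversion of v(d) = x/100 by root finding on the interpolant
oracle_dose_at_volume <- function(curve, x_percent) {
  f <- curve_fun(curve)
  v <- x_percent / 100
  dmax <- max(curve$dose_grid)
  if (f(dmax) >= v) return(dmax)      # still above v at the end of support
  uniroot(function(d) f(d) - v, c(0, dmax), tol = 1e-12)$root
}

oracle_volume_at_dose <- function(curve, dose) 100 * curve_fun(curve)(dose)

oracle_mean_dose <- function(curve, step = 1e-3) {
  g <- dense_vf(curve, step)
  sum((head(g$v, -1) + tail(g$v, -1)) / 2 * diff(g$d))
}

# end of support from the knots: piecewise-linear curves hit zero exactly
# at the first zero knot after a positive one
oracle_max_dose <- function(curve) {
  v <- curve$volume_fraction; d <- curve$dose_grid
  if (all(v <= 1e-12)) return(0)
  last_pos <- max(which(v > 1e-12))
  if (last_pos == length(v)) d[last_pos] else d[last_pos + 1L]
}

# plug-in MI oracle from an explicit 2x2 probability table
oracle_mi <- function(split, target) {
  n <- length(split)
  p <- table(factor(split, c(FALSE, TRUE)),
             factor(target, c(FALSE, TRUE))) / n
  rows <- rowSums(p); cols <- colSums(p)
  s <- 0
  for (i in 1:2) for (j in 1:2)
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (rows[i] * cols[j]))
  unname(s)
}

# exhaustive rule search over the candidate-threshold space, depth <= 2,
# with the documented ordering: max MI, then higher recall, fewer rules,
# lexicographic feature names, lower thresholds.  Plain loops, no beam.
exhaustive_rules <- function(features, y, depth = 2) {
  y <- as.logical(y)
  n <- nrow(features)
  cands <- list()
  for (j in seq_len(ncol(features))) {
    th <- candidate_thresholds(features[, j])
    for (t in th)
      cands[[length(cands) + 1L]] <-
        list(feature = colnames(features)[j], threshold = t,
             member = features[, j] > t)
  }
  best <- NULL
  consider <- function(feats, ths, member) {
    mi <- oracle_mi(member, y)
    rec <- sum(member & y) / sum(y)
    key <- list(mi = mi, recall = rec, nr = length(feats),
                fkey = paste(sort(feats), collapse = "|"),
                tkey = paste(sprintf("%020.9f", sort(ths)), collapse = "|"),
                member = member, feats = feats, ths = ths)
    if (is.null(best)) { best <<- key; return(invisible()) }
    better <- FALSE
    if (mi > best$mi + 1e-12) better <- TRUE
    else if (mi >= best$mi - 1e-12) {
      if (rec > best$recall + 1e-12) better <- TRUE
      else if (abs(rec - best$recall) <= 1e-12) {
        if (key$nr < best$nr) better <- TRUE
        else if (key$nr == best$nr) {
          if (key$fkey < best$fkey) better <- TRUE
          else if (key$fkey == best$fkey && key$tkey < best$tkey)
            better <- TRUE
        }
      }
    }
    if (better) best <<- key
  }
  for (a in seq_along(cands))
    consider(cands[[a]]$feature, cands[[a]]$threshold, cands[[a]]$member)
  if (depth >= 2) {
    for (a in seq_along(cands)) for (b in seq_along(cands)) {
      if (a >= b) next
      consider(c(cands[[a]]$feature, cands[[b]]$feature),
               c(cands[[a]]$threshold, cands[[b]]$threshold),
               cands[[a]]$member & cands[[b]]$member)
    }
  }
  best
}

# vectorized exhaustive search over all depth <= 2 conjunctions of
# candidate-threshold splits: all-pairs joint counts via matrix products,
# then the documented ordering (max MI; ties by higher recall, fewer
# rules, lexicographic features, lower thresholds) applied to the argmax
# set only.  Independent of the beam implementation.
exhaustive_rules_fast <- function(features, y, depth = 2) {
  y <- as.logical(y)
  n <- nrow(features); npos <- sum(y)
  feat <- character(); thr <- numeric(); cols <- list()
  for (j in seq_len(ncol(features))) {
    th <- candidate_thresholds(features[, j])
    if (!length(th)) next
    cols[[length(cols) + 1L]] <- outer(features[, j], th, ">") * 1
    feat <- c(feat, rep(colnames(features)[j], length(th)))
    thr <- c(thr, th)
  }
  A <- do.call(cbind, cols)
  m <- ncol(A)
  mi_of <- function(a, sz) {
    dosestrat:::mi_counts(a, sz - a, npos - a, n - sz - npos + a, n)
  }
  # singles
  a1 <- as.numeric(crossprod(A, y))
  s1 <- colSums(A)
  mi1 <- mi_of(a1, s1)
  cands <- data.frame(i = seq_len(m), j = NA_integer_, mi = mi1,
                      recall = a1 / npos, nr = 1L)
  if (depth >= 2) {
    a2 <- crossprod(A * y, A)            # joint positive counts
    s2 <- crossprod(A)                   # joint sizes
    mi2 <- matrix(mi_of(as.numeric(a2), as.numeric(s2)), m, m)
    ut <- which(upper.tri(mi2), arr.ind = TRUE)
    cands <- rbind(cands,
                   data.frame(i = ut[, 1], j = ut[, 2],
                              mi = mi2[upper.tri(mi2)],
                              recall = a2[upper.tri(a2)] / npos,
                              nr = 2L))
  }
  top <- cands[cands$mi >= max(cands$mi) - 1e-12, , drop = FALSE]
  fkey <- vapply(seq_len(nrow(top)), function(r) {
    idx <- c(top$i[r], top$j[r]); idx <- idx[!is.na(idx)]
    paste(sort(feat[idx]), collapse = "|")
  }, character(1))
  tkey <- vapply(seq_len(nrow(top)), function(r) {
    idx <- c(top$i[r], top$j[r]); idx <- idx[!is.na(idx)]
    paste(sprintf("%020.9f", sort(thr[idx])), collapse = "|")
  }, character(1))
  best <- top[order(-top$mi, -top$recall, top$nr, fkey, tkey)[1L], ]
  idx <- c(best$i, best$j); idx <- idx[!is.na(idx)]
  member <- rowSums(A[, idx, drop = FALSE]) == length(idx)
  list(mi = best$mi, member = member, feats = feat[idx], ths = thr[idx])
}

# uniform-dose curve: whole organ at `dose` Gy
uniform_curve <- function(dose, roi = "organ") {
  if (dose == 0) return(dvh_curve(roi, c(0, 1e-6), c(1, 0)))
  dvh_curve(roi, c(0, dose, dose + 1e-6), c(1, 1, 0))
}

# linear cumulative curve v(d) = 1 - d/dmax on [0, dmax]
linear_curve <- function(dmax = 70, roi = "organ") {
  dvh_curve(roi, c(0, dmax), c(1, 0))
}

# small random feature matrix with named columns; round_gy > 0 snaps the
# values to that dose resolution (typical of tabulated DVH exports), which
# leaves clean gaps around planted rule boundaries
make_features <- function(n, m, lo = 0, hi = 80, round_gy = 0) {
  x <- matrix(runif(n * m, lo, hi), n, m)
  if (round_gy > 0) x <- round(x / round_gy) * round_gy
  colnames(x) <- paste0("organ", seq_len(m), ":V50")
  rownames(x) <- sprintf("P%04d", seq_len(n))
  x
}

# low-rank longitudinal symptom table: patient latent x symptom loading x
# time profile, ratings = binomial(10, q); baselines observed
lowrank_symptoms <- function(n = 150, n_symptoms = 12) {
  tp <- symptom_timepoints()
  latent <- runif(n, 0.1, 0.9)
  loading <- runif(n_symptoms, 0.3, 1)
  profile <- c(0.5, seq(0.5, 0.9, length.out = 7), 0.8, 0.7)
  arr <- array(NA_integer_, c(n, length(tp), n_symptoms),
               dimnames = list(sprintf("P%04d", 1:n), tp,
                               paste0("s", 1:n_symptoms)))
  for (s in 1:n_symptoms) {
    q <- outer(latent * loading[s], profile)
    arr[, , s] <- matrix(rbinom(length(q), 10, pmin(q, 1)), n, length(tp))
  }
  symptom_table(arr)
}
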