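#' Variational Bayesian Gaussian mixture model of dose patterns
#'
#' Fits a k-component Gaussian mixture with full covariances by mean-field
#' variational inference, using a Dirichlet prior on the component weights
#' (concentration `1/k` per component, so superfluous components are driven
#' towards zero weight) and a Gaussian-Wishart prior on the component
#' parameters.  Features are standardized internally (mean 0, sd 1); labels
#' and reported means/covariances are on the original Gy scale.  The fit is
#' deterministic given `seed`: `n_init` k-means initializations are run and
#' the one with the best converged data-fit score is kept.
#'
#' @param features numeric matrix (patients x features), e.g. a
#'   [build_feature_matrix()] result.
#' @param k number of mixture components (3 for the low/mid/high dose
#'   stratification).
#' @param seed integer seed; required for reproducibility.
#' @param n_init number of random initializations.
#' @param max_iter,tol variational iteration cap and convergence tolerance
#'   on the per-sample data-fit score.
#' @param reg_covar ridge added to component covariance diagonals.
#' @param weight_concentration Dirichlet prior concentration per component.
#' @return an object of class `"bgmm"` with elements `weights`, `means`,
#'   `covariances` (original scale), `labels` (named integer vector, 1..k),
#'   `responsibilities`, `converged`, `k`, `seed`.
#' @export
fit_bgmm <- function(features, k = 3, seed = NULL, n_init = 5,
                     max_iter = 200, tol = 1e-5, reg_covar = 1e-4,
                     weight_concentration = 1 / k) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  n <- nrow(X); d <- ncol(X)
  if (!all(is.finite(X))) stop("features must be finite", call. = FALSE)
  if (k <= 0 || k > n)
    stop("k must be in 1..nrow(features)", call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  # Wishart prior scale = empirical covariance: keeps the prior
  # commensurate with the data's (strongly correlated) geometry, so
  # genuinely tight clusters are not swamped by an isotropic prior
  prior <- list(alpha0 = weight_concentration, beta0 = 1,
                m0 = rep(0, d), nu0 = d,
                W0inv = NULL)   # filled below (needs Z)
  prior$W0inv <- if (n > 1) stats::cov(Z) + diag(reg_covar, d)
                 else diag(d)

  fit1 <- function() {
    # k-means one-hot initialization (the reference variational-mixture
    # behaviour: restarts differ only through the k-means seed)
    cl <- if (k >= n) seq_len(n)
          else suppressWarnings(stats::kmeans(Z, centers = k, nstart = 10,
                                              iter.max = 30))$cluster
    r <- matrix(1e-10, n, k)
    r[cbind(seq_len(n), cl)] <- 1
    r <- r / rowSums(r)
    prev <- -Inf; converged <- FALSE; est <- NULL; bound <- -Inf
    for (iter in seq_len(max_iter)) {
      est <- vb_mstep(Z, r, prior, reg_covar)
      e <- vb_estep(Z, est)
      r <- e$resp
      bound <- vb_elbo(Z, r, est, prior)
      if (is.finite(prev) && abs(bound - prev) < tol * abs(bound)) {
        converged <- TRUE
        break
      }
      prev <- bound
    }
    list(est = est, resp = r, score = bound, converged = converged)
  }

  best <- with_seed(seed, {
    runs <- lapply(seq_len(max(1L, n_init)), function(i) fit1())
    runs[[which.max(vapply(runs, `[[`, numeric(1), "score"))]]
  })
  if (!best$converged)
    warning("variational fit did not converge; best-so-far model returned")

  est <- best$est
  labels <- max.col(best$resp, ties.method = "first")
  names(labels) <- rownames(X)
  weights <- est$alpha / sum(est$alpha)
  # de-standardize component parameters to the original Gy scale
  means <- sweep(sweep(est$m, 2, scl, "*"), 2, ctr, "+")
  covs <- lapply(seq_len(k), function(j) {
    S <- est$Winv[[j]] / est$nu[j]          # posterior point covariance
    S <- diag(scl) %*% S %*% diag(scl)
    dimnames(S) <- list(colnames(X), colnames(X))
    (S + t(S)) / 2
  })
  rownames(means) <- paste0("component", seq_len(k))
  colnames(means) <- colnames(X)
  structure(list(k = k, weights = weights, means = means,
                 covariances = covs, labels = labels,
                 responsibilities = best$resp, converged = best$converged,
                 seed = seed, center = ctr, scale = scl,
                 variational = est, feature_names = colnames(X)),
            class = "bgmm")
}

# M-step: Gaussian-Wishart / Dirichlet posterior updates from responsibilities
vb_mstep <- function(Z, r, prior, reg_covar) {
  n <- nrow(Z); d <- ncol(Z); k <- ncol(r)
  Nk <- colSums(r) + 1e-10
  xbar <- crossprod(r, Z) / Nk               # k x d
  alpha <- prior$alpha0 + colSums(r)
  beta <- prior$beta0 + Nk
  nu <- prior$nu0 + Nk
  m <- (prior$beta0 * matrix(prior$m0, k, d, byrow = TRUE) + Nk * xbar) / beta
  Winv <- vector("list", k)
  for (j in seq_len(k)) {
    C <- sweep(Z, 2, xbar[j, ])
    Sk <- crossprod(C * r[, j], C)           # Nk * weighted scatter
    dm <- xbar[j, ] - prior$m0
    Winv[[j]] <- prior$W0inv + Sk +
      (prior$beta0 * Nk[j] / (prior$beta0 + Nk[j])) * tcrossprod(dm) +
      diag(reg_covar * Nk[j], d)
  }
  list(alpha = alpha, beta = beta, nu = nu, m = m, Winv = Winv)
}

# E-step: expected log responsibilities; score = mean log-sum-exp, a
# per-sample data-fit surrogate used for convergence and init selection
vb_estep <- function(Z, est) {
  n <- nrow(Z); d <- ncol(Z); k <- length(est$alpha)
  elog_pi <- digamma(est$alpha) - digamma(sum(est$alpha))
  lrho <- matrix(0, n, k)
  for (j in seq_len(k)) {
    L <- chol(est$Winv[[j]])                 # upper triangular
    logdet_winv <- 2 * sum(log(diag(L)))
    elog_lambda <- sum(digamma((est$nu[j] + 1 - seq_len(d)) / 2)) +
      d * log(2) - logdet_winv
    dev <- sweep(Z, 2, est$m[j, ])
    y <- backsolve(L, t(dev), transpose = TRUE)
    quad <- d / est$beta[j] + est$nu[j] * colSums(y^2)
    lrho[, j] <- elog_pi[j] + 0.5 * elog_lambda - 0.5 * d * log(2 * pi) -
      0.5 * quad
  }
  mx <- apply(lrho, 1, max)
  lse <- mx + log(rowSums(exp(lrho - mx)))
  resp <- exp(lrho - lse)
  list(resp = resp, score = mean(lse))
}

# log of the Wishart normalizing constant B(W, nu), parameterized by
# ln|Winv| (= -ln|W|)
log_wishart_b <- function(logdet_winv, nu, d) {
  (nu / 2) * logdet_winv - (nu * d / 2) * log(2) -
    (d * (d - 1) / 4) * log(pi) -
    sum(lgamma((nu + 1 - seq_len(d)) / 2))
}

# full variational lower bound (evidence lower bound) of the
# Dirichlet/Gaussian-Wishart mixture given responsibilities and the
# current posterior parameters; used for convergence and init selection —
# unlike a pure data-fit score it penalizes superfluous components
vb_elbo <- function(Z, r, est, prior) {
  n <- nrow(Z); d <- ncol(Z); k <- ncol(r)
  Nk <- colSums(r) + 1e-10
  xbar <- crossprod(r, Z) / Nk
  elog_pi <- digamma(est$alpha) - digamma(sum(est$alpha))
  lnC <- function(a) lgamma(sum(a)) - sum(lgamma(a))
  t_data <- 0; t_prior_mu_lambda <- 0; t_q_mu_lambda <- 0
  for (j in seq_len(k)) {
    L <- chol(est$Winv[[j]])
    logdet_winv <- 2 * sum(log(diag(L)))
    elog_lambda <- sum(digamma((est$nu[j] + 1 - seq_len(d)) / 2)) +
      d * log(2) - logdet_winv
    C <- sweep(Z, 2, xbar[j, ])
    Sk <- crossprod(C * r[, j], C) / Nk[j]
    W_S <- backsolve(L, backsolve(L, Sk, transpose = TRUE))
    tr_SW <- est$nu[j] * sum(diag(W_S))
    dmk <- xbar[j, ] - est$m[j, ]
    ym <- backsolve(L, dmk, transpose = TRUE)
    quad_xm <- est$nu[j] * sum(ym^2)
    t_data <- t_data + 0.5 * Nk[j] *
      (elog_lambda - d / est$beta[j] - tr_SW - quad_xm - d * log(2 * pi))
    dm0 <- est$m[j, ] - prior$m0
    y0 <- backsolve(L, dm0, transpose = TRUE)
    quad_m0 <- est$nu[j] * sum(y0^2)
    W_W0 <- backsolve(L, backsolve(L, prior$W0inv, transpose = TRUE))
    t_prior_mu_lambda <- t_prior_mu_lambda +
      0.5 * (d * log(prior$beta0 / (2 * pi)) + elog_lambda -
               d * prior$beta0 / est$beta[j] - prior$beta0 * quad_m0) +
      (prior$nu0 - d - 1) / 2 * elog_lambda -
      0.5 * est$nu[j] * sum(diag(W_W0))
    h_wishart <- -log_wishart_b(logdet_winv, est$nu[j], d) -
      (est$nu[j] - d - 1) / 2 * elog_lambda + est$nu[j] * d / 2
    t_q_mu_lambda <- t_q_mu_lambda + 0.5 * elog_lambda +
      d / 2 * log(est$beta[j] / (2 * pi)) - d / 2 - h_wishart
  }
  logdet_w0inv <- as.numeric(determinant(prior$W0inv)$modulus)
  t_prior_mu_lambda <- t_prior_mu_lambda +
    k * log_wishart_b(logdet_w0inv, prior$nu0, d)
  t_z <- sum(r * rep(elog_pi, each = n))
  t_prior_pi <- lnC(rep(prior$alpha0, k)) +
    (prior$alpha0 - 1) * sum(elog_pi)
  rl <- r * log(pmax(r, 1e-300))
  t_q_z <- sum(rl)
  t_q_pi <- sum((est$alpha - 1) * elog_pi) + lnC(est$alpha)
  t_data + t_z + t_prior_pi + t_prior_mu_lambda -
    t_q_z - t_q_pi - t_q_mu_lambda
}

#' @export
print.bgmm <- function(x, ...) {
  cat(sprintf("<bgmm> %d components on %d patients x %d features\n",
              x$k, length(x$labels), length(x$feature_names)))
  cat("weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  cat("cluster sizes:",
      paste(tabulate(x$labels, x$k), collapse = " "), "\n")
  invisible(x)
}

#' Assign feature vectors to mixture components
#'
#' Posterior-responsibility argmax under the fitted variational model; ties
#' resolve to the lower component id.  Applied to the training matrix this
#' reproduces `model$labels`.
#'
#' @param model a fitted [fit_bgmm()] object.
#' @param x numeric vector (one patient) or matrix (patients x features) on
#'   the original Gy scale, with the model's feature dimension.
#' @return integer component id(s) in 1..k.
#' @export
assign_cluster <- function(model, x) {
  stopifnot(inherits(model, "bgmm"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != length(model$feature_names))
    stop("feature dimension mismatch: expected ",
         length(model$feature_names), ", got ", ncol(x), call. = FALSE)
  Z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  r <- vb_estep(Z, model$variational)$resp
  max.col(r, ties.method = "first")
}
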