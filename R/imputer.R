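# ---- minimal dense denoising autoencoder -----------------------------------
#
# Architecture: input -> FC -> ReLU -> BatchNorm -> FC -> ReLU -> BatchNorm
# -> FC -> linear output, trained full-batch with Adam (lr 1e-3) on a
# masked mean-squared-error; inputs are corrupted by multiplicative
# Bernoulli zeroing (p = 0.5) each epoch so the network learns to
# reconstruct ratings from the remaining ones.  Written with explicit
# matrix backpropagation; no external deep-learning dependency.

ae_init <- function(d_in, hidden) {
  dims <- c(d_in, hidden, d_in)
  L <- length(dims) - 1L
  par <- list()
  for (l in seq_len(L)) {
    par[[paste0("W", l)]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                                 sd = sqrt(2 / dims[l])),
                                    dims[l], dims[l + 1L])
    par[[paste0("b", l)]] <- rep(0, dims[l + 1L])
  }
  for (l in seq_len(L - 1L)) {           # batch-norm after each hidden layer
    par[[paste0("g", l)]] <- rep(1, dims[l + 1L])
    par[[paste0("beta", l)]] <- rep(0, dims[l + 1L])
  }
  attr(par, "L") <- L
  par
}

ae_forward <- function(par, X, running = NULL, train = TRUE,
                       momentum = 0.9, eps = 1e-5) {
  L <- attr(par, "L")
  cache <- list(H0 = X)
  H <- X
  for (l in seq_len(L - 1L)) {
    Zl <- sweep(H %*% par[[paste0("W", l)]], 2, par[[paste0("b", l)]], "+")
    A <- pmax(Zl, 0)
    if (train) {
      mu <- colMeans(A)
      v <- colMeans(sweep(A, 2, mu)^2)
      if (is.null(running[[paste0("mu", l)]])) {
        running[[paste0("mu", l)]] <- mu
        running[[paste0("var", l)]] <- v
      } else {
        running[[paste0("mu", l)]] <-
          momentum * running[[paste0("mu", l)]] + (1 - momentum) * mu
        running[[paste0("var", l)]] <-
          momentum * running[[paste0("var", l)]] + (1 - momentum) * v
      }
    } else {
      mu <- running[[paste0("mu", l)]]
      v <- running[[paste0("var", l)]]
    }
    Ahat <- sweep(sweep(A, 2, mu), 2, sqrt(v + eps), "/")
    H <- sweep(sweep(Ahat, 2, par[[paste0("g", l)]], "*"), 2,
               par[[paste0("beta", l)]], "+")
    cache[[paste0("Z", l)]] <- Zl
    cache[[paste0("A", l)]] <- A
    cache[[paste0("Ahat", l)]] <- Ahat
    cache[[paste0("v", l)]] <- v
    cache[[paste0("H", l)]] <- H
  }
  Yhat <- sweep(H %*% par[[paste0("W", L)]], 2, par[[paste0("b", L)]], "+")
  list(yhat = Yhat, cache = cache, running = running)
}

ae_backward <- function(par, fwd, dY, eps = 1e-5) {
  L <- attr(par, "L")
  cache <- fwd$cache
  grads <- list()
  H_prev <- cache[[paste0("H", L - 1L)]]
  grads[[paste0("W", L)]] <- crossprod(H_prev, dY)
  grads[[paste0("b", L)]] <- colSums(dY)
  dH <- tcrossprod(dY, par[[paste0("W", L)]])
  for (l in rev(seq_len(L - 1L))) {
    Ahat <- cache[[paste0("Ahat", l)]]
    v <- cache[[paste0("v", l)]]
    m <- nrow(Ahat)
    grads[[paste0("g", l)]] <- colSums(dH * Ahat)
    grads[[paste0("beta", l)]] <- colSums(dH)
    dAhat <- sweep(dH, 2, par[[paste0("g", l)]], "*")
    s1 <- colSums(dAhat)
    s2 <- colSums(dAhat * Ahat)
    dA <- sweep(m * dAhat, 2, s1) - sweep(Ahat, 2, s2, "*")
    dA <- sweep(dA, 2, m * sqrt(v + eps), "/")
    dZ <- dA * (cache[[paste0("Z", l)]] > 0)
    H_in <- if (l == 1L) cache$H0 else cache[[paste0("H", l - 1L)]]
    grads[[paste0("W", l)]] <- crossprod(H_in, dZ)
    grads[[paste0("b", l)]] <- colSums(dZ)
    if (l > 1L) dH <- tcrossprod(dZ, par[[paste0("W", l)]])
  }
  grads
}

ae_adam_step <- function(par, grads, state, lr = 1e-3, b1 = 0.9, b2 = 0.999,
                         eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * (state$m[[nm]] %||% (g * 0)) + (1 - b1) * g
    state$v[[nm]] <- b2 * (state$v[[nm]] %||% (g * 0)) + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

#' Train a denoising autoencoder on a ratings matrix
#'
#' Low-level trainer behind [impute_baseline()]; exposed so reconstruction
#' behaviour can be validated directly.  `X` is scaled to \[0, 1\] inputs
#' (ratings / 10); `obs` marks which entries contribute to the loss.
#'
#' @param X numeric matrix (patients x flattened ratings) in \[0, 1\];
#'   missing entries 0.
#' @param obs logical matrix, same shape: observed-entry mask.
#' @param hidden hidden-layer widths.
#' @param corruption probability an input is zeroed during training.
#' @param lr Adam learning rate.
#' @param epochs epoch cap (early stopping usually ends sooner).
#' @param patience early-stopping patience (epochs) on validation MSE.
#' @param val_fraction fraction of rows held out for early stopping.
#' @param batch_size minibatch size (shuffled each epoch).
#' @param seed RNG seed (weights, corruption masks, validation split).
#' @return a list with `par`, `running` (batch-norm statistics), `predict`
#'   (function of a new \[0,1\]-scaled matrix) and `history`.
#' @export
train_denoiser <- function(X, obs, hidden = c(32, 16), corruption = 0.5,
                           lr = 1e-3, epochs = 2000, patience = 50,
                           val_fraction = 0.1, batch_size = 32,
                           seed = NULL) {
  X <- as.matrix(X); obs <- as.matrix(obs)
  stopifnot(all(dim(X) == dim(obs)))
  n <- nrow(X); d <- ncol(X)
  with_seed(seed, {
    par <- ae_init(d, hidden)
    n_val <- max(1L, round(val_fraction * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (!length(tr_idx)) { tr_idx <- val_idx }
    Xtr <- X[tr_idx, , drop = FALSE]; Otr <- obs[tr_idx, , drop = FALSE]
    Xval <- X[val_idx, , drop = FALSE]; Oval <- obs[val_idx, , drop = FALSE]
    # fixed corruption mask so validation measures the denoising objective
    vmask <- matrix(stats::rbinom(length(Xval), 1L, 1 - corruption),
                    nrow(Xval), d)
    running <- list()
    state <- list(t = 0L, m = list(), v = list())
    best <- list(loss = Inf, par = par, running = running)
    wait <- 0L
    hist <- numeric(0)
    ntr <- nrow(Xtr)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(ntr)
      starts <- seq(1L, ntr, by = batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, ntr)]
        if (length(idx) < 2L) next          # batch norm needs >= 2 rows
        Xb <- Xtr[idx, , drop = FALSE]
        Ob <- Otr[idx, , drop = FALSE]
        mask <- matrix(stats::rbinom(length(Xb), 1L, 1 - corruption),
                       nrow(Xb), d)
        fwd <- ae_forward(par, Xb * mask, running, train = TRUE)
        running <- fwd$running
        dY <- 2 * (fwd$yhat - Xb) * Ob / max(1, sum(Ob))
        grads <- ae_backward(par, fwd, dY)
        upd <- ae_adam_step(par, grads, state, lr = lr)
        par <- upd$par; state <- upd$state
      }
      # validation: fixed-mask corrupted forward with running statistics
      vf <- ae_forward(par, Xval * vmask, running, train = FALSE)
      vloss <- sum(((vf$yhat - Xval) * Oval)^2) / max(1, sum(Oval))
      hist <- c(hist, vloss)
      if (vloss < best$loss - 1e-7) {
        best <- list(loss = vloss, par = par, running = running)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    par <- best$par
    # recalibrate batch-norm statistics on the clean training inputs:
    # imputation-time inputs are mostly uncorrupted, unlike the half-zeroed
    # training batches the running statistics were accumulated on
    running <- if (nrow(Xtr) >= 2L)
      ae_forward(par, Xtr, list(), train = TRUE)$running
    else best$running
    list(par = par, running = running, history = hist,
         predict = function(Xnew)
           ae_forward(par, as.matrix(Xnew), running, train = FALSE)$yhat)
  })
}

#' Impute missing baseline symptom ratings
#'
#' Trains the denoising autoencoder on patients with a fully observed
#' baseline questionnaire and at least `min_completeness` of all their
#' ratings, using every rating at every timepoint (scaled to \[0, 1\]) as
#' input, then fills missing baseline cells for the remaining patients.
#' Outputs are rescaled to the 0-10 scale, clipped and rounded to integers;
#' observed values are never overwritten.  With fewer than `min_train`
#' trainable patients the imputer falls back to per-symptom medians of the
#' observed baselines, with a warning.
#'
#' @param st a [symptom_table()].
#' @param seed RNG seed (the imputation is deterministic given it).
#' @param min_completeness completeness requirement for training patients.
#' @param min_train minimum training-set size before the median fallback.
#' @param ... passed to [train_denoiser()] (`hidden`, `epochs`, ...).
#' @return a [symptom_table()] with baselines filled where possible and an
#'   attribute `"imputed_baseline"` (matrix of patient/symptom pairs).
#' @export
impute_baseline <- function(st, seed = NULL, min_completeness = 0.7,
                            min_train = 30, ...) {
  stopifnot(inherits(st, "symptom_table"))
  r <- st$ratings
  base_missing <- is.na(r[, "baseline", , drop = FALSE])
  if (!any(base_missing)) return(st)
  d3 <- dim(r)
  flat <- matrix(as.numeric(r), d3[1L], d3[2L] * d3[3L])
  obs <- !is.na(flat)
  X <- flat / 10
  X[!obs] <- 0
  completeness <- rowMeans(obs)
  full_base <- apply(!is.na(r[, "baseline", , drop = FALSE]), 1L, all)
  train_rows <- which(full_base & completeness >= min_completeness)
  miss_idx <- which(is.na(r[, "baseline", ]), arr.ind = TRUE)
  if (length(dim(miss_idx)) < 2L)   # single-symptom table edge case
    miss_idx <- cbind(row = which(is.na(r[, "baseline", 1L])), col = 1L)
  if (length(train_rows) < min_train) {
    warning("fewer than ", min_train,
            " trainable patients; median baseline imputation used")
    med <- apply(r[, "baseline", , drop = FALSE], 3L,
                 stats::median, na.rm = TRUE)
    med[!is.finite(med)] <- 0
    fill <- as.integer(round(med[miss_idx[, 2L]]))
  } else {
    net <- train_denoiser(X[train_rows, , drop = FALSE],
                          obs[train_rows, , drop = FALSE],
                          seed = seed, ...)
    pred <- net$predict(X)
    pred_arr <- array(pred * 10, dim = d3)
    fill <- as.integer(round(pmin(10, pmax(0,
      pred_arr[cbind(miss_idx[, 1L], 1L, miss_idx[, 2L])]))))
  }
  r[cbind(miss_idx[, 1L], 1L, miss_idx[, 2L])] <- fill
  out <- symptom_table(r)
  attr(out, "imputed_baseline") <-
    cbind(patient = dimnames(r)[[1L]][miss_idx[, 1L]],
          symptom = dimnames(r)[[3L]][miss_idx[, 2L]])
  out
}
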