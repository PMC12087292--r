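# mini-batch optimisation engine for the trainable dense block + softmax head

.softmax <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# forward pass through the trainable part; X is standardised features
.denseForward <- function(X, par) {
  H <- X %*% par$W1
  H <- H + rep(par$b1, each = nrow(X))
  H[H < 0] <- 0
  P <- .softmax(H %*% par$W2 + rep(par$b2, each = nrow(X)))
  list(H = H, P = P)
}

# one optimiser step; state carries per-parameter moments
.optimStep <- function(par, grad, state, cfg, t) {
  lr <- cfg@learningRate
  for (nm in names(grad)) {
    g <- grad[[nm]]
    if (is.null(g)) next
    if (cfg@optimizer == "sgdm") {
      state$v[[nm]] <- 0.9 * (state$v[[nm]] %||% 0) - lr * g
      par[[nm]] <- par[[nm]] + state$v[[nm]]
    } else if (cfg@optimizer == "rmsprop") {
      state$s[[nm]] <- 0.99 * (state$s[[nm]] %||% 0) + 0.01 * g^2
      par[[nm]] <- par[[nm]] - lr * g / sqrt(state$s[[nm]] + 1e-8)
    } else {  # adam
      state$m[[nm]] <- 0.9 * (state$m[[nm]] %||% 0) + 0.1 * g
      state$s[[nm]] <- 0.999 * (state$s[[nm]] %||% 0) + 0.001 * g^2
      mh <- state$m[[nm]] / (1 - 0.9^t)
      sh <- state$s[[nm]] / (1 - 0.999^t)
      par[[nm]] <- par[[nm]] - lr * mh / (sqrt(sh) + 1e-8)
    }
  }
  list(par = par, state = state)
}

.lossAcc <- function(X, y, par, w = NULL) {
  fw <- .denseForward(X, par)
  p <- fw$P[cbind(seq_along(y), y)]
  wt <- if (is.null(w)) rep(1, length(y)) else w[y]
  list(loss = -sum(wt * log(pmax(p, 1e-12))) / sum(wt),
       acc = mean(max.col(fw$P, ties.method = "first") == y))
}

# fine-tune the dense block + head on cached trunk features
# X*: standardised feature matrices; y*: integer class indices in 1..K
.trainHead <- function(Xtr, ytr, Xva, yva, K, hidden, cfg, trainDense) {
  d <- ncol(Xtr)
  n <- nrow(Xtr)
  set.seed(cfg@seed)
  par <- list(W1 = matrix(rnorm(d * hidden, sd = sqrt(2 / d)), d, hidden),
              b1 = rep(0, hidden),
              W2 = matrix(rnorm(hidden * K, sd = sqrt(1 / hidden)), hidden, K),
              b2 = rep(0, K))
  w <- NULL
  if (cfg@classWeighting) {
    freq <- tabulate(ytr, K)
    w <- sum(freq) / (K * pmax(freq, 1))
  }
  state <- new.env(parent = emptyenv())
  state$m <- list(); state$s <- list(); state$v <- list()
  hasVal <- nrow(Xva) > 0L
  log <- vector("list", cfg@maxEpochs)
  best <- list(metric = -Inf, par = par, epoch = 0L)
  stall <- 0L
  t <- 0L
  for (epoch in seq_len(cfg@maxEpochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg@miniBatchSize)
    for (s in starts) {
      ix <- ord[s:min(s + cfg@miniBatchSize - 1L, n)]
      Xb <- Xtr[ix, , drop = FALSE]
      yb <- ytr[ix]
      fw <- .denseForward(Xb, par)
      Y <- matrix(0, length(ix), K)
      Y[cbind(seq_along(ix), yb)] <- 1
      wt <- if (is.null(w)) rep(1, length(ix)) else w[yb]
      dZ <- (fw$P - Y) * (wt / sum(wt))
      grad <- list(W2 = crossprod(fw$H, dZ), b2 = colSums(dZ))
      if (trainDense) {
        dH <- tcrossprod(dZ, par$W2)
        dH[fw$H <= 0] <- 0
        grad$W1 <- crossprod(Xb, dH)
        grad$b1 <- colSums(dH)
      }
      t <- t + 1L
      upd <- .optimStep(par, grad, state, cfg, t)
      par <- upd$par
    }
    tr <- .lossAcc(Xtr, ytr, par, w)
    if (!is.finite(tr$loss))
      stop("non-finite training loss at epoch ", epoch,
           "; reduce the learning rate")
    va <- if (hasVal) .lossAcc(Xva, yva, par, w) else list(loss = NA_real_, acc = NA_real_)
    log[[epoch]] <- data.frame(epoch = epoch, train_loss = tr$loss,
                               train_accuracy = tr$acc, val_loss = va$loss,
                               val_accuracy = va$acc)
    metric <- if (hasVal) va$acc else tr$acc
    if (metric > best$metric) {
      best <- list(metric = metric, par = par, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg@earlyStoppingPatience) break
    }
  }
  list(par = best$par, bestEpoch = best$epoch,
       log = do.call(rbind, log[!vapply(log, is.null, logical(1))]))
}
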