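# Minimal feed-forward network engine (matrix ops + hand-written backprop +
# Adam), shared by the hybrid and fully-learned regressors.  Two
# architectures:
#
# hybrid:        K split arms (one per fascicle block of NNLS weights)
#                -> concat -> batch norm -> ReLU MLP -> sigmoid outputs.
# fully_learned: per-shell SH coefficients -> shared ReLU trunk -> sigmoid
#                scalar head + orientation head (default: rank-2 orientation
#                tensor, eigenvector extracted at inference; optional direct
#                vector head with softplus-positive z).
#
# Dropout (inverted, retention `keep`) follows every ReLU layer during
# training.  All randomness flows through R's RNG so training is
# reproducible from a seed.

.heMat <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)

.dropoutMask <- function(n, p, keep) {
  if (keep >= 1) return(NULL)
  matrix((runif(n * p) < keep) / keep, n, p)
}

.applyMask <- function(H, mask) if (is.null(mask)) H else H * mask

.initHybridPar <- function(K, N, armWidth, hidden, nOut, shareArms = FALSE) {
  # shareArms is a test-oriented fully-tied configuration: one arm, one
  # batch-norm, one common MLP applied to every fascicle block (outputs are
  # per-fascicle triples), so identical block inputs give identical outputs
  par <- list()
  nArm <- if (shareArms) 1L else K
  for (k in seq_len(nArm)) {
    par[[paste0("armW", k)]] <- .heMat(N, armWidth)
    par[[paste0("armb", k)]] <- numeric(armWidth)
  }
  nbn <- if (shareArms) armWidth else K * armWidth
  par$bnG <- rep(1, nbn); par$bnB <- numeric(nbn)
  sizes <- c(nbn, hidden)
  for (i in seq_along(hidden)) {
    par[[paste0("W", i)]] <- .heMat(sizes[i], sizes[i + 1])
    par[[paste0("b", i)]] <- numeric(sizes[i + 1])
  }
  par$Wo <- .heMat(sizes[length(sizes)], if (shareArms) nOut %/% K else nOut)
  par$bo <- numeric(if (shareArms) nOut %/% K else nOut)
  par
}

.initFlPar <- function(nIn, hidden, nOut, branch = 0, nScal = 0) {
  par <- list()
  sizes <- c(nIn, hidden)
  for (i in seq_along(hidden)) {
    par[[paste0("W", i)]] <- .heMat(sizes[i], sizes[i + 1])
    par[[paste0("b", i)]] <- numeric(sizes[i + 1])
  }
  last <- sizes[length(sizes)]
  if (branch > 0) {
    # separate scalar / orientation head branches off the shared trunk
    par$Ws <- .heMat(last, branch); par$bs <- numeric(branch)
    par$Wu <- .heMat(last, branch); par$bu <- numeric(branch)
    par$Wos <- .heMat(branch, nScal); par$bos <- numeric(nScal)
    par$Wou <- .heMat(branch, nOut - nScal); par$bou <- numeric(nOut - nScal)
  } else {
    par$Wo <- .heMat(last, nOut)
    par$bo <- numeric(nOut)
  }
  par
}

.bnStateInit <- function(n) list(rm = numeric(n), rv = rep(1, n))

# ---- hybrid architecture ---------------------------------------------------

# fully-tied variant: all fascicle blocks pass through one shared pipeline
.hybridForwardShared <- function(par, state, X, K, N, cfg, train = FALSE) {
  keep <- if (train) cfg$keep else 1
  n <- nrow(X)
  Xs <- do.call(rbind, lapply(seq_len(K), function(k)
    X[, (k - 1) * N + seq_len(N), drop = FALSE]))
  f1 <- .denseFwdCpp(Xs, par$armW1, par$armb1, keep, train)
  H0 <- f1$A
  eps <- 1e-5
  if (train) {
    mu <- colMeans(H0)
    va <- colMeans(H0^2) - mu^2
    state$rm <- 0.9 * state$rm + 0.1 * mu
    state$rv <- 0.9 * state$rv + 0.1 * va
  } else { mu <- state$rm; va <- state$rv }
  sdev <- sqrt(va + eps)
  xhat <- sweep(sweep(H0, 2, mu, `-`), 2, sdev, `/`)
  H <- sweep(sweep(xhat, 2, par$bnG, `*`), 2, par$bnB, `+`)
  nH <- length(cfg$hidden)
  masks <- vector("list", nH); act <- vector("list", nH)
  Hin <- H
  for (i in seq_len(nH)) {
    fwi <- .denseFwdCpp(Hin, par[[paste0("W", i)]], par[[paste0("b", i)]],
                        keep, train)
    masks[[i]] <- fwi$M
    act[[i]] <- fwi$A
    Hin <- act[[i]]
  }
  Zo <- Hin %*% par$Wo
  Zo <- Zo + rep(par$bo, each = nrow(Zo))
  O <- .sigmoid(Zo)                      # (K n) x 3 per-fascicle triples
  Y <- matrix(NA_real_, n, 3 * K)
  for (k in seq_len(K))
    Y[, c(k, K + k, 2 * K + k)] <- O[(k - 1) * n + seq_len(n), ]
  list(Y = Y,
       cache = list(Xs = Xs, armMask = f1$M, H0 = H0, xhat = xhat, s = sdev,
                    bnIn = H, masks = masks, act = act, O = O, n = n),
       state = state)
}

.hybridBackwardShared <- function(par, cache, dY, K, N, cfg) {
  g <- list()
  n <- cache$n
  dO <- matrix(NA_real_, K * n, 3)
  for (k in seq_len(K))
    dO[(k - 1) * n + seq_len(n), ] <- dY[, c(k, K + k, 2 * K + k)]
  dZ <- dO * cache$O * (1 - cache$O)
  nH <- length(cfg$hidden)
  Hlast <- if (nH > 0) cache$act[[nH]] else cache$bnIn
  g$Wo <- crossprod(Hlast, dZ)
  g$bo <- colSums(dZ)
  dH <- tcrossprod(dZ, par$Wo)
  for (i in rev(seq_len(nH))) {
    Hin <- if (i > 1) cache$act[[i - 1]] else cache$bnIn
    bw <- .denseBwdCpp(Hin, par[[paste0("W", i)]], cache$masks[[i]], dH)
    g[[paste0("W", i)]] <- bw$dW
    g[[paste0("b", i)]] <- drop(bw$db)
    dH <- bw$dX
  }
  xhat <- cache$xhat; sdev <- cache$s
  g$bnG <- colSums(dH * xhat)
  g$bnB <- colSums(dH)
  dxhat <- sweep(dH, 2, par$bnG, `*`)
  nn <- nrow(dH)
  dH0 <- sweep(dxhat - matrix(colMeans(dxhat), nn, ncol(dxhat), byrow = TRUE) -
                 xhat * matrix(colMeans(dxhat * xhat), nn, ncol(dxhat),
                               byrow = TRUE), 2, sdev, `/`)
  bw <- .denseBwdCpp(cache$Xs, par$armW1, cache$armMask, dH0)
  g$armW1 <- bw$dW
  g$armb1 <- drop(bw$db)
  g
}

.hybridForward <- function(par, state, X, K, N, cfg, train = FALSE) {
  if (isTRUE(cfg$shareArms))
    return(.hybridForwardShared(par, state, X, K, N, cfg, train))
  keep <- if (train) cfg$keep else 1
  arms <- vector("list", K)
  armMask <- vector("list", K)
  for (k in seq_len(K)) {
    fwk <- .denseFwdCpp(X[, (k - 1) * N + seq_len(N), drop = FALSE],
                        par[[paste0("armW", k)]], par[[paste0("armb", k)]],
                        keep, train)
    armMask[[k]] <- fwk$M
    arms[[k]] <- fwk$A
  }
  H0 <- do.call(cbind, arms)
  eps <- 1e-5
  if (train) {
    mu <- colMeans(H0)
    va <- colMeans(H0^2) - mu^2
    state$rm <- 0.9 * state$rm + 0.1 * mu
    state$rv <- 0.9 * state$rv + 0.1 * va
  } else { mu <- state$rm; va <- state$rv }
  s <- sqrt(va + eps)
  xhat <- sweep(sweep(H0, 2, mu, `-`), 2, s, `/`)
  H <- sweep(sweep(xhat, 2, par$bnG, `*`), 2, par$bnB, `+`)
  nH <- length(cfg$hidden)
  masks <- vector("list", nH); act <- vector("list", nH)
  Hin <- H
  for (i in seq_len(nH)) {
    fwi <- .denseFwdCpp(Hin, par[[paste0("W", i)]], par[[paste0("b", i)]],
                        keep, train)
    masks[[i]] <- fwi$M
    act[[i]] <- fwi$A
    Hin <- act[[i]]
  }
  Zo <- Hin %*% par$Wo
  Zo <- Zo + rep(par$bo, each = nrow(Zo))
  Y <- .sigmoid(Zo)
  list(Y = Y,
       cache = list(X = X, armMask = armMask, H0 = H0,
                    xhat = xhat, s = s, bnIn = H, masks = masks,
                    act = act, Y = Y),
       state = state)
}

.hybridBackward <- function(par, cache, dY, K, N, cfg) {
  if (isTRUE(cfg$shareArms))
    return(.hybridBackwardShared(par, cache, dY, K, N, cfg))
  g <- list()
  Y <- cache$Y
  dZ <- dY * Y * (1 - Y)
  nH <- length(cfg$hidden)
  Hlast <- if (nH > 0) cache$act[[nH]] else cache$bnIn
  g$Wo <- crossprod(Hlast, dZ)
  g$bo <- colSums(dZ)
  dH <- tcrossprod(dZ, par$Wo)
  for (i in rev(seq_len(nH))) {
    Hin <- if (i > 1) cache$act[[i - 1]] else cache$bnIn
    bw <- .denseBwdCpp(Hin, par[[paste0("W", i)]], cache$masks[[i]], dH)
    g[[paste0("W", i)]] <- bw$dW
    g[[paste0("b", i)]] <- drop(bw$db)
    dH <- bw$dX
  }
  # batch norm backward
  xhat <- cache$xhat; s <- cache$s
  g$bnG <- colSums(dH * xhat)
  g$bnB <- colSums(dH)
  dxhat <- sweep(dH, 2, par$bnG, `*`)
  n <- nrow(dH)
  dH0 <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dxhat), byrow = TRUE) -
                 xhat * matrix(colMeans(dxhat * xhat), n, ncol(dxhat),
                               byrow = TRUE), 2, s, `/`)
  aw <- ncol(dH0) / K
  for (k in seq_len(K)) {
    Xk <- cache$X[, (k - 1) * N + seq_len(N), drop = FALSE]
    bw <- .denseBwdCpp(Xk, par[[paste0("armW", k)]], cache$armMask[[k]],
                       dH0[, (k - 1) * aw + seq_len(aw), drop = FALSE])
    g[[paste0("armW", k)]] <- bw$dW
    g[[paste0("armb", k)]] <- drop(bw$db)
  }
  g
}

# ---- fully-learned architecture -------------------------------------------

.flForward <- function(par, X, K, cfg, train = FALSE) {
  keep <- if (train) cfg$keep else 1
  nH <- length(cfg$hidden)
  branch <- !is.null(par$Ws)
  masks <- vector("list", nH); act <- vector("list", nH)
  Hin <- X
  for (i in seq_len(nH)) {
    fwi <- .denseFwdCpp(Hin, par[[paste0("W", i)]], par[[paste0("b", i)]],
                        keep, train)
    masks[[i]] <- fwi$M
    act[[i]] <- fwi$A
    Hin <- act[[i]]
  }
  brCache <- NULL
  if (branch) {
    fs <- .denseFwdCpp(Hin, par$Ws, par$bs, keep, train)
    fu <- .denseFwdCpp(Hin, par$Wu, par$bu, keep, train)
    Zs <- fs$A %*% par$Wos
    Zs <- Zs + rep(par$bos, each = nrow(Zs))
    Zu <- fu$A %*% par$Wou
    Zu <- Zu + rep(par$bou, each = nrow(Zu))
    Zo <- cbind(Zs, Zu)
    brCache <- list(Asd = fs$A, ms = fs$M, Aud = fu$A, mu = fu$M)
  } else {
    Zo <- Hin %*% par$Wo
    Zo <- Zo + rep(par$bo, each = nrow(Zo))
  }
  nS <- 3 * K
  S <- .sigmoid(Zo[, seq_len(nS), drop = FALSE])
  Oraw <- Zo[, -seq_len(nS), drop = FALSE]
  tensorHead <- identical(cfg$orientHead, "tensor")
  if (tensorHead) {
    # per fascicle 6 linear outputs: the embedded symmetric rank-2 tensor
    # (xx, yy, zz, sqrt2*xy, sqrt2*xz, sqrt2*yz); the unit orientation is
    # its leading eigenvector (computed at inference, z flipped >= 0)
    U <- NULL
    rho <- NULL
  } else {
    # direct head: (x, y, softplus(z)) normalized -> unit, z > 0
    U <- matrix(NA_real_, nrow(Zo), 3 * K)
    rho <- matrix(NA_real_, nrow(Zo), K)
    for (k in seq_len(K)) {
      i3 <- (k - 1) * 3
      v3 <- .softplus(Oraw[, i3 + 3])
      r <- sqrt(Oraw[, i3 + 1]^2 + Oraw[, i3 + 2]^2 + v3^2)
      rho[, k] <- r
      U[, i3 + 1] <- Oraw[, i3 + 1] / r
      U[, i3 + 2] <- Oraw[, i3 + 2] / r
      U[, i3 + 3] <- v3 / r
    }
  }
  list(S = S, U = U, O = Oraw,
       cache = list(X = X, masks = masks, act = act, S = S,
                    Oraw = Oraw, U = U, rho = rho, br = brCache))
}

# embed a unit vector as the 6-vector whose Euclidean metric equals the
# Frobenius metric on u u^T
.tensorEmbed <- function(U3) {
  s2 <- sqrt(2)
  cbind(U3[, 1]^2, U3[, 2]^2, U3[, 3]^2,
        s2 * U3[, 1] * U3[, 2], s2 * U3[, 1] * U3[, 3],
        s2 * U3[, 2] * U3[, 3])
}

# leading eigenvector of the symmetric matrix encoded by a 6-vector row,
# flipped to the z >= 0 half-sphere
.tensorToUnit <- function(Trow) {
  s2 <- sqrt(2)
  Mx <- matrix(c(Trow[1], Trow[4] / s2, Trow[5] / s2,
                 Trow[4] / s2, Trow[2], Trow[6] / s2,
                 Trow[5] / s2, Trow[6] / s2, Trow[3]), 3, 3)
  v <- eigen(Mx, symmetric = TRUE)$vectors[, 1]
  if (v[3] < 0) v <- -v
  v / sqrt(sum(v^2))
}

.flBackward <- function(par, cache, dS, dU, K, cfg) {
  g <- list()
  S <- cache$S
  nS <- ncol(S)
  dZs <- dS * S * (1 - S)
  if (identical(cfg$orientHead, "tensor")) {
    dZo <- dU                        # linear head: loss gradient passes through
  } else {
  dZo <- matrix(0, nrow(S), 3 * K)
  for (k in seq_len(K)) {
    i3 <- (k - 1) * 3
    u <- cache$U[, i3 + (1:3), drop = FALSE]
    du <- dU[, i3 + (1:3), drop = FALSE]
    r <- cache$rho[, k]
    # through the normalization: dv = (du - u (u . du)) / rho
    dot <- rowSums(u * du)
    dv <- (du - u * dot) / r
    dZo[, i3 + 1] <- dv[, 1]
    dZo[, i3 + 2] <- dv[, 2]
    dZo[, i3 + 3] <- dv[, 3] * .sigmoid(cache$Oraw[, i3 + 3])  # softplus'
  }
  }
  nH <- length(cfg$hidden)
  Hlast <- if (nH > 0) cache$act[[nH]] else cache$X
  if (!is.null(par$Ws)) {
    br <- cache$br
    g$Wos <- crossprod(br$Asd, dZs); g$bos <- colSums(dZs)
    g$Wou <- crossprod(br$Aud, dZo); g$bou <- colSums(dZo)
    bs_ <- .denseBwdCpp(Hlast, par$Ws, br$ms, tcrossprod(dZs, par$Wos))
    bu_ <- .denseBwdCpp(Hlast, par$Wu, br$mu, tcrossprod(dZo, par$Wou))
    g$Ws <- bs_$dW; g$bs <- drop(bs_$db)
    g$Wu <- bu_$dW; g$bu <- drop(bu_$db)
    dH <- bs_$dX + bu_$dX
  } else {
    dZ <- cbind(dZs, dZo)
    g$Wo <- crossprod(Hlast, dZ)
    g$bo <- colSums(dZ)
    dH <- tcrossprod(dZ, par$Wo)
  }
  for (i in rev(seq_len(nH))) {
    Hin <- if (i > 1) cache$act[[i - 1]] else cache$X
    bw <- .denseBwdCpp(Hin, par[[paste0("W", i)]], cache$masks[[i]], dH)
    g[[paste0("W", i)]] <- bw$dW
    g[[paste0("b", i)]] <- drop(bw$db)
    dH <- bw$dX
  }
  g
}

# antipodally symmetric orientation loss 1 - (u_hat . u)^2, averaged over
# voxels and summed over fascicles; returns loss and d/dU
.orientationLoss <- function(U, Utrue, K) {
  n <- nrow(U)
  loss <- 0
  dU <- matrix(0, n, 3 * K)
  for (k in seq_len(K)) {
    i3 <- (k - 1) * 3
    uh <- U[, i3 + (1:3), drop = FALSE]
    ut <- Utrue[, i3 + (1:3), drop = FALSE]
    s <- rowSums(uh * ut)
    loss <- loss + mean(1 - s^2)
    dU[, i3 + (1:3)] <- -2 * (s / n) * ut
  }
  list(loss = loss, dU = dU)
}

# ---- Adam ------------------------------------------------------------------

.adamInit <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0)
}

# deep copy guarding in-place-updated buffers before they leave the loop
.deepCopy <- function(par) lapply(par, function(p) p + 0)

.adamStep <- function(par, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  # buffers are private to the training loop: updated in place in C++
  opt$t <- opt$t + 1
  for (nm in names(grads)) {
    .adamInplaceCpp(par[[nm]], grads[[nm]], opt$m[[nm]], opt$v[[nm]],
                    opt$t, lr, beta1, beta2, eps)
  }
  list(par = par, opt = opt)
}

# ---- shared training loop --------------------------------------------------

# stepFun(par, state, idx, epoch) -> list(loss, grads, state); called per
# minibatch.
.trainLoop <- function(par, state, n, config, seed, stepFun) {
  withSeed(seed, {
    opt <- .adamInit(par)
    lossHist <- numeric(config$epochs)
    decay <- if (is.null(config$lrDecay)) 1 else config$lrDecay
    for (ep in seq_len(config$epochs)) {
      lrEp <- config$lr * decay^(ep - 1)
      perm <- sample.int(n)
      tot <- 0; nb <- 0
      for (start in seq(1, n, by = config$batch)) {
        idx <- perm[start:min(start + config$batch - 1, n)]
        st <- stepFun(par, state, idx, ep)
        state <- st$state
        res <- .adamStep(par, st$grads, opt, lrEp)
        par <- res$par; opt <- res$opt
        tot <- tot + st$loss; nb <- nb + 1
      }
      lossHist[ep] <- tot / nb
    }
    list(par = .deepCopy(par), state = state, lossHist = lossHist)
  })
}

# feature standardization (stored with the model; zero-variance columns are
# left unscaled)
.featStats <- function(X) {
  mu <- colMeans(X)
  sd_ <- sqrt(pmax(colMeans(X^2) - mu^2, 0))
  sd_[sd_ < 1e-10] <- 1
  list(mu = mu, sd = sd_)
}
.standardize <- function(X, st) sweep(sweep(X, 2, st$mu, `-`), 2, st$sd, `/`)
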