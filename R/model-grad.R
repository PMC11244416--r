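# Reference (double-precision, plain R) batch forward/backward.
#
# This is the semantic definition of the network's training-time
# computation: the fused compiled path used by fitModel() is tested
# against it. Batch normalisation uses biased batch variance with
# eps = 1e-5; dropout is inverted (kept units scaled by 1/(1-q)).

bnEps <- 1e-5

refBatchForward <- function(params, cfg, Slist, training = TRUE,
                            dropMasks = NULL) {
  B <- length(Slist)
  K <- cfg@K; l <- cfg@l
  Ds <- vector("list", B)
  caches <- vector("list", B)
  for (s in seq_len(B)) {
    S <- Slist[[s]]
    cache <- list()
    if (cfg@variant == "masked") {
      E <- featureConv(S, params$Wf, params$bf)
      Ep <- channelGAP(E)
      L <- extractSegment(Ep, cfg@P, cfg@l)
      Lm <- matrix(L[, 1L, ], nrow = K)
      cat2 <- cbind(Lm, params$W)
      z1 <- cat2 %*% t(params$Wm1) + rep(params$bm1, each = K)   # K x l
      z2 <- as.numeric(z1 %*% params$Wm2 + params$bm2)           # K
      r <- sigmoid(z2)
      M <- softMask(r, l, cfg@lambda)
      Wv <- params$W * M
      cache <- list(cat2 = cat2, z1 = z1, r = r, M = M)
    } else {
      Wv <- params$W
    }
    Spad <- padInput(S, l)
    Ds[[s]] <- dynamicConv(Spad, Wv, params$bv)
    cache$Spad <- Spad
    cache$Sbar <- colMeans(S)
    caches[[s]] <- cache
  }
  flat <- vapply(Ds, function(D) matrix(D, nrow = K), matrix(0, K, length(Ds[[1]]) / K))
  # flat: K x (C*T) x B
  if (training) {
    mu <- apply(flat, 1L, mean)
    v <- apply(flat, 1L, function(x) mean(x^2)) - mu^2
  } else {
    mu <- params$runMean; v <- params$runVar
  }
  inv <- 1 / sqrt(v + bnEps)
  logits <- numeric(B)
  zs <- vector("list", B); xh <- vector("list", B)
  wK <- matrix(params$w, nrow = K)
  for (s in seq_len(B)) {
    xhat <- (matrix(flat[, , s], nrow = K) - mu) * inv
    z <- params$gamma * xhat + params$beta
    if (training && cfg@dropoutRate > 0) {
      dm <- matrix(dropMasks[[s]], nrow = K)
      z <- z * dm / (1 - cfg@dropoutRate)
    }
    xh[[s]] <- xhat; zs[[s]] <- z
    logits[s] <- sum(wK * z) + params$b
  }
  list(logits = logits, Ds = Ds, caches = caches, mu = mu, v = v, inv = inv,
       xhat = xh, z = zs)
}

refBatchLoss <- function(params, cfg, Slist, y, posWeight = 1,
                         training = TRUE, dropMasks = NULL) {
  fw <- refBatchForward(params, cfg, Slist, training, dropMasks)
  weightedBCE(fw$logits, y, posWeight)
}

refBatchGrad <- function(params, cfg, Slist, y, posWeight = 1,
                         dropMasks = NULL) {
  B <- length(Slist)
  K <- cfg@K; l <- cfg@l; lam <- cfg@lambda
  C <- nrow(Slist[[1L]]); T <- ncol(Slist[[1L]])
  fw <- refBatchForward(params, cfg, Slist, training = TRUE, dropMasks)
  p <- sigmoid(fw$logits)
  gY <- (p * (posWeight * y + 1 - y) - posWeight * y) / B

  wK <- matrix(params$w, nrow = K)
  N <- B * C * T
  g <- list(Wf = params$Wf * 0, bf = numeric(K), W = params$W * 0,
            bv = numeric(K), Wm1 = params$Wm1 * 0, bm1 = numeric(l),
            Wm2 = numeric(l), bm2 = 0, gamma = numeric(K), beta = numeric(K),
            w = array(0, dim(params$w)), b = 0)

  # classifier + dropout backward -> dz per sample; BN stats accumulated
  dzs <- vector("list", B)
  for (s in seq_len(B)) {
    g$w <- g$w + array(gY[s] * fw$z[[s]], dim(params$w))
    g$b <- g$b + gY[s]
    dz <- gY[s] * wK
    if (cfg@dropoutRate > 0) {
      dm <- matrix(dropMasks[[s]], nrow = K)
      dz <- dz * dm / (1 - cfg@dropoutRate)
    }
    dzs[[s]] <- dz
  }
  sum_dxh <- numeric(K); sum_dxh_xh <- numeric(K)
  for (s in seq_len(B)) {
    dxh <- dzs[[s]] * params$gamma
    g$gamma <- g$gamma + rowSums(dzs[[s]] * fw$xhat[[s]])
    g$beta <- g$beta + rowSums(dzs[[s]])
    sum_dxh <- sum_dxh + rowSums(dxh)
    sum_dxh_xh <- sum_dxh_xh + rowSums(dxh * fw$xhat[[s]])
  }
  idx <- outer(seq_len(T), 0:(l - 1L), `+`)
  h <- (cfg@featureKernelWidth - 1L) %/% 2L
  for (s in seq_len(B)) {
    dxh <- dzs[[s]] * params$gamma
    dD <- fw$inv * (dxh - sum_dxh / N - fw$xhat[[s]] * (sum_dxh_xh / N))
    g$bv <- g$bv + rowSums(dD)
    # per-sample kernel gradient: dWv[k, p] = sum_{c,t} dD[k, (c,t)] * Spad[c, t+p-1]
    Spad <- fw$caches[[s]]$Spad
    dWv <- matrix(0, K, l)
    for (ch in seq_len(C)) {
      H <- Spad[ch, ][idx]; dim(H) <- c(T, l)
      dDk <- matrix(dD[, seq(ch, by = C, length.out = T)], nrow = K)
      dWv <- dWv + dDk %*% H
    }
    if (cfg@variant == "masked") {
      ca <- fw$caches[[s]]
      g$W <- g$W + dWv * ca$M
      dM <- dWv * params$W
      dli <- rowSums(dM * lam * ca$M * (1 - ca$M))
      dz2 <- dli * l * ca$r * (1 - ca$r)
      g$Wm2 <- g$Wm2 + as.numeric(t(ca$z1) %*% dz2)
      g$bm2 <- g$bm2 + sum(dz2)
      dz1 <- outer(dz2, params$Wm2)                 # K x l
      g$Wm1 <- g$Wm1 + t(dz1) %*% ca$cat2
      g$bm1 <- g$bm1 + colSums(dz1)
      dcat <- dz1 %*% params$Wm1                    # K x 2l
      g$W <- g$W + dcat[, (l + 1L):(2L * l), drop = FALSE]
      dL <- dcat[, seq_len(l), drop = FALSE]
      # back through segment slice, GAP and feature conv
      dEp <- matrix(0, K, T)
      dEp[, (cfg@P + 1L):(cfg@P + l)] <- dL
      Sbarpad <- c(rep(0, h), ca$Sbar, rep(0, h))
      for (u in seq_len(cfg@featureKernelWidth)) {
        g$Wf[, u] <- g$Wf[, u] + dEp %*% Sbarpad[u:(u + T - 1L)]
      }
      g$bf <- g$bf + rowSums(dEp)
    } else {
      g$W <- g$W + dWv
    }
  }
  list(loss = weightedBCE(fw$logits, y, posWeight), logits = fw$logits,
       grads = g, batchMean = fw$mu, batchVar = fw$v)
}
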