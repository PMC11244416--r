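test_that("feature convolution matches the direct-sum oracle", {
  S <- matrix(c(1, 2, 3, 4, 5), 1, 5)
  # identity kernel reproduces the input
  E <- featureConv(S, matrix(c(0, 1, 0), 1, 3))
  expect_equal(E[1, 1, ], as.numeric(S))
  # left-aligned kernel against the brute-force oracle
  E2 <- featureConv(S, matrix(c(1, 0, 0), 1, 3))
  expect_equal(E2[1, 1, ], bruteSameConv(as.numeric(S), c(1, 0, 0)))
  # random filters, several channels
  set.seed(2)
  S3 <- matrix(rnorm(4 * 20), 4, 20)
  Wf <- matrix(rnorm(2 * 3), 2, 3)
  bf <- c(0.3, -0.1)
  E3 <- featureConv(S3, Wf, bf)
  expect_equal(dim(E3), c(2, 4, 20))
  for (k in 1:2) for (ch in 1:4)
    expect_equal(E3[k, ch, ], bruteSameConv(S3[ch, ], Wf[k, ]) + bf[k])
})

test_that("channel pooling averages channels and keeps shape", {
  E <- array(0, c(2, 3, 4))
  E[1, , ] <- 7                       # constant channels pool to the constant
  E[2, 1, ] <- 1; E[2, 2, ] <- 3; E[2, 3, ] <- 5
  Ep <- channelGAP(E)
  expect_equal(dim(Ep), c(2, 1, 4))
  expect_true(all(Ep[1, 1, ] == 7))
  expect_true(all(Ep[2, 1, ] == 3))
})

test_that("segment extraction uses 0-based half-open slice semantics", {
  Ep <- array(rep(0:9, each = 1), c(1, 1, 10))
  L <- extractSegment(Ep, P = 4, l = 3)
  expect_equal(as.numeric(L), c(4, 5, 6))
  expect_equal(extractSegment(Ep, 0, 10), Ep)
  expect_error(extractSegment(Ep, 8, 5), "out of range")
})

test_that("mask ratio follows the two fully connected layers and sigmoid", {
  l <- 2; K <- 2
  L <- matrix(c(0.5, -1, 2, 0.25), K, l)
  W <- matrix(c(1, -0.5, 0, 2), K, l)
  # all-zero fc weights give r = sigmoid(0) = 0.5
  r0 <- maskRatio(L, W, matrix(0, l, 2 * l), rep(0, l), rep(0, l), 0)
  expect_equal(r0, c(0.5, 0.5))
  # raising the final bias raises every ratio (sigmoid monotone)
  rUp <- maskRatio(L, W, matrix(0, l, 2 * l), rep(0, l), rep(0, l), 1)
  expect_true(all(rUp > r0))
  # hand computation through the fc pair for scale 1:
  # cat = (0.5, 2, 1, 0), z1 = Wm1 cat + bm1, r = sigmoid(Wm2 z1 + bm2)
  Wm1 <- matrix(c(0.1, -0.2, 0.3, 0.4,
                  0.5, 0.6, -0.7, 0.8), nrow = l, byrow = TRUE)
  bm1 <- c(0.05, -0.05)
  Wm2 <- c(1.5, -2); bm2 <- 0.2
  cat1 <- c(L[1, ], W[1, ])
  z1 <- as.numeric(Wm1 %*% cat1) + bm1
  rHand <- 1 / (1 + exp(-(sum(Wm2 * z1) + bm2)))
  r <- maskRatio(L, W, Wm1, bm1, Wm2, bm2)
  expect_equal(r[1], rHand, tolerance = 1e-12)
  expect_true(all(r > 0 & r < 1))
})

test_that("soft masks are strictly decreasing sigmoid ramps", {
  M <- softMask(r = c(0.5, 0.35), l = 10, lambda = 5)
  expect_equal(dim(M), c(2, 10))
  # at j = l_i the entry is sigmoid(0) = 0.5 exactly
  expect_identical(M[1, 5], 0.5)
  # one step before the cut: sigmoid(lambda * 1)
  expect_equal(M[1, 4], 1 / (1 + exp(-5)), tolerance = 1e-12)
  expect_true(all(diff(M[1, ]) < 0))
  expect_true(all(diff(M[2, ]) < 0))
  expect_true(all(M > 0 & M < 1))
  # large lambda approaches a hard cutoff at l_i = 3.5
  Mh <- softMask(0.35, 10, 1000)
  expect_true(all(abs(Mh[1, 1:3] - 1) < 1e-6))
  expect_true(all(Mh[1, 4:10] < 1e-6))
})

test_that("kernel masking is elementwise with shape checks", {
  W <- matrix(2, 2, 3); M <- matrix(0.25, 2, 3)
  expect_equal(maskedKernels(W, M), matrix(0.5, 2, 3))
  expect_equal(maskedKernels(W, matrix(1, 2, 3)), W)
  expect_true(all(maskedKernels(W, matrix(0, 2, 3)) == 0))
  expect_error(maskedKernels(W, matrix(1, 3, 2)), "identical dimensions")
})

test_that("padding appends exactly l zeros per channel", {
  S <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3)
  P <- padInput(S, 2)
  expect_equal(dim(P), c(2, 5))
  expect_equal(P[, 1:3], S)
  expect_true(all(P[, 4:5] == 0))
})

test_that("dynamic convolution matches delta-kernel and brute-force oracles", {
  set.seed(5)
  C <- 3; T <- 15; l <- 4; K <- 2
  S <- matrix(rnorm(C * T), C, T)
  Spad <- padInput(S, l)
  # delta kernel reproduces each channel
  delta <- matrix(rep(c(1, 0, 0, 0), each = 1), 1, l)
  D <- dynamicConv(Spad, delta)
  for (ch in seq_len(C)) expect_equal(D[1, ch, ], S[ch, ])
  # all-zero kernel with bias returns the bias
  D0 <- dynamicConv(Spad, matrix(0, 1, l), bv = 2.5)
  expect_true(all(D0 == 2.5))
  # random kernels against the brute-force valid convolution
  Wv <- matrix(rnorm(K * l), K, l)
  bv <- c(0.1, -0.2)
  Dr <- dynamicConv(Spad, Wv, bv)
  expect_equal(dim(Dr), c(K, C, T))
  for (k in seq_len(K)) for (ch in seq_len(C))
    expect_equal(Dr[k, ch, ], bruteValidConv(Spad[ch, ], Wv[k, ], T) + bv[k])
  expect_error(dynamicConv(matrix(0, 2, 3), matrix(0, 1, 5)), "too long")
})

test_that("a hard binary mask equals convolution with the truncated kernel", {
  set.seed(6)
  C <- 2; T <- 12; l <- 5
  S <- matrix(rnorm(C * T), C, T)
  W <- matrix(rnorm(l), 1, l)
  hard <- matrix(c(1, 1, 1, 0, 0), 1, l)
  D <- dynamicConv(padInput(S, l), maskedKernels(W, hard))
  for (ch in seq_len(C))
    expect_equal(D[1, ch, ],
                 bruteValidConv(padInput(S, 3)[ch, ], W[1, 1:3], T))
})

test_that("classification head is affine and deterministic in eval mode", {
  set.seed(7)
  cfg <- tinyConfig()
  C <- 4; T <- 60
  m <- newModel(cfg, C, T, seed = 1)
  D1 <- array(rnorm(cfg@K * C * T), c(cfg@K, C, T))
  D2 <- array(rnorm(cfg@K * C * T), c(cfg@K, C, T))
  # zero classifier weight gives the bias
  p0 <- m@params; p0$w[] <- 0; p0$b <- 1.25
  expect_equal(classifyHead(D1, p0), 1.25)
  # determinism in evaluation mode
  expect_identical(classifyHead(D1, m@params), classifyHead(D1, m@params))
  # affinity in D with frozen statistics, dropout off
  a <- 0.3
  y1 <- classifyHead(D1, m@params); y2 <- classifyHead(D2, m@params)
  yc <- classifyHead(a * D1 + (1 - a) * D2, m@params)
  expect_equal(yc, a * y1 + (1 - a) * y2, tolerance = 1e-9)
})

test_that("forward trace fields have the contracted shapes", {
  es <- tinySim(seed = 3)
  cfg <- tinyConfig()
  m <- newModel(cfg, nChannels(es), nTimes(es), seed = 2)
  S <- t(epochData(es)[, , 1])
  out <- dynForward(m, S)
  K <- cfg@K; C <- nChannels(es); T <- nTimes(es); l <- cfg@l
  expect_equal(dim(out$trace$E), c(K, C, T))
  expect_equal(dim(out$trace$Epooled), c(K, 1, T))
  expect_equal(dim(out$trace$L), c(K, 1, l))
  expect_equal(dim(out$trace$Wv), c(K, l))
  expect_equal(dim(out$trace$Spad), c(C, T + l))
  expect_equal(dim(out$trace$D), c(K, C, T))
  expect_true(all(vapply(out$trace, function(x) all(is.finite(x)), logical(1))))
  expect_true(all(out$maskDiagnostics$r > 0 & out$maskDiagnostics$r < 1))
  expect_true(all(out$maskDiagnostics$li > 0 & out$maskDiagnostics$li < l))
  expect_true(all(apply(out$maskDiagnostics$M, 1, function(x) all(diff(x) < 0))))
  expect_error(dynForward(m, S[1:2, ]), "built for")
})

test_that("standard variant ignores the mask generator entirely", {
  es <- tinySim(seed = 4)
  cfg <- tinyConfig(variant = "standard")
  m <- newModel(cfg, nChannels(es), nTimes(es), seed = 2)
  S <- t(epochData(es)[, , 1])
  y0 <- dynForward(m, S)$logit
  m2 <- m
  m2@params$Wm1 <- m2@params$Wm1 + 5
  m2@params$Wm2 <- m2@params$Wm2 - 3
  m2@params$bm2 <- 10
  expect_identical(dynForward(m2, S)$logit, y0)
  expect_null(dynForward(m, S)$maskDiagnostics)
})

test_that("forcing r toward 1 approaches the full-length-kernel model", {
  # With the mask generator saturated (large positive bm2) the soft mask
  # tends to sigmoid(lambda(l - j)): all ones except a half-weighted
  # final tap, so the convolution output approaches the unmasked model's
  # up to that residual (magnitude ~ |W_l| / ||W||).
  set.seed(31)
  C <- 3; T <- 200; l <- 64; K <- 2
  cfg <- modelConfig(K = K, l = l, P = 100, lambda = 50, dropoutRate = 0)
  m <- newModel(cfg, C, T, seed = 3)
  S <- matrix(rnorm(C * T), C, T)
  Spad <- padInput(S, l)
  Dstd <- dynamicConv(Spad, m@params$W, m@params$bv)
  gap <- function(b) {
    mm <- m; mm@params$bm2 <- b
    Dm <- dynForward(mm, S)$trace$D
    sqrt(sum((Dm - Dstd)^2) / sum(Dstd^2))
  }
  g0 <- gap(0); gInf <- gap(30)
  expect_lt(gInf, g0)
  expect_lt(gInf, 0.15)
})

test_that("checkpoints round-trip bit-exactly", {
  cfg <- tinyConfig()
  m <- newModel(cfg, 4, 120, seed = 6)
  path <- tempfile(fileext = ".rds")
  saveCheckpoint(m, path)
  back <- loadCheckpoint(path)
  expect_identical(back@params, m@params)
  expect_equal(back@config@K, cfg@K)
  expect_equal(back@config@variant, cfg@variant)
  expect_error(loadCheckpoint(tempfile()), "no such checkpoint")
  bad <- readRDS(path); bad$params <- NULL
  p2 <- tempfile(fileext = ".rds"); saveRDS(bad, p2)
  expect_error(loadCheckpoint(p2), "params")
})
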