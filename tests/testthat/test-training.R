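test_that("weighted cross-entropy matches closed forms", {
  expect_equal(weightedBCE(0, 0, 4), log(2), tolerance = 1e-12)
  expect_equal(weightedBCE(0, 1, 4), 4 * log(2), tolerance = 1e-12)
  set.seed(10)
  z <- rnorm(20); y <- rbinom(20, 1, 0.3)
  plain <- -mean(y * log(plogis(z)) + (1 - y) * log(1 - plogis(z)))
  expect_equal(weightedBCE(z, y, 1), plain, tolerance = 1e-10)
  expect_gte(weightedBCE(z, y, 4), 0)
  expect_error(weightedBCE(numeric(0), numeric(0), 1), "empty batch")
})

test_that("loss is monotone in the logit in the expected direction", {
  grid <- seq(-4, 4, by = 0.25)
  lossPos <- vapply(grid, function(z) weightedBCE(z, 1, 4), numeric(1))
  lossNeg <- vapply(grid, function(z) weightedBCE(z, 0, 4), numeric(1))
  expect_true(all(diff(lossPos) < 0))   # decreasing for label 1
  expect_true(all(diff(lossNeg) > 0))   # increasing for label 0
})

test_that("compiled batch step reproduces the reference implementation", {
  set.seed(21)
  es <- tinySim(seed = 21, nSubjects = 2, trialsPerSubject = 8)
  for (variant in c("masked", "standard")) {
    cfg <- tinyConfig(variant = variant)
    m <- newModel(cfg, nChannels(es), nTimes(es), seed = 4)
    idx <- 1:6
    Slist <- lapply(idx, function(i) t(epochData(es)[, , i]))
    y <- epochLabels(es)[idx]
    ref <- DynMaskERP:::refBatchGrad(m@params, cfg, Slist, y, posWeight = 4)
    xp <- DynMaskERP:::.packEpochs(as.numeric(epochData(es)), dim(epochData(es)),
                                   cfg@l, 1L)
    st <- DynMaskERP:::.batchStep(xp, idx, as.numeric(y), m@params,
                                  DynMaskERP:::cfgList(cfg), 4, 99)
    expect_equal(st$loss, ref$loss, tolerance = 1e-5)
    expect_equal(st$logits, ref$logits, tolerance = 1e-4)
    expect_equal(st$batchMean, ref$batchMean, tolerance = 1e-5)
    expect_equal(st$batchVar, ref$batchVar, tolerance = 1e-5)
    for (nm in names(ref$grads)) {
      a <- as.numeric(ref$grads[[nm]]); b <- as.numeric(st$grads[[nm]])
      # mixed criterion: relative on sizeable gradients, absolute floor
      # for analytically-zero ones (bv vanishes under batch norm)
      expect_lt(max(abs(a - b)), max(1e-3 * max(abs(a)), 5e-5))
    }
  }
})

test_that("evaluation logits agree between compiled and reference paths", {
  es <- tinySim(seed = 22)
  cfg <- tinyConfig()
  m <- newModel(cfg, nChannels(es), nTimes(es), seed = 5)
  pred <- predictEpochs(m, es)
  for (i in c(1, 5, 9)) {
    ref <- dynForward(m, t(epochData(es)[, , i]))$logit
    expect_equal(qlogis(pred$scores[i]), ref, tolerance = 1e-4)
  }
  expect_true(all(pred$scores > 0 & pred$scores < 1))
})

test_that("training reduces loss on separable data and is seed-reproducible", {
  es <- simulateEpochs(syntheticSpec(
    nSubjects = 3, trialsPerSubject = 10, nChannels = 4, nTimes = 120,
    p300Window = c(40, 80), p300Latency = 60,
    n200Window = c(10, 35), n200Latency = 22,
    noiseSd = 0, seed = 12))
  cfg <- tinyConfig()
  tc <- trainConfig(epochs = 20L, batchSize = 8L, learningRate = 1e-4,
                    seed = 2L)
  m <- fitModel(es, cfg, tc)
  expect_true(m@trained)
  expect_equal(nrow(m@history), 20)
  expect_true(all(is.finite(m@history$trainLoss)))
  expect_lt(tail(m@history$trainLoss, 1), m@history$trainLoss[1])
  m2 <- fitModel(es, cfg, tc)
  expect_identical(m@history, m2@history)
  expect_identical(m@params, m2@params)
})

test_that("fit validates its inputs", {
  es <- tinySim(seed = 13)
  onlyNeg <- es[epochLabels(es) == 0]
  expect_error(fitModel(onlyNeg, tinyConfig(), trainConfig(epochs = 1L)),
               "single class")
  empty <- es[integer(0)]
  expect_error(fitModel(empty, tinyConfig(), trainConfig(epochs = 1L)))
})

test_that("validation loss is recorded when a validation set is given", {
  es <- tinySim(seed = 14)
  sp <- splitBySubject(es, trainFraction = 0.75, nFolds = 1, seed = 1)[[1]]
  m <- fitModel(sp$train, tinyConfig(),
                trainConfig(epochs = 3L, batchSize = 8L, seed = 3L),
                validation = sp$test)
  expect_true(all(is.finite(m@history$valLoss)))
})

test_that("prediction applies the threshold with ties classified positive", {
  es <- tinySim(seed = 15)
  cfg <- tinyConfig()
  m <- newModel(cfg, nChannels(es), nTimes(es), seed = 7)
  pred <- predictEpochs(m, es, threshold = 0.5)
  expect_equal(pred$labels, as.integer(pred$scores >= 0.5))
  # scores 0.7 / 0.3 against threshold 0.5; exact tie goes positive
  expect_equal(as.integer(c(0.7, 0.3) >= 0.5), c(1L, 0L))
  expect_equal(as.integer(0.5 >= 0.5), 1L)
  # threshold sweeps move monotonically
  p2 <- predictEpochs(m, es, threshold = 0.9)
  expect_true(all(p2$labels <= pred$labels))
  single <- predictEpochs(m, es[1])
  expect_length(single$scores, 1)
  wrongDims <- tinySim(seed = 15, C = 3)
  expect_error(predictEpochs(m, wrongDims), "do not match")
})

test_that("dropout masks differ across steps but respect the seed", {
  es <- tinySim(seed = 16)
  cfg <- modelConfig(K = 3, l = 12, P = 30, dropoutRate = 0.5)
  tc <- trainConfig(epochs = 2L, batchSize = 8L, seed = 9L)
  m1 <- fitModel(es, cfg, tc)
  m2 <- fitModel(es, cfg, tc)
  expect_identical(m1@history, m2@history)
  tc2 <- trainConfig(epochs = 2L, batchSize = 8L, seed = 10L)
  m3 <- fitModel(es, cfg, tc2)
  expect_false(identical(m1@history$trainLoss, m3@history$trainLoss))
})
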