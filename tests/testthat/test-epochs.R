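test_that("EpochSet validity catches malformed containers", {
  arr <- array(rnorm(20 * 2 * 3), c(20, 2, 3))
  es <- EpochSet(arr, labels = c(1, 0, 0), subjectIds = c(1, 1, 2))
  expect_s4_class(es, "EpochSet")
  expect_equal(nTrials(es), 3)
  expect_equal(nChannels(es), 2)
  expect_equal(nTimes(es), 20)
  expect_error(EpochSet(arr, labels = c(2, 0, 0), subjectIds = c(1, 1, 2)),
               "labels")
  expect_error(EpochSet(arr, labels = c(1, 0), subjectIds = c(1, 1, 2)),
               "labels")
  arr2 <- arr; arr2[1] <- NA
  expect_error(EpochSet(arr2, labels = c(1, 0, 0), subjectIds = c(1, 1, 2)),
               "finite")
  expect_error(EpochSet(arr, labels = c(1, 0, 0), subjectIds = c(1, 1, 2),
                        samplingRate = -1), "samplingRate")
})

test_that("trial subsetting and binding preserve metadata", {
  es <- tinyEpochs()
  sub <- es[es@subjectIds == 2]
  expect_equal(nTrials(sub), 6)
  expect_true(all(subjectIds(sub) == 2))
  expect_equal(epochData(sub)[, , 1], epochData(es)[, , 7])
  both <- bindEpochs(sub, es[1:2])
  expect_equal(nTrials(both), 8)
  expect_equal(epochLabels(both), c(epochLabels(sub), epochLabels(es)[1:2]))
})

test_that("simulated class counts realise the CTP imbalance per subject", {
  es <- simulateEpochs(syntheticSpec(nSubjects = 2, trialsPerSubject = 50,
                                     imbalanceRatio = 4, nChannels = 3,
                                     nTimes = 300, seed = 2,
                                     p300Window = c(90, 180),
                                     p300Latency = 130,
                                     n200Window = c(40, 80), n200Latency = 60))
  expect_equal(nTrials(es), 100)
  expect_equal(sum(epochLabels(es) == 1), 20)
  expect_equal(sum(epochLabels(es) == 0), 80)
  for (s in 1:2)
    expect_equal(sum(epochLabels(es)[subjectIds(es) == s]), 10)
  expect_error(
    simulateEpochs(syntheticSpec(nSubjects = 1, trialsPerSubject = 3,
                                 imbalanceRatio = 4)),
    "imbalanceRatio")
})

test_that("noise-free positives peak at the subject amplitude on Pz", {
  spec <- syntheticSpec(nSubjects = 3, trialsPerSubject = 10, nChannels = 4,
                        nTimes = 800, noiseSd = 0, seed = 9)
  es <- simulateEpochs(spec)
  pz <- which(channelNames(es) == "Pz")
  tMs <- timesMs(es)
  for (s in 1:3) {
    pos <- which(subjectIds(es) == s & epochLabels(es) == 1)
    tr <- epochData(es)[, pz, pos[1]]
    peakT <- tMs[which.max(tr)]
    # the peak value is the subject amplitude (topography gain 1 at Pz)
    expect_gt(max(tr), 0)
    expect_true(peakT >= spec@p300Window[1] && peakT <= spec@p300Window[2])
    # identical construction for every positive trial of the subject
    expect_equal(epochData(es)[, pz, pos[2]], tr)
  }
})

test_that("noise-free difference wave is positive in both component windows", {
  # self-face trials add a positivity in the P300 window; stranger-face
  # trials add a negativity in the N200 window, so the positive-minus-
  # negative difference is >= 0 everywhere and strictly positive inside
  # both windows
  spec <- syntheticSpec(nSubjects = 4, trialsPerSubject = 10, nChannels = 3,
                        nTimes = 700, noiseSd = 0, seed = 4)
  es <- simulateEpochs(spec)
  pz <- which(channelNames(es) == "Pz")
  diffw <- rowMeans(epochData(es)[, pz, epochLabels(es) == 1]) -
    rowMeans(epochData(es)[, pz, epochLabels(es) == 0])
  expect_true(all(diffw >= -1e-12))
  tMs <- timesMs(es)
  inP3 <- tMs > spec@p300Window[1] & tMs < spec@p300Window[2]
  expect_gt(max(diffw[inP3]), 1)
  # grand-average difference peaks inside the P300 window
  expect_true(tMs[which.max(diffw)] >= spec@p300Window[1] &&
              tMs[which.max(diffw)] <= spec@p300Window[2])
})

test_that("difference wave peaks inside the P300 window under noise", {
  es <- simulateEpochs(syntheticSpec(seed = 1))
  pz <- which(channelNames(es) == "Pz")
  diffw <- rowMeans(epochData(es)[, pz, epochLabels(es) == 1]) -
    rowMeans(epochData(es)[, pz, epochLabels(es) == 0])
  tPeak <- timesMs(es)[which.max(diffw)]
  expect_true(tPeak >= 300 && tPeak <= 500)
})

test_that("1/f-shaped noise preserves the marginal variance", {
  set.seed(8)
  x <- DynMaskERP:::noiseMatrix(2048, 40, sd = 2, beta = 1)
  expect_equal(sd(as.numeric(x)), 2, tolerance = 0.1)
  # low-frequency power dominates under beta > 0
  sp <- Mod(stats::mvfft(x))^2
  expect_gt(mean(sp[2:20, ]), mean(sp[200:400, ]))
})

test_that("block averaging is stratified, mean-preserving and SNR-raising", {
  es <- tinyEpochs(nSubj = 2, perSubj = 8)
  expect_identical(averageBlocks(es, 1), es)

  # a group of identical trials averages to any member
  arr <- array(rep(epochData(es)[, , 1], 4), c(30, 2, 4))
  same <- EpochSet(arr, labels = rep(1, 4), subjectIds = rep(1, 4),
                   samplingRate = 1000)
  av <- averageBlocks(same, 4)
  expect_equal(nTrials(av), 1)
  expect_equal(epochData(av)[, , 1], epochData(es)[, , 1])

  # x and -x average to zero
  arr2 <- array(c(arr[, , 1], -arr[, , 1]), c(30, 2, 2))
  pm <- EpochSet(arr2, labels = c(0, 0), subjectIds = c(1, 1),
                 samplingRate = 1000)
  expect_equal(max(abs(epochData(averageBlocks(pm, 2)))), 0)

  # group size exceeding all strata errors
  expect_error(averageBlocks(es, 100), "stratum")

  # i.i.d. noise: averaging 4 epochs halves the sd (Monte-Carlo)
  set.seed(33)
  n <- 1000
  noise <- EpochSet(array(rnorm(50 * 1 * n), c(50, 1, n)),
                    labels = rep(0, n), subjectIds = rep(1, n),
                    samplingRate = 1000)
  av4 <- averageBlocks(noise, 4)
  expect_equal(nTrials(av4), 250)
  expect_equal(sd(as.numeric(epochData(av4))), 0.5, tolerance = 0.05)
})

test_that("subject-disjoint splits partition whole subjects", {
  es <- tinyEpochs(nSubj = 10, perSubj = 4)
  sp <- splitBySubject(es, trainFraction = 0.9, nFolds = 1, seed = 3)
  expect_length(sp, 1)
  expect_equal(length(unique(subjectIds(sp[[1]]$train))), 9)
  expect_equal(length(unique(subjectIds(sp[[1]]$test))), 1)
  expect_length(intersect(subjectIds(sp[[1]]$train), subjectIds(sp[[1]]$test)), 0)

  es9 <- tinyEpochs(nSubj = 9, perSubj = 4)
  cv <- splitBySubject(es9, nFolds = 3, seed = 5)
  testSets <- lapply(cv, function(f) sort(unique(subjectIds(f$test))))
  expect_true(all(lengths(testSets) == 3))
  expect_equal(sort(unlist(testSets)), 1:9)   # disjoint, exhaustive
  for (f in cv)
    expect_length(intersect(subjectIds(f$train), subjectIds(f$test)), 0)
  expect_error(splitBySubject(es9, nFolds = 10), "nFolds")
})

test_that("split assignment is invariant to trial order", {
  es <- tinyEpochs(nSubj = 6, perSubj = 5, seed = 2)
  perm <- sample(nTrials(es))
  esPerm <- es[perm]
  a <- splitBySubject(es, nFolds = 3, seed = 7)
  b <- splitBySubject(esPerm, nFolds = 3, seed = 7)
  for (f in 1:3)
    expect_equal(sort(unique(subjectIds(a[[f]]$test))),
                 sort(unique(subjectIds(b[[f]]$test))))
})

test_that("epoch containers round-trip exactly and fail loudly", {
  es <- tinyEpochs(nSubj = 2, perSubj = 3)
  path <- tempfile(fileext = ".rds")
  saveEpochs(es, path)
  back <- loadEpochs(path)
  expect_identical(epochData(back), epochData(es))
  expect_identical(epochLabels(back), epochLabels(es))
  expect_true(is.integer(epochLabels(back)))
  expect_identical(subjectIds(back), subjectIds(es))
  expect_identical(channelNames(back), channelNames(es))
  expect_equal(samplingRate(back), samplingRate(es))

  expect_error(loadEpochs(tempfile()), "no such epoch")
  broken <- readRDS(path); broken$labels <- NULL
  p2 <- tempfile(fileext = ".rds"); saveRDS(broken, p2)
  expect_error(loadEpochs(p2), "labels")
})
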