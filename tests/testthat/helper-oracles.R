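# Shared fixtures and independent brute-force oracles.

# direct-sum cross-correlation with same padding (oracle for featureConv)
bruteSameConv <- function(x, kern) {
  fw <- length(kern)
  h <- (fw - 1) %/% 2
  xp <- c(rep(0, h), x, rep(0, h))
  vapply(seq_along(x), function(t) sum(kern * xp[t:(t + fw - 1)]), numeric(1))
}

# direct-sum valid cross-correlation of a padded channel with one kernel,
# cropped to the first T outputs (oracle for dynamicConv)
bruteValidConv <- function(xpad, kern, T) {
  l <- length(kern)
  vapply(seq_len(T), function(t) sum(kern * xpad[t:(t + l - 1)]), numeric(1))
}

# exhaustive pairwise AUC with ties counted half (oracle for rocAUC)
bruteAUC <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# brute-force confusion recount (oracle for confusionCounts/metrics)
bruteCounts <- function(yt, yp) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(yt)) {
    if (yt[i] == 1 && yp[i] == 1) tp <- tp + 1L
    else if (yt[i] == 0 && yp[i] == 1) fp <- fp + 1L
    else if (yt[i] == 0 && yp[i] == 0) tn <- tn + 1L
    else fn <- fn + 1L
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

# a small EpochSet with arbitrary content for protocol tests
tinyEpochs <- function(nSubj = 5, perSubj = 6, C = 2, T = 30, seed = 1) {
  set.seed(seed)
  n <- nSubj * perSubj
  EpochSet(array(rnorm(T * C * n), c(T, C, n)),
           labels = rep(c(1, rep(0, perSubj - 1)), nSubj),
           subjectIds = rep(seq_len(nSubj), each = perSubj),
           samplingRate = 1000)
}

# a small realistic simulated set for end-to-end smoke tests
tinySim <- function(seed = 1, nSubjects = 4, trialsPerSubject = 10,
                    C = 4, T = 120) {
  simulateEpochs(syntheticSpec(
    nSubjects = nSubjects, trialsPerSubject = trialsPerSubject,
    nChannels = C, nTimes = T, samplingRate = 1000,
    p300Window = c(40, 80), p300Latency = 60, p300LatencySd = 5,
    n200Window = c(10, 35), n200Latency = 22, n200LatencySd = 3,
    noiseSd = 1, seed = seed))
}

tinyConfig <- function(lambda = 5, ...) {
  modelConfig(K = 3, l = 12, P = 30, lambda = lambda, dropoutRate = 0, ...)
}
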