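#' @import methods
NULL

#' EpochSet: labelled multichannel ERP epochs
#'
#' Container for epoched, stimulus-locked multichannel EEG. Trials are stored
#' in a 3-D array with time as the fastest-varying dimension
#' (\code{data[t, c, i]}: time point \code{t}, channel \code{c}, trial
#' \code{i}), in microvolts. Each trial carries a binary label (1 =
#' self-face/probe, 0 = stranger-face/irrelevant) and a subject identifier,
#' so that subject-disjoint splits can be formed.
#'
#' @slot data numeric array \code{[T, C, n]}, microvolts.
#' @slot labels integer vector of length n with values in \{0, 1\}.
#' @slot subjectIds integer vector of length n.
#' @slot samplingRate sampling rate in Hz.
#' @slot onsetOffset time of the first sample relative to stimulus onset, ms.
#' @slot channelNames character vector of length C.
#'
#' @seealso [EpochSet()] for the constructor, [simulateEpochs()],
#'   [averageBlocks()], [splitBySubject()].
#' @export
setClass("EpochSet",
  representation(
    data = "array",
    labels = "integer",
    subjectIds = "integer",
    samplingRate = "numeric",
    onsetOffset = "numeric",
    channelNames = "character"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- object@data
  if (length(dim(d)) != 3L) {
    return("data must be a 3-D array [time, channel, trial]")
  }
  nT <- dim(d)[1L]; nC <- dim(d)[2L]; n <- dim(d)[3L]
  if (nT < 1L || nC < 1L) msg <- c(msg, "need at least one channel and one time point")
  if (!all(is.finite(d))) msg <- c(msg, "data contains non-finite values")
  if (length(object@labels) != n) msg <- c(msg, "length(labels) must equal the number of trials")
  if (length(object@subjectIds) != n) msg <- c(msg, "length(subjectIds) must equal the number of trials")
  if (!all(object@labels %in% c(0L, 1L))) msg <- c(msg, "labels must be 0 or 1")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0) msg <- c(msg, "samplingRate must be a positive scalar")
  if (length(object@onsetOffset) != 1L || !is.finite(object@onsetOffset))
    msg <- c(msg, "onsetOffset must be a finite scalar")
  if (length(object@channelNames) != nC)
    msg <- c(msg, "length(channelNames) must equal the number of channels")
  if (length(msg)) msg else TRUE
})

#' SyntheticSpec: parameterisation of the synthetic CTP ERP simulator
#'
#' Describes a simulated Complex-Trial-Protocol dataset: number of subjects
#' and trials, class imbalance (irrelevant:probe ratio), montage size,
#' epoch length, the two class-specific ERP components (a P300-like
#' positivity for self-face trials and an N200-like negativity for
#' stranger-face trials, each a raised-cosine bump with subject-specific
#' latency and amplitude), background noise, and a spatial topography that
#' peaks at a designated Pz-like channel. Windows and latencies are in
#' milliseconds post-stimulus, amplitudes in microvolts.
#'
#' @seealso [syntheticSpec()] for the constructor with defaults,
#'   [simulateEpochs()].
#' @export
setClass("SyntheticSpec",
  representation(
    nSubjects = "integer",
    trialsPerSubject = "integer",
    imbalanceRatio = "integer",
    nChannels = "integer",
    nTimes = "integer",
    samplingRate = "numeric",
    p300Window = "numeric",
    p300Latency = "numeric",
    p300LatencySd = "numeric",
    p300Amplitude = "numeric",
    p300AmplitudeSd = "numeric",
    n200Window = "numeric",
    n200Latency = "numeric",
    n200LatencySd = "numeric",
    n200Amplitude = "numeric",
    n200AmplitudeSd = "numeric",
    noiseSd = "numeric",
    noiseExponent = "numeric",
    topography = "numeric",
    pzChannel = "integer",
    seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  if (object@trialsPerSubject < 1L) msg <- c(msg, "trialsPerSubject must be >= 1")
  if (object@imbalanceRatio < 1L) msg <- c(msg, "imbalanceRatio must be >= 1")
  if (object@nChannels < 1L || object@nTimes < 1L) msg <- c(msg, "need nChannels >= 1 and nTimes >= 1")
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be positive")
  epochMs <- object@nTimes / object@samplingRate * 1000
  for (win in list(p300 = object@p300Window, n200 = object@n200Window)) {
    if (length(win) != 2L || win[1L] < 0 || win[2L] > epochMs || win[1L] >= win[2L])
      msg <- c(msg, "component windows must be increasing ms pairs inside the epoch")
  }
  if (object@p300Amplitude <= 0) msg <- c(msg, "p300Amplitude must be positive (positivity)")
  if (object@n200Amplitude >= 0) msg <- c(msg, "n200Amplitude must be negative (negativity)")
  if (length(object@topography) != object@nChannels)
    msg <- c(msg, "topography must have one gain per channel")
  if (any(object@topography < 0 | object@topography > 1) ||
      abs(max(object@topography) - 1) > 1e-12)
    msg <- c(msg, "topography gains must lie in [0, 1] with max exactly 1")
  if (object@pzChannel < 1L || object@pzChannel > object@nChannels)
    msg <- c(msg, "pzChannel out of range")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ModelConfig: architecture hyperparameters
#'
#' Hyperparameters of the dynamic multi-scale masked convolution network:
#' the number of scales \code{K} (one base kernel per scale), the base
#' kernel length \code{l} in samples, the start \code{P} (0-based, samples)
#' of the segment of pooled features fed to the mask generator, the mask
#' sharpness \code{lambda}, the width of the feature-convolution kernel,
#' the dropout rate of the classification head, and the model variant
#' (\code{"masked"} applies the generated soft masks to the base kernels;
#' \code{"standard"} uses the full-length kernels unmasked).
#'
#' @seealso [modelConfig()] for the constructor with defaults.
#' @export
setClass("ModelConfig",
  representation(
    K = "integer",
    l = "integer",
    P = "integer",
    lambda = "numeric",
    featureKernelWidth = "integer",
    dropoutRate = "numeric",
    variant = "character",
    baseKernelsTrainable = "logical",
    initStd = "numeric"
  )
)

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (object@K < 1L) msg <- c(msg, "K must be >= 1")
  if (object@l < 1L) msg <- c(msg, "l must be >= 1")
  if (object@P < 0L) msg <- c(msg, "P must be >= 0")
  if (object@lambda <= 0) msg <- c(msg, "lambda must be > 0")
  if (object@featureKernelWidth < 1L || object@featureKernelWidth %% 2L == 0L)
    msg <- c(msg, "featureKernelWidth must be a positive odd number")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must be in [0, 1)")
  if (!object@variant %in% c("masked", "standard"))
    msg <- c(msg, "variant must be 'masked' or 'standard'")
  if (!is.na(object@initStd) && object@initStd <= 0)
    msg <- c(msg, "initStd must be positive")
  if (length(msg)) msg else TRUE
})

#' TrainConfig: optimisation and protocol hyperparameters
#'
#' Learning rate and decoupled weight decay of the optimiser, the positive
#' class weight of the logit cross-entropy loss (defaults to the 4:1
#' inverse class frequency of the CTP paradigm), epoch and batch counts,
#' the decision threshold on the predicted score, and the subject-disjoint
#' evaluation protocol (train fraction and number of cross-validation
#' folds).
#'
#' @seealso [trainConfig()] for the constructor with defaults.
#' @export
setClass("TrainConfig",
  representation(
    learningRate = "numeric",
    weightDecay = "numeric",
    positiveClassWeight = "numeric",
    epochs = "integer",
    batchSize = "integer",
    threshold = "numeric",
    nFolds = "integer",
    trainFraction = "numeric",
    optimizer = "character",
    bnMomentum = "numeric",
    seed = "integer"
  )
)

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@weightDecay < 0) msg <- c(msg, "weightDecay must be >= 0")
  if (object@positiveClassWeight <= 0) msg <- c(msg, "positiveClassWeight must be > 0")
  if (object@threshold <= 0 || object@threshold >= 1) msg <- c(msg, "threshold must be in (0, 1)")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@nFolds < 1L) msg <- c(msg, "nFolds must be >= 1")
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    msg <- c(msg, "trainFraction must be in (0, 1)")
  if (!object@optimizer %in% c("adamw", "sgd")) msg <- c(msg, "optimizer must be 'adamw' or 'sgd'")
  if (object@bnMomentum <= 0 || object@bnMomentum > 1) msg <- c(msg, "bnMomentum must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' DynMaskModel: a (possibly trained) dynamic masked convolution model
#'
#' Bundles a [ModelConfig-class], the full set of learnable and fixed
#' parameter arrays (feature filters, Gaussian-initialised base kernels,
#' the two mask-generator fully connected layers, batch-norm scale/shift
#' and running statistics, and the linear classification head), the input
#' dimensions it was built for, and the training history.
#'
#' @slot config a [ModelConfig-class].
#' @slot params named list of numeric parameter arrays.
#' @slot nChannels,nTimes input dimensions (C, T) the model was built for.
#' @slot history data.frame of per-epoch losses (empty until fitted).
#' @slot trained logical flag.
#'
#' @seealso [newModel()], [fitModel()], [predictEpochs()].
#' @export
setClass("DynMaskModel",
  representation(
    config = "ModelConfig",
    params = "list",
    nChannels = "integer",
    nTimes = "integer",
    history = "data.frame",
    trained = "logical"
  )
)

#' EvalReport: confusion counts and imbalance-aware metrics
#'
#' Confusion counts (TP, FP, TN, FN) together with the derived
#' imbalance-aware metrics: TPR (recall), TNR, FPR, precision, balanced
#' accuracy BA = (TPR + TNR) / 2, F1, and the rank-based AUC. Ratios with a
#' zero denominator are reported as \code{NA} (undefined), never silently
#' as 0. When built from cross-validation folds, \code{perFold} holds one
#' row per fold and the scalar slots hold pooled counts / mean metrics.
#'
#' @seealso [evalReport()], [classificationMetrics()], [writeReport()].
#' @export
setClass("EvalReport",
  representation(
    TP = "integer", FP = "integer", TN = "integer", FN = "integer",
    metrics = "numeric",
    perFold = "data.frame"
  )
)

setValidity("EvalReport", function(object) {
  counts <- c(object@TP, object@FP, object@TN, object@FN)
  if (any(counts < 0L)) return("confusion counts must be non-negative")
  need <- c("TPR", "TNR", "FPR", "precision", "recall", "BA", "F1", "AUC")
  if (!all(need %in% names(object@metrics)))
    return(paste("metrics must contain", paste(need, collapse = ", ")))
  ok <- object@metrics[!is.na(object@metrics)]
  if (any(ok < -1e-12 | ok > 1 + 1e-12)) return("defined metrics must lie in [0, 1]")
  TRUE
})
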