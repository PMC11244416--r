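#' Construct a TrainConfig
#'
#' Defaults follow the study protocol: learning rate 1e-5, decoupled
#' weight decay 1e-4, positive class weight 4 (the inverse class
#' frequency of the 1:4 paradigm), decision threshold 0.5, 9:1
#' subject-disjoint train:test split and 3-fold cross-validation.
#' Batch size 32 and 100 epochs are package defaults.
#'
#' @param learningRate,weightDecay optimiser hyperparameters.
#' @param positiveClassWeight weight on positive samples in the logit
#'   cross-entropy loss.
#' @param epochs,batchSize training duration and minibatch size.
#' @param threshold decision threshold on the predicted score; a score
#'   exactly at the threshold is classified positive.
#' @param nFolds,trainFraction evaluation protocol.
#' @param optimizer \code{"adamw"} (adaptive moments, decoupled weight
#'   decay) or \code{"sgd"}.
#' @param bnMomentum running-statistics update rate of batch norm.
#' @param seed seed for shuffling and dropout.
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(learningRate = 1e-5, weightDecay = 1e-4,
                        positiveClassWeight = 4, epochs = 100L,
                        batchSize = 32L, threshold = 0.5, nFolds = 3L,
                        trainFraction = 0.9,
                        optimizer = c("adamw", "sgd"),
                        bnMomentum = 0.1, seed = 1L) {
  optimizer <- match.arg(optimizer)
  new("TrainConfig", learningRate = as.numeric(learningRate),
      weightDecay = as.numeric(weightDecay),
      positiveClassWeight = as.numeric(positiveClassWeight),
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      threshold = as.numeric(threshold), nFolds = as.integer(nFolds),
      trainFraction = as.numeric(trainFraction), optimizer = optimizer,
      bnMomentum = as.numeric(bnMomentum), seed = as.integer(seed))
}

#' Class-weighted binary cross-entropy on logits
#'
#' Mean over samples of
#' \eqn{-[w\,y\log\sigma(z) + (1-y)\log(1-\sigma(z))]} with
#' \eqn{w} the positive class weight; computed in the numerically stable
#' softplus form. With \code{posWeight = 1} this is the ordinary binary
#' cross-entropy.
#'
#' @param logits real-valued model outputs.
#' @param labels binary labels.
#' @param posWeight weight applied to positive-sample terms.
#' @return non-negative scalar loss.
#' @export
weightedBCE <- function(logits, labels, posWeight = 1) {
  if (length(logits) == 0L) stop("empty batch")
  stopifnot(length(logits) == length(labels), all(labels %in% c(0, 1)),
            all(is.finite(logits)), posWeight > 0)
  softplus <- ifelse(logits > 0,
                     logits + log1p(exp(-logits)),
                     log1p(exp(logits)))
  mean(ifelse(labels == 1, posWeight * (softplus - logits), softplus))
}

cfgList <- function(cfg) {
  list(P = cfg@P, lambda = cfg@lambda, dropoutRate = cfg@dropoutRate,
       masked = cfg@variant == "masked")
}

adamInit <- function(params) {
  lapply(params, function(x) list(m = x * 0, v = x * 0))
}

# AdamW / SGD update; `fixed` names parameters excluded from updates
optimStep <- function(params, grads, state, tc, stepNo, fixed = character()) {
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  lr <- tc@learningRate; wd <- tc@weightDecay
  decayed <- c("Wf", "W", "Wm1", "Wm2", "w")   # no decay on biases/BN
  for (nm in names(grads)) {
    if (nm %in% fixed) next
    gnm <- grads[[nm]]
    if (tc@optimizer == "adamw") {
      st <- state[[nm]]
      st$m <- b1 * st$m + (1 - b1) * gnm
      st$v <- b2 * st$v + (1 - b2) * gnm^2
      mhat <- st$m / (1 - b1^stepNo)
      vhat <- st$v / (1 - b2^stepNo)
      upd <- lr * mhat / (sqrt(vhat) + epsA)
      state[[nm]] <- st
    } else {
      upd <- lr * gnm
    }
    if (nm %in% decayed) upd <- upd + lr * wd * params[[nm]]
    params[[nm]] <- params[[nm]] - upd
  }
  list(params = params, state = state)
}

#' Fit a dynamic masked convolution model
#'
#' Minimises the class-weighted logit cross-entropy by minibatch
#' gradient descent (AdamW by default) using the fused compiled
#' forward/backward path. Batch-norm running statistics are updated with
#' momentum \code{bnMomentum}; the per-epoch mean training loss (and,
#' when a validation set is given, the evaluation-mode validation loss)
#' is recorded in the returned model's history. Deterministic given
#' \code{trainConfig@seed}.
#'
#' @param train an [EpochSet-class] containing both classes.
#' @param config a [ModelConfig-class].
#' @param tc a [TrainConfig-class].
#' @param validation optional [EpochSet-class] for per-epoch validation
#'   loss.
#' @param initSeed seed for parameter initialisation (defaults to
#'   \code{tc@seed}).
#' @return a trained [DynMaskModel-class].
#' @export
fitModel <- function(train, config = modelConfig(), tc = trainConfig(),
                     validation = NULL, initSeed = NULL) {
  stopifnot(is(train, "EpochSet"))
  n <- nTrials(train)
  if (n == 0L) stop("empty training set")
  y <- epochLabels(train)
  if (length(unique(y)) < 2L)
    stop("training set contains a single class; need both positives and negatives")
  if (is.null(initSeed)) initSeed <- tc@seed
  C <- nChannels(train); T <- nTimes(train)
  model <- newModel(config, C, T, seed = initSeed)
  params <- model@params
  h <- (config@featureKernelWidth - 1L) %/% 2L
  xp <- .packEpochs(as.numeric(train@data), dim(train@data), config@l, h)
  xpVal <- if (!is.null(validation))
    .packEpochs(as.numeric(validation@data), dim(validation@data), config@l, h)
  cl <- cfgList(config)
  fixed <- character()
  if (!config@baseKernelsTrainable) fixed <- c(fixed, "W")
  if (config@variant == "standard")
    fixed <- c(fixed, "Wf", "bf", "Wm1", "bm1", "Wm2", "bm2")
  state <- if (tc@optimizer == "adamw") adamInit(params[setdiff(
    c("Wf", "bf", "W", "bv", "Wm1", "bm1", "Wm2", "bm2", "gamma", "beta", "w", "b"),
    fixed)])
  stepNo <- 0L
  hist <- data.frame(epoch = integer(), trainLoss = numeric(),
                     valLoss = numeric())
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  for (ep in seq_len(tc@epochs)) {
    set.seed(tc@seed * 1000L + ep)
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / tc@batchSize))
    epLoss <- 0
    for (bi in seq_along(batches)) {
      stepNo <- stepNo + 1L
      rngSeed <- as.double(tc@seed) * 1e6 + stepNo
      res <- .batchStep(xp, as.integer(batches[[bi]]), as.numeric(y[batches[[bi]]]),
                        params, cl, tc@positiveClassWeight, rngSeed)
      if (!is.finite(res$loss))
        stop("non-finite loss at epoch ", ep, ", batch ", bi,
             "; consider lowering the learning rate")
      epLoss <- epLoss + res$loss * length(batches[[bi]])
      upd <- optimStep(params, res$grads, state, tc, stepNo, fixed)
      params <- upd$params; state <- upd$state
      params$runMean <- (1 - tc@bnMomentum) * params$runMean + tc@bnMomentum * res$batchMean
      params$runVar <- (1 - tc@bnMomentum) * params$runVar + tc@bnMomentum * res$batchVar
    }
    valLoss <- NA_real_
    if (!is.null(validation)) {
      vlog <- .batchLogits(xpVal, seq_len(nTrials(validation)), params, cl)
      valLoss <- weightedBCE(vlog, epochLabels(validation), tc@positiveClassWeight)
    }
    hist <- rbind(hist, data.frame(epoch = ep, trainLoss = epLoss / n,
                                   valLoss = valLoss))
  }
  new("DynMaskModel", config = config, params = params,
      nChannels = C, nTimes = T,
      history = hist, trained = TRUE)
}

#' Predict scores and labels for epochs
#'
#' Evaluation-mode forward pass (running batch-norm statistics, dropout
#' off): scores are \eqn{\sigma(\mathrm{logit})} in (0, 1); the predicted
#' label is 1 exactly when the score is at or above the threshold (ties
#' at the threshold classify positive).
#'
#' @param model a [DynMaskModel-class].
#' @param es an [EpochSet-class] with matching channel/time dimensions.
#' @param threshold decision threshold in (0, 1).
#' @return list with numeric \code{scores} and integer \code{labels}.
#' @export
predictEpochs <- function(model, es, threshold = 0.5) {
  stopifnot(is(model, "DynMaskModel"), is(es, "EpochSet"))
  if (nChannels(es) != model@nChannels || nTimes(es) != model@nTimes)
    stop("epoch dimensions ", nChannels(es), " x ", nTimes(es),
         " do not match the model (", model@nChannels, " x ", model@nTimes, ")")
  cfg <- model@config
  h <- (cfg@featureKernelWidth - 1L) %/% 2L
  xp <- .packEpochs(as.numeric(es@data), dim(es@data), cfg@l, h)
  logits <- .batchLogits(xp, seq_len(nTrials(es)), model@params, cfgList(cfg))
  scores <- sigmoid(logits)
  list(scores = scores, labels = as.integer(scores >= threshold))
}
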