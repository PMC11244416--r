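#' Construct an EpochSet
#'
#' @param data numeric array of epoched EEG. Either \code{[T, C, n]}
#'   (time, channel, trial; the native storage order) or \code{[n, C, T]}
#'   with \code{trialsFirst = TRUE}. Microvolts.
#' @param labels binary vector (1 = self-face/probe, 0 = stranger-face/
#'   irrelevant), one per trial.
#' @param subjectIds integer subject identifier per trial.
#' @param samplingRate sampling rate in Hz.
#' @param onsetOffset time of the first sample relative to stimulus onset, ms.
#' @param channelNames optional character vector of channel names.
#' @param trialsFirst set \code{TRUE} if \code{data} is \code{[n, C, T]}.
#' @return an [EpochSet-class].
#' @examples
#' es <- EpochSet(array(rnorm(20 * 2 * 3), c(20, 2, 3)),
#'                labels = c(1, 0, 0), subjectIds = c(1, 1, 1),
#'                samplingRate = 100)
#' nTrials(es)
#' @export
EpochSet <- function(data, labels, subjectIds, samplingRate = 1000,
                     onsetOffset = 0, channelNames = NULL,
                     trialsFirst = FALSE) {
  if (trialsFirst) data <- aperm(data, c(3L, 2L, 1L))
  nC <- dim(data)[2L]
  if (is.null(channelNames)) channelNames <- sprintf("Ch%02d", seq_len(nC))
  new("EpochSet",
      data = data,
      labels = as.integer(labels),
      subjectIds = as.integer(subjectIds),
      samplingRate = as.numeric(samplingRate),
      onsetOffset = as.numeric(onsetOffset),
      channelNames = as.character(channelNames))
}

#' @describeIn EpochSet number of trials.
#' @param es an [EpochSet-class].
#' @export
nTrials <- function(es) dim(es@data)[3L]

#' @describeIn EpochSet number of channels.
#' @export
nChannels <- function(es) dim(es@data)[2L]

#' @describeIn EpochSet number of time points per epoch.
#' @export
nTimes <- function(es) dim(es@data)[1L]

#' @describeIn EpochSet the \code{[T, C, n]} data array.
#' @export
epochData <- function(es) es@data

#' @describeIn EpochSet integer 0/1 label per trial.
#' @export
epochLabels <- function(es) es@labels

#' @describeIn EpochSet subject identifier per trial.
#' @export
subjectIds <- function(es) es@subjectIds

#' @describeIn EpochSet sampling rate in Hz.
#' @export
samplingRate <- function(es) es@samplingRate

#' @describeIn EpochSet channel names.
#' @export
channelNames <- function(es) es@channelNames

#' @describeIn EpochSet sample times in ms relative to stimulus onset.
#' @export
timesMs <- function(es) {
  es@onsetOffset + (seq_len(nTimes(es)) - 1) / es@samplingRate * 1000
}

#' @export
setMethod("show", "EpochSet", function(object) {
  n <- nTrials(object)
  cat(sprintf("EpochSet: %d trials x %d channels x %d samples @ %g Hz\n",
              n, nChannels(object), nTimes(object), object@samplingRate))
  cat(sprintf("  positives (self-face): %d, negatives (stranger-face): %d\n",
              sum(object@labels == 1L), sum(object@labels == 0L)))
  cat(sprintf("  subjects: %d, epoch span %g..%g ms\n",
              length(unique(object@subjectIds)),
              object@onsetOffset,
              object@onsetOffset + (nTimes(object) - 1) / object@samplingRate * 1000))
})

#' @export
setMethod("[", "EpochSet", function(x, i, j, ..., drop = FALSE) {
  i <- seq_len(nTrials(x))[i]
  new("EpochSet",
      data = x@data[, , i, drop = FALSE],
      labels = x@labels[i],
      subjectIds = x@subjectIds[i],
      samplingRate = x@samplingRate,
      onsetOffset = x@onsetOffset,
      channelNames = x@channelNames)
})

#' Combine two epoch sets trial-wise
#' @param e1,e2 [EpochSet-class] objects with identical montage and timing.
#' @export
bindEpochs <- function(e1, e2) {
  stopifnot(nChannels(e1) == nChannels(e2), nTimes(e1) == nTimes(e2),
            e1@samplingRate == e2@samplingRate)
  arr <- array(c(e1@data, e2@data),
               c(nTimes(e1), nChannels(e1), nTrials(e1) + nTrials(e2)))
  new("EpochSet", data = arr,
      labels = c(e1@labels, e2@labels),
      subjectIds = c(e1@subjectIds, e2@subjectIds),
      samplingRate = e1@samplingRate, onsetOffset = e1@onsetOffset,
      channelNames = e1@channelNames)
}

#' Average trials in blocks to raise the signal-to-noise ratio
#'
#' Emulates the CTP practice of averaging corresponding single trials
#' across blocks: within each (subject, label) stratum, consecutive groups
#' of \code{groupSize} trials are replaced by their pointwise mean. Strata
#' remainders smaller than \code{groupSize} are dropped. With
#' \code{groupSize = 1} this is the identity.
#'
#' @param es an [EpochSet-class].
#' @param groupSize number of trials averaged into each output trial.
#' @return an [EpochSet-class] of block-averaged trials.
#' @export
averageBlocks <- function(es, groupSize) {
  groupSize <- as.integer(groupSize)
  stopifnot(groupSize >= 1L)
  if (groupSize == 1L) return(es)
  strata <- split(seq_len(nTrials(es)),
                  list(subject = es@subjectIds, label = es@labels), drop = TRUE)
  if (all(lengths(strata) < groupSize))
    stop("groupSize exceeds the size of every (subject, label) stratum")
  outIdx <- list(); outArr <- list()
  for (idx in strata) {
    ng <- length(idx) %/% groupSize
    if (ng == 0L) next
    for (g in seq_len(ng)) {
      grp <- idx[((g - 1L) * groupSize + 1L):(g * groupSize)]
      sl <- es@data[, , grp, drop = FALSE]
      outArr[[length(outArr) + 1L]] <- rowMeans(sl, dims = 2L)
      outIdx[[length(outIdx) + 1L]] <- grp[1L]
    }
  }
  first <- unlist(outIdx)
  arr <- array(unlist(outArr), c(nTimes(es), nChannels(es), length(first)))
  new("EpochSet", data = arr,
      labels = es@labels[first],
      subjectIds = es@subjectIds[first],
      samplingRate = es@samplingRate, onsetOffset = es@onsetOffset,
      channelNames = es@channelNames)
}

#' Subject-disjoint train/test splits
#'
#' Whole participants are the smallest unit of division, so no subject's
#' trials ever appear on both sides of a split. With \code{nFolds = 1} a
#' single random \code{trainFraction} : \code{1 - trainFraction} split of
#' the subjects is produced (9:1 by default). With \code{nFolds > 1},
#' subjects are permuted once and partitioned into \code{nFolds} disjoint
#' test groups (cross-validation); each subject is tested exactly once.
#' The assignment depends only on the set of subject identifiers and the
#' seed, never on trial order.
#'
#' @param es an [EpochSet-class] with at least \code{nFolds} subjects.
#' @param trainFraction fraction of subjects assigned to training when
#'   \code{nFolds = 1}.
#' @param nFolds number of cross-validation folds.
#' @param seed integer seed controlling the subject permutation.
#' @return a list of \code{list(train = , test = )} pairs of
#'   [EpochSet-class] objects, one per fold.
#' @export
splitBySubject <- function(es, trainFraction = 0.9, nFolds = 1L, seed = 1L) {
  subjects <- sort(unique(es@subjectIds))
  nFolds <- as.integer(nFolds)
  if (nFolds > length(subjects))
    stop("nFolds exceeds the number of subjects (", length(subjects), ")")
  # local RNG scope: save/restore .Random.seed
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  shuffled <- sample(subjects)
  folds <- vector("list", nFolds)
  if (nFolds == 1L) {
    nTest <- max(1L, length(subjects) - floor(trainFraction * length(subjects)))
    testS <- shuffled[seq_len(nTest)]
    folds[[1L]] <- list(train = es[!(es@subjectIds %in% testS)],
                        test = es[es@subjectIds %in% testS])
  } else {
    grp <- rep(seq_len(nFolds), length.out = length(subjects))
    for (f in seq_len(nFolds)) {
      testS <- shuffled[grp == f]
      folds[[f]] <- list(train = es[!(es@subjectIds %in% testS)],
                         test = es[es@subjectIds %in% testS])
    }
  }
  folds
}

#' Save / load an epoch container
#'
#' Writes a versioned, schema-checked single-file container holding the
#' data array, labels, subject identifiers and timing metadata. Loading
#' validates the schema and reports any missing field by name; arrays and
#' metadata round-trip bit-exactly at stored precision, and integer fields
#' stay integer.
#'
#' @param es an [EpochSet-class].
#' @param path file path to write to / read from.
#' @return \code{loadEpochs} returns an [EpochSet-class].
#' @export
saveEpochs <- function(es, path) {
  stopifnot(is(es, "EpochSet"))
  obj <- list(
    container = "DynMaskERP-epochs", version = 1L,
    data = es@data, labels = es@labels, subject_ids = es@subjectIds,
    sampling_rate = es@samplingRate, onset_offset = es@onsetOffset,
    channel_names = es@channelNames)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveEpochs
#' @export
loadEpochs <- function(path) {
  if (!file.exists(path)) stop("no such epoch container: ", path)
  obj <- readRDS(path)
  required <- c("data", "labels", "subject_ids", "sampling_rate",
                "onset_offset", "channel_names")
  if (!is.list(obj) || !identical(obj$container, "DynMaskERP-epochs"))
    stop("not a DynMaskERP epoch container: ", path)
  missing <- setdiff(required, names(obj))
  if (length(missing))
    stop("epoch container is missing required field(s): ",
         paste(missing, collapse = ", "))
  new("EpochSet", data = obj$data, labels = as.integer(obj$labels),
      subjectIds = as.integer(obj$subject_ids),
      samplingRate = obj$sampling_rate, onsetOffset = obj$onset_offset,
      channelNames = obj$channel_names)
}
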