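#' AblationGrid: the sweep definition for masked-vs-standard experiments
#'
#' Cartesian grid over model variant, scale count K, mask sharpness
#' lambda, mask-generator window length l and start P, replicate seeds,
#' and cross-validation folds. Defaults mirror the study's sweeps
#' (K in 5/10/20/30; lambda in 3,4,5,6,7,8,10; l in 100/200/300/600);
#' positions are in samples, which coincide with ms at 1000 Hz.
#'
#' @export
setClass("AblationGrid",
  representation(variants = "character", K = "integer", lambda = "numeric",
                 l = "integer", P = "integer", seeds = "integer",
                 folds = "integer"))

setValidity("AblationGrid", function(object) {
  msg <- character()
  if (!length(object@variants) || !all(object@variants %in% c("masked", "standard")))
    msg <- c(msg, "variants must be a non-empty subset of {masked, standard}")
  for (nm in c("K", "lambda", "l", "P", "seeds"))
    if (!length(slot(object, nm))) msg <- c(msg, paste(nm, "grid must be non-empty"))
  if (object@folds < 1L) msg <- c(msg, "folds must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname AblationGrid-class
#' @param variants,K,lambda,l,P,seeds,folds grid axes (see class docs).
#' @export
ablationGrid <- function(variants = c("masked", "standard"),
                         K = c(5L, 10L, 20L, 30L),
                         lambda = c(3, 4, 5, 6, 7, 8, 10),
                         l = c(100L, 200L, 300L, 600L),
                         P = 400L, seeds = 1L, folds = 1L) {
  new("AblationGrid", variants = variants, K = as.integer(K),
      lambda = as.numeric(lambda), l = as.integer(l), P = as.integer(P),
      seeds = as.integer(seeds), folds = as.integer(folds))
}

#' Run the masked-vs-standard ablation / window sweep
#'
#' Trains and evaluates one model per grid cell — every combination of
#' (variant, K, lambda, l, P, seed, fold) — on subject-disjoint splits.
#' Matched masked/standard cells share the identical split and seeds, so
#' the derived \code{maskedMinusStandardBA} column (populated on masked
#' rows when the matched standard row exists) is a paired comparison. A
#' cell whose training fails is marked \code{status = "failed"} with the
#' diagnostic, and the sweep continues; the table always contains the
#' full grid product.
#'
#' @param dataset an [EpochSet-class].
#' @param grid an [AblationGrid-class] (every l + P must fit the epoch).
#' @param tc a [TrainConfig-class]; its \code{nFolds}/\code{seed} are
#'   overridden by the grid's folds and seeds.
#' @return data.frame with one row per grid cell: the axes, confusion
#'   counts, all scalar metrics, \code{status} and
#'   \code{maskedMinusStandardBA}.
#' @export
runAblation <- function(dataset, grid, tc = trainConfig()) {
  stopifnot(is(dataset, "EpochSet"), is(grid, "AblationGrid"))
  validObject(grid)
  T <- nTimes(dataset)
  for (li in grid@l) for (pi in grid@P)
    if (pi + li > T) stop("grid cell with P + l = ", pi + li,
                          " exceeds the epoch length T = ", T)
  cells <- expand.grid(variant = grid@variants, K = grid@K,
                       lambda = grid@lambda, l = grid@l, P = grid@P,
                       seed = grid@seeds, fold = seq_len(grid@folds),
                       stringsAsFactors = FALSE)
  mcols <- c("TPR", "TNR", "FPR", "precision", "recall", "BA", "F1", "AUC")
  rows <- vector("list", nrow(cells))
  splitCache <- new.env()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    key <- paste0("s", cell$seed)
    if (is.null(splitCache[[key]]))
      splitCache[[key]] <- splitBySubject(dataset, trainFraction = tc@trainFraction,
                                          nFolds = grid@folds, seed = cell$seed)
    fold <- splitCache[[key]][[cell$fold]]
    res <- tryCatch({
      cfg <- modelConfig(K = cell$K, l = cell$l, P = cell$P,
                         lambda = cell$lambda, variant = cell$variant)
      tcc <- tc
      tcc@seed <- as.integer(cell$seed)
      model <- fitModel(fold$train, cfg, tcc)
      pred <- predictEpochs(model, fold$test, threshold = tc@threshold)
      rep <- evalReport(epochLabels(fold$test), pred$scores, threshold = tc@threshold)
      cbind(cell,
            data.frame(TP = rep@TP, FP = rep@FP, TN = rep@TN, FN = rep@FN),
            as.data.frame(as.list(rep@metrics)),
            data.frame(status = "ok", message = "", stringsAsFactors = FALSE))
    }, error = function(e) {
      na <- as.data.frame(as.list(stats::setNames(rep(NA_real_, length(mcols)), mcols)))
      cbind(cell, data.frame(TP = NA_integer_, FP = NA_integer_,
                             TN = NA_integer_, FN = NA_integer_),
            na, data.frame(status = "failed", message = conditionMessage(e),
                           stringsAsFactors = FALSE))
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$maskedMinusStandardBA <- NA_real_
  if (all(c("masked", "standard") %in% grid@variants)) {
    keyOf <- function(d) paste(d$K, d$lambda, d$l, d$P, d$seed, d$fold)
    std <- out[out$variant == "standard", ]
    stdBA <- stats::setNames(std$BA, keyOf(std))
    isM <- out$variant == "masked"
    out$maskedMinusStandardBA[isM] <- out$BA[isM] - stdBA[keyOf(out[isM, ])]
  }
  out
}
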