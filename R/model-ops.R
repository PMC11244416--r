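#' @useDynLib DynMaskERP, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# numerically stable logistic (plogis keeps sigma(x) > 0 down to x ~ -745)
sigmoid <- function(x) stats::plogis(x)

#' Construct a ModelConfig
#'
#' @param K number of scales (one base kernel per scale).
#' @param l base kernel length, samples.
#' @param P start of the mask-generator input segment, samples (0-based;
#'   the segment is the half-open slice \code{[P, P + l)} of the pooled
#'   feature maps).
#' @param lambda sharpness of the soft mask: with mask entries
#'   \eqn{m_{ij} = \sigma(\lambda(l_i - j))}, larger \code{lambda} brings
#'   the soft mask closer to a hard 0--1 cutoff.
#' @param featureKernelWidth width of the feature-convolution kernel.
#' @param dropoutRate dropout rate of the classification head.
#' @param variant \code{"masked"} (dynamic soft-masked kernels) or
#'   \code{"standard"} (fixed full-length kernels).
#' @param baseKernelsTrainable whether the Gaussian-initialised base
#'   kernels are updated during training.
#' @param initStd sd of the Gaussian base-kernel initialisation
#'   (default \code{1/sqrt(l)}).
#' @return a [ModelConfig-class].
#' @export
modelConfig <- function(K = 30L, l = 200L, P = 400L, lambda = 5,
                        featureKernelWidth = 3L, dropoutRate = 0.5,
                        variant = c("masked", "standard"),
                        baseKernelsTrainable = TRUE, initStd = NA_real_) {
  variant <- match.arg(variant)
  new("ModelConfig", K = as.integer(K), l = as.integer(l), P = as.integer(P),
      lambda = as.numeric(lambda),
      featureKernelWidth = as.integer(featureKernelWidth),
      dropoutRate = as.numeric(dropoutRate), variant = variant,
      baseKernelsTrainable = isTRUE(baseKernelsTrainable),
      initStd = as.numeric(initStd))
}

#' @export
setMethod("show", "ModelConfig", function(object) {
  cat(sprintf("ModelConfig (%s): K = %d scales, kernel length l = %d, segment [%d, %d), lambda = %g\n",
              object@variant, object@K, object@l, object@P, object@P + object@l,
              object@lambda))
  cat(sprintf("  feature kernel width %d, dropout %g, base kernels %s\n",
              object@featureKernelWidth, object@dropoutRate,
              if (object@baseKernelsTrainable) "trainable" else "frozen"))
})

#' Initialise model parameters
#'
#' Base kernels \code{W} are drawn from a zero-mean Gaussian with sd
#' \code{initStd} (default \code{1/sqrt(l)}); feature filters and the
#' mask-generator fully connected layers use variance-preserving Gaussian
#' initialisation; batch-norm starts at identity (gamma 1, beta 0) with
#' zero running mean and unit running variance; the classifier weight is
#' Gaussian with sd \code{1/sqrt(K*C*T)}.
#'
#' @param config a [ModelConfig-class].
#' @param nChannels,nTimes input epoch dimensions C and T.
#' @param seed integer seed.
#' @return named list of parameter arrays. The classifier weight \code{w}
#'   has dim \code{c(K, C, T)}, matching the flattened convolution output.
#' @export
initParams <- function(config, nChannels, nTimes, seed = 1L) {
  K <- config@K; l <- config@l; fw <- config@featureKernelWidth
  C <- as.integer(nChannels); T <- as.integer(nTimes)
  if (config@P + l > T)
    stop("mask-generator segment [P, P+l) = [", config@P, ", ", config@P + l,
         ") exceeds the epoch length T = ", T)
  sdW <- if (is.na(config@initStd)) 1 / sqrt(l) else config@initStd
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  list(
    Wf = matrix(stats::rnorm(K * fw, sd = 1 / sqrt(fw)), K, fw),
    bf = numeric(K),
    W = matrix(stats::rnorm(K * l, sd = sdW), K, l),
    bv = numeric(K),
    Wm1 = matrix(stats::rnorm(l * 2 * l, sd = 1 / sqrt(2 * l)), l, 2 * l),
    bm1 = numeric(l),
    Wm2 = stats::rnorm(l, sd = 1 / sqrt(l)),
    bm2 = 0,
    gamma = rep(1, K),
    beta = numeric(K),
    runMean = numeric(K),
    runVar = rep(1, K),
    w = array(stats::rnorm(K * C * T, sd = 1 / sqrt(K * C * T)), c(K, C, T)),
    b = 0
  )
}

#' Create an untrained model
#'
#' @param config a [ModelConfig-class].
#' @param nChannels,nTimes input epoch dimensions.
#' @param seed seed for parameter initialisation.
#' @return a [DynMaskModel-class].
#' @export
newModel <- function(config, nChannels, nTimes, seed = 1L) {
  new("DynMaskModel", config = config,
      params = initParams(config, nChannels, nTimes, seed),
      nChannels = as.integer(nChannels), nTimes = as.integer(nTimes),
      history = data.frame(), trained = FALSE)
}

#' @export
setMethod("show", "DynMaskModel", function(object) {
  show(object@config)
  cat(sprintf("  built for %d channels x %d samples; %s\n",
              object@nChannels, object@nTimes,
              if (object@trained) sprintf("trained (%d epochs)", nrow(object@history))
              else "untrained"))
})

#' Feature convolution (first stage)
#'
#' Convolves every channel of an epoch with each of the K width-\code{fw}
#' feature filters (cross-correlation with same-padding: zeros added
#' symmetrically so the time length is preserved) and adds the filter
#' bias.
#'
#' @param S epoch matrix \code{[C, T]}.
#' @param Wf filter matrix \code{[K, fw]}.
#' @param bf bias vector of length K.
#' @return feature maps \code{E}, array \code{[K, C, T]}.
#' @export
featureConv <- function(S, Wf, bf = numeric(nrow(Wf))) {
  stopifnot(is.matrix(S), all(is.finite(S)), is.matrix(Wf))
  K <- nrow(Wf); fw <- ncol(Wf); C <- nrow(S); T <- ncol(S)
  h <- (fw - 1L) %/% 2L
  Spad <- cbind(matrix(0, C, h), S, matrix(0, C, h))
  E <- array(0, c(K, C, T))
  for (k in seq_len(K)) {
    acc <- matrix(0, C, T)
    for (u in seq_len(fw)) acc <- acc + Wf[k, u] * Spad[, u:(u + T - 1L), drop = FALSE]
    E[k, , ] <- acc + bf[k]
  }
  E
}

#' Global average pooling over channels
#'
#' @param E feature maps \code{[K, C, T]}.
#' @return pooled maps \code{[K, 1, T]}.
#' @export
channelGAP <- function(E) {
  stopifnot(length(dim(E)) == 3L)
  K <- dim(E)[1L]; T <- dim(E)[3L]
  array(apply(E, c(1L, 3L), mean), c(K, 1L, T))
}

#' Extract the mask-generator input segment
#'
#' Takes the half-open time slice \code{[P, P + l)} (0-based, so samples
#' \code{P + 1 .. P + l} in R's 1-based indexing) of the pooled feature
#' maps.
#'
#' @param Ep pooled maps \code{[K, 1, T]}.
#' @param P 0-based segment start.
#' @param l segment length.
#' @return segment \code{L}, array \code{[K, 1, l]}.
#' @export
extractSegment <- function(Ep, P, l) {
  T <- dim(Ep)[3L]
  if (P < 0 || P + l > T)
    stop("segment [P, P+l) = [", P, ", ", P + l, ") out of range for T = ", T)
  Ep[, , (P + 1L):(P + l), drop = FALSE]
}

#' Mask ratio from the two fully connected layers
#'
#' Per scale i, the segment \code{L_i} is concatenated with the base
#' kernel \code{W_i} (length 2l), passed through the shared 2l-to-l and
#' l-to-1 fully connected layers, and squashed by a sigmoid:
#' \eqn{r_i = \sigma(W_{m2}(W_{m1}(L_i \oplus W_i) + b_{m1}) + b_{m2})}.
#'
#' @param L segment \code{[K, 1, l]} or matrix \code{[K, l]}.
#' @param W base kernels \code{[K, l]}.
#' @param Wm1 first fc weight \code{[l, 2l]}; \code{bm1} its bias (length l).
#' @param Wm2 second fc weight (length l); \code{bm2} its scalar bias.
#' @param bm1,bm2 biases.
#' @return vector of K ratios, each strictly inside (0, 1).
#' @export
maskRatio <- function(L, W, Wm1, bm1, Wm2, bm2) {
  if (length(dim(L)) == 3L) L <- matrix(L[, 1L, ], nrow = dim(L)[1L])
  stopifnot(ncol(L) == ncol(W))
  cat2 <- cbind(L, W)                       # [K, 2l]
  z1 <- cat2 %*% t(Wm1) + rep(bm1, each = nrow(cat2))
  r <- as.numeric(sigmoid(z1 %*% Wm2 + bm2))
  if (!all(is.finite(r))) stop("non-finite intermediate in mask-ratio computation")
  r
}

#' Differentiable soft mask
#'
#' Turns each ratio \code{r_i} into a real-valued ideal length
#' \eqn{l_i = r_i l} and a soft 0--1 mask
#' \eqn{m_{ij} = \sigma(\lambda(l_i - j))} over 1-based time steps
#' \eqn{j = 1..l}. Every row is strictly decreasing in j with entries in
#' (0, 1); at an integer \eqn{j = l_i} the entry is exactly 0.5.
#'
#' @param r ratios in (0, 1), length K.
#' @param l kernel length.
#' @param lambda sharpness parameter.
#' @return mask matrix \code{M}, \code{[K, l]}.
#' @export
softMask <- function(r, l, lambda) {
  # r is strictly inside (0,1) analytically; the sigmoid saturates to
  # exactly 1 in double precision for large inputs, which is accepted
  stopifnot(all(r > 0 & r <= 1), lambda > 0)
  li <- r * l
  j <- seq_len(l)
  t(vapply(li, function(x) sigmoid(lambda * (x - j)), numeric(l)))
}

#' Apply soft masks to the base kernels
#'
#' @param W base kernels \code{[K, l]}.
#' @param M soft masks \code{[K, l]}.
#' @return masked kernels \code{W ⊗ M}.
#' @export
maskedKernels <- function(W, M) {
  if (!all(dim(W) == dim(M))) stop("W and M must have identical dimensions")
  W * M
}

#' Zero-pad an epoch at the end of the time axis
#'
#' @param S epoch \code{[C, T]}.
#' @param l number of zeros appended per channel.
#' @return padded epoch \code{[C, T + l]}.
#' @export
padInput <- function(S, l) {
  stopifnot(l >= 1)
  cbind(S, matrix(0, nrow(S), l))
}

#' Masked channel-wise (depthwise) convolution
#'
#' Convolves every channel of the zero-padded epoch with each scale's
#' (masked) kernel — cross-correlation, valid alignment, cropped to the
#' first T output samples — keeping one map per (scale, channel) pair.
#' No cross-channel or cross-scale summation is performed.
#'
#' @param Spad padded epoch \code{[C, T + l]}.
#' @param Wv kernels \code{[K, l]}.
#' @param bv per-scale bias, length K.
#' @return output \code{D}, array \code{[K, C, T]}.
#' @export
dynamicConv <- function(Spad, Wv, bv = numeric(nrow(Wv))) {
  C <- nrow(Spad); l <- ncol(Wv); K <- nrow(Wv)
  T <- ncol(Spad) - l
  if (T < 1L) stop("kernel length ", l, " too long for padded input of length ", ncol(Spad))
  idx <- outer(seq_len(T), 0:(l - 1L), `+`)
  D <- array(0, c(K, C, T))
  tWv <- t(Wv)
  for (ch in seq_len(C)) {
    # linear (vector) indexing: idx is T x l positions into the channel
    H <- Spad[ch, ][idx]
    dim(H) <- c(T, l)
    D[, ch, ] <- t(H %*% tWv) + bv
  }
  D
}

#' Classification head
#'
#' Batch normalisation over the scale dimension (per-scale statistics;
#' batch statistics when \code{training}, running statistics otherwise),
#' dropout (active only when \code{training}), flatten, and a single
#' linear unit producing one real logit. Deterministic in evaluation
#' mode.
#'
#' @param D convolution output \code{[K, C, T]}.
#' @param params model parameter list (uses gamma, beta, runMean, runVar,
#'   w, b).
#' @param training logical flag.
#' @param dropoutRate dropout rate used when \code{training}.
#' @param dropMask optional fixed 0/1 mask of \code{dim(D)} (for
#'   reproducible training-mode evaluation); when \code{NULL} and
#'   \code{training}, a Bernoulli mask is drawn from the R RNG.
#' @param eps batch-norm variance floor.
#' @return scalar logit.
#' @export
classifyHead <- function(D, params, training = FALSE, dropoutRate = 0,
                         dropMask = NULL, eps = 1e-5) {
  stopifnot(all(is.finite(D)))
  K <- dim(D)[1L]
  flat <- matrix(D, nrow = K)                     # K x (C*T)
  if (training) {
    mu <- rowMeans(flat)
    v <- rowMeans(flat^2) - mu^2
  } else {
    mu <- params$runMean; v <- params$runVar
  }
  xhat <- (flat - mu) / sqrt(v + eps)
  z <- params$gamma * xhat + params$beta
  if (training && dropoutRate > 0) {
    if (is.null(dropMask))
      dropMask <- array(stats::rbinom(length(D), 1L, 1 - dropoutRate), dim(D))
    z <- z * matrix(dropMask, nrow = K) / (1 - dropoutRate)
  }
  sum(matrix(params$w, nrow = K) * z) + params$b
}

#' Full forward pass with trace and mask diagnostics
#'
#' Composes feature convolution, channel pooling, segment extraction,
#' mask-ratio generation, soft masking, kernel masking, input padding,
#' dynamic channel-wise convolution and the classification head. The
#' \code{"standard"} variant skips mask generation (mask identically 1)
#' but is otherwise identical. Intended for inspection and testing; batch
#' training uses the fused compiled path inside [fitModel()].
#'
#' @param model a [DynMaskModel-class] (or a list with \code{params} and
#'   \code{config}).
#' @param S epoch matrix \code{[C, T]}.
#' @param training forwarded to [classifyHead()].
#' @param dropMask forwarded to [classifyHead()].
#' @return list with elements \code{logit}, \code{trace} (fields E,
#'   Epooled, L, Wv, Spad, D) and \code{maskDiagnostics} (fields r, li, M;
#'   NULL for the standard variant).
#' @export
dynForward <- function(model, S, training = FALSE, dropMask = NULL) {
  cfg <- model@config; p <- model@params
  if (nrow(S) != model@nChannels || ncol(S) != model@nTimes)
    stop("epoch is ", nrow(S), " x ", ncol(S), " but the model was built for ",
         model@nChannels, " x ", model@nTimes)
  E <- featureConv(S, p$Wf, p$bf)
  Ep <- channelGAP(E)
  L <- extractSegment(Ep, cfg@P, cfg@l)
  diag <- NULL
  if (cfg@variant == "masked") {
    r <- maskRatio(L, p$W, p$Wm1, p$bm1, p$Wm2, p$bm2)
    M <- softMask(r, cfg@l, cfg@lambda)
    diag <- list(r = r, li = r * cfg@l, M = M)
    Wv <- maskedKernels(p$W, M)
  } else {
    Wv <- p$W
  }
  Spad <- padInput(S, cfg@l)
  D <- dynamicConv(Spad, Wv, p$bv)
  logit <- classifyHead(D, p, training = training,
                        dropoutRate = cfg@dropoutRate, dropMask = dropMask)
  list(logit = logit,
       trace = list(E = E, Epooled = Ep, L = L, Wv = Wv, Spad = Spad, D = D),
       maskDiagnostics = diag)
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint holding all parameter arrays, the architecture
#' configuration, input dimensions and training history; loading is
#' bit-exact at stored precision.
#'
#' @param model a [DynMaskModel-class].
#' @param path file path.
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "DynMaskModel"))
  cfg <- model@config
  obj <- list(
    container = "DynMaskERP-checkpoint", version = 1L,
    config = list(K = cfg@K, l = cfg@l, P = cfg@P, lambda = cfg@lambda,
                  featureKernelWidth = cfg@featureKernelWidth,
                  dropoutRate = cfg@dropoutRate, variant = cfg@variant,
                  baseKernelsTrainable = cfg@baseKernelsTrainable,
                  initStd = cfg@initStd),
    params = model@params, nChannels = model@nChannels, nTimes = model@nTimes,
    history = model@history, trained = model@trained)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @return \code{loadCheckpoint} returns the restored [DynMaskModel-class].
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("no such checkpoint: ", path)
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$container, "DynMaskERP-checkpoint"))
    stop("not a DynMaskERP checkpoint: ", path)
  missing <- setdiff(c("config", "params", "nChannels", "nTimes"), names(obj))
  if (length(missing))
    stop("checkpoint is missing required field(s): ", paste(missing, collapse = ", "))
  cc <- obj$config
  cfg <- modelConfig(K = cc$K, l = cc$l, P = cc$P, lambda = cc$lambda,
                     featureKernelWidth = cc$featureKernelWidth,
                     dropoutRate = cc$dropoutRate, variant = cc$variant,
                     baseKernelsTrainable = cc$baseKernelsTrainable,
                     initStd = cc$initStd)
  new("DynMaskModel", config = cfg, params = obj$params,
      nChannels = as.integer(obj$nChannels), nTimes = as.integer(obj$nTimes),
      history = if (is.null(obj$history)) data.frame() else obj$history,
      trained = isTRUE(obj$trained))
}
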