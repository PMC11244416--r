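#' Construct a SyntheticSpec
#'
#' Defaults describe a desk-scale analogue of the CTP self-face study:
#' 10 subjects, 60 block-averaged trials each at the paradigm's 1:4
#' probe-to-irrelevant ratio (12 positives, 48 negatives per subject),
#' 30 channels, 1 s epochs at 1000 Hz. Positive (self-face) trials carry a
#' P300-like positivity inside 300--500 ms peaking near 400 ms; negative
#' (stranger-face) trials carry an N200-like negativity inside 180--250 ms
#' peaking near 211 ms. Amplitudes, between-subject variability and the
#' noise level are stated in microvolts and reflect 10-trial block
#' averages.
#'
#' @param nSubjects,trialsPerSubject dataset size.
#' @param imbalanceRatio negatives per positive (4 = the CTP ratio).
#' @param nChannels,nTimes,samplingRate montage size, epoch length
#'   (samples) and rate (Hz).
#' @param p300Window,p300Latency,p300LatencySd,p300Amplitude,p300AmplitudeSd
#'   positive-class component: confinement window (ms), mean/sd of the
#'   subject-level peak latency (ms) and amplitude (uV, positive).
#' @param n200Window,n200Latency,n200LatencySd,n200Amplitude,n200AmplitudeSd
#'   negative-class component (amplitude negative).
#' @param noiseSd additive Gaussian noise sd per channel/sample (uV).
#' @param noiseExponent spectral slope of the noise (0 = white; beta > 0
#'   gives 1/f^beta shaping).
#' @param topography per-channel gain in [0, 1] applied to the ERP
#'   components, maximum 1 at the Pz-like channel. Default: Gaussian
#'   falloff around \code{pzChannel}.
#' @param pzChannel index of the Pz-like channel (default: middle).
#' @param seed integer seed making the simulated set reproducible.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nSubjects = 10L, trialsPerSubject = 60L,
                          imbalanceRatio = 4L,
                          nChannels = 30L, nTimes = 1000L, samplingRate = 1000,
                          p300Window = c(300, 500),
                          p300Latency = 400, p300LatencySd = 25,
                          p300Amplitude = 5, p300AmplitudeSd = 1.5,
                          n200Window = c(180, 250),
                          n200Latency = 211, n200LatencySd = 10,
                          n200Amplitude = -3, n200AmplitudeSd = 1,
                          noiseSd = 3, noiseExponent = 0,
                          topography = NULL, pzChannel = NULL,
                          seed = 1L) {
  nChannels <- as.integer(nChannels)
  if (is.null(pzChannel)) pzChannel <- as.integer(ceiling(nChannels / 2))
  if (is.null(topography)) {
    d <- seq_len(nChannels) - pzChannel
    topography <- exp(-d^2 / (2 * (nChannels / 6)^2))
    topography <- topography / max(topography)
  }
  new("SyntheticSpec",
      nSubjects = as.integer(nSubjects),
      trialsPerSubject = as.integer(trialsPerSubject),
      imbalanceRatio = as.integer(imbalanceRatio),
      nChannels = nChannels, nTimes = as.integer(nTimes),
      samplingRate = as.numeric(samplingRate),
      p300Window = as.numeric(p300Window),
      p300Latency = as.numeric(p300Latency), p300LatencySd = as.numeric(p300LatencySd),
      p300Amplitude = as.numeric(p300Amplitude), p300AmplitudeSd = as.numeric(p300AmplitudeSd),
      n200Window = as.numeric(n200Window),
      n200Latency = as.numeric(n200Latency), n200LatencySd = as.numeric(n200LatencySd),
      n200Amplitude = as.numeric(n200Amplitude), n200AmplitudeSd = as.numeric(n200AmplitudeSd),
      noiseSd = as.numeric(noiseSd), noiseExponent = as.numeric(noiseExponent),
      topography = as.numeric(topography), pzChannel = as.integer(pzChannel),
      seed = as.integer(seed))
}

#' @export
setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %d subjects x %d trials (1:%d pos:neg), %d ch x %d samples @ %g Hz\n",
              object@nSubjects, object@trialsPerSubject, object@imbalanceRatio,
              object@nChannels, object@nTimes, object@samplingRate))
  cat(sprintf("  P300 %g uV in [%g, %g] ms (peak ~%g ms); N200 %g uV in [%g, %g] ms (peak ~%g ms)\n",
              object@p300Amplitude, object@p300Window[1], object@p300Window[2], object@p300Latency,
              object@n200Amplitude, object@n200Window[1], object@n200Window[2], object@n200Latency))
  cat(sprintf("  noise sd %g uV (spectral exponent %g), Pz-like channel %d, seed %d\n",
              object@noiseSd, object@noiseExponent, object@pzChannel, object@seed))
})

# Asymmetric raised-cosine bump: 0 at the window edges, exactly `amp` at
# `peakMs`, smooth, identically zero outside [win[1], win[2]].
componentBump <- function(tMs, win, peakMs, amp) {
  out <- numeric(length(tMs))
  peakMs <- min(max(peakMs, win[1] + 0.05 * diff(win)), win[2] - 0.05 * diff(win))
  rise <- tMs >= win[1] & tMs <= peakMs
  fall <- tMs > peakMs & tMs <= win[2]
  out[rise] <- 0.5 * (1 - cos(pi * (tMs[rise] - win[1]) / (peakMs - win[1])))
  out[fall] <- 0.5 * (1 + cos(pi * (tMs[fall] - peakMs) / (win[2] - peakMs)))
  amp * out
}

# Gaussian noise matrix [T, C], optionally 1/f^beta shaped along time,
# scaled so the marginal sd stays `sd`.
noiseMatrix <- function(nT, nC, sd, beta) {
  if (sd == 0) return(matrix(0, nT, nC))
  x <- matrix(stats::rnorm(nT * nC, sd = sd), nT, nC)
  if (beta == 0) return(x)
  freq <- c(1, seq_len(nT - 1))            # guard the DC bin
  freq <- pmin(freq, nT - freq + 1)        # mirrored frequency index
  gain <- freq^(-beta / 2)
  gain <- gain / sqrt(mean(gain^2))        # preserve total power
  Re(stats::mvfft(stats::mvfft(x) * gain, inverse = TRUE)) / nT
}

#' Simulate a CTP-paradigm ERP dataset
#'
#' Generates labelled, subject-tagged epochs per a [SyntheticSpec-class]:
#' each subject receives its own component latencies and amplitudes
#' (drawn from the spec's between-subject distributions, latencies kept
#' inside the component window), positive trials carry the P300-like
#' bump, negative trials the N200-like bump, both scaled by the channel
#' topography, plus additive Gaussian noise. Per subject the class split
#' is exactly 1 positive per \code{imbalanceRatio} negatives (at least one
#' positive). Deterministic given \code{spec@seed}.
#'
#' @param spec a [SyntheticSpec-class].
#' @return an [EpochSet-class].
#' @examples
#' es <- simulateEpochs(syntheticSpec(nSubjects = 2, trialsPerSubject = 10,
#'                                    nChannels = 4, nTimes = 200))
#' table(epochLabels(es))
#' @export
simulateEpochs <- function(spec) {
  validObject(spec)
  if (spec@trialsPerSubject < spec@imbalanceRatio + 1L)
    stop("trialsPerSubject must be at least imbalanceRatio + 1 to realise the class ratio")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(spec@seed)

  nT <- spec@nTimes; nC <- spec@nChannels
  tMs <- (seq_len(nT) - 1) / spec@samplingRate * 1000
  nPos <- max(1L, as.integer(round(spec@trialsPerSubject / (spec@imbalanceRatio + 1))))
  nNeg <- spec@trialsPerSubject - nPos
  n <- spec@nSubjects * spec@trialsPerSubject

  arr <- array(0, c(nT, nC, n))
  labels <- integer(n); subj <- integer(n)
  k <- 0L
  for (s in seq_len(spec@nSubjects)) {
    p3lat <- stats::rnorm(1, spec@p300Latency, spec@p300LatencySd)
    p3amp <- max(0.1, stats::rnorm(1, spec@p300Amplitude, spec@p300AmplitudeSd))
    n2lat <- stats::rnorm(1, spec@n200Latency, spec@n200LatencySd)
    n2amp <- min(-0.1, stats::rnorm(1, spec@n200Amplitude, spec@n200AmplitudeSd))
    posSig <- outer(componentBump(tMs, spec@p300Window, p3lat, p3amp), spec@topography)
    negSig <- outer(componentBump(tMs, spec@n200Window, n2lat, n2amp), spec@topography)
    lab <- sample(c(rep(1L, nPos), rep(0L, nNeg)))
    for (i in seq_along(lab)) {
      k <- k + 1L
      base <- if (lab[i] == 1L) posSig else negSig
      arr[, , k] <- base + noiseMatrix(nT, nC, spec@noiseSd, spec@noiseExponent)
      labels[k] <- lab[i]; subj[k] <- s
    }
  }
  chn <- sprintf("Ch%02d", seq_len(nC))
  chn[spec@pzChannel] <- "Pz"
  new("EpochSet", data = arr, labels = labels, subjectIds = subj,
      samplingRate = spec@samplingRate, onsetOffset = 0, channelNames = chn)
}
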