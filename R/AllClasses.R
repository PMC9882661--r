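#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' Raw single-channel bioimpedance recording
#'
#' Holds a continuous \eqn{\Delta Z} amplitude series together with the
#' sample rate, an optional baseline impedance \eqn{Z_0}, beat-start
#' boundaries (sample indices) and one session label per beat. Sessions
#' delimit e.g. cold-pressor vs recovery periods; several downstream
#' operations (smoothing windows, Taylor-residual pairs) never span a
#' session boundary.
#'
#' @slot samples numeric vector, \eqn{\Delta Z} amplitude (m\eqn{\Omega}, or
#'   dimensionless after normalisation by \eqn{Z_0}).
#' @slot sampleRate sampling rate in Hz.
#' @slot Z0 baseline impedance in Ohm, or \code{NA_real_} when unavailable.
#' @slot beatBoundaries strictly increasing integer sample indices marking
#'   beat starts; \code{m} boundaries delimit \code{m - 1} beats.
#' @slot sessionIds character, one label per beat.
#' @slot mode \code{"delta-z"} (raw) or \code{"delta-z-over-z0"} (normalised).
#' @exportClass RawRecording
setClass("RawRecording",
  representation(
    samples = "numeric",
    sampleRate = "numeric",
    Z0 = "numeric",
    beatBoundaries = "integer",
    sessionIds = "character",
    mode = "character"
  ),
  prototype(Z0 = NA_real_, mode = "delta-z")
)

setValidity("RawRecording", function(object) {
  msg <- NULL
  if (length(object@samples) == 0L)
    msg <- c(msg, "samples must be non-empty")
  if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
      object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (length(object@Z0) != 1L)
    msg <- c(msg, "Z0 must be a single value (NA when unavailable)")
  if (!is.na(object@Z0) && object@Z0 <= 0)
    msg <- c(msg, "Z0 must be positive when present")
  b <- object@beatBoundaries
  if (length(b) && any(diff(b) <= 0))
    msg <- c(msg, "beatBoundaries must be strictly increasing")
  if (length(b) && (b[1] < 1L || b[length(b)] > length(object@samples) + 1L))
    msg <- c(msg, "beatBoundaries out of range")
  nb <- max(length(b) - 1L, 0L)
  if (length(object@sessionIds) != nb)
    msg <- c(msg, "sessionIds must have one label per beat")
  if (!object@mode %in% c("delta-z", "delta-z-over-z0"))
    msg <- c(msg, "mode must be 'delta-z' or 'delta-z-over-z0'")
  if (is.null(msg)) TRUE else msg
})

#' One segmented cardiac-cycle waveform
#'
#' A single beat-to-beat interval of the recording: the waveform samples,
#' the beat duration, its start time, ordinal index, session label and an
#' optional reference blood-pressure label in mmHg.
#'
#' @slot x numeric waveform samples (\eqn{\Delta Z} scale of the recording).
#' @slot sampleRate Hz of \code{x}.
#' @slot duration beat duration in seconds.
#' @slot tStart seconds from the start of the recording.
#' @slot beatIndex ordinal beat number.
#' @slot sessionId session label.
#' @slot yTrue reference BP in mmHg, \code{NA_real_} when unlabeled.
#' @exportClass BeatRecord
setClass("BeatRecord",
  representation(
    x = "numeric",
    sampleRate = "numeric",
    duration = "numeric",
    tStart = "numeric",
    beatIndex = "integer",
    sessionId = "character",
    yTrue = "numeric"
  ),
  prototype(yTrue = NA_real_, tStart = 0, beatIndex = 1L, sessionId = "s1")
)

setValidity("BeatRecord", function(object) {
  msg <- NULL
  if (length(object@x) < 2L) msg <- c(msg, "waveform needs >= 2 samples")
  if (object@duration <= 0) msg <- c(msg, "duration must be positive")
  if (object@sampleRate <= 0) msg <- c(msg, "sampleRate must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Nine fiducial landmarks of one beat
#'
#' The morphological landmarks A--J (letter I unused, following the
#' conventional lettering of pulse-waveform fiducials) detected on the
#' inverted waveform \eqn{-\Delta Z}: A beat foot/onset, B systolic peak,
#' C point of maximal excursion (amplitude reference), D systolic downslope,
#' E dicrotic notch, F reflection-wave peak, G reflection downslope,
#' H late-diastolic decay point, J beat end. Only A, B, C, F and J carry
#' the downstream features; the remainder complete the morphological
#' description. Times are seconds within the beat and non-decreasing in
#' letter order; \code{dz} values are on the \eqn{\Delta Z} scale of the
#' input (so peaks of \eqn{-\Delta Z} have the most negative \code{dz}).
#'
#' @slot points data.frame with columns \code{point} (letter), \code{t_s},
#'   \code{dz}, exactly nine rows ordered A,B,C,D,E,F,G,H,J.
#' @slot duration beat duration in seconds.
#' @exportClass FiducialSet
setClass("FiducialSet",
  representation(points = "data.frame", duration = "numeric")
)

.FIDUCIAL_LETTERS <- c("A", "B", "C", "D", "E", "F", "G", "H", "J")

setValidity("FiducialSet", function(object) {
  msg <- NULL
  p <- object@points
  if (!identical(names(p), c("point", "t_s", "dz")))
    msg <- c(msg, "points must have columns point, t_s, dz")
  else {
    if (!identical(p$point, .FIDUCIAL_LETTERS))
      msg <- c(msg, "points must be the nine landmarks A,B,C,D,E,F,G,H,J in order")
    if (any(diff(p$t_s) < -1e-12))
      msg <- c(msg, "landmark times must be non-decreasing A..J")
    if (any(p$t_s < -1e-12) || any(p$t_s > object@duration + 1e-9))
      msg <- c(msg, "landmark times must lie within [0, duration]")
  }
  if (is.null(msg)) TRUE else msg
})

#' Beat dataset container
#'
#' The central container: a \linkS4class{SummarizedExperiment} whose single
#' assay \code{"waveform"} is the N x R matrix of resampled, zero-padded
#' beat waveforms (rows = waveform samples, columns = beats), with per-beat
#' metadata in \code{colData}: the three physiological features \code{u1}
#' (amplitude swing \eqn{(\Delta Z)_A - (\Delta Z)_C}), \code{u2} (inverse
#' systolic-to-reflection delay, 1/s), \code{u3} (beat-to-beat heart rate,
#' bpm), the optional reference label \code{bp} (mmHg), \code{session_id},
#' \code{t_start}, \code{duration_s} and \code{beat_index}.
#' \code{metadata()} carries \code{norm_stats} (the standardisation means
#' and SDs for waveform, features and label), a \code{standardized} flag and
#' the sampling geometry.
#'
#' Construct via \code{\link{extractBeatDataset}}, \code{\link{simulateBeats}}
#' or \code{\link{BeatDataset}}.
#'
#' @exportClass BeatDataset
setClass("BeatDataset", contains = "SummarizedExperiment")

.BD_REQUIRED <- c("beat_index", "t_start", "duration_s", "session_id",
                  "u1", "u2", "u3", "bp")

setValidity("BeatDataset", function(object) {
  msg <- NULL
  if (!"waveform" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'waveform' is required")
  cd <- SummarizedExperiment::colData(object)
  missing <- setdiff(.BD_REQUIRED, colnames(cd))
  if (length(missing))
    msg <- c(msg, paste0("colData lacks: ", paste(missing, collapse = ", ")))
  if (!length(missing) && ncol(object) > 1L) {
    if (is.unsorted(cd$t_start))
      msg <- c(msg, "beats must be ordered by t_start")
  }
  if (is.null(msg)) TRUE else msg
})

#' Configuration of the synthetic beat generator
#'
#' Parameters of the simulator used for validation studies: a piecewise
#' blood-pressure schedule (cold-pressor-like ramps, plateaus, recoveries),
#' three hemodynamic couplings that tie the waveform to BP, beat-to-beat
#' AR(1) pressure variability and additive waveform noise. Couplings, with
#' \eqn{\Delta = BP - bpBaseline}: pulse amplitude
#' \eqn{a(BP) = \alpha_0 - \alpha_1 \Delta} (vasoconstriction: amplitude
#' falls as pressure rises), reflection-wave delay
#' \eqn{d(BP) = d_0 - d_1 \Delta} (higher pressure, faster pulse-wave
#' velocity, earlier reflection), heart rate
#' \eqn{HR(BP) = h_0 + h_1 \Delta - h_2 \Delta^2} (biphasic cold-pressor
#' response: initial rise, later fall).
#'
#' @slot nBeats number of beats to generate.
#' @slot bpBaseline baseline BP in mmHg.
#' @slot bpProfile data.frame with columns \code{duration_s},
#'   \code{target_mmhg}, \code{session}: piecewise-linear schedule; each
#'   segment ramps linearly from the previous target to its own.
#' @slot alpha0,alpha1 base pulse amplitude (a.u.) and vasoconstriction
#'   gain (a.u. per mmHg).
#' @slot d0,d1 base reflection delay (s) and delay reduction (s per mmHg).
#' @slot h0,h1,h2 HR coupling: base bpm, linear gain, quadratic fall-off.
#' @slot reflAmp relative amplitude of the reflection wave.
#' @slot sigma1,sigma2 widths (s) of the systolic and reflection Gaussians.
#' @slot mu1 systolic peak time (s) within the beat.
#' @slot ar1Rho,ar1Sigma AR(1) beat-to-beat BP noise: lag-1 correlation and
#'   stationary SD (mmHg).
#' @slot ampJitterSd relative beat-to-beat pulse-amplitude jitter SD
#'   (respiratory/vasomotor modulation not explained by BP).
#' @slot delayJitterSd reflection-delay jitter SD in seconds.
#' @slot hrJitterSd heart-rate variability SD in bpm.
#' @slot noiseSd additive waveform noise SD (a.u.).
#' @slot sampleRate raw sampling rate in Hz.
#' @slot seed integer RNG seed.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    nBeats = "integer", bpBaseline = "numeric", bpProfile = "data.frame",
    alpha0 = "numeric", alpha1 = "numeric",
    d0 = "numeric", d1 = "numeric",
    h0 = "numeric", h1 = "numeric", h2 = "numeric",
    reflAmp = "numeric", sigma1 = "numeric", sigma2 = "numeric",
    mu1 = "numeric",
    ar1Rho = "numeric", ar1Sigma = "numeric",
    ampJitterSd = "numeric", delayJitterSd = "numeric",
    hrJitterSd = "numeric",
    noiseSd = "numeric", sampleRate = "numeric", seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- NULL
  if (object@nBeats < 2L) msg <- c(msg, "nBeats must be >= 2")
  if (object@alpha0 <= 0) msg <- c(msg, "alpha0 must be positive")
  if (object@d0 <= 0) msg <- c(msg, "d0 must be positive")
  if (object@sampleRate <= 0) msg <- c(msg, "sampleRate must be positive")
  if (object@ar1Rho < 0 || object@ar1Rho >= 1)
    msg <- c(msg, "ar1Rho must be in [0, 1)")
  pf <- object@bpProfile
  if (!all(c("duration_s", "target_mmhg", "session") %in% names(pf)))
    msg <- c(msg, "bpProfile needs columns duration_s, target_mmhg, session")
  else if (any(pf$duration_s <= 0))
    msg <- c(msg, "bpProfile durations must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Network architecture configuration
#'
#' The regressor: two 1D convolution layers (ReLU) on the waveform, max
#' pooling, flattening, concatenation with the three physiological
#' features, then a ReLU fully connected layer and a single linear output
#' neuron. The \code{"reference"} preset (32 filters/kernel 5; 64/3; pool
#' 3 stride 1; 60 FC units) is the architecture used for real recordings;
#' the \code{"compact"} preset (8/5; 8/3; pool 3/1; 16 FC units) is the
#' economical variant used in the package's simulation studies.
#'
#' @slot conv1Filters,conv1Kernel first convolution layer.
#' @slot conv2Filters,conv2Kernel second convolution layer.
#' @slot poolSize,poolStride max-pooling window and stride.
#' @slot fcUnits hidden fully connected units.
#' @slot inputLen waveform length N fed to the network.
#' @slot nFeatures number of physiological features M (3).
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(
    conv1Filters = "integer", conv1Kernel = "integer",
    conv2Filters = "integer", conv2Kernel = "integer",
    poolSize = "integer", poolStride = "integer",
    fcUnits = "integer", inputLen = "integer", nFeatures = "integer"
  )
)

setValidity("ModelConfig", function(object) {
  msg <- NULL
  sizes <- c(object@conv1Filters, object@conv1Kernel, object@conv2Filters,
             object@conv2Kernel, object@poolSize, object@poolStride,
             object@fcUnits, object@inputLen, object@nFeatures)
  if (any(sizes <= 0L)) msg <- c(msg, "all layer sizes must be positive")
  L1 <- object@inputLen - object@conv1Kernel + 1L
  L2 <- L1 - object@conv2Kernel + 1L
  if (L2 < object@poolSize)
    msg <- c(msg, "inputLen too short for the convolution/pool stack")
  if (object@poolStride != 1L)
    msg <- c(msg, "only poolStride = 1 is supported")
  if (is.null(msg)) TRUE else msg
})

#' Trained (or initialised) PINN model
#'
#' Bundles the architecture, the trainable parameters, the standardisation
#' statistics the model was trained under, the BP target it predicts and
#' the training report (epochs run, convergence flag, final losses,
#' per-epoch loss history, seed, physics-loss weight).
#'
#' @slot config a \linkS4class{ModelConfig}.
#' @slot params named list of weight matrices/vectors
#'   (W1, b1, W2, b2, Wf, bf, wo, bo).
#' @slot normStats standardisation statistics (as stored in the dataset).
#' @slot target which BP output the model predicts ("SBP", "DBP", "PP", ...).
#' @slot report list: \code{epochs}, \code{converged}, \code{final}
#'   (a \linkS4class{LossBundle}), \code{history} (matrix epoch x losses),
#'   \code{seed}, \code{lambdaPhys}, \code{stopLoss}.
#' @exportClass PinnModel
setClass("PinnModel",
  representation(
    config = "ModelConfig",
    params = "list",
    normStats = "list",
    target = "character",
    report = "list"
  ),
  prototype(target = "BP", report = list())
)

#' Loss decomposition at one parameter state
#'
#' The supervised mean-squared loss over the S labeled beats, the physics
#' loss (mean squared Taylor residual over within-session consecutive beat
#' pairs), their weighted total, and the per-pair residuals.
#'
#' @slot lConv supervised loss (standardized units squared).
#' @slot lPhys physics loss.
#' @slot lTotal \code{lConv + lambdaPhys * lPhys}.
#' @slot residuals per-pair Taylor residuals \eqn{h_i}.
#' @slot lambdaPhys physics-loss weight (default 1).
#' @slot nLabeled,nPairs the S and pair counts actually used.
#' @exportClass LossBundle
setClass("LossBundle",
  representation(
    lConv = "numeric", lPhys = "numeric", lTotal = "numeric",
    residuals = "numeric", lambdaPhys = "numeric",
    nLabeled = "integer", nPairs = "integer"
  )
)

setValidity("LossBundle", function(object) {
  msg <- NULL
  if (object@lConv < 0) msg <- c(msg, "lConv must be non-negative")
  if (object@lPhys < 0) msg <- c(msg, "lPhys must be non-negative")
  tot <- object@lConv + object@lambdaPhys * object@lPhys
  if (abs(object@lTotal - tot) > 1e-9 * max(1, abs(tot)))
    msg <- c(msg, "lTotal must equal lConv + lambdaPhys * lPhys")
  if (is.null(msg)) TRUE else msg
})

#' Labeled/unlabeled split of a beat dataset
#'
#' Indices of the beats whose labels enter the supervised loss
#' (\code{trainIdx}, size S) and the held-out remainder (\code{testIdx}),
#' with the binning metadata of the label-budget protocol that produced it.
#'
#' @slot trainIdx,testIdx integer beat indices (disjoint, covering all
#'   labeled beats).
#' @slot binWidth bin width in mmHg (1.0 minimal criterion, 0.5 growing sets).
#' @slot nBins number of bins K tiling the label range.
#' @slot seed RNG seed used for the draw.
#' @exportClass SplitSpec
setClass("SplitSpec",
  representation(
    trainIdx = "integer", testIdx = "integer",
    binWidth = "numeric", nBins = "integer", seed = "integer"
  )
)

setValidity("SplitSpec", function(object) {
  msg <- NULL
  if (length(intersect(object@trainIdx, object@testIdx)))
    msg <- c(msg, "trainIdx and testIdx must be disjoint")
  if (anyDuplicated(object@trainIdx))
    msg <- c(msg, "trainIdx must be unique")
  if (is.null(msg)) TRUE else msg
})

#' Accuracy report for BP predictions
#'
#' Mean error, SD of error, RMSE, Pearson correlation, Bland-Altman bias
#' and 95\% limits of agreement (bias +/- 1.96 SDE), and a simplified AAMI
#' flag (|ME| <= 5 mmHg and SDE <= 8 mmHg). All in mmHg on destandardised
#' predictions.
#'
#' @slot me,sde,rmse mmHg.
#' @slot pearsonR dimensionless; \code{NA} when undefined (constant input).
#' @slot n number of pairs.
#' @slot baBias,baLow,baHigh Bland-Altman bias and limits of agreement.
#' @slot aamiPass simplified AAMI flag.
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(
    me = "numeric", sde = "numeric", rmse = "numeric",
    pearsonR = "numeric", n = "integer",
    baBias = "numeric", baLow = "numeric", baHigh = "numeric",
    aamiPass = "logical"
  )
)

setValidity("MetricsReport", function(object) {
  msg <- NULL
  if (!is.na(object@pearsonR) &&
      (object@pearsonR < -1 - 1e-12 || object@pearsonR > 1 + 1e-12))
    msg <- c(msg, "pearsonR must lie in [-1, 1]")
  if (object@n >= 2L) {
    lhs <- object@rmse^2
    rhs <- object@me^2 + object@sde^2 * (object@n - 1L) / object@n
    if (abs(lhs - rhs) > 1e-6 * max(1, lhs))
      msg <- c(msg, "RMSE^2 must equal ME^2 + SDE^2 (n-1)/n")
  }
  if (is.null(msg)) TRUE else msg
})

#' Gradient-interpretation trace of a trained model
#'
#' Per-beat network predictions and feature gradients
#' \eqn{\partial y_{NN}/\partial u^k} destandardised to mmHg per physical
#' feature unit, plus per-session (and pooled, session \code{"all"}) trend
#' lines: the mean gradient within each integer-mmHg bin of the predicted
#' pressure.
#'
#' @slot beats data.frame: \code{beat_index}, \code{y_nn_mmhg}, \code{g1},
#'   \code{g2}, \code{g3}, \code{session_id}.
#' @slot trend data.frame: \code{session_id}, \code{bp_mmhg}, \code{g1},
#'   \code{g2}, \code{g3}; includes pooled rows with session_id "all".
#' @exportClass GradientTrace
setClass("GradientTrace",
  representation(beats = "data.frame", trend = "data.frame")
)
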