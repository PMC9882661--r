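#' @include accessors.R
NULL

#' Create a RawRecording
#'
#' @param samples numeric Delta-Z amplitude series.
#' @param sampleRate sampling rate in Hz.
#' @param Z0 baseline impedance in Ohm, or NA when unavailable.
#' @param beatBoundaries strictly increasing sample indices of beat starts.
#' @param sessionIds one session label per beat (length
#'   \code{length(beatBoundaries) - 1}); recycled if length 1.
#' @return a \linkS4class{RawRecording}.
#' @export
RawRecording <- function(samples, sampleRate, Z0 = NA_real_,
                         beatBoundaries = integer(), sessionIds = "s1") {
  nb <- max(length(beatBoundaries) - 1L, 0L)
  if (length(sessionIds) == 1L && nb > 1L)
    sessionIds <- rep(sessionIds, nb)
  if (nb == 0L) sessionIds <- character()
  methods::new("RawRecording", samples = as.numeric(samples),
               sampleRate = sampleRate, Z0 = Z0,
               beatBoundaries = as.integer(beatBoundaries),
               sessionIds = as.character(sessionIds))
}

#' Normalise a recording by its baseline impedance
#'
#' Divides the Delta-Z series by the baseline impedance \eqn{Z_0} when one
#' is available, yielding the dimensionless \eqn{\Delta Z / Z_0}; when
#' \eqn{Z_0} is unavailable the samples pass through unchanged and the
#' recording's \code{mode} flag records that raw \eqn{\Delta Z} is in use.
#'
#' @param rec a \linkS4class{RawRecording}.
#' @return the recording with samples normalised (or untouched) and its
#'   \code{mode} slot set to \code{"delta-z-over-z0"} or \code{"delta-z"}.
#' @examples
#' rec <- RawRecording(c(50, 100), sampleRate = 100, Z0 = 50)
#' normalizeDeltaZ(rec)@samples  # 1, 2
#' @export
normalizeDeltaZ <- function(rec) {
  stopifnot(is(rec, "RawRecording"))
  if (length(rec@samples) == 0L) stop("recording has no samples")
  if (is.na(rec@Z0)) {
    rec@mode <- "delta-z"
    return(rec)
  }
  if (rec@Z0 <= 0) stop("invalid baseline: Z0 must be positive")
  rec@samples <- rec@samples / rec@Z0
  rec@mode <- "delta-z-over-z0"
  rec
}

#' Segment a recording into beat-to-beat intervals
#'
#' Cuts the sample series at the supplied beat boundaries: each pair of
#' consecutive boundaries \code{[b_i, b_{i+1})} becomes one
#' \linkS4class{BeatRecord} with duration \code{(b_{i+1} - b_i)/sampleRate}.
#' Sample values are retained untouched.
#'
#' @param rec a \linkS4class{RawRecording} with at least two boundaries.
#' @param labels optional per-beat reference BP (mmHg).
#' @return list of \linkS4class{BeatRecord}.
#' @export
segmentBeats <- function(rec, labels = NULL) {
  stopifnot(is(rec, "RawRecording"))
  b <- rec@beatBoundaries
  if (length(b) < 2L)
    stop("insufficient boundaries: need >= 2 beat boundaries to segment")
  if (any(diff(b) <= 0))
    stop("boundary error: beatBoundaries must be strictly increasing")
  nb <- length(b) - 1L
  if (is.null(labels)) labels <- rep(NA_real_, nb)
  if (length(labels) != nb) stop("labels must have one value per beat")
  lapply(seq_len(nb), function(i) {
    idx <- b[i]:(b[i + 1L] - 1L)
    methods::new("BeatRecord",
      x = rec@samples[idx],
      sampleRate = rec@sampleRate,
      duration = (b[i + 1L] - b[i]) / rec@sampleRate,
      tStart = (b[i] - 1L) / rec@sampleRate,
      beatIndex = i,
      sessionId = rec@sessionIds[i],
      yTrue = labels[i])
  })
}

# sub-sample refinement of a peak location: least-squares quadratic over
# a +/- halfWin window around the integer argmax, vertex clamped to the
# window. Averages noise and removes sample-grid quantisation.
.refinePeak <- function(w, i, rate, halfWin = NULL) {
  n <- length(w)
  if (is.null(halfWin)) halfWin <- max(2L, as.integer(round(rate * 0.03)))
  lo <- max(1L, i - halfWin); hi <- min(n, i + halfWin)
  if (hi - lo < 4L) return((i - 1L) / rate)
  tt <- (lo:hi - 1) / rate
  fit <- stats::lm.fit(cbind(1, tt, tt^2), w[lo:hi])
  a2 <- fit$coefficients[3]
  if (!is.finite(a2) || a2 >= 0) return((i - 1L) / rate)
  vx <- -fit$coefficients[2] / (2 * a2)
  min(max(vx, tt[1]), tt[length(tt)])
}

# light moving-average smoother used before peak detection
.smoothForPeaks <- function(w, rate) {
  k <- max(3L, as.integer(round(rate * 0.04)))
  if (k %% 2L == 0L) k <- k + 1L
  if (k >= length(w)) return(w)
  as.numeric(stats::filter(w, rep(1 / k, k), sides = 2)) -> ws
  # fill filter() NA edges with the original samples
  nas <- is.na(ws)
  ws[nas] <- w[nas]
  ws
}

#' Extract the nine fiducial landmarks of a beat
#'
#' Detects, on the inverted waveform \eqn{-\Delta Z}, the landmarks
#' A (beat foot/onset), B (systolic peak), C (point of maximal excursion,
#' the amplitude reference for u1), D (systolic downslope), E (dicrotic
#' notch), F (reflection-wave peak), G (reflection downslope), H
#' (late-diastolic decay point) and J (beat end). Peak candidates come
#' from prominence-filtered local maxima of a lightly smoothed
#' \eqn{-\Delta Z}; beats without a distinguishable systolic and
#' reflection wave are rejected.
#'
#' @param beat a \linkS4class{BeatRecord}.
#' @param minPeakFrac minimum peak height as a fraction of the largest
#'   excursion for a local maximum to count as a wave.
#' @return a \linkS4class{FiducialSet}.
#' @export
extractFiducials <- function(beat, minPeakFrac = 0.2) {
  stopifnot(is(beat, "BeatRecord"))
  x <- beat@x
  rate <- beat@sampleRate
  n <- length(x)
  w <- -x                      # pulses point up on -Delta Z
  w <- w - min(w)
  ws <- .smoothForPeaks(w, rate)

  pk <- tryCatch(
    pracma::findpeaks(ws, minpeakheight = minPeakFrac * max(ws),
                      minpeakdistance = max(2L, as.integer(round(rate * 0.08)))),
    error = function(e) NULL)
  if (is.null(pk) || nrow(pk) < 2L)
    stop(sprintf(
      "fiducial-detection error at beat %d: fewer than two wave peaks found",
      beat@beatIndex))
  pk <- pk[order(pk[, 2]), , drop = FALSE]   # by time

  iB <- pk[1, 2]                             # systolic (first) wave
  after <- pk[pk[, 2] > iB, , drop = FALSE]
  iF <- after[which.max(after[, 1]), 2]      # strongest later wave
  iC <- which.max(ws)                        # maximal excursion
  iE <- (iB:iF)[which.min(ws[iB:iF])]        # dicrotic notch
  dws <- diff(ws)
  iD <- if (iE > iB) (iB:(iE - 1L))[which.min(dws[iB:(iE - 1L)])] else iB
  iG <- if (iF < n - 1L) (iF:(n - 1L))[which.min(dws[iF:(n - 1L)])] else iF
  # H: where the decay falls to half the reflection height, else midpoint
  half <- ws[iF] / 2
  tail_idx <- which(ws[iG:n] <= half)
  iH <- if (length(tail_idx)) iG + tail_idx[1] - 1L else (iG + n) %/% 2L
  iA <- 1L
  iJ <- n

  idx <- c(A = iA, B = iB, C = iC, D = iD, E = iE, F = iF, G = iG,
           H = iH, J = iJ)
  if (any(diff(idx) < 0L))
    stop(sprintf(
      "fiducial-detection error at beat %d: landmark ordering violated",
      beat@beatIndex))
  tRef <- pmin((idx - 1L) / rate, beat@duration)
  # sub-sample peak times for the landmarks feeding u2 (B and F)
  tRef["B"] <- .refinePeak(ws, iB, rate)
  tRef["F"] <- .refinePeak(ws, iF, rate)
  tRef["C"] <- if (iC == iB) tRef["B"] else if (iC == iF) tRef["F"]
               else tRef["C"]
  tRef <- cummax(tRef)            # refinement must not break the ordering
  pts <- data.frame(point = .FIDUCIAL_LETTERS,
                    t_s = tRef,
                    dz = x[idx])
  pts$t_s[pts$point == "J"] <- beat@duration
  methods::new("FiducialSet", points = pts, duration = beat@duration)
}

#' Compute the three physiological features of a beat
#'
#' The printed feature definitions on the fiducial landmarks:
#' \deqn{u^1 = (\Delta Z)_A - (\Delta Z)_C}
#' (amplitude swing, a blood-volume proxy),
#' \deqn{u^2 = 1 / (t_F - t_B)}
#' (inverse systolic-to-reflection delay, a pulse-wave-velocity proxy,
#' 1/s), and
#' \deqn{u^3 = 60 / (t_J - t_A)}
#' (beat-to-beat heart rate, bpm).
#'
#' @param fids a \linkS4class{FiducialSet}.
#' @return named numeric vector \code{c(u1, u2, u3)}.
#' @examples
#' # (dZ)_A = 0, (dZ)_C = -0.08, t_B = 0.1, t_F = 0.3, t_A = 0, t_J = 0.8
#' # gives u1 = 0.08, u2 = 5, u3 = 75
#' @export
computeFeatures <- function(fids) {
  stopifnot(is(fids, "FiducialSet"))
  p <- fids@points
  g <- function(letter, col) p[p$point == letter, col]
  tB <- g("B", "t_s"); tF <- g("F", "t_s")
  tA <- g("A", "t_s"); tJ <- g("J", "t_s")
  if (tF <= tB)
    stop("non-physical timing: t_F must exceed t_B")
  if (tJ <= tA)
    stop("non-physical timing: t_J must exceed t_A")
  c(u1 = g("A", "dz") - g("C", "dz"),
    u2 = 1 / (tF - tB),
    u3 = 60 / (tJ - tA))
}

#' Resample a beat to a target rate and zero-pad to fixed length
#'
#' Linearly resamples the beat waveform onto the target-rate sample grid
#' and right-pads with zeros to exactly \code{padLen} samples, so all beats
#' in a dataset share one length N. A beat whose resampled length exceeds
#' \code{padLen} raises an error rather than being truncated.
#'
#' @param beat a \linkS4class{BeatRecord}.
#' @param targetRate target sampling rate in Hz (default 30).
#' @param padLen output length N (default 60, i.e. 2 s at 30 Hz).
#' @return the beat with \code{x} replaced by the padded resampled waveform
#'   and \code{sampleRate} set to \code{targetRate}.
#' @export
resampleAndPad <- function(beat, targetRate = 30, padLen = 60) {
  stopifnot(is(beat, "BeatRecord"))
  nOut <- as.integer(ceiling(beat@duration * targetRate))
  if (nOut > padLen)
    stop(sprintf(
      "beat too long: %.3g s needs %d samples at %g Hz but padLen is %d",
      beat@duration, nOut, targetRate, padLen))
  tOld <- (seq_along(beat@x) - 1) / beat@sampleRate
  tNew <- (seq_len(nOut) - 1) / targetRate
  y <- stats::approx(tOld, beat@x, xout = pmin(tNew, max(tOld)),
                     rule = 2)$y
  beat@x <- c(y, rep(0, padLen - nOut))
  beat@sampleRate <- targetRate
  methods::validObject(beat)
  beat
}

#' Build a BeatDataset from a recording
#'
#' The full per-beat preprocessing chain: segment at the beat boundaries,
#' extract fiducial landmarks and the three physiological features from
#' each raw-rate beat, resample and zero-pad each waveform, and assemble
#' the container. Optionally applies \code{\link{movingAverageSmooth}}.
#' Beats whose fiducials cannot be detected raise an error carrying the
#' beat index (no silent dropping), unless \code{onError = "drop"}.
#'
#' @param rec a \linkS4class{RawRecording}.
#' @param labels optional per-beat BP labels (mmHg).
#' @param targetRate,padLen see \code{\link{resampleAndPad}}.
#' @param smooth logical; apply the three-beat moving average.
#' @param window,overlap smoothing window parameters.
#' @param onError \code{"stop"} (default) or \code{"drop"} failing beats.
#' @return a \linkS4class{BeatDataset} (unstandardized).
#' @export
extractBeatDataset <- function(rec, labels = NULL, targetRate = 30,
                               padLen = 60, smooth = FALSE, window = 3L,
                               overlap = 1L, onError = c("stop", "drop")) {
  onError <- match.arg(onError)
  beats <- segmentBeats(rec, labels)
  feats <- matrix(NA_real_, length(beats), 3)
  keep <- rep(TRUE, length(beats))
  for (i in seq_along(beats)) {
    u <- tryCatch(computeFeatures(extractFiducials(beats[[i]])),
                  error = function(e) {
                    if (onError == "stop") stop(e)
                    NULL
                  })
    if (is.null(u)) keep[i] <- FALSE else feats[i, ] <- u
  }
  beats <- beats[keep]
  feats <- feats[keep, , drop = FALSE]
  padded <- lapply(beats, resampleAndPad, targetRate = targetRate,
                   padLen = padLen)
  wf <- vapply(padded, methods::slot, numeric(padLen), "x")
  ds <- BeatDataset(
    waveform = wf, features = feats,
    labels = vapply(beats, methods::slot, numeric(1), "yTrue"),
    sessionId = vapply(beats, methods::slot, character(1), "sessionId"),
    tStart = vapply(beats, methods::slot, numeric(1), "tStart"),
    duration = vapply(beats, methods::slot, numeric(1), "duration"),
    sampleRate = targetRate,
    beatIndex = vapply(beats, methods::slot, integer(1), "beatIndex"))
  if (smooth) ds <- movingAverageSmooth(ds, window = window,
                                        overlap = overlap)
  ds
}

#' Three-beat moving average over waveforms, features and labels
#'
#' Averages aligned waveforms, feature rows and labels over windows of
#' \code{window} consecutive beats advancing by \code{window - overlap}
#' beats (default: three-beat windows sharing one beat, stride 2).
#' Windows never span a session boundary; within each session of length
#' R the output has \code{floor((R - window)/stride) + 1} beats.
#'
#' @param ds a \linkS4class{BeatDataset}.
#' @param window window length in beats (default 3).
#' @param overlap beats shared by consecutive windows (default 1).
#' @return the smoothed \linkS4class{BeatDataset}.
#' @export
movingAverageSmooth <- function(ds, window = 3L, overlap = 1L) {
  stopifnot(is(ds, "BeatDataset"))
  window <- as.integer(window); overlap <- as.integer(overlap)
  if (overlap >= window)
    stop("invalid window: overlap must be smaller than window")
  stride <- window - overlap
  cd <- SummarizedExperiment::colData(ds)
  sess <- cd$session_id
  runs <- rle(sess)
  starts <- cumsum(c(1L, runs$lengths))[seq_along(runs$lengths)]
  pieces <- list()
  for (s in seq_along(runs$lengths)) {
    R <- runs$lengths[s]
    if (R < window) next
    w0 <- seq.int(0L, R - window, by = stride)
    for (w in w0) {
      pieces[[length(pieces) + 1L]] <-
        starts[s] + w + seq_len(window) - 1L
    }
  }
  if (!length(pieces))
    stop(sprintf("dataset too short: need >= %d beats within a session",
                 window))
  wf <- waveforms(ds); U <- beatFeatures(ds); y <- bpLabels(ds)
  wfS <- vapply(pieces, function(ix) rowMeans(wf[, ix, drop = FALSE]),
                numeric(nrow(wf)))
  uS <- t(vapply(pieces, function(ix) colMeans(U[ix, , drop = FALSE]),
                 numeric(3)))
  yS <- vapply(pieces, function(ix) mean(y[ix]), numeric(1))
  first <- vapply(pieces, `[`, integer(1), 1L)
  BeatDataset(
    waveform = wfS, features = uS, labels = yS,
    sessionId = sess[first],
    tStart = cd$t_start[first],
    duration = vapply(pieces, function(ix) mean(cd$duration_s[ix]),
                      numeric(1)),
    sampleRate = S4Vectors::metadata(ds)$sample_rate_hz,
    normStats = normStats(ds),
    standardized = isStandardized(ds))
}

#' Standardize a beat dataset
#'
#' Zero-mean/unit-SD transform of all model inputs and the output label,
#' with statistics computed over the complete dataset (transductive, i.e.
#' unlabeled test beats contribute to the statistics; pass
#' \code{idx = trainIdx(split)} for a strictly train-only variant).
#' The waveform uses a single mean/SD over the whole matrix (one channel);
#' each feature column and the label use their own. Statistics are stored
#' in \code{normStats} so the transform is exactly invertible.
#'
#' @param ds an unstandardized \linkS4class{BeatDataset} with labels.
#' @param idx optional beat indices over which to compute the statistics
#'   (default: all beats).
#' @return the standardized dataset.
#' @export
standardizeDataset <- function(ds, idx = NULL) {
  stopifnot(is(ds, "BeatDataset"))
  if (isStandardized(ds)) stop("dataset is already standardized")
  if (is.null(idx)) idx <- seq_len(ncol(ds))
  wf <- waveforms(ds); U <- beatFeatures(ds); y <- bpLabels(ds)
  sdn <- function(v) stats::sd(v)
  st <- list(
    x_mean = mean(wf[, idx]), x_sd = sdn(as.numeric(wf[, idx])),
    u_mean = colMeans(U[idx, , drop = FALSE]),
    u_sd = apply(U[idx, , drop = FALSE], 2, sdn),
    y_mean = mean(y[idx], na.rm = TRUE),
    y_sd = stats::sd(y[idx][!is.na(y[idx])])
  )
  if (!is.finite(st$y_sd) || st$y_sd == 0)
    stop("degenerate channel: label column has zero variance")
  if (st$x_sd == 0 || any(st$u_sd == 0))
    stop("degenerate channel: zero-variance input channel")
  cd <- SummarizedExperiment::colData(ds)
  BeatDataset(
    waveform = (wf - st$x_mean) / st$x_sd,
    features = sweep(sweep(U, 2, st$u_mean), 2, st$u_sd, "/"),
    labels = (y - st$y_mean) / st$y_sd,
    sessionId = cd$session_id, tStart = cd$t_start,
    duration = cd$duration_s,
    sampleRate = S4Vectors::metadata(ds)$sample_rate_hz,
    normStats = st, standardized = TRUE)
}

#' Invert the standardization of a beat dataset
#'
#' @param ds a standardized \linkS4class{BeatDataset}.
#' @return the dataset on the original physical scales (norm_stats kept).
#' @export
destandardizeDataset <- function(ds) {
  stopifnot(is(ds, "BeatDataset"))
  st <- normStats(ds)
  if (!isStandardized(ds) || is.null(st))
    stop("dataset is not standardized")
  cd <- SummarizedExperiment::colData(ds)
  BeatDataset(
    waveform = waveforms(ds) * st$x_sd + st$x_mean,
    features = sweep(sweep(beatFeatures(ds), 2, st$u_sd, "*"), 2,
                     st$u_mean, "+"),
    labels = bpLabels(ds) * st$y_sd + st$y_mean,
    sessionId = cd$session_id, tStart = cd$t_start,
    duration = cd$duration_s,
    sampleRate = S4Vectors::metadata(ds)$sample_rate_hz,
    normStats = st, standardized = FALSE)
}

#' Map standardized predictions back to mmHg
#'
#' @param y numeric standardized predictions.
#' @param st a norm_stats list (from \code{\link{normStats}}).
#' @return predictions in mmHg.
#' @export
destandardizeY <- function(y, st) y * st$y_sd + st$y_mean
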