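#' @include AllGenerics.R
NULL

#' Construct a BeatDataset
#'
#' Low-level constructor assembling the container from aligned per-beat
#' pieces. Most users obtain datasets from \code{\link{extractBeatDataset}}
#' or \code{\link{simulateBeats}} instead.
#'
#' @param waveform N x R numeric matrix (waveform samples x beats).
#' @param features R x 3 matrix or data.frame with columns u1, u2, u3.
#' @param labels numeric length-R reference BP (mmHg), NA allowed.
#' @param sessionId character length-R session labels.
#' @param tStart,duration numeric length-R beat start times and durations (s).
#' @param sampleRate waveform sample rate in Hz after resampling.
#' @param normStats optional standardisation statistics list.
#' @param standardized logical flag.
#' @param beatIndex optional original beat indices (default 1..R).
#' @return a \linkS4class{BeatDataset}.
#' @export
BeatDataset <- function(waveform, features, labels = NULL, sessionId = NULL,
                        tStart = NULL, duration = NULL, sampleRate = 30,
                        normStats = NULL, standardized = FALSE,
                        beatIndex = NULL) {
  waveform <- as.matrix(waveform)
  R <- ncol(waveform)
  features <- as.matrix(features)
  if (nrow(features) != R)
    stop("features must have one row per beat")
  colnames(features) <- c("u1", "u2", "u3")
  if (is.null(labels)) labels <- rep(NA_real_, R)
  if (is.null(sessionId)) sessionId <- rep("s1", R)
  if (is.null(tStart)) tStart <- seq_len(R) - 1
  if (is.null(duration)) duration <- rep(1, R)
  if (is.null(beatIndex)) beatIndex <- seq_len(R)
  cd <- S4Vectors::DataFrame(
    beat_index = as.integer(beatIndex),
    t_start = as.numeric(tStart),
    duration_s = as.numeric(duration),
    session_id = as.character(sessionId),
    u1 = features[, 1], u2 = features[, 2], u3 = features[, 3],
    bp = as.numeric(labels)
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(waveform = unname(waveform)),
    colData = cd,
    metadata = list(norm_stats = normStats, standardized = standardized,
                    sample_rate_hz = sampleRate)
  )
  methods::new("BeatDataset", se)
}

#' @rdname BeatDataset-accessors
#' @export
setMethod("waveforms", "BeatDataset", function(x)
  SummarizedExperiment::assay(x, "waveform"))

#' @rdname BeatDataset-accessors
#' @export
setMethod("beatFeatures", "BeatDataset", function(x) {
  cd <- SummarizedExperiment::colData(x)
  m <- cbind(u1 = cd$u1, u2 = cd$u2, u3 = cd$u3)
  rownames(m) <- NULL
  m
})

#' @rdname BeatDataset-accessors
#' @export
setMethod("bpLabels", "BeatDataset", function(x)
  SummarizedExperiment::colData(x)$bp)

#' @rdname BeatDataset-accessors
#' @export
setMethod("sessionIds", "BeatDataset", function(x)
  SummarizedExperiment::colData(x)$session_id)

#' @rdname BeatDataset-accessors
#' @export
setMethod("normStats", "BeatDataset", function(x)
  S4Vectors::metadata(x)$norm_stats)

#' @rdname BeatDataset-accessors
#' @export
setMethod("isStandardized", "BeatDataset", function(x)
  isTRUE(S4Vectors::metadata(x)$standardized))

#' @rdname BeatDataset-accessors
#' @export
setMethod("nBeats", "BeatDataset", function(x) ncol(x))

#' @rdname SplitSpec-accessors
#' @export
setMethod("trainIdx", "SplitSpec", function(x) x@trainIdx)

#' @rdname SplitSpec-accessors
#' @export
setMethod("testIdx", "SplitSpec", function(x) x@testIdx)

#' @rdname trainReport
#' @export
setMethod("trainReport", "PinnModel", function(x) x@report)

#' Convert a MetricsReport to a one-row data.frame
#'
#' @param x a \linkS4class{MetricsReport}.
#' @param ... ignored.
#' @return one-row data.frame of the metric fields.
#' @export
setMethod("as.data.frame", "MetricsReport", function(x, ...) {
  data.frame(me = x@me, sde = x@sde, rmse = x@rmse, pearson_r = x@pearsonR,
             n = x@n, ba_bias = x@baBias, ba_low = x@baLow,
             ba_high = x@baHigh, aami_pass = x@aamiPass)
})

setMethod("show", "BeatDataset", function(object) {
  cat("BeatDataset with", ncol(object), "beats,",
      nrow(object), "waveform samples/beat\n")
  cat("  sessions:", paste(unique(sessionIds(object)), collapse = ", "), "\n")
  nl <- sum(!is.na(bpLabels(object)))
  cat("  labeled beats:", nl, "/", ncol(object), "\n")
  cat("  standardized:", isStandardized(object), "\n")
})

setMethod("show", "SplitSpec", function(object) {
  cat("SplitSpec: S =", length(object@trainIdx), "labeled /",
      length(object@testIdx), "held out; bin width",
      object@binWidth, "mmHg, K =", object@nBins, "bins\n")
})

setMethod("show", "LossBundle", function(object) {
  cat(sprintf("LossBundle: L_conv %.6g + %.3g * L_phys %.6g = L_total %.6g (S=%d, pairs=%d)\n",
              object@lConv, object@lambdaPhys, object@lPhys, object@lTotal,
              object@nLabeled, object@nPairs))
})

setMethod("show", "PinnModel", function(object) {
  cfg <- object@config
  cat(sprintf("PinnModel [%s]: conv %d/k%d -> %d/k%d, pool %d/%d, fc %d -> 1; input %d + %d features\n",
              object@target, cfg@conv1Filters, cfg@conv1Kernel,
              cfg@conv2Filters, cfg@conv2Kernel, cfg@poolSize,
              cfg@poolStride, cfg@fcUnits, cfg@inputLen, cfg@nFeatures))
  if (length(object@report)) {
    r <- object@report
    cat(sprintf("  trained %d epochs, converged: %s, lambda_phys = %g\n",
                r$epochs, r$converged, r$lambdaPhys))
  }
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport (n=%d): ME %.2f, SDE %.2f, RMSE %.2f mmHg, r %.3f\n",
              object@n, object@me, object@sde, object@rmse, object@pearsonR))
  cat(sprintf("  Bland-Altman %.2f [%.2f, %.2f] mmHg; simplified AAMI flag: %s\n",
              object@baBias, object@baLow, object@baHigh, object@aamiPass))
})

setMethod("show", "FiducialSet", function(object) {
  cat("FiducialSet (9 landmarks, beat duration",
      format(object@duration, digits = 4), "s)\n")
  print(object@points, row.names = FALSE)
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d beats, baseline %g mmHg, %d profile segments, seed %d\n",
              object@nBeats, object@bpBaseline, nrow(object@bpProfile),
              object@seed))
})
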