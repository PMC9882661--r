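#' @include evaluation.R
NULL

#' Read a raw recording from CSV
#'
#' Expected columns: \code{time_s}, \code{dz}, \code{session_id},
#' \code{beat_start} (1 at samples where a beat begins), and optionally
#' \code{z0} (constant baseline impedance) and \code{bp} (per-sample
#' reference BP; the value at each beat start becomes the beat label).
#'
#' @param path CSV file path.
#' @return list with \code{recording} (a \linkS4class{RawRecording}) and
#'   \code{labels} (per-beat BP or NA).
#' @export
readRawRecording <- function(path) {
  df <- as.data.frame(readr::read_csv(path, show_col_types = FALSE))
  need <- c("time_s", "dz", "session_id", "beat_start")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("format error: missing columns: ",
         paste(missing, collapse = ", "))
  rate <- 1 / stats::median(diff(df$time_s))
  bounds <- which(df$beat_start == 1)
  nb <- max(length(bounds) - 1L, 0L)
  rec <- RawRecording(df$dz, sampleRate = rate,
                      Z0 = if ("z0" %in% names(df)) df$z0[1] else NA_real_,
                      beatBoundaries = bounds,
                      sessionIds = df$session_id[bounds[seq_len(nb)]])
  labels <- if ("bp" %in% names(df)) df$bp[bounds[seq_len(nb)]]
            else rep(NA_real_, nb)
  list(recording = rec, labels = labels)
}

#' Write / read a BeatDataset as a plain-text bundle
#'
#' The dataset is stored as a directory of text files: \code{waveform.csv}
#' (one column per beat), \code{beats.csv} (per-beat metadata, features and
#' labels) and \code{meta.json} (standardisation statistics and flags).
#' Doubles round-trip exactly.
#'
#' @param ds a \linkS4class{BeatDataset}.
#' @param dir directory to create/fill.
#' @return \code{writeBeatDataset}: the directory, invisibly;
#'   \code{readBeatDataset}: the \linkS4class{BeatDataset}.
#' @export
writeBeatDataset <- function(ds, dir) {
  stopifnot(is(ds, "BeatDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wf <- as.data.frame(waveforms(ds))
  names(wf) <- paste0("beat_", seq_len(ncol(wf)))
  readr::write_csv(wf, file.path(dir, "waveform.csv"))
  cd <- as.data.frame(SummarizedExperiment::colData(ds))
  readr::write_csv(cd, file.path(dir, "beats.csv"))
  meta <- list(standardized = isStandardized(ds),
               sample_rate_hz = S4Vectors::metadata(ds)$sample_rate_hz,
               norm_stats = normStats(ds))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname writeBeatDataset
#' @export
readBeatDataset <- function(dir) {
  fw <- file.path(dir, "waveform.csv")
  fb <- file.path(dir, "beats.csv")
  fm <- file.path(dir, "meta.json")
  if (!all(file.exists(c(fw, fb, fm))))
    stop("format error: dataset bundle needs waveform.csv, beats.csv, meta.json")
  wf <- as.matrix(as.data.frame(readr::read_csv(fw, show_col_types = FALSE)))
  cd <- as.data.frame(readr::read_csv(fb, show_col_types = FALSE))
  missing <- setdiff(.BD_REQUIRED, names(cd))
  if (length(missing))
    stop("format error: beats.csv missing fields: ",
         paste(missing, collapse = ", "))
  meta <- jsonlite::read_json(fm, simplifyVector = TRUE)
  st <- meta$norm_stats
  if (!is.null(st) && length(st)) {
    st <- as.list(st)
  } else st <- NULL
  BeatDataset(waveform = wf,
              features = as.matrix(cd[, c("u1", "u2", "u3")]),
              labels = cd$bp, sessionId = cd$session_id,
              tStart = cd$t_start, duration = cd$duration_s,
              sampleRate = meta$sample_rate_hz,
              normStats = st,
              standardized = isTRUE(meta$standardized),
              beatIndex = cd$beat_index)
}

#' Write / read a split as JSON
#'
#' @param split a \linkS4class{SplitSpec}.
#' @param path JSON file path.
#' @return \code{writeSplit}: the path, invisibly; \code{readSplit}: the
#'   \linkS4class{SplitSpec}.
#' @export
writeSplit <- function(split, path) {
  stopifnot(is(split, "SplitSpec"))
  jsonlite::write_json(
    list(train_idx = split@trainIdx, test_idx = split@testIdx,
         bin_width_mmhg = split@binWidth, n_bins = split@nBins,
         seed = split@seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSplit
#' @export
readSplit <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("SplitSpec", trainIdx = as.integer(j$train_idx),
               testIdx = as.integer(j$test_idx),
               binWidth = j$bin_width_mmhg, nBins = as.integer(j$n_bins),
               seed = as.integer(j$seed))
}

#' Run the end-to-end pipeline
#'
#' Simulate (or take) a beat dataset, smooth, standardize, build the
#' minimal-labeling split, train the PINN (and optionally the matched
#' conventional-CNN baseline), evaluate on the held-out beats and compute
#' the gradient trace. All randomness flows through the explicit seeds;
#' re-running with an identical configuration reproduces identical splits
#' and loss curves.
#'
#' @param simCfg a \linkS4class{SimConfig}, or NULL when \code{data} given.
#' @param data an unstandardized labeled \linkS4class{BeatDataset}
#'   (alternative to \code{simCfg}).
#' @param modelCfg a \linkS4class{ModelConfig} (default: compact preset).
#' @param target BP output name stamped on the model.
#' @param smooth apply the three-beat moving average (default TRUE).
#' @param binWidth minimal-criterion bin width, mmHg.
#' @param lambdaPhys physics-loss weight of the main model.
#' @param baseline also train the lambda = 0 conventional CNN.
#' @param stopLoss,maxEpochs,lr training controls (see
#'   \code{\link{trainPINN}}).
#' @param splitSeed,initSeed seeds of the split draw and the weight init.
#' @param outDir optional directory: writes dataset bundle, split.json,
#'   loss_history.csv, metrics.json and trace.csv.
#' @return list: \code{dataset} (standardized), \code{split},
#'   \code{model}, \code{metrics}, \code{trace}, optionally
#'   \code{baselineModel}/\code{baselineMetrics}, and \code{seeds}.
#' @export
runPipeline <- function(simCfg = NULL, data = NULL, modelCfg = NULL,
                        target = "SBP", smooth = TRUE, binWidth = 1,
                        lambdaPhys = 1, baseline = FALSE, stopLoss = 0.01,
                        maxEpochs = 20000, lr = 3e-3, splitSeed = 0,
                        initSeed = 0, outDir = NULL) {
  if (is.null(simCfg) && is.null(data))
    stop("dependency error at stage 'data': supply simCfg or data")
  ds <- if (!is.null(data)) data else simulateBeats(simCfg)$dataset
  if (all(is.na(bpLabels(ds))))
    stop(sprintf(
      "dependency error at stage 'split': dataset lacks %s labels", target))
  if (smooth) ds <- movingAverageSmooth(ds)
  ds <- standardizeDataset(ds)
  st <- normStats(ds)
  labsMm <- destandardizeY(bpLabels(ds), st)
  split <- minimalSplit(labsMm, binWidth = binWidth, seed = splitSeed)
  model <- trainPINN(ds, split, config = modelCfg,
                     lambdaPhys = lambdaPhys, stopLoss = stopLoss,
                     maxEpochs = maxEpochs, lr = lr, seed = initSeed,
                     target = target)
  pred <- predictBP(model, ds)
  metrics <- computeMetrics(labsMm[testIdx(split)], pred[testIdx(split)])
  trace <- gradientTrace(model, ds)
  out <- list(dataset = ds, split = split, model = model,
              metrics = metrics, trace = trace,
              seeds = list(sim = if (is.null(simCfg)) NA_integer_
                           else simCfg@seed,
                           split = splitSeed, init = initSeed))
  if (baseline) {
    bm <- trainPINN(ds, split, config = modelCfg, lambdaPhys = 0,
                    stopLoss = stopLoss, maxEpochs = maxEpochs, lr = lr,
                    seed = initSeed, target = target)
    out$baselineModel <- bm
    bpred <- predictBP(bm, ds)
    out$baselineMetrics <- computeMetrics(labsMm[testIdx(split)],
                                          bpred[testIdx(split)])
  }
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeBeatDataset(ds, file.path(outDir, "dataset"))
    writeSplit(split, file.path(outDir, "split.json"))
    hist <- as.data.frame(trainReport(model)$history)
    hist$epoch <- seq_len(nrow(hist)) - 1L
    readr::write_csv(hist, file.path(outDir, "loss_history.csv"))
    jsonlite::write_json(
      c(as.data.frame(metrics)[1, ], out$seeds, target = target),
      file.path(outDir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    readr::write_csv(trace@beats, file.path(outDir, "trace.csv"))
  }
  out
}

#' Sweep the growing-training-set protocol
#'
#' Trains one model per nested split emitted by \code{\link{growingSets}}
#' (optionally restricted to chosen training-set sizes) and reports the
#' held-out metrics and gradient trace of each.
#'
#' @param ds a standardized \linkS4class{BeatDataset}.
#' @param sizes optional vector of training-set sizes to keep (default:
#'   all emitted splits).
#' @param config,lambdaPhys,stopLoss,maxEpochs,lr,initSeed training
#'   controls (see \code{\link{trainPINN}}).
#' @param splitSeed seed of the pool draw.
#' @param trace also compute gradient traces (default TRUE).
#' @return list of per-model reports: \code{size}, \code{split},
#'   \code{model}, \code{metrics}, \code{trace}.
#' @export
sweepGrowingSets <- function(ds, sizes = NULL, config = NULL,
                             lambdaPhys = 1, stopLoss = 0.01,
                             maxEpochs = 20000, lr = 3e-3, splitSeed = 0,
                             initSeed = 0, trace = TRUE) {
  stopifnot(is(ds, "BeatDataset"))
  if (!isStandardized(ds)) stop("dataset must be standardized")
  st <- normStats(ds)
  labsMm <- destandardizeY(bpLabels(ds), st)
  splits <- growingSets(labsMm, seed = splitSeed)
  if (!is.null(sizes))
    splits <- Filter(function(s) length(trainIdx(s)) %in% sizes, splits)
  lapply(splits, function(s) {
    model <- trainPINN(ds, s, config = config, lambdaPhys = lambdaPhys,
                       stopLoss = stopLoss, maxEpochs = maxEpochs,
                       lr = lr, seed = initSeed)
    pred <- predictBP(model, ds)
    list(size = length(trainIdx(s)), split = s, model = model,
         metrics = computeMetrics(labsMm[testIdx(s)], pred[testIdx(s)]),
         trace = if (trace) gradientTrace(model, ds) else NULL)
  })
}
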