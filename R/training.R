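#' @include pinn-loss.R
NULL

# bin index of each label on a grid of binWidth tiles anchored at min;
# the final bin is closed on the right
.binIndex <- function(labels, binWidth) {
  lo <- min(labels); hi <- max(labels)
  K <- as.integer(ceiling((hi - lo) / binWidth))
  list(bin = pmin(as.integer(floor((labels - lo) / binWidth)) + 1L, K),
       K = K)
}

# one uniformly drawn index per non-empty bin (seeded)
.onePerBin <- function(labels, idx, binWidth, seed) {
  b <- .binIndex(labels, binWidth)
  picks <- withr::with_seed(as.integer(seed), {
    vapply(sort(unique(b$bin)), function(k) {
      cand <- idx[b$bin == k]
      cand[sample.int(length(cand), 1L)]
    }, integer(1))
  })
  list(picks = picks, K = b$K)
}

#' Minimal-labeling train/test split
#'
#' The minimal training criterion: tile the label range with K bins of
#' \code{binWidth} mmHg (K = ceiling(range / binWidth)), draw exactly one
#' beat uniformly from each non-empty bin into the supervised training
#' set, and hold out everything else. With labels spread over a 40 mmHg
#' range this yields ~40 training beats regardless of dataset size.
#'
#' @param labels numeric BP labels in mmHg (NA labels are excluded from
#'   both sets).
#' @param binWidth bin width in mmHg (default 1).
#' @param seed integer RNG seed for the per-bin draws.
#' @return a \linkS4class{SplitSpec}.
#' @export
minimalSplit <- function(labels, binWidth = 1, seed = 0) {
  idx <- which(is.finite(labels))
  if (!length(idx)) stop("no finite labels")
  y <- labels[idx]
  if (max(y) <= min(y))
    stop("degenerate range: labels are constant")
  res <- .onePerBin(y, idx, binWidth, seed)
  train <- sort(res$picks)
  methods::new("SplitSpec", trainIdx = train,
               testIdx = setdiff(idx, train),
               binWidth = binWidth, nBins = res$K,
               seed = as.integer(seed))
}

#' Growing-training-set protocol
#'
#' Builds one seeded pool with one beat per non-empty 0.5-mmHg bin
#' (pool size k = number of non-empty bins), shuffles it once, and emits
#' nested splits of sizes 1, 3, 5, ..., up to k -- each split's training
#' set is the previous one plus two new pool points, giving ceiling(k/2)
#' splits in total.
#'
#' @inheritParams minimalSplit
#' @param binWidth bin width in mmHg (default 0.5).
#' @return list of \linkS4class{SplitSpec}, ordered by training-set size.
#' @export
growingSets <- function(labels, binWidth = 0.5, seed = 0) {
  idx <- which(is.finite(labels))
  if (!length(idx)) stop("no finite labels")
  y <- labels[idx]
  if (max(y) <= min(y))
    stop("degenerate range: labels are constant")
  res <- .onePerBin(y, idx, binWidth, seed)
  pool <- withr::with_seed(as.integer(seed) + 1L,
                           res$picks[sample.int(length(res$picks))])
  k <- length(pool)
  sizes <- seq.int(1L, k, by = 2L)
  lapply(sizes, function(s) {
    train <- sort(pool[seq_len(s)])
    methods::new("SplitSpec", trainIdx = train,
                 testIdx = setdiff(idx, train),
                 binWidth = binWidth, nBins = res$K,
                 seed = as.integer(seed))
  })
}

#' Train a PINN (or conventional CNN) on a beat dataset
#'
#' Full-batch adaptive-moment (Adam) minimisation of
#' \eqn{L_{total} = L_{conv} + \lambda L_{phys}}, stopping as soon as the
#' supervised loss reaches \code{stopLoss} (on the standardized scale) --
#' the same stopping rule for any \eqn{\lambda}, so \eqn{\lambda = 0}
#' gives the matched conventional-CNN baseline under identical data,
#' split, initialisation and stopping. Deterministic given the seed.
#'
#' @param ds a standardized \linkS4class{BeatDataset}.
#' @param split a \linkS4class{SplitSpec} naming the labeled beats.
#' @param config a \linkS4class{ModelConfig}; default: compact preset
#'   sized to the dataset's waveform length.
#' @param lambdaPhys physics-loss weight (1 = PINN, 0 = conventional CNN).
#' @param stopLoss supervised-loss stopping threshold (default 0.01).
#' @param maxEpochs epoch cap; hitting it flags non-convergence (no error).
#' @param lr Adam learning rate.
#' @param seed integer seed for weight initialisation.
#' @param target label of the BP output being predicted.
#' @return a \linkS4class{PinnModel} whose \code{\link{trainReport}}
#'   carries epochs, convergence flag, final \linkS4class{LossBundle} and
#'   the per-epoch loss history.
#' @export
trainPINN <- function(ds, split, config = NULL, lambdaPhys = 1,
                      stopLoss = 0.01, maxEpochs = 20000, lr = 3e-3,
                      seed = 0, target = "BP") {
  stopifnot(is(ds, "BeatDataset"), is(split, "SplitSpec"))
  if (!isStandardized(ds))
    stop("dataset must be standardized before training")
  if (is.null(config))
    config <- modelConfig("compact", inputLen = nrow(ds))
  methods::validObject(config)
  X <- t(waveforms(ds))
  U <- beatFeatures(ds)
  labelIdx <- trainIdx(split)
  yl <- bpLabels(ds)[labelIdx]
  if (anyNA(yl)) stop("split points at unlabeled beats")
  anchors <- .pairAnchors(sessionIds(ds))
  geom <- .geometry(config, nrow(X))

  params <- initParams(config, seed)
  mstate <- lapply(params, function(p) p * 0)
  vstate <- mstate
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  hist <- matrix(NA_real_, maxEpochs + 1L, 3,
                 dimnames = list(NULL, c("l_conv", "l_phys", "l_total")))
  converged <- FALSE
  epochs <- 0L
  finalBundle <- NULL
  for (epoch in 0:(maxEpochs - 1L)) {
    gr <- tryCatch(
      .lossGradients(params, X, U, config, labelIdx, yl, anchors,
                     lambdaPhys = lambdaPhys, geom = geom),
      error = function(e) {
        if (grepl("non-finite", conditionMessage(e)))
          stop(sprintf("training diverged at epoch %d (non-finite activations)",
                       epoch), call. = FALSE)
        stop(e)
      })
    if (!is.finite(gr$lTotal))
      stop(sprintf("training diverged at epoch %d (non-finite loss)",
                   epoch))
    hist[epoch + 1L, ] <- c(gr$lConv, gr$lPhys, gr$lTotal)
    if (gr$lConv <= stopLoss) {
      converged <- TRUE
      epochs <- epoch
      finalBundle <- gr
      break
    }
    t <- epoch + 1L
    corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
    for (nm in names(params)) {
      g <- gr$grads[[nm]]
      mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g
      vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g^2
      params[[nm]] <- params[[nm]] -
        lr * (mstate[[nm]] / corr1) / (sqrt(vstate[[nm]] / corr2) + epsA)
    }
    epochs <- epoch + 1L
  }
  if (is.null(finalBundle)) {
    finalBundle <- .lossGradients(params, X, U, config, labelIdx, yl,
                                  anchors, lambdaPhys = lambdaPhys,
                                  geom = geom)
    hist[epochs + 1L, ] <- c(finalBundle$lConv, finalBundle$lPhys,
                             finalBundle$lTotal)
    converged <- finalBundle$lConv <= stopLoss
  }
  h <- .residualsFromCache(finalBundle$cache$y,
                           .featureGradFromCache(params, finalBundle$cache,
                                                 config),
                           U, anchors)
  bundle <- methods::new("LossBundle",
    lConv = finalBundle$lConv, lPhys = finalBundle$lPhys,
    lTotal = finalBundle$lTotal, residuals = h,
    lambdaPhys = lambdaPhys, nLabeled = length(labelIdx),
    nPairs = length(h))
  methods::new("PinnModel",
    config = config, params = params, normStats = normStats(ds),
    target = target,
    report = list(epochs = epochs, converged = converged,
                  final = bundle,
                  history = hist[seq_len(epochs + 1L), , drop = FALSE],
                  seed = as.integer(seed), lambdaPhys = lambdaPhys,
                  stopLoss = stopLoss, lr = lr))
}

#' @rdname predictBP
#' @export
setMethod("predictBP", "PinnModel", function(object, ds) {
  stopifnot(is(ds, "BeatDataset"))
  if (!isStandardized(ds))
    stop("dataset must be standardized (with the training statistics)")
  destandardizeY(pinnForward(object, ds), object@normStats)
})
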