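#' @include training.R
NULL

#' Accuracy metrics for BP predictions
#'
#' ME = mean(pred - true), SDE = SD of the errors, RMSE, Pearson
#' correlation, Bland-Altman bias with 95\% limits of agreement
#' (bias +/- 1.96 SDE), and the simplified AAMI flag
#' (|ME| <= 5 mmHg and SDE <= 8 mmHg). Inputs are expected in mmHg
#' (destandardised). When either input is constant the correlation is
#' undefined: the report carries \code{pearsonR = NA} with a warning and
#' the remaining metrics are still returned.
#'
#' @param yTrue,yPred numeric vectors of equal length >= 2, mmHg.
#' @return a \linkS4class{MetricsReport}.
#' @export
computeMetrics <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length")
  n <- length(yTrue)
  if (n < 2L) stop("need at least two prediction pairs")
  err <- yPred - yTrue
  me <- mean(err)
  sde <- stats::sd(err)
  rmse <- sqrt(mean(err^2))
  r <- if (stats::sd(yTrue) == 0 || stats::sd(yPred) == 0) {
    warning("correlation undefined: constant input; pearsonR set to NA")
    NA_real_
  } else stats::cor(yTrue, yPred)
  methods::new("MetricsReport",
    me = me, sde = sde, rmse = rmse, pearsonR = r, n = as.integer(n),
    baBias = me, baLow = me - 1.96 * sde, baHigh = me + 1.96 * sde,
    aamiPass = abs(me) <= 5 && sde <= 8)
}

#' Gradient-interpretation trace of a trained model
#'
#' Computes the per-beat feature gradients
#' \eqn{\partial y_{NN}/\partial u^k} by exact differentiation of the
#' network, destandardises them to mmHg per physical feature unit
#' (chain rule with the stored standardisation statistics:
#' \eqn{g_k^{phys} = g_k^{std}\, \sigma_y / \sigma_{u_k}}), and summarises
#' the gradient-vs-prediction distribution as trend lines: the mean
#' gradient within each integer-mmHg bin of the predicted pressure, per
#' session and pooled over sessions (session_id \code{"all"}).
#'
#' @param model a trained \linkS4class{PinnModel}.
#' @param ds the standardized \linkS4class{BeatDataset} the model was
#'   trained against.
#' @return a \linkS4class{GradientTrace}.
#' @export
gradientTrace <- function(model, ds) {
  stopifnot(is(model, "PinnModel"), is(ds, "BeatDataset"))
  if (!isStandardized(ds))
    stop("dataset must be standardized (with the training statistics)")
  st <- model@normStats
  G <- featureGradients(model, ds)
  G <- sweep(G, 2, st$y_sd / st$u_sd, `*`)
  yMm <- destandardizeY(pinnForward(model, ds), st)
  beats <- data.frame(
    beat_index = SummarizedExperiment::colData(ds)$beat_index,
    y_nn_mmhg = yMm,
    g1 = G[, 1], g2 = G[, 2], g3 = G[, 3],
    session_id = sessionIds(ds),
    stringsAsFactors = FALSE)
  bin <- as.integer(round(yMm))
  trendOf <- function(df, sid) {
    sp <- split(df, as.integer(round(df$y_nn_mmhg)))
    data.frame(
      session_id = sid,
      bp_mmhg = as.integer(names(sp)),
      g1 = vapply(sp, function(d) mean(d$g1), numeric(1)),
      g2 = vapply(sp, function(d) mean(d$g2), numeric(1)),
      g3 = vapply(sp, function(d) mean(d$g3), numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  trends <- do.call(rbind, lapply(split(beats, beats$session_id),
                                  function(d) trendOf(d, d$session_id[1])))
  trends <- rbind(trends, trendOf(beats, "all"))
  rownames(trends) <- NULL
  methods::new("GradientTrace", beats = beats, trend = trends)
}

#' Across-model consistency of gradient trends (SD_avg)
#'
#' For a group of models trained on the same data (e.g. with different
#' label budgets): at each integer BP value supported by at least two
#' traces, take the SD of the pooled trend values across the traces, then
#' average over the supported BP values -- one scalar per feature
#' component. Small values mean the models agree on the learned
#' feature-to-pressure map.
#'
#' @param traces list of \linkS4class{GradientTrace} (>= 2).
#' @return named numeric vector \code{c(g1, g2, g3)}.
#' @export
sdAvg <- function(traces) {
  if (length(traces) < 2L) stop("need at least two traces")
  pooled <- lapply(traces, function(tr) {
    d <- tr@trend
    d[d$session_id == "all", c("bp_mmhg", "g1", "g2", "g3")]
  })
  bps <- sort(unique(unlist(lapply(pooled, `[[`, "bp_mmhg"))))
  perBp <- lapply(bps, function(b) {
    vals <- do.call(rbind, lapply(pooled, function(d)
      if (b %in% d$bp_mmhg) unlist(d[d$bp_mmhg == b, c("g1", "g2", "g3")])
      else NULL))
    if (is.null(vals) || nrow(vals) < 2L) return(NULL)
    apply(vals, 2, stats::sd)
  })
  perBp <- perBp[!vapply(perBp, is.null, logical(1))]
  if (!length(perBp))
    stop("empty support: no integer BP value shared by >= 2 traces")
  out <- colMeans(do.call(rbind, perBp))
  names(out) <- c("g1", "g2", "g3")
  out
}
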