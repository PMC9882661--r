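#' @include pinn-model.R
NULL

# indices i of within-session consecutive pairs (i, i+1)
.pairAnchors <- function(sessions) {
  R <- length(sessions)
  if (R < 2L) integer()
  else which(sessions[-R] == sessions[-1L])
}

# residuals h_i from a forward cache:
#   h_i = f(x_{i+1}, u_{i+1}) - [f(x_i, u_i) + g(i) . (u_{i+1} - u_i)]
.residualsFromCache <- function(y, G, U, anchors) {
  if (!length(anchors)) return(numeric())
  dU <- U[anchors + 1L, , drop = FALSE] - U[anchors, , drop = FALSE]
  y[anchors + 1L] - y[anchors] - rowSums(G[anchors, , drop = FALSE] * dU)
}

#' Taylor residuals over a beat dataset
#'
#' For every within-session consecutive beat pair (i, i+1):
#' \eqn{h_i = f_{NN}(x_{i+1}, u_{i+1}, \Theta) - P_i(u_{i+1})}, the gap
#' between the network prediction at the next beat and the first-order
#' Taylor extrapolation anchored at the current one. Pairs spanning a
#' session boundary are excluded (the sequential-locality premise fails
#' across gaps).
#'
#' @param model a \linkS4class{PinnModel}.
#' @param ds a standardized \linkS4class{BeatDataset} with >= 2 beats.
#' @return numeric vector of residuals, one per evaluated pair.
#' @export
pinnResiduals <- function(model, ds) {
  stopifnot(is(ds, "BeatDataset"))
  if (ncol(ds) < 2L)
    stop("insufficient sequence: residuals need >= 2 beats")
  mp <- .modelParts(model)
  X <- t(waveforms(ds)); U <- beatFeatures(ds)
  cache <- .forwardCache(mp$params, X, U, mp$cfg)
  G <- .featureGradFromCache(mp$params, cache, mp$cfg)
  .residualsFromCache(cache$y, G, U, .pairAnchors(sessionIds(ds)))
}

#' Physics loss: mean squared Taylor residual
#'
#' \deqn{L_{physics} = \frac{1}{|pairs|} \sum_i h_i^2}
#' computed over all consecutive within-session pairs -- entirely
#' unsupervised, labels are never consulted.
#'
#' @inheritParams pinnResiduals
#' @return scalar loss (standardized units squared).
#' @export
physicsLoss <- function(model, ds) {
  h <- pinnResiduals(model, ds)
  if (!length(h)) stop("no residual pairs to evaluate")
  mean(h^2)
}

#' Supervised loss over the labeled beats
#'
#' \deqn{L_{conventional} = \frac{1}{S} \sum_{i \in labeled}
#'   (y_{NN,i} - y_{true,i})^2}
#'
#' @param model a \linkS4class{PinnModel}.
#' @param ds a standardized \linkS4class{BeatDataset}.
#' @param labelIdx integer indices of the S labeled beats (e.g.
#'   \code{trainIdx(split)}).
#' @return scalar mean squared error on the standardized scale.
#' @export
supervisedLoss <- function(model, ds, labelIdx) {
  stopifnot(is(ds, "BeatDataset"))
  labelIdx <- as.integer(labelIdx)
  if (!length(labelIdx)) stop("no labels: supervised loss needs S >= 1")
  y <- bpLabels(ds)[labelIdx]
  if (anyNA(y)) stop("labelIdx points at unlabeled beats")
  yhat <- pinnForward(model, t(waveforms(ds)[, labelIdx, drop = FALSE]),
                      beatFeatures(ds)[labelIdx, , drop = FALSE])
  mean((yhat - y)^2)
}

#' Total training loss
#'
#' \deqn{L_{total} = L_{conventional} + \lambda L_{physics}} with
#' \eqn{\lambda = 1} reproducing the unweighted sum; \eqn{\lambda = 0} is
#' exactly the conventional CNN objective (same code path).
#'
#' @inheritParams supervisedLoss
#' @param lambdaPhys weight of the physics loss (default 1).
#' @return a \linkS4class{LossBundle}.
#' @export
totalLoss <- function(model, ds, labelIdx, lambdaPhys = 1) {
  stopifnot(is(ds, "BeatDataset"))
  mp <- .modelParts(model)
  X <- t(waveforms(ds)); U <- beatFeatures(ds)
  cache <- .forwardCache(mp$params, X, U, mp$cfg)
  labelIdx <- as.integer(labelIdx)
  if (!length(labelIdx)) stop("no labels: supervised loss needs S >= 1")
  yl <- bpLabels(ds)[labelIdx]
  lConv <- mean((cache$y[labelIdx] - yl)^2)
  anchors <- .pairAnchors(sessionIds(ds))
  G <- .featureGradFromCache(mp$params, cache, mp$cfg)
  h <- .residualsFromCache(cache$y, G, U, anchors)
  lPhys <- if (length(h)) mean(h^2) else 0
  methods::new("LossBundle", lConv = lConv, lPhys = lPhys,
               lTotal = lConv + lambdaPhys * lPhys, residuals = h,
               lambdaPhys = lambdaPhys, nLabeled = length(labelIdx),
               nPairs = length(h))
}

# ---------------------------------------------------------------------------
# Reverse-mode gradient of the total loss with respect to the parameters.
#
# The supervised part backpropagates output cotangents dL/dy_r through the
# whole network. The physics part additionally needs d/dTheta of the
# per-anchor feature gradients g_k(i) = sum_j wo_j 1[a3_ij>0] Wf[u_k, j]:
# since the ReLU indicator has zero derivative almost everywhere, only wo
# and the feature rows of Wf receive these second-order contributions --
# exactly what autodiff double-backprop yields for ReLU networks.
# ---------------------------------------------------------------------------
.lossGradients <- function(params, X, U, cfg, labelIdx, yLabels,
                           anchors, lambdaPhys = 1, geom = NULL,
                           cache = NULL) {
  R <- nrow(X)
  if (is.null(cache))
    cache <- .forwardCache(params, X, U, cfg, geom)
  g <- cache$g
  y <- cache$y
  M <- cfg@nFeatures
  S <- length(labelIdx)

  lConv <- mean((y[labelIdx] - yLabels)^2)
  dy <- numeric(R)
  dy[labelIdx] <- dy[labelIdx] + (2 / S) * (y[labelIdx] - yLabels)

  Wfu <- params$Wf[g$uidx, , drop = FALSE]            # M x fc
  dG <- NULL
  lPhys <- 0
  if (lambdaPhys != 0 && length(anchors)) {
    Gmat <- .featureGradFromCache(params, cache, cfg)
    dU <- U[anchors + 1L, , drop = FALSE] - U[anchors, , drop = FALSE]
    h <- y[anchors + 1L] - y[anchors] -
      rowSums(Gmat[anchors, , drop = FALSE] * dU)
    lPhys <- mean(h^2)
    cp <- (2 / length(h)) * h * lambdaPhys
    dy[anchors + 1L] <- dy[anchors + 1L] + cp
    dy[anchors] <- dy[anchors] - cp
    dG <- matrix(0, R, M)
    dG[anchors, ] <- -cp * dU
  }

  # ---- standard backprop of the output cotangents -------------------------
  dwo <- drop(crossprod(cache$H3, dy))
  dbo <- sum(dy)
  dA3 <- (dy %o% params$wo) * cache$S3                 # R x fc
  dWf <- crossprod(cache$Zc, dA3)
  dbf <- colSums(dA3)

  # ---- second-order physics contributions via the feature gradients ------
  if (!is.null(dG)) {
    dwo <- dwo + colSums(cache$S3 * (dG %*% Wfu))
    dWf[g$uidx, ] <- dWf[g$uidx, ] +
      crossprod(dG, sweep(cache$S3 * 1, 2, params$wo, `*`))
  }

  dZc <- tcrossprod(dA3, params$Wf)                    # R x Din
  dFlat <- dZc[, seq_len(g$Dflat), drop = FALSE]
  dP <- dFlat
  dim(dP) <- c(R * g$L3, cfg@conv2Filters)
  dH2 <- matrix(0, R * g$L2, cfg@conv2Filters)
  for (o in seq_len(cfg@poolSize)) {
    sel <- cache$Amax == o
    if (any(sel)) {
      tmp <- dP * sel
      dH2[g$Ip[[o]], ] <- dH2[g$Ip[[o]], ] + tmp
    }
  }
  dZ2 <- dH2 * cache$S2
  dW2 <- crossprod(cache$A2, dZ2)
  db2 <- colSums(dZ2)
  dA2 <- tcrossprod(dZ2, params$W2)                    # (R*L2) x (k2*F1)
  F1 <- cfg@conv1Filters
  dH1 <- matrix(0, R * g$L1, F1)
  for (o in seq_len(cfg@conv2Kernel)) {
    cols <- ((o - 1L) * F1 + 1L):(o * F1)
    dH1[g$I2[[o]], ] <- dH1[g$I2[[o]], ] + dA2[, cols, drop = FALSE]
  }
  dZ1 <- dH1 * cache$S1
  dW1 <- crossprod(cache$A1, dZ1)
  db1 <- colSums(dZ1)

  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                    Wf = dWf, bf = dbf, wo = dwo, bo = dbo),
       lConv = lConv, lPhys = lPhys,
       lTotal = lConv + lambdaPhys * lPhys, cache = cache)
}
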