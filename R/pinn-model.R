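#' @include simulate.R
NULL

#' Build a network architecture configuration
#'
#' @param preset \code{"reference"} -- the full architecture (conv 32/k5,
#'   64/k3, max-pool 3/1, 60 FC units); \code{"compact"} -- a small variant
#'   (8/k5, 8/k3, pool 3/1, 16 FC units) used in the package's simulation
#'   studies.
#' @param inputLen waveform length N (default 60).
#' @param nFeatures number of physiological features M (default 3).
#' @param conv1Filters,conv1Kernel,conv2Filters,conv2Kernel,poolSize,
#'   poolStride,fcUnits explicit overrides of the preset.
#' @return a \linkS4class{ModelConfig}.
#' @export
modelConfig <- function(preset = c("reference", "compact"), inputLen = 60,
                        nFeatures = 3, conv1Filters = NULL,
                        conv1Kernel = NULL, conv2Filters = NULL,
                        conv2Kernel = NULL, poolSize = NULL,
                        poolStride = NULL, fcUnits = NULL) {
  preset <- match.arg(preset)
  def <- if (preset == "reference")
    list(c1 = 32L, k1 = 5L, c2 = 64L, k2 = 3L, p = 3L, ps = 1L, fc = 60L)
  else
    list(c1 = 8L, k1 = 5L, c2 = 8L, k2 = 3L, p = 3L, ps = 1L, fc = 16L)
  pick <- function(x, d) if (is.null(x)) d else as.integer(x)
  methods::new("ModelConfig",
    conv1Filters = pick(conv1Filters, def$c1),
    conv1Kernel = pick(conv1Kernel, def$k1),
    conv2Filters = pick(conv2Filters, def$c2),
    conv2Kernel = pick(conv2Kernel, def$k2),
    poolSize = pick(poolSize, def$p),
    poolStride = pick(poolStride, def$ps),
    fcUnits = pick(fcUnits, def$fc),
    inputLen = as.integer(inputLen), nFeatures = as.integer(nFeatures))
}

# derived layer lengths
.dims <- function(cfg) {
  L1 <- cfg@inputLen - cfg@conv1Kernel + 1L
  L2 <- L1 - cfg@conv2Kernel + 1L
  L3 <- L2 - cfg@poolSize + 1L
  list(L1 = L1, L2 = L2, L3 = L3,
       Dflat = L3 * cfg@conv2Filters,
       Din = L3 * cfg@conv2Filters + cfg@nFeatures)
}

#' Initialise network parameters
#'
#' He-style Gaussian initialisation, deterministic given the seed.
#'
#' @param cfg a \linkS4class{ModelConfig}.
#' @param seed integer RNG seed.
#' @return named list of parameter arrays (W1, b1, W2, b2, Wf, bf, wo, bo).
#' @export
initParams <- function(cfg, seed = 0) {
  d <- .dims(cfg)
  withr::with_seed(as.integer(seed), {
    he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)),
                                  nr, nc)
    list(
      W1 = he(cfg@conv1Kernel, cfg@conv1Filters),
      b1 = rep(0, cfg@conv1Filters),
      W2 = he(cfg@conv2Kernel * cfg@conv1Filters, cfg@conv2Filters),
      b2 = rep(0, cfg@conv2Filters),
      Wf = he(d$Din, cfg@fcUnits),
      bf = rep(0, cfg@fcUnits),
      wo = stats::rnorm(cfg@fcUnits, 0, sqrt(1 / cfg@fcUnits)),
      bo = 0
    )
  })
}

# index geometry for the vectorised batched forward/backward pass.
# Layer activations are stored as (R*L) x filters matrices whose row for
# beat r at position p is r + R*(p-1).
.geometry <- function(cfg, R) {
  d <- .dims(cfg)
  k1 <- cfg@conv1Kernel; k2 <- cfg@conv2Kernel; pk <- cfg@poolSize
  cols1 <- as.vector(outer(seq_len(d$L1), 0:(k1 - 1L), `+`))
  r2 <- rep(seq_len(R), times = d$L2)
  q2 <- rep(seq_len(d$L2), each = R)
  I2 <- lapply(0:(k2 - 1L), function(o) r2 + R * (q2 + o - 1L))
  r3 <- rep(seq_len(R), times = d$L3)
  m3 <- rep(seq_len(d$L3), each = R)
  Ip <- lapply(0:(pk - 1L), function(o) r3 + R * (m3 + o - 1L))
  c(d, list(R = R, cols1 = cols1, I2 = I2, Ip = Ip,
            uidx = d$Dflat + seq_len(cfg@nFeatures)))
}

# full forward pass with cached intermediates.
# X: R x N (beats in rows), U: R x M, both standardized.
.forwardCache <- function(params, X, U, cfg, geom = NULL) {
  R <- nrow(X)
  if (ncol(X) != cfg@inputLen)
    stop(sprintf("shape error: waveform length %d, expected %d",
                 ncol(X), cfg@inputLen))
  if (!is.matrix(U)) U <- matrix(U, nrow = R)
  if (ncol(U) != cfg@nFeatures)
    stop(sprintf("shape error: %d features, expected %d",
                 ncol(U), cfg@nFeatures))
  g <- if (is.null(geom)) .geometry(cfg, R) else geom
  F1 <- cfg@conv1Filters; F2 <- cfg@conv2Filters
  k2 <- cfg@conv2Kernel; pk <- cfg@poolSize

  A1 <- X[, g$cols1, drop = FALSE]
  dim(A1) <- c(R * g$L1, cfg@conv1Kernel)
  Z1 <- sweep(A1 %*% params$W1, 2, params$b1, `+`)
  S1 <- Z1 > 0
  H1 <- pmax(Z1, 0)

  A2 <- do.call(cbind, lapply(seq_len(k2),
                              function(o) H1[g$I2[[o]], , drop = FALSE]))
  Z2 <- sweep(A2 %*% params$W2, 2, params$b2, `+`)
  if (anyNA(Z2))
    stop("numeric error: non-finite activations in forward pass")
  S2 <- Z2 > 0
  H2 <- pmax(Z2, 0)

  P <- H2[g$Ip[[1]], , drop = FALSE]
  Amax <- matrix(1L, nrow(P), ncol(P))
  for (o in seq_len(pk)[-1]) {
    Ho <- H2[g$Ip[[o]], , drop = FALSE]
    upd <- Ho > P
    P[upd] <- Ho[upd]
    Amax[upd] <- o
  }
  Flat <- P
  dim(Flat) <- c(R, g$Dflat)
  Zc <- cbind(Flat, U)
  A3 <- sweep(Zc %*% params$Wf, 2, params$bf, `+`)
  S3 <- A3 > 0
  H3 <- pmax(A3, 0)
  y <- drop(H3 %*% params$wo) + params$bo

  list(y = y, A1 = A1, S1 = S1, H1 = H1, A2 = A2, S2 = S2, H2 = H2,
       Amax = Amax, Zc = Zc, S3 = S3, H3 = H3, g = g)
}

# feature gradients dy/du (R x M, standardized scale) from a cache:
# only the fully connected path touches u, so
#   g_k = sum_j wo_j * 1[a3_j > 0] * Wf[u_k, j].
.featureGradFromCache <- function(params, cache, cfg) {
  Wfu <- params$Wf[cache$g$uidx, , drop = FALSE]     # M x fc
  Msk <- sweep(cache$S3 * 1, 2, params$wo, `*`)      # R x fc
  G <- Msk %*% t(Wfu)
  colnames(G) <- paste0("u", seq_len(cfg@nFeatures))
  G
}

.asXU <- function(x, u, cfg) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  U <- if (is.matrix(u)) u else matrix(u, nrow = 1)
  list(X = X, U = U)
}

.modelParts <- function(model) {
  if (is(model, "PinnModel")) list(params = model@params,
                                   cfg = model@config)
  else stop("model must be a PinnModel")
}

#' Network forward pass
#'
#' Evaluates \eqn{y_{NN} = f_{NN}(x, u, \Theta)} for one beat or a batch.
#' Inputs are on the standardized scale; the output is the standardized
#' BP prediction (use \code{\link{predictBP}} or
#' \code{\link{destandardizeY}} for mmHg).
#'
#' @param model a \linkS4class{PinnModel}.
#' @param x waveform vector of length N, or an R x N matrix of beats, or a
#'   \linkS4class{BeatDataset} (in which case \code{u} is ignored).
#' @param u feature vector of length M, or R x M matrix.
#' @return numeric vector of standardized predictions.
#' @export
pinnForward <- function(model, x, u = NULL) {
  mp <- .modelParts(model)
  if (is(x, "BeatDataset")) {
    u <- beatFeatures(x)
    x <- t(waveforms(x))
  }
  xu <- .asXU(x, u, mp$cfg)
  .forwardCache(mp$params, xu$X, xu$U, mp$cfg)$y
}

#' Gradients of the network output with respect to the features
#'
#' The exact reverse-mode derivatives \eqn{\partial y_{NN} / \partial u^k}
#' (with respect to the feature inputs only, not the waveform), on the
#' standardized scale -- the quantities the Taylor polynomial and the
#' interpretation analyses are built from.
#'
#' @inheritParams pinnForward
#' @return R x M matrix of gradients.
#' @export
featureGradients <- function(model, x, u = NULL) {
  mp <- .modelParts(model)
  if (is(x, "BeatDataset")) {
    u <- beatFeatures(x)
    x <- t(waveforms(x))
  }
  xu <- .asXU(x, u, mp$cfg)
  if (any(!is.finite(unlist(mp$params))))
    stop("numeric error: non-finite network parameters")
  cache <- .forwardCache(mp$params, xu$X, xu$U, mp$cfg)
  .featureGradFromCache(mp$params, cache, mp$cfg)
}

#' Evaluate the first-order Taylor polynomial anchored at one beat
#'
#' \deqn{P_i(u) = f_{NN}(x_i, u_i, \Theta) + \sum_k
#'   \left.\frac{\partial f_{NN}}{\partial u^k}\right|_i (u^k - u_i^k)}
#'
#' @param model a \linkS4class{PinnModel}.
#' @param xAnchor,uAnchor the anchor beat's waveform and features
#'   (standardized).
#' @param uTarget feature vector (or matrix) at which to evaluate.
#' @return numeric vector of polynomial values.
#' @export
taylorEvaluate <- function(model, xAnchor, uAnchor, uTarget) {
  mp <- .modelParts(model)
  xu <- .asXU(xAnchor, uAnchor, mp$cfg)
  cache <- .forwardCache(mp$params, xu$X, xu$U, mp$cfg)
  G <- .featureGradFromCache(mp$params, cache, mp$cfg)
  UT <- if (is.matrix(uTarget)) uTarget else matrix(uTarget, nrow = 1)
  drop(cache$y + rowSums(G[rep(1, nrow(UT)), , drop = FALSE] *
                           sweep(UT, 2, xu$U[1, ], `-`)))
}
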