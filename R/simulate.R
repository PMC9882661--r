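#' @include signal-features.R
NULL

#' Default cold-pressor-like blood-pressure schedule
#'
#' Two cold-pressor cycles (ramp to an elevated plateau, then recovery)
#' separated by rest, spanning a little over 40 mmHg from baseline -- wide
#' enough that the minimal-labeling criterion yields a non-trivial label
#' budget.
#'
#' @param bpBaseline baseline BP in mmHg.
#' @param rise pressure elevation of the plateaus in mmHg.
#' @return data.frame with columns duration_s, target_mmhg, session.
#' @export
defaultBpProfile <- function(bpBaseline = 120, rise = 42) {
  peak <- bpBaseline + rise
  data.frame(
    duration_s = c(120, 60, 45, 120, 60, 45, 120, 300),
    target_mmhg = c(bpBaseline, peak, peak, bpBaseline, peak, peak,
                    bpBaseline, bpBaseline),
    session = c("rest-1", "cpt-1", "cpt-1", "recovery-1", "cpt-2",
                "cpt-2", "recovery-2", "rest-2"),
    stringsAsFactors = FALSE
  )
}

#' Configure the synthetic beat generator
#'
#' Defaults emulate a cold-pressor protocol on a peripheral-artery
#' bioimpedance channel: pulse amplitude of order 1 a.u. falling ~0.8% per
#' mmHg of pressure rise (vasoconstriction), reflection wave arriving
#' 0.25 s after the systolic wave at baseline and ~1.5 ms earlier per mmHg
#' (faster pulse-wave velocity), biphasic heart-rate response
#' (70 + 0.9 dBP - 0.02 dBP^2 bpm), AR(1) beat-to-beat BP variability of
#' 1.2 mmHg (lag-1 correlation 0.9), and 3% additive waveform noise.
#' On top of the couplings, each beat carries physiological variability
#' that is not explained by BP: heart-rate variability (SD 2 bpm),
#' respiratory/vasomotor amplitude modulation (5% relative SD) and
#' reflection-timing jitter (SD 6 ms) -- calibrated so the feature-BP
#' correlations land near the 0.9 seen on well-instrumented participants
#' rather than at an unphysiological 0.99+.
#'
#' @param nBeats number of beats (default 1000).
#' @param bpBaseline baseline BP, mmHg.
#' @param bpProfile schedule data.frame (see \code{\link{defaultBpProfile}}).
#' @param alpha0,alpha1 amplitude coupling: base (a.u.) and gain (a.u./mmHg).
#' @param d0,d1 reflection-delay coupling: base (s) and reduction (s/mmHg).
#' @param h0,h1,h2 HR coupling: base (bpm), linear, quadratic terms.
#' @param reflAmp relative reflection-wave amplitude.
#' @param sigma1,sigma2,mu1 Gaussian widths (s) and systolic peak time (s).
#' @param ar1Rho,ar1Sigma AR(1) BP noise: correlation and stationary SD.
#' @param ampJitterSd,delayJitterSd,hrJitterSd beat-to-beat physiological
#'   jitter of amplitude (relative), reflection delay (s) and HR (bpm).
#' @param noiseSd additive waveform noise SD (a.u.).
#' @param sampleRate raw sampling rate, Hz.
#' @param seed integer RNG seed.
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(nBeats = 1000, bpBaseline = 120,
                      bpProfile = defaultBpProfile(bpBaseline),
                      alpha0 = 1.0, alpha1 = 0.008,
                      d0 = 0.25, d1 = 0.0015,
                      h0 = 70, h1 = 0.9, h2 = 0.02,
                      reflAmp = 0.45, sigma1 = 0.045, sigma2 = 0.09,
                      mu1 = 0.15,
                      ar1Rho = 0.9, ar1Sigma = 1.2,
                      ampJitterSd = 0.05, delayJitterSd = 0.006,
                      hrJitterSd = 2,
                      noiseSd = 0.03, sampleRate = 100, seed = 0) {
  methods::new("SimConfig",
    nBeats = as.integer(nBeats), bpBaseline = bpBaseline,
    bpProfile = bpProfile,
    alpha0 = alpha0, alpha1 = alpha1, d0 = d0, d1 = d1,
    h0 = h0, h1 = h1, h2 = h2,
    reflAmp = reflAmp, sigma1 = sigma1, sigma2 = sigma2, mu1 = mu1,
    ar1Rho = ar1Rho, ar1Sigma = ar1Sigma,
    ampJitterSd = ampJitterSd, delayJitterSd = delayJitterSd,
    hrJitterSd = hrJitterSd,
    noiseSd = noiseSd, sampleRate = sampleRate, seed = as.integer(seed))
}

# deterministic BP target and session label at time t (piecewise linear;
# held at the final target beyond the schedule)
.profileAt <- function(cfg, t) {
  pf <- cfg@bpProfile
  ends <- cumsum(pf$duration_s)
  starts <- c(0, ends[-length(ends)])
  v0 <- c(cfg@bpBaseline, pf$target_mmhg[-nrow(pf)])
  seg <- findInterval(t, starts, rightmost.closed = FALSE)
  seg <- pmin(pmax(seg, 1L), nrow(pf))
  over <- t >= ends[length(ends)]
  frac <- pmin((t - starts[seg]) / pf$duration_s[seg], 1)
  bp <- v0[seg] + frac * (pf$target_mmhg[seg] - v0[seg])
  bp[over] <- pf$target_mmhg[nrow(pf)]
  list(bp = bp, session = pf$session[seg])
}

# the three couplings; dbp = BP - baseline
.coupA <- function(cfg, dbp) cfg@alpha0 - cfg@alpha1 * dbp
.coupD <- function(cfg, dbp) cfg@d0 - cfg@d1 * dbp
.coupHR <- function(cfg, dbp) cfg@h0 + cfg@h1 * dbp - cfg@h2 * dbp^2

#' Simulate a beat-segmented bioimpedance recording
#'
#' Generates beats sequentially along the BP schedule: per beat the true
#' pressure is the schedule value plus AR(1) noise; the beat period is
#' 60/HR(BP); the waveform is
#' \eqn{-\Delta Z(t) = a(BP)[G(t; \mu_1, \sigma_1) + r\,G(t; \mu_1 + d(BP),
#' \sigma_2)] + \epsilon(t)} with Gaussian bumps of unit peak height,
#' \eqn{\epsilon \sim N(0, noiseSd^2)}. Beat boundaries are exact. The
#' returned dataset runs the full feature-extraction pipeline
#' (\code{\link{extractBeatDataset}}); \code{truth} carries the per-beat
#' true BP, the realized latent features (amplitude, inverse delay, HR --
#' couplings plus physiological jitter, free of waveform measurement
#' noise) and the analytic coupling gradients \eqn{\partial BP/\partial u}.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param targetRate,padLen resampling parameters of the returned dataset.
#' @return list with elements \code{recording} (\linkS4class{RawRecording}),
#'   \code{dataset} (\linkS4class{BeatDataset}, unstandardized), and
#'   \code{truth} (data.frame: beat_index, bp_mmhg, session, u1_true,
#'   u2_true, u3_true, dbp_du1, dbp_du2, dbp_du3), aligned with the
#'   dataset's beats via beat_index.
#' @export
simulateBeats <- function(cfg, targetRate = 30, padLen = 60) {
  stopifnot(is(cfg, "SimConfig"))
  methods::validObject(cfg)
  # feasibility over the whole schedule, not just the beats generated:
  # couplings must stay positive across the profile's target range
  bpRange <- range(c(cfg@bpBaseline, cfg@bpProfile$target_mmhg))
  dbpGrid <- seq(bpRange[1], bpRange[2], length.out = 101) - cfg@bpBaseline
  if (any(.coupA(cfg, dbpGrid) <= 0) || any(.coupD(cfg, dbpGrid) <= 0) ||
      any(.coupHR(cfg, dbpGrid) <= 0))
    stop("infeasible config: a coupling is non-positive somewhere on the profile")
  rate <- cfg@sampleRate
  n <- cfg@nBeats
  out <- withr::with_seed(cfg@seed, {
    innov_sd <- cfg@ar1Sigma * sqrt(1 - cfg@ar1Rho^2)
    e <- numeric(n)
    if (cfg@ar1Sigma > 0) {
      e[1] <- stats::rnorm(1, 0, cfg@ar1Sigma)
      for (i in seq_len(n)[-1])
        e[i] <- cfg@ar1Rho * e[i - 1] + stats::rnorm(1, 0, innov_sd)
    }
    bp <- numeric(n); hr <- numeric(n); aa <- numeric(n); dd <- numeric(n)
    sess <- character(n)
    nSamp <- integer(n)
    segs <- vector("list", n)
    tCur <- 0
    for (i in seq_len(n)) {
      prof <- .profileAt(cfg, tCur)
      bp[i] <- prof$bp + e[i]
      sess[i] <- prof$session
      dbp <- bp[i] - cfg@bpBaseline
      # couplings plus physiological jitter not explained by BP
      aa[i] <- .coupA(cfg, dbp) *
        (1 + if (cfg@ampJitterSd > 0)
               stats::rnorm(1, 0, cfg@ampJitterSd) else 0)
      dd[i] <- .coupD(cfg, dbp) +
        (if (cfg@delayJitterSd > 0)
           stats::rnorm(1, 0, cfg@delayJitterSd) else 0)
      hr[i] <- .coupHR(cfg, dbp) +
        (if (cfg@hrJitterSd > 0)
           stats::rnorm(1, 0, cfg@hrJitterSd) else 0)
      if (aa[i] <= 0 || dd[i] <= 0 || hr[i] <= 0)
        stop(sprintf(
          "infeasible config: coupling non-positive at BP %.1f mmHg (a=%.3g, d=%.3g, HR=%.3g)",
          bp[i], aa[i], dd[i], hr[i]))
      nSamp[i] <- max(as.integer(round(60 / hr[i] * rate)), 8L)
      tt <- (seq_len(nSamp[i]) - 1) / rate
      pulse <- aa[i] * (exp(-(tt - cfg@mu1)^2 / (2 * cfg@sigma1^2)) +
                        cfg@reflAmp *
                          exp(-(tt - (cfg@mu1 + dd[i]))^2 / (2 * cfg@sigma2^2)))
      eps <- if (cfg@noiseSd > 0) stats::rnorm(nSamp[i], 0, cfg@noiseSd)
             else 0
      segs[[i]] <- -pulse + eps
      tCur <- tCur + nSamp[i] / rate
    }
    list(bp = bp, hr = hr, aa = aa, dd = dd, sess = sess,
         nSamp = nSamp, samples = unlist(segs))
  })
  boundaries <- as.integer(cumsum(c(1L, out$nSamp)))
  rec <- RawRecording(out$samples, sampleRate = rate,
                      beatBoundaries = boundaries,
                      sessionIds = out$sess)
  ds <- extractBeatDataset(rec, labels = out$bp, targetRate = targetRate,
                           padLen = padLen, onError = "drop")
  dbp <- out$bp - cfg@bpBaseline
  truth <- data.frame(
    beat_index = seq_len(n),
    bp_mmhg = out$bp,
    session = out$sess,
    u1_true = out$aa,
    u2_true = 1 / out$dd,
    u3_true = out$hr,
    dbp_du1 = if (cfg@alpha1 != 0) -1 / cfg@alpha1 else NA_real_,
    dbp_du2 = if (cfg@d1 != 0) out$dd^2 / cfg@d1 else NA_real_,
    dbp_du3 = ifelse(abs(cfg@h1 - 2 * cfg@h2 * dbp) > 0,
                     1 / (cfg@h1 - 2 * cfg@h2 * dbp), NA_real_)
  )
  kept <- SummarizedExperiment::colData(ds)$beat_index
  list(recording = rec, dataset = ds, truth = truth[kept, , drop = FALSE])
}

#' Analytic feature-to-pressure gradients of the generator
#'
#' By implicit differentiation of the planted couplings: with
#' \eqn{u^1 = \alpha_0 - \alpha_1 \Delta}, \eqn{u^2 = 1/(d_0 - d_1 \Delta)}
#' and \eqn{u^3 = h_0 + h_1 \Delta - h_2 \Delta^2}
#' (\eqn{\Delta = BP - baseline}):
#' \eqn{\partial BP/\partial u^1 = -1/\alpha_1},
#' \eqn{\partial BP/\partial u^2 = d(BP)^2 / d_1},
#' \eqn{\partial BP/\partial u^3 = 1/(h_1 - 2 h_2 \Delta)}.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param bp BP value(s) in mmHg at which to evaluate.
#' @param components which of 1:3 to return (default all).
#' @return matrix (length(bp) x length(components)) of gradients, in mmHg
#'   per feature unit.
#' @export
trueGradient <- function(cfg, bp, components = 1:3) {
  stopifnot(is(cfg, "SimConfig"))
  dbp <- bp - cfg@bpBaseline
  out <- matrix(NA_real_, length(bp), length(components))
  colnames(out) <- paste0("dbp_du", components)
  for (j in seq_along(components)) {
    k <- components[j]
    out[, j] <- switch(as.character(k),
      "1" = {
        if (cfg@alpha1 == 0)
          stop("non-identifiable gradient: alpha1 = 0 (component 1)")
        rep(-1 / cfg@alpha1, length(bp))
      },
      "2" = {
        if (cfg@d1 == 0)
          stop("non-identifiable gradient: d1 = 0 (component 2)")
        .coupD(cfg, dbp)^2 / cfg@d1
      },
      "3" = {
        slope <- cfg@h1 - 2 * cfg@h2 * dbp
        if (any(slope == 0))
          stop("non-identifiable gradient: HR coupling not invertible at this BP")
        1 / slope
      },
      stop("components must be in 1:3"))
  }
  out
}
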