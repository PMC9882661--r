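# Shared fixtures and independent oracles. Everything is generated in code;
# expensive objects are built once when the helpers load.

# small architecture for fast exact-math tests
tinyConfig <- function(inputLen = 20L) {
  modelConfig(preset = "compact", inputLen = inputLen,
              conv1Filters = 3, conv1Kernel = 3,
              conv2Filters = 4, conv2Kernel = 3,
              poolSize = 3, fcUnits = 8)
}

randomModel <- function(cfg = tinyConfig(), seed = 1, scale = 1) {
  p <- initParams(cfg, seed)
  if (scale != 1) p <- lapply(p, function(w) w * scale)
  new("PinnModel", config = cfg, params = p,
      normStats = list(y_mean = 130, y_sd = 10,
                       u_mean = c(0.8, 4, 75), u_sd = c(0.1, 0.5, 6)))
}

# random standardized-looking dataset with no physical structure
tinyDataset <- function(R = 12, cfg = tinyConfig(), seed = 2,
                        sessions = NULL, labels = NULL) {
  withr::with_seed(seed, {
    wf <- matrix(rnorm(cfg@inputLen * R), cfg@inputLen, R)
    U <- matrix(rnorm(R * 3), R, 3)
    if (is.null(labels)) labels <- rnorm(R)
    if (is.null(sessions)) sessions <- rep("s1", R)
    BeatDataset(wf, U, labels = labels, sessionId = sessions,
                tStart = seq_len(R), duration = rep(0.8, R),
                normStats = list(x_mean = 0, x_sd = 1,
                                 u_mean = c(0, 0, 0), u_sd = c(1, 1, 1),
                                 y_mean = 0, y_sd = 1),
                standardized = TRUE)
  })
}

# a model that is exactly linear in u and ignores x: conv stack zeroed,
# FC biases large enough that every ReLU stays active near the data
linearModel <- function(w = c(2, -1, 0.5), b = 0.3, cfg = tinyConfig()) {
  p <- initParams(cfg, 0)
  p$W1[] <- 0; p$b1[] <- 0; p$W2[] <- 0; p$b2[] <- 0
  d <- pinnBP:::.dims(cfg)
  p$Wf[] <- 0
  # route u_k through hidden units 1..3 with big positive bias
  p$Wf[d$Dflat + 1, 1] <- 1
  p$Wf[d$Dflat + 2, 2] <- 1
  p$Wf[d$Dflat + 3, 3] <- 1
  p$bf[] <- 0
  p$bf[1:3] <- 50
  p$wo[] <- 0
  p$wo[1:3] <- w
  p$bo <- b - 50 * sum(w)
  new("PinnModel", config = cfg, params = p,
      normStats = list(y_mean = 0, y_sd = 1, u_mean = c(0, 0, 0),
                       u_sd = c(1, 1, 1)))
}

# independent brute-force oracle: per-pair scalar forward calls with
# central finite-difference feature gradients (never touches the
# analytic gradient path)
bruteResiduals <- function(model, ds, step = 1e-5) {
  X <- t(waveforms(ds)); U <- beatFeatures(ds)
  sess <- sessionIds(ds)
  out <- c()
  for (i in seq_len(nrow(X) - 1)) {
    if (sess[i] != sess[i + 1]) next
    fi <- pinnForward(model, X[i, ], U[i, ])
    g <- numeric(3)
    for (k in 1:3) {
      up <- U[i, ]; um <- U[i, ]
      up[k] <- up[k] + step; um[k] <- um[k] - step
      g[k] <- (pinnForward(model, X[i, ], up) -
                 pinnForward(model, X[i, ], um)) / (2 * step)
    }
    Pi <- fi + sum(g * (U[i + 1, ] - U[i, ]))
    out <- c(out, pinnForward(model, X[i + 1, ], U[i + 1, ]) - Pi)
  }
  out
}

# one shared realistic simulation for feature-level checks (built once)
sharedSim <- simulateBeats(simConfig(nBeats = 400, seed = 42))
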