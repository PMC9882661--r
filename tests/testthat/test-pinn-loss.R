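test_that("Taylor polynomial reduces to the anchor value at zero displacement", {
  cfg <- tinyConfig()
  m <- randomModel(cfg, seed = 5)
  ds <- tinyDataset(4, cfg, seed = 6)
  X <- t(waveforms(ds)); U <- beatFeatures(ds)
  f <- pinnForward(m, X[1, ], U[1, ])
  expect_equal(taylorEvaluate(m, X[1, ], U[1, ], U[1, ]), f)
})

test_that("Taylor polynomial is the printed first-order expression", {
  # linear-in-u network: P_i(u) = f(anchor) + w . (u - u_i), checkable by hand
  w <- c(2, -1, 0)
  m <- linearModel(w, b = 5)
  uA <- c(0, 0, 0)
  xA <- rep(0, 20)
  # f(anchor) = 5, gradients (2, -1, 0), displacement (1, 1, 7) -> 6
  expect_equal(taylorEvaluate(m, xA, uA, uA + c(1, 1, 7)), 6)
  # exactness for arbitrary displacements (first order is the whole map)
  for (s in 1:5) {
    du <- withr::with_seed(s, rnorm(3, sd = 3))
    expect_equal(taylorEvaluate(m, xA, uA, uA + du),
                 pinnForward(m, xA, uA + du), tolerance = 1e-9)
  }
})

test_that("residuals vanish for identical consecutive beats", {
  cfg <- tinyConfig()
  m <- randomModel(cfg, seed = 2)
  wf <- matrix(rnorm(cfg@inputLen), cfg@inputLen, 6)  # same beat 6 times
  U <- matrix(rep(rnorm(3), each = 6), 6, 3)
  ds <- BeatDataset(wf, U, labels = rnorm(6), standardized = TRUE,
                    normStats = list(y_mean = 0, y_sd = 1))
  expect_equal(pinnResiduals(m, ds), rep(0, 5), tolerance = 1e-12)
})

test_that("residuals vanish identically for a network linear in u", {
  m <- linearModel(c(1.5, -2, 0.7), b = -1)
  ds <- tinyDataset(10)
  expect_equal(pinnResiduals(m, ds), rep(0, 9), tolerance = 1e-9)
})

test_that("residuals match the brute-force scalar oracle", {
  cfg <- tinyConfig()
  for (s in 1:3) {
    m <- randomModel(cfg, seed = s + 10)
    ds <- tinyDataset(8, cfg, seed = s,
                      sessions = rep(c("a", "b"), each = 4))
    h <- pinnResiduals(m, ds)
    expect_length(h, 6)  # pair (4,5) spans the session boundary
    expect_equal(h, bruteResiduals(m, ds), tolerance = 1e-6)
  }
})

test_that("residual limit: h -> 0 as consecutive beats coalesce", {
  cfg <- tinyConfig()
  m <- randomModel(cfg, seed = 4)
  x0 <- withr::with_seed(20, rnorm(cfg@inputLen))
  u0 <- withr::with_seed(21, rnorm(3))
  dx <- withr::with_seed(22, rnorm(cfg@inputLen))
  du <- withr::with_seed(23, rnorm(3))
  hs <- vapply(c(1e-1, 1e-2, 1e-3, 1e-4), function(delta) {
    wf <- cbind(x0, x0 + delta * dx)
    U <- rbind(u0, u0 + delta * du)
    ds <- BeatDataset(wf, U, labels = c(0, 0), standardized = TRUE)
    abs(pinnResiduals(m, ds))
  }, numeric(1))
  # at least linear decay once inside the locally-linear region
  expect_true(all(diff(log10(hs)) < 0))
  expect_lt(hs[4], hs[2] / 50)
})

test_that("physics loss is the mean squared residual and oracle-consistent", {
  cfg <- tinyConfig()
  m <- randomModel(cfg, seed = 7)
  ds <- tinyDataset(9, cfg, seed = 8)
  h <- pinnResiduals(m, ds)
  expect_equal(physicsLoss(m, ds), mean(h^2))
  expect_equal(physicsLoss(m, ds), mean(bruteResiduals(m, ds)^2),
               tolerance = 1e-6)
  # residuals [1, -1] -> mean square 1 (definition check on the bundle)
  lb <- new("LossBundle", lConv = 0, lPhys = 1, lTotal = 1,
            residuals = c(1, -1), lambdaPhys = 1, nLabeled = 0L,
            nPairs = 2L)
  expect_equal(lb@lPhys, mean(c(1, -1)^2))
})

test_that("physics loss ignores which beats are labeled", {
  cfg <- tinyConfig()
  m <- randomModel(cfg, seed = 3)
  ds1 <- tinyDataset(10, cfg, seed = 5)
  ds2 <- ds1
  SummarizedExperiment::colData(ds2)$bp <-
    c(bpLabels(ds1)[1:3], rep(NA_real_, 7))
  expect_identical(physicsLoss(m, ds1), physicsLoss(m, ds2))
})

test_that("supervised loss is the labeled-beat MSE", {
  cfg <- tinyConfig()
  ds <- tinyDataset(6, cfg, seed = 11)
  # predictions equal labels -> 0
  m <- randomModel(cfg, scale = 0)
  yhat <- pinnForward(m, ds)   # all equal bo = 0
  ds0 <- ds
  SummarizedExperiment::colData(ds0)$bp <- yhat
  expect_equal(supervisedLoss(m, ds0, 1:6), 0)
  # predictions [0,0] vs labels [1,-1] -> 1
  ds1 <- ds
  SummarizedExperiment::colData(ds1)$bp <- c(1, -1, rep(NA, 4))
  expect_equal(supervisedLoss(m, ds1, 1:2), 1)
  expect_error(supervisedLoss(m, ds, integer()), "no labels")
})

test_that("supervised loss matches an independent recomputation", {
  cfg <- tinyConfig()
  for (s in 1:10) {
    m <- randomModel(cfg, seed = s)
    ds <- tinyDataset(7, cfg, seed = 100 + s)
    idx <- withr::with_seed(s, sample(7, 3))
    manual <- mean((vapply(idx, function(i)
      pinnForward(m, t(waveforms(ds))[i, ], beatFeatures(ds)[i, ]),
      numeric(1)) - bpLabels(ds)[idx])^2)
    expect_equal(supervisedLoss(m, ds, idx), manual, tolerance = 1e-8)
  }
})

test_that("total loss composes the bundle correctly for any lambda", {
  cfg <- tinyConfig()
  ds <- tinyDataset(8, cfg, seed = 13)
  for (s in 1:10) {
    m <- randomModel(cfg, seed = 200 + s)
    lam <- withr::with_seed(s, runif(1, 0, 2))
    lb <- totalLoss(m, ds, 1:4, lambdaPhys = lam)
    expect_equal(lb@lTotal, lb@lConv + lam * lb@lPhys)
    expect_equal(lb@lConv, supervisedLoss(m, ds, 1:4))
    expect_equal(lb@lPhys, physicsLoss(m, ds))
    expect_gte(lb@lConv, 0); expect_gte(lb@lPhys, 0)
  }
  # lambda = 0 collapses to the conventional objective
  m <- randomModel(cfg, seed = 99)
  lb0 <- totalLoss(m, ds, 1:4, lambdaPhys = 0)
  expect_identical(lb0@lTotal, lb0@lConv)
})

test_that("worked arithmetic: 0.3 + 1 * 0.2 = 0.5 bundle invariant", {
  lb <- new("LossBundle", lConv = 0.3, lPhys = 0.2, lTotal = 0.5,
            residuals = numeric(), lambdaPhys = 1, nLabeled = 1L,
            nPairs = 0L)
  expect_equal(lb@lTotal, 0.5)
  expect_error(new("LossBundle", lConv = 0.3, lPhys = 0.2, lTotal = 0.6,
                   residuals = numeric(), lambdaPhys = 1, nLabeled = 1L,
                   nPairs = 0L))
})

test_that("residuals require at least two beats", {
  cfg <- tinyConfig()
  m <- randomModel(cfg)
  ds <- tinyDataset(5, cfg)[, 1]
  expect_error(pinnResiduals(m, ds), "insufficient sequence")
})
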