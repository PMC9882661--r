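test_that("minimal split reproduces the worked 40/960 example", {
  labels <- withr::with_seed(1, runif(1000, 120, 160))
  sp <- minimalSplit(labels, binWidth = 1, seed = 3)
  expect_length(trainIdx(sp), 40)
  expect_length(testIdx(sp), 960)
  expect_equal(sp@nBins, 40L)
  # 4% / 96%
  expect_equal(length(trainIdx(sp)) / 1000, 0.04)
})

test_that("labels inside one bin give a single training point", {
  labels <- c(120.1, 120.3, 120.6, 120.9)
  sp <- minimalSplit(labels, binWidth = 1, seed = 0)
  expect_length(trainIdx(sp), 1)
  expect_length(testIdx(sp), 3)
  expect_error(minimalSplit(rep(130, 5)), "degenerate range")
})

test_that("every non-empty bin contributes exactly one training point", {
  for (s in 1:5) {
    labels <- withr::with_seed(s, rnorm(300, 140, 12))
    sp <- minimalSplit(labels, binWidth = 1, seed = s)
    # brute-force bin audit
    lo <- min(labels)
    K <- ceiling((max(labels) - lo) / 1)
    bin <- pmin(floor((labels - lo) / 1) + 1, K)
    counts <- table(factor(bin[trainIdx(sp)], levels = 1:K))
    occupied <- sort(unique(bin))
    expect_true(all(counts[occupied] == 1))
    expect_true(all(counts[setdiff(1:K, occupied)] == 0))
    expect_setequal(c(trainIdx(sp), testIdx(sp)), seq_along(labels))
  }
})

test_that("growing sets emit nested splits of sizes 1,3,5,...", {
  labels <- 100 + seq(0, 62.4, length.out = 1000)   # 125 half-mmHg bins
  splits <- growingSets(labels, seed = 2)
  expect_length(splits, 63)
  sizes <- vapply(splits, function(s) length(trainIdx(s)), integer(1))
  expect_equal(sizes, seq(1, 125, by = 2))
  for (i in 2:length(splits))
    expect_true(all(trainIdx(splits[[i - 1]]) %in% trainIdx(splits[[i]])))
  # one point per 0.5-mmHg bin in the full pool
  pool <- trainIdx(splits[[63]])
  bin <- pmin(floor((labels[pool] - min(labels)) / 0.5) + 1, 125)
  expect_equal(sort(unique(bin)), 1:125)
})

test_that("pool sizes 125/77/69 give 63+39+35 = 137 splits", {
  mk <- function(span) 100 + seq(0, span, length.out = 800)
  counts <- vapply(c(62.4, 38.4, 34.4),
                   function(sp) length(growingSets(mk(sp))), integer(1))
  expect_equal(counts, c(63L, 39L, 35L))
  expect_equal(sum(counts), 137L)
  expect_length(growingSets(c(100, 100.2)), 1L)  # single-bin pool
})

test_that("parameter gradients match central finite differences", {
  cfg <- tinyConfig()
  ds <- tinyDataset(10, cfg, seed = 31)
  X <- t(waveforms(ds)); U <- beatFeatures(ds)
  yl <- bpLabels(ds)[1:4]
  anchors <- pinnBP:::.pairAnchors(sessionIds(ds))
  for (s in c(2, 9)) {
    p <- initParams(cfg, s)
    lossAt <- function(pp) {
      g <- pinnBP:::.lossGradients(pp, X, U, cfg, 1:4, yl, anchors,
                                   lambdaPhys = 1)
      g$lTotal
    }
    gr <- pinnBP:::.lossGradients(p, X, U, cfg, 1:4, yl, anchors,
                                  lambdaPhys = 1)
    eps <- 1e-6
    for (nm in c("W1", "W2", "Wf", "wo", "bo", "b1", "bf")) {
      w <- p[[nm]]
      picks <- withr::with_seed(s, sample(length(w), min(6, length(w))))
      for (j in picks) {
        pp <- p; pm <- p
        pp[[nm]][j] <- pp[[nm]][j] + eps
        pm[[nm]][j] <- pm[[nm]][j] - eps
        fd <- (lossAt(pp) - lossAt(pm)) / (2 * eps)
        an <- gr$grads[[nm]][j]
        expect_equal(an, fd, tolerance = 5e-4,
                     label = sprintf("grad %s[%d] seed %d", nm, j, s))
      }
    }
  }
})

test_that("stopping rule triggers immediately when already converged", {
  ds <- tinyDataset(8, tinyConfig())
  sp <- new("SplitSpec", trainIdx = 1:3, testIdx = 4:8, binWidth = 1,
            nBins = 3L, seed = 0L)
  m <- trainPINN(ds, sp, config = tinyConfig(), stopLoss = 100,
                 maxEpochs = 50, seed = 1)
  rep <- trainReport(m)
  expect_true(rep$converged)
  expect_identical(rep$epochs, 0L)
})

test_that("training is reproducible for identical seeds", {
  ds <- tinyDataset(12, tinyConfig(), seed = 41)
  sp <- new("SplitSpec", trainIdx = c(1L, 5L, 9L), testIdx = 2:4,
            binWidth = 1, nBins = 3L, seed = 0L)
  run <- function() trainPINN(ds, sp, config = tinyConfig(),
                              stopLoss = 1e-8, maxEpochs = 40, seed = 7)
  a <- run(); b <- run()
  expect_equal(trainReport(a)$history, trainReport(b)$history,
               tolerance = 1e-6)
  expect_equal(a@params, b@params, tolerance = 1e-6)
})

test_that("training reduces the total loss on a small dataset", {
  cfg <- tinyConfig()
  ds <- tinyDataset(30, cfg, seed = 51,
                    labels = withr::with_seed(52, rnorm(30)))
  sp <- new("SplitSpec", trainIdx = seq(1L, 30L, by = 3L),
            testIdx = setdiff(1:30, seq(1L, 30L, by = 3L)),
            binWidth = 1, nBins = 10L, seed = 0L)
  m <- trainPINN(ds, sp, config = cfg, stopLoss = 1e-9, maxEpochs = 150,
                 seed = 3)
  h <- trainReport(m)$history
  expect_lt(h[nrow(h), "l_total"], h[1, "l_total"] / 2)
})

test_that("lambda = 0 training never touches the physics loss trajectory", {
  # identical data/seed: the lambda=0 run must equal a run whose physics
  # term exists but is weighted away (shared implementation contract)
  ds <- tinyDataset(10, tinyConfig(), seed = 61)
  sp <- new("SplitSpec", trainIdx = 1:4, testIdx = 5:10, binWidth = 1,
            nBins = 4L, seed = 0L)
  m0 <- trainPINN(ds, sp, config = tinyConfig(), lambdaPhys = 0,
                  stopLoss = 1e-8, maxEpochs = 30, seed = 5)
  expect_equal(trainReport(m0)$final@lTotal, trainReport(m0)$final@lConv)
})

test_that("diverging training raises an informative error", {
  ds <- tinyDataset(8, tinyConfig(), seed = 71)
  sp <- new("SplitSpec", trainIdx = 1:4, testIdx = 5:8, binWidth = 1,
            nBins = 4L, seed = 0L)
  expect_error(trainPINN(ds, sp, config = tinyConfig(), lr = 1e200,
                         stopLoss = 1e-12, maxEpochs = 50, seed = 1),
               "diverged")
})
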