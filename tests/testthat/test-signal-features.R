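test_that("baseline normalisation divides by Z0 and flags the mode", {
  rec <- RawRecording(c(50, 100), sampleRate = 100, Z0 = 50,
                      beatBoundaries = c(1L, 2L))
  out <- normalizeDeltaZ(rec)
  expect_equal(out@samples, c(1, 2))
  expect_identical(out@mode, "delta-z-over-z0")

  raw <- RawRecording(c(50, 100), sampleRate = 100,
                      beatBoundaries = c(1L, 2L))
  out2 <- normalizeDeltaZ(raw)
  expect_equal(out2@samples, c(50, 100))
  expect_identical(out2@mode, "delta-z")

  expect_error(RawRecording(c(1, 2), 100, Z0 = 0), "Z0")
})

test_that("beat segmentation cuts at boundaries with correct durations", {
  rec <- RawRecording(seq_len(260), sampleRate = 100,
                      beatBoundaries = c(1L, 101L, 221L),
                      sessionIds = c("a", "a"))
  beats <- segmentBeats(rec)
  expect_length(beats, 2)
  expect_equal(vapply(beats, slot, numeric(1), "duration"), c(1.0, 1.2))
  expect_equal(beats[[1]]@x, 1:100)
  expect_equal(beats[[2]]@x, 101:220)

  one <- RawRecording(1:10, 100, beatBoundaries = 5L)
  expect_error(segmentBeats(one), "insufficient boundaries")
})

test_that("segmentation of a simulated recording matches generator truth", {
  sim <- sharedSim
  beats <- segmentBeats(sim$recording)
  durations <- vapply(beats, slot, numeric(1), "duration")
  # generator periods: 60/HR rounded to the sample grid
  expect_equal(durations[sim$truth$beat_index],
               round(60 / sim$truth$u3_true * 100) / 100,
               tolerance = 1e-12)
  expect_equal(vapply(beats, slot, character(1), "sessionId")[
                 sim$truth$beat_index],
               sim$truth$session)
})

test_that("fiducial detection finds planted systolic and reflection peaks", {
  rate <- 100
  tt <- (0:89) / rate
  pulse <- exp(-(tt - 0.15)^2 / (2 * 0.045^2)) +
    0.5 * exp(-(tt - 0.40)^2 / (2 * 0.08^2))
  beat <- new("BeatRecord", x = -pulse, sampleRate = rate, duration = 0.9)
  fids <- extractFiducials(beat)
  p <- fids@points
  expect_equal(p$t_s[p$point == "B"], 0.15, tolerance = 1 / rate)
  expect_equal(p$t_s[p$point == "F"], 0.40, tolerance = 1 / rate)
  expect_true(all(diff(p$t_s) >= -1e-12))
  expect_identical(p$point, c("A", "B", "C", "D", "E", "F", "G", "H", "J"))
})

test_that("degenerate morphology raises a fiducial-detection error", {
  beat <- new("BeatRecord", x = seq(0, -1, length.out = 50),
              sampleRate = 100, duration = 0.5, beatIndex = 7L)
  expect_error(extractFiducials(beat), "fiducial-detection error at beat 7")
})

test_that("fiducial times are non-decreasing on realistic beats", {
  beats <- segmentBeats(sharedSim$recording)
  for (b in beats[seq(1, length(beats), by = 37)]) {
    p <- extractFiducials(b)@points
    expect_true(all(diff(p$t_s) >= -1e-12))
    expect_true(all(p$t_s >= 0 & p$t_s <= b@duration + 1e-9))
  }
})

test_that("features follow the printed fiducial formulas", {
  pts <- data.frame(
    point = c("A", "B", "C", "D", "E", "F", "G", "H", "J"),
    t_s = c(0, 0.10, 0.12, 0.2, 0.25, 0.30, 0.4, 0.6, 0.8),
    dz = c(0, -0.07, -0.08, -0.05, -0.04, -0.05, -0.03, -0.01, 0))
  fids <- new("FiducialSet", points = pts, duration = 0.8)
  u <- computeFeatures(fids)
  expect_equal(unname(u), c(0.08, 5.0, 75))

  # t_F == t_B (still a valid non-decreasing landmark set) is non-physical
  bad <- pts
  bad$t_s <- c(0, 0.30, 0.30, 0.30, 0.30, 0.30, 0.4, 0.6, 0.8)
  expect_error(computeFeatures(new("FiducialSet", points = bad,
                                   duration = 0.8)),
               "non-physical timing")
})

test_that("extracted features carry the planted coupling signs", {
  U <- beatFeatures(sharedSim$dataset)
  bp <- sharedSim$truth$bp_mmhg
  expect_gt(nrow(U), 350)
  expect_lt(cor(U[, 1], bp), -0.8)   # vasoconstriction: amplitude falls
  expect_gt(cor(U[, 2], bp), 0.8)    # earlier reflection: 1/delay rises
  expect_true(all(is.finite(U)) && all(U[, 2] > 0) && all(U[, 3] > 0))
})

test_that("moving average matches hand-computed windows and strides", {
  wf <- matrix(rep(c(100, 110, 120, 130, 140), each = 4), 4)
  U <- matrix(rep(c(100, 110, 120, 130, 140), 3), ncol = 3)
  ds <- BeatDataset(wf, U, labels = c(100, 110, 120, 130, 140),
                    tStart = 1:5, duration = rep(1, 5))
  sm <- movingAverageSmooth(ds, window = 3, overlap = 1)
  expect_equal(bpLabels(sm), c(110, 130))
  expect_equal(unname(waveforms(sm)[1, ]), c(110, 130))
  expect_equal(unname(beatFeatures(sm)[, 2]), c(110, 130))

  ds3 <- BeatDataset(wf[, 1:3], U[1:3, ], labels = c(100, 110, 120),
                     tStart = 1:3, duration = rep(1, 3))
  sm3 <- movingAverageSmooth(ds3)
  expect_equal(bpLabels(sm3), 110)

  expect_error(movingAverageSmooth(ds, window = 3, overlap = 3),
               "invalid window")
})

test_that("smoothing windows never span sessions; length is closed-form", {
  R <- 37
  ds <- tinyDataset(R, sessions = rep(c("cpt-1", "rec-1"), c(20, 17)),
                    labels = seq_len(R))
  sm <- movingAverageSmooth(ds)
  perSession <- function(n) floor((n - 3) / 2) + 1
  expect_equal(nBeats(sm), perSession(20) + perSession(17))
  # window means of within-session consecutive triples only
  expect_true(all(sessionIds(sm) %in% c("cpt-1", "rec-1")))
  lab <- bpLabels(sm)
  expect_equal(lab[perSession(20) + 1], mean(21:23))
})

test_that("resampling pads to fixed length and rejects long beats", {
  beat <- new("BeatRecord", x = sin(seq(0, 3, length.out = 100)),
              sampleRate = 100, duration = 1.0)
  out <- resampleAndPad(beat, targetRate = 30, padLen = 60)
  expect_length(out@x, 60)
  expect_equal(out@x[31:60], rep(0, 30))

  const <- new("BeatRecord", x = rep(2.5, 100), sampleRate = 100,
               duration = 1.0)
  rc <- resampleAndPad(const, 30, 60)
  expect_equal(rc@x[1:30], rep(2.5, 30), tolerance = 1e-12)

  long <- new("BeatRecord", x = rep(0, 250), sampleRate = 100,
              duration = 2.5)
  expect_error(resampleAndPad(long, 30, 60), "beat too long")
})

test_that("standardization is exact, invertible and guarded", {
  wf <- matrix(seq(-1, 1, length.out = 60), 6)
  U <- cbind(u1 = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
             u2 = seq(2, 4, length.out = 10),
             u3 = seq(60, 90, length.out = 10))[1:10, ]
  ds <- BeatDataset(wf, U, labels = seq(110, 150, length.out = 10))
  st <- standardizeDataset(ds)
  expect_equal(mean(beatFeatures(st)[, 1]), 0, tolerance = 1e-12)
  expect_equal(sd(beatFeatures(st)[, 1]), 1, tolerance = 1e-12)
  expect_equal(mean(bpLabels(st)), 0, tolerance = 1e-12)
  back <- destandardizeDataset(st)
  expect_equal(waveforms(back), waveforms(ds), tolerance = 1e-12)
  expect_equal(beatFeatures(back), beatFeatures(ds), tolerance = 1e-12)
  expect_equal(bpLabels(back), bpLabels(ds), tolerance = 1e-12)

  dsconst <- BeatDataset(wf, U, labels = rep(120, 10))
  expect_error(standardizeDataset(dsconst), "degenerate channel")
})
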