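test_that("resting epoching cuts non-overlapping windows and drops the remainder", {
  fs <- 1000
  rec <- recordingOf(matrix(rnorm(2 * 300 * fs), 2), fs)
  ep <- epochResting(rec, 6)
  expect_equal(dim(ep@data), c(50, 2, 6000))
  ## 11.9 s -> one epoch; 5.9 s -> none
  short <- recordingOf(matrix(rnorm(2 * round(11.9 * fs)), 2), fs)
  expect_equal(nEpochs(epochResting(short, 6)), 1)
  tiny <- recordingOf(matrix(rnorm(2 * round(5.9 * fs)), 2), fs)
  expect_error(epochResting(tiny, 6), "shorter than one")
})

test_that("TMS epoching is stimulus-locked and baseline-corrected", {
  fs <- 500
  n <- 30 * fs
  mk <- as.integer(c(5, 12, 19, 26) * fs)
  data <- matrix(rnorm(2 * n), 2)
  data[1, ] <- data[1, ] + 50   # constant offset channel
  rec <- recordingOf(data, fs, markers = mk)
  ep <- epochTMS(rec)
  expect_equal(nEpochs(ep), 4)
  expect_equal(dim(ep@data)[3], 4 * fs)
  ## per-channel mean over the baseline window is zero
  b1 <- round((-1.55 - (-2)) * fs) + 1
  b2 <- round((-0.05 - (-2)) * fs)
  for (e in 1:4) for (ch in 1:2) {
    expect_equal(mean(ep@data[e, ch, b1:b2]), 0, tolerance = 1e-10)
  }
  ## offsets removed in every epoch
  expect_lt(max(abs(rowMeans(ep@data[, 1, ]))), 1)
  ## markers too close to an edge are dropped with a warning
  rec2 <- recordingOf(data, fs, markers = c(100L, mk))
  expect_warning(ep2 <- epochTMS(rec2), "dropped")
  expect_equal(nEpochs(ep2), 4)
  expect_error(epochTMS(recordingOf(data, fs)), "no markers")
})

test_that("amplitude rejection drops bad channels and bad epochs separately", {
  fs <- 400
  set.seed(20)
  arr <- array(rnorm(10 * 3 * fs, sd = 10), dim = c(10, 3, fs))
  ep <- tmseegdx:::epochSet(arr, fs, c(0, 1), c("A", "B", "C"))
  ## clean set: nothing rejected
  r0 <- rejectBad(ep, testPreproc())
  expect_equal(nEpochs(r0$epochs), 10)
  expect_length(r0$report$channels_dropped, 0)
  ## channel driven to +-500 uV throughout: channel dropped
  arr1 <- arr; arr1[, 2, ] <- 500 * sign(arr1[, 2, ])
  r1 <- rejectBad(tmseegdx:::epochSet(arr1, fs, c(0, 1), c("A", "B", "C")),
                  testPreproc())
  expect_equal(r1$report$channels_dropped, "B")
  expect_equal(nEpochs(r1$epochs), 10)
  ## single 400 uV spike: epoch dropped, channel kept
  arr2 <- arr; arr2[4, 2, 17] <- 400
  r2 <- rejectBad(tmseegdx:::epochSet(arr2, fs, c(0, 1), c("A", "B", "C")),
                  testPreproc())
  expect_length(r2$report$channels_dropped, 0)
  expect_equal(r2$report$epochs_dropped, 4)
  expect_equal(nEpochs(r2$epochs), 9)
  ## flat channel dropped
  arr3 <- arr; arr3[, 1, ] <- 0.01
  r3 <- rejectBad(tmseegdx:::epochSet(arr3, fs, c(0, 1), c("A", "B", "C")),
                  testPreproc())
  expect_equal(r3$report$channels_flat, "A")
})

test_that("downsampling preserves counts, spectra and is the identity at target", {
  fs <- 3000
  set.seed(21)
  arr <- array(rnorm(2 * 2 * 4 * fs), dim = c(2, 2, 4 * fs))
  ep <- tmseegdx:::epochSet(arr, fs, c(0, 4), c("A", "B"))
  dn <- downsampleEpochs(ep, 1000)
  expect_equal(dim(dn@data)[3], 4000)
  expect_equal(dn@fs, 1000)
  ## alpha band power preserved within 5%
  p0 <- bandPower(ep@data[1, 1, ], 8, 13, fs)
  p1 <- bandPower(dn@data[1, 1, ], 8, 13, 1000)
  expect_equal(p1 / p0, 1, tolerance = 0.05)
  ## already at target: identity payload
  ep1k <- tmseegdx:::epochSet(array(rnorm(2 * 2 * 4000), c(2, 2, 4000)),
                              1000, c(0, 4), c("A", "B"))
  same <- downsampleEpochs(ep1k, 1000)
  expect_identical(same@data, ep1k@data)
  expect_error(downsampleEpochs(ep, 900), "integer multiple")
})

test_that("analysis windows exclude the 50 ms around the pulse", {
  fs <- 1000
  nsamp <- 4 * fs
  ## encode each sample's time in the signal to track the cut exactly
  tgrid <- seq(-2, 2 - 1 / fs, by = 1 / fs)
  arr <- array(rep(tgrid, each = 2), dim = c(1, 2, nsamp))
  ep <- tmseegdx:::epochSet(arr, fs, c(-2, 2), c("A", "B"))
  w <- extractWindows(ep)
  expect_equal(dim(w$pre@data)[3], 1500)
  expect_equal(dim(w$post@data)[3], 500)
  pre_t <- w$pre@data[1, 1, ]
  post_t <- w$post@data[1, 1, ]
  ## half-open [start, end): boundaries behave exactly
  expect_equal(pre_t[1], -1.55)
  expect_equal(pre_t[1500], -0.051)
  expect_equal(post_t[1], 0.05)
  expect_equal(post_t[500], 0.549)
  expect_false(any(c(pre_t, post_t) == 0))
  expect_false(any(abs(c(pre_t, post_t)) < 0.049))
  short <- tmseegdx:::epochSet(array(0, c(1, 2, fs)), fs, c(0, 1), c("A", "B"))
  expect_error(extractWindows(short), "must span")
})

test_that("evoked averaging matches a brute-force mean", {
  set.seed(22)
  arr <- array(rnorm(5 * 3 * 100), dim = c(5, 3, 100))
  ep <- tmseegdx:::epochSet(arr, 100, c(0, 1), c("A", "B", "C"))
  av <- evokedAverage(ep)
  brute <- matrix(0, 3, 100)
  for (e in 1:5) brute <- brute + arr[e, , ] / 5
  expect_equal(unname(av), brute)
  ## identical epochs average to any one epoch; +x and -x cancel
  arr2 <- array(rep(arr[1, , ], each = 5), dim = c(5, 3, 100))
  ep2 <- tmseegdx:::epochSet(arr2, 100, c(0, 1), c("A", "B", "C"))
  expect_equal(unname(evokedAverage(ep2)), arr[1, , ])
  arr3 <- array(0, dim = c(2, 3, 100))
  arr3[1, , ] <- arr[1, , ]; arr3[2, , ] <- -arr[1, , ]
  ep3 <- tmseegdx:::epochSet(arr3, 100, c(0, 1), c("A", "B", "C"))
  expect_equal(max(abs(evokedAverage(ep3))), 0)
})

test_that("operations append provenance and never mutate their input", {
  fs <- 400
  set.seed(23)
  rec <- recordingOf(matrix(rnorm(2 * 30 * fs, sd = 10), 2), fs)
  before <- rec@data
  ep <- epochResting(rec)
  snapshot <- ep@data
  f <- filterEpochs(ep, testPreproc())
  expect_identical(rec@data, before)
  expect_identical(ep@data, snapshot)
  expect_match(tail(provenance(f), 1), "filter")
  expect_match(provenance(f)[1], "epoch_resting")
})

test_that("filtering and downsampling commute with epoch averaging", {
  fs <- 2000
  set.seed(24)
  arr <- array(rnorm(4 * 2 * 4 * fs, sd = 10), dim = c(4, 2, 4 * fs))
  ep <- tmseegdx:::epochSet(arr, fs, c(0, 4), c("A", "B"))
  cfg <- testPreproc()
  ## average-then-process vs process-then-average (linear operations)
  chain <- function(e) downsampleEpochs(filterEpochs(e, cfg), 1000)
  a <- evokedAverage(chain(ep))
  avEp <- tmseegdx:::epochSet(array(evokedAverage(ep), c(1, 2, 4 * fs)),
                              fs, c(0, 4), c("A", "B"))
  b <- evokedAverage(chain(avEp))
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("the artifact-free chain is near-identity in the analysis band", {
  spec <- testSpec(nPerGroup = 2, seed = 25)
  coh <- generateCohort(spec)
  rec <- coh[[1]]@resting
  out <- preprocessRecording(rec, "resting", testPreproc())
  expect_equal(nEpochs(out$epochs), 3)
  fs <- spec@fs
  for (ch in c(1, 9, 17)) {
    raw <- tmseegdx:::bandFilter(rec@data[ch, 1:(6 * fs)], fs, 1, 45)
    cln <- tmseegdx:::bandFilter(out$epochs@data[1, ch, ], fs, 1, 45)
    expect_gt(cor(raw, cln), 0.95)
  }
})
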