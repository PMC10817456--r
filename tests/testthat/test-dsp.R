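test_that("zero-phase filtering attenuates the stopband and passes the passband", {
  fs <- 1000
  t50 <- sine(50, fs, 4)
  t10 <- sine(10, fs, 4)
  mid <- 1001:3000  # steady-state section
  ## notch 48-52 Hz: >= 20 dB down
  y50 <- zeroPhaseFilter(t50, fs, 48, 52, order = 2, type = "stop")
  att <- 20 * log10(sqrt(mean(y50[mid]^2)) / sqrt(mean(t50[mid]^2)))
  expect_lt(att, -20)
  ## band-pass 0.5-100: 10 Hz within +-1 dB
  y10 <- zeroPhaseFilter(t10, fs, 0.5, 100, order = 4)
  gain <- 20 * log10(sqrt(mean(y10[mid]^2)) / sqrt(mean(t10[mid]^2)))
  expect_lt(abs(gain), 1)
  ## linearity: zero in, zero out
  expect_equal(zeroPhaseFilter(numeric(1000), fs, 0.5, 100), numeric(1000))
})

test_that("zero-phase filtering introduces no phase shift", {
  fs <- 500
  x <- sine(10, fs, 4)
  y <- zeroPhaseFilter(x, fs, 8, 13, order = 4)
  mid <- 501:1500
  expect_gt(cor(x[mid], y[mid]), 0.999)
})

test_that("analytic signal recovers amplitude and phase of a sinusoid", {
  fs <- 500
  x <- 2.5 * sine(10, fs, 4)
  a <- tmseegdx:::analyticSignal(x)
  mid <- 201:1800
  expect_equal(mean(Mod(a[mid])), 2.5, tolerance = 1e-3)
  ## instantaneous frequency ~ 10 Hz
  dphi <- diff(Arg(a[mid]))
  dphi <- dphi[abs(dphi) < pi]
  expect_equal(mean(dphi) * fs / (2 * pi), 10, tolerance = 0.05)
})

test_that("Welch band power matches spectral expectations", {
  fs <- 500
  x <- sine(10, fs, 8)
  expect_gt(bandPower(x, 8, 13, fs) / bandPower(x, 14, 30, fs), 100)
  ## flat spectrum: band powers proportional to bandwidth
  set.seed(1)
  w <- rnorm(fs * 120)
  ratio <- bandPower(w, 14, 30, fs) / bandPower(w, 8, 13, fs)
  expect_equal(ratio, (30 - 14) / (13 - 8), tolerance = 0.15)
  expect_identical(bandPower(numeric(1000), 8, 13, fs), 0)
})

test_that("welchPsd falls back to a single segment with a warning", {
  fs <- 500
  expect_warning(ps <- welchPsd(rnorm(100), fs), "single-segment")
  expect_length(ps$psd, 51)
})

test_that("wPLI reproduces the defining formula on listed imaginary parts", {
  ## |1 - 0.5 + 2 - 0.5| / (1 + 0.5 + 2 + 0.5) = 2/4
  expect_equal(tmseegdx:::wpliFromImag(c(1, -0.5, 2, -0.5)), 0.5)
  expect_equal(tmseegdx:::wpliFromImag(c(1, 2, 3)), 1)
  expect_equal(tmseegdx:::wpliFromImag(numeric(0)), 0)  # convention
})

test_that("wPLI hits its boundary cases", {
  fs <- 250
  x <- sine(10, fs, 4)
  y <- sine(10, fs, 4, phase = -pi / 2)
  expect_equal(wpli(x, y, 8, 13, fs), 1, tolerance = 1e-3)
  expect_equal(wpli(x, x, 8, 13, fs), 0)            # zero lag convention
  expect_error(wpli(x, y[-1], 8, 13, fs), "length")
})

test_that("wPLI is bounded, symmetric and amplitude-invariant", {
  fs <- 250
  set.seed(42)
  for (i in 1:5) {
    x <- rnorm(fs * 4); y <- rnorm(fs * 4)
    v <- wpli(x, y, 8, 13, fs)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(wpli(y, x, 8, 13, fs), v)
    expect_equal(wpli(3.7 * x, 0.2 * y, 8, 13, fs), v)
  }
})

test_that("independent signals carry little consistent phase lag", {
  fs <- 250
  set.seed(7)
  v <- replicate(10, {
    bg <- synthBackground(8, fs, 2)
    wpli(bg[1, ], bg[2, ], 8, 13, fs)
  })
  expect_lt(mean(v), 0.25)
})

test_that("modulation index matches its closed forms", {
  expect_equal(miFromDistribution(rep(1 / 18, 18)), 0)
  expect_equal(miFromDistribution(c(1, rep(0, 17))), 1)
  expect_equal(miFromDistribution(c(0.5, 0.5, rep(0, 16))),
               1 - log(2) / log(18))
  ## equals a brute-force KL computation on random distributions
  set.seed(3)
  for (i in 1:5) {
    p <- runif(18); p <- p / sum(p)
    kl <- sum(p * log(p / (1 / 18)))
    expect_equal(miFromDistribution(p), kl / log(18))
  }
})

test_that("pacMI responds to planted modulation and not to its absence", {
  fs <- 400
  set.seed(5)
  x <- synthBackground(20, fs, 1)[1, ] +
    4 * tmseegdx:::bandNoise(20 * fs, fs, 4, 7) +
    3 * tmseegdx:::bandNoise(20 * fs, fs, 30, 45)
  mi0 <- pacMI(x, 4, 7, 30, 45, fs)
  mi3 <- pacMI(plantPAC(x, 4, 7, 30, 45, 0.3, fs), 4, 7, 30, 45, fs)
  mi8 <- pacMI(plantPAC(x, 4, 7, 30, 45, 0.8, fs), 4, 7, 30, 45, fs)
  expect_lt(mi0, 0.02)            # depth 0: noise floor
  expect_gt(mi3, mi0)
  expect_gt(mi8, mi3)             # monotone in depth
})

test_that("full-depth modulation of a clean two-component signal matches the closed form", {
  fs <- 400
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 5.5 * t)
  carrier <- sin(2 * pi * 37 * t)
  xm <- x + carrier * (1 + 1 * cos(2 * pi * 5.5 * t)) * 0.5
  ## binned amplitude ~ 1 + cos(phi): closed-form MI over 18 bins, using
  ## exact bin-averaged values of the density
  edges <- seq(-pi, pi, length.out = 19)
  m <- 1 + (sin(edges[-1]) - sin(edges[-19])) / diff(edges)
  expected <- miFromDistribution(m)
  got <- pacMI(xm, 4, 7, 30, 45, fs)
  ## band-limited envelope extraction smooths the modulation troughs, so
  ## the estimate sits somewhat below the analytic value
  expect_equal(got, expected, tolerance = 0.25)
  expect_gt(got, 0.5 * expected)
})

test_that("pacMI rejects overlapping bands and short signals", {
  fs <- 400
  expect_error(pacMI(rnorm(fs * 4), 4, 10, 8, 20, fs), "above the phase band")
  expect_error(pacMI(rnorm(100), 4, 7, 30, 45, fs), "two cycles")
})
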