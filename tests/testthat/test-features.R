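test_that("resting features average per-epoch values and count 614", {
  fs <- 400
  set.seed(50)
  seg <- synthBackground(6, fs, 17)
  arr2 <- array(0, dim = c(2, 17, 6 * fs))
  arr2[1, , ] <- seg; arr2[2, , ] <- seg
  ep2 <- tmseegdx:::epochSet(arr2, fs, c(0, 6), frontalMontage())
  ep1 <- tmseegdx:::epochSet(array(seg, c(1, 17, 6 * fs)), fs, c(0, 6),
                             frontalMontage())
  f2 <- computeRstFeatures(ep2)
  expect_length(f2, 614)
  expect_identical(names(f2), modalityFeatureNames("RST"))
  ## two identical epochs equal the single-epoch features
  one <- tmseegdx:::.epochFeatures(seg, fs, frontalMontage(),
                                   wpli_dec = floor(fs / 100))
  expect_equal(unname(f2), one)
  expect_error(computeRstFeatures(ep1), "at least 2")
})

test_that("doubling an oscillation's amplitude quadruples its band power feature", {
  fs <- 400
  set.seed(51)
  base <- synthBackground(6, fs, 17, sd_pink = 1, sd_white = 0.2)
  osc <- 5 * tmseegdx:::bandNoise(6 * fs, fs, 14, 30)
  mk <- function(gain) {
    seg <- base
    seg[6, ] <- seg[6, ] + gain * osc   # AFz is channel 6
    arr <- array(0, dim = c(2, 17, 6 * fs))
    arr[1, , ] <- seg; arr[2, , ] <- seg
    computeRstFeatures(tmseegdx:::epochSet(arr, fs, c(0, 6),
                                           frontalMontage()))
  }
  f1 <- mk(1); f2 <- mk(2)
  expect_equal(f2[["RST_power_AFz_beta"]] / f1[["RST_power_AFz_beta"]], 4,
               tolerance = 0.1)
})

test_that("window features treat identical epochs like a single trial", {
  fs <- 400
  set.seed(52)
  seg <- synthBackground(0.5, fs, 17)
  arr <- array(0, dim = c(3, 17, 0.5 * fs))
  for (e in 1:3) arr[e, , ] <- seg
  ep3 <- tmseegdx:::epochSet(arr, fs, c(0.05, 0.55), frontalMontage())
  ep1 <- tmseegdx:::epochSet(array(seg, c(1, 17, 0.5 * fs)), fs,
                             c(0.05, 0.55), frontalMontage())
  f3 <- computeWindowFeatures(ep3, "PST")
  f1 <- computeWindowFeatures(ep1, "PST")
  expect_equal(f3, f1)
  expect_length(f3, 614)
  expect_true(all(startsWith(names(f3), "PST_")))
})

test_that("incoherent activity cancels from evoked-average power with n", {
  fs <- 400
  set.seed(53)
  nsamp <- 0.5 * fs
  mk <- function(nep) {
    arr <- array(rnorm(nep * 17 * nsamp, sd = 10), c(nep, 17, nsamp))
    ep <- tmseegdx:::epochSet(arr, fs, c(0.05, 0.55), frontalMontage())
    sum(computeWindowFeatures(ep, "PST")[1:68])
  }
  expect_lt(mk(40), mk(4) / 4)
})

test_that("DIF features subtract PST minus PRE by name", {
  pre <- c(PRE_power_AFz_beta = 1.5, `PRE_wPLI_AF3-F5_alpha` = 0.7)
  pst <- c(PST_power_AFz_beta = 2.0, `PST_wPLI_AF3-F5_alpha` = 0.4)
  dif <- computeDifFeatures(pre, pst)
  expect_equal(dif[["DIF_power_AFz_beta"]], 0.5)
  expect_equal(dif[["DIF_wPLI_AF3-F5_alpha"]], -0.3)
  ## PST = PRE -> all zero
  pst0 <- pre; names(pst0) <- sub("^PRE_", "PST_", names(pre))
  expect_true(all(computeDifFeatures(pre, pst0) == 0))
  expect_error(computeDifFeatures(pre, pst[1]), "must match")
})

test_that("feature extraction is deterministic and full tables are 2456 wide", {
  ft <- plantedTable()
  v <- featureValues(ft)
  expect_equal(dim(v), c(24, 2456))
  expect_false(anyNA(v))
  sets <- vapply(strsplit(colnames(v), "_"), `[`, "", 1)
  expect_equal(unname(table(sets)[featureSets()]), rep(614L, 4),
               ignore_attr = TRUE)
  ## wPLI features live in [0, 1] (DIF is a difference, so [-1, 1])
  wp <- v[, grepl("^(RST|PRE|PST)_wPLI_", colnames(v))]
  expect_true(all(wp >= 0 & wp <= 1))
  dif <- v[, grepl("^DIF_wPLI_", colnames(v))]
  expect_true(all(abs(dif) <= 1))
  ## the feature-vector layout maps each wPLI value to its named pair:
  ## the planted F4-F6 gamma coupling must appear at its own name, not at
  ## a neighbouring position
  g <- groupLabels(ft)
  gam <- colMeans(v[g == "MDD", grepl("^RST_wPLI_.*_gamma$", colnames(v))])
  expect_equal(names(which.max(gam)), "RST_wPLI_F4-F6_gamma")
  ## determinism: rebuilding one subject reproduces its row
  coh <- generateCohort(testSpec(nPerGroup = 12, seed = 402))
  ft2 <- buildFeatureTable(coh[1], testPreproc())
  expect_equal(featureValues(ft2)[1, ], v[1, ])
})

test_that("FeatureTable accessors and subsetting behave", {
  ft <- plantedTable()
  expect_s4_class(ft, "FeatureTable")
  expect_equal(levels(groupLabels(ft)), c("HC", "MDD"))
  expect_true(all(c("age", "MADRS", "MMSE") %in% colnames(clinicalData(ft))))
  sub <- subsetFeatureSets(ft, c("RST", "DIF"))
  expect_equal(nrow(sub), 2 * 614)
  expect_error(subsetFeatureSets(ft, "XXX"))
})
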