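## A small synthetic feature table with two informative columns, cheap to
## evaluate, used for most modeling tests.
syntheticTable <- function(n = 30, p = 10, d = 2, seed = 70) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n * p), 2 * n, p)
  X[, 1] <- X[, 1] + rep(c(d, 0), each = n)
  X[, 2] <- X[, 2] - rep(c(d, 0), each = n)
  colnames(X) <- paste0("RST_power_AFz_f", seq_len(p))
  rownames(X) <- sprintf("S%03d", seq_len(2 * n))
  featureTable(X, rep(c("MDD", "HC"), each = n))
}

test_that("the 15 feature-set combinations enumerate by size then lexically", {
  cmb <- enumerateCombinations()
  expect_length(cmb, 15)
  expect_equal(cmb[[1]], "DIF")
  expect_equal(cmb[[2]], "PRE")
  expect_equal(cmb[[15]], c("DIF", "PRE", "PST", "RST"))
  sizes <- vapply(cmb, length, 0L)
  expect_true(!is.unsorted(sizes))
})

test_that("stratified folds contain both classes and are seed-stable", {
  y <- factor(rep(c("MDD", "HC"), times = c(23, 17)))
  f <- makeStratifiedFolds(y, 5, seed = 3)
  expect_identical(f, makeStratifiedFolds(y, 5, seed = 3))
  for (k in 1:5) expect_equal(nlevels(droplevels(y[f == k])), 2)
  expect_error(makeStratifiedFolds(factor(rep("MDD", 3)), 5), "fewer members")
})

test_that("rank AUC matches pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(71)
  for (i in 1:5) {
    y <- factor(rep(c("HC", "MDD"), each = 20), levels = c("HC", "MDD"))
    s <- rnorm(40) + (as.integer(y) - 1) * runif(1, 0, 2)
    ours <- tmseegdx:::aucFromScores(s, y)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, levels = c("HC", "MDD"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(ours, ref)
  }
})

test_that("ROC vertical averaging matches a hand-computed oracle", {
  ## two step ROCs from small printed score sets
  y <- factor(c("MDD", "MDD", "HC", "HC"), levels = c("HC", "MDD"))
  c1 <- tmseegdx:::rocPoints(c(0.9, 0.6, 0.7, 0.1), y)   # one FP before last TP
  c2 <- tmseegdx:::rocPoints(c(0.9, 0.8, 0.2, 0.1), y)   # perfect
  avg <- averageRoc(list(c1, c2))
  expect_equal(avg$mean_auc, mean(c(c1$auc, c2$auc)))
  expect_equal(c2$auc, 1)
  expect_equal(c1$auc, 0.75)
  ## brute-force linear interpolation of both curves onto the grid, with
  ## the tpr(0) = 0 convention
  interp <- function(cv, x) {
    v <- approx(c(cv$fpr, 1), c(cv$tpr, 1), xout = x, ties = max, rule = 2)$y
    v[1] <- 0
    v
  }
  grid <- seq(0, 1, length.out = 101)
  expect_equal(avg$mean_tpr, (interp(c1, grid) + interp(c2, grid)) / 2)
  ## identical curves average to themselves; single fold is the identity
  same <- averageRoc(list(c1, c1, c1))
  expect_equal(same$mean_tpr, interp(c1, grid))
  expect_equal(same$sd_auc, 0)
  one <- averageRoc(list(c2))
  expect_equal(one$mean_auc, 1)
  expect_true(all(diff(avg$mean_tpr) >= -1e-12))
  expect_equal(avg$mean_tpr[1], 0)
  expect_equal(avg$mean_tpr[101], 1)
})

test_that("the registry carries all nine models with non-empty grids", {
  reg <- modelRegistry()
  expect_setequal(names(reg),
                  c("LR", "LDA", "SVM", "KNN", "NB", "DT", "RF", "ET", "LG"))
  for (m in reg) {
    expect_gte(length(m$grid), 1)
    expect_true(all(lengths(m$grid) >= 1))
    expect_true(is.function(m$fit) && is.function(m$score))
  }
  expect_error(modelRegistry("XX"), "unknown model")
})

test_that("every model fits and scores a separable problem above chance", {
  ft <- syntheticTable(n = 20, d = 2.5)
  X <- scale(featureValues(ft))
  y <- groupLabels(ft)
  for (m in modelRegistry()) {
    draws <- tmseegdx:::sampleGrid(m$grid, 3, seed = 5)
    fit <- m$fit(X, y, as.list(draws[1, , drop = FALSE]), seed = 9)
    auc <- tmseegdx:::aucFromScores(m$score(fit, X), y)
    expect_gt(auc, 0.8)
  }
})

test_that("a perfectly separating feature yields AUC 1 for the linear models", {
  set.seed(72)
  n <- 20
  X <- matrix(rnorm(2 * n * 5), 2 * n, 5)
  X[, 3] <- rep(c(4, 0), each = n) + rnorm(2 * n, sd = 0.1)
  colnames(X) <- paste0("RST_power_AFz_f", 1:5)
  rownames(X) <- sprintf("S%03d", seq_len(2 * n))
  ft <- featureTable(X, rep(c("MDD", "HC"), each = n))
  cv <- cvConfig(outer_k = 5, inner_k = 3, budget = 2, seed = 4)
  for (id in c("LDA", "LR", "SVM")) {
    r <- nestedCvEvaluate(ft, "RST", id, cv, alpha = 0.05)
    expect_equal(r@meanAuc, 1)
  }
})

test_that("nested CV is deterministic given the seed", {
  ft <- syntheticTable()
  cv <- cvConfig(outer_k = 5, inner_k = 3, budget = 3, seed = 17)
  for (id in c("LDA", "RF", "LG")) {
    a <- nestedCvEvaluate(ft, "RST", id, cv, alpha = 0.05)
    b <- nestedCvEvaluate(ft, "RST", id, cv, alpha = 0.05)
    expect_identical(a@foldAucs, b@foldAucs)
  }
})

test_that("permuted labels score near chance", {
  set.seed(73)
  X <- matrix(rnorm(60 * 30), 60, 30)
  colnames(X) <- paste0("RST_power_AFz_f", 1:30)
  rownames(X) <- sprintf("S%03d", 1:60)
  cv <- cvConfig(outer_k = 5, inner_k = 3, budget = 2, seed = 2)
  aucs <- vapply(1:4, function(s) {
    set.seed(100 + s)
    ft <- featureTable(X, sample(rep(c("MDD", "HC"), each = 30)))
    nestedCvEvaluate(ft, "RST", "LDA", cv, alpha = 0.05)@meanAuc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
})

test_that("the fallback engages when fewer than two features pass the screen", {
  set.seed(74)
  X <- matrix(rnorm(40 * 6), 40, 6)
  colnames(X) <- paste0("RST_power_AFz_f", 1:6)
  rownames(X) <- sprintf("S%03d", 1:40)
  ft <- featureTable(X, rep(c("MDD", "HC"), each = 20))
  cv <- cvConfig(outer_k = 5, inner_k = 3, budget = 2, seed = 6)
  r <- nestedCvEvaluate(ft, "RST", "LDA", cv, alpha = 1e-6)
  expect_length(r@fallbackFolds, 5)
  expect_true(all(r@selectedCounts == 2))
})

test_that("per-fold selection never sees the outer test fold", {
  ## leakage canary: a feature equal to the label on the subjects of one
  ## outer test fold and pure noise on that fold's training subjects. The
  ## per-fold screen for that fold sees only noise and must not select it;
  ## whole-sample screening sees the aligned block and ranks it far higher.
  set.seed(75)
  n <- 60
  y <- rep(c("MDD", "HC"), each = n / 2)
  yf <- factor(y, levels = c("HC", "MDD"))
  cv <- cvConfig(outer_k = 5, inner_k = 3, budget = 2, seed = 31)
  folds <- makeStratifiedFolds(yf, 5, seed = cv$seed)
  X <- matrix(rnorm(n * 12), n, 12)
  canary <- rnorm(n)
  canary[folds == 1] <- ifelse(y[folds == 1] == "MDD", 10, -10)
  X[, 6] <- canary
  colnames(X) <- paste0("RST_power_AFz_f", 1:12)
  rownames(X) <- sprintf("S%03d", 1:n)
  ft <- featureTable(X, y)
  sel1 <- selectFeatures(ft, alpha = 0.01, subjects = which(folds != 1))
  expect_false(sel1$selected[6])
  expect_gt(sel1$p[6], 0.05)
  selG <- selectFeatures(ft, alpha = 0.01, placement = "global")
  expect_lt(selG$p[6], 0.05)
  expect_lt(selG$p[6], sel1$p[6])
  expect_equal(attr(selG, "placement"), "global")
})

test_that("rankModels assembles the AUC grid and finds the best cell", {
  ft <- syntheticTable(n = 15)
  cv <- cvConfig(outer_k = 3, inner_k = 3, budget = 2, seed = 8)
  res <- list(nestedCvEvaluate(ft, "RST", "LDA", cv, alpha = 0.05),
              nestedCvEvaluate(ft, "RST", "DT", cv, alpha = 0.05))
  grid <- rankModels(res)
  expect_equal(dim(grid), c(1, 2))
  expect_true(attr(grid, "argmax")["model"] %in% c("LDA", "DT"))
  expect_error(rankModels(list()), "no evaluation")
})
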