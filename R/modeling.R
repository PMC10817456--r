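## Nested (double) cross-validation: a stratified 5-fold outer loop
## estimates generalization; within each outer training fold, features are
## screened (Mann-Whitney, p < alpha), standardized, and hyperparameters
## are tuned by random grid search scored with stratified 10-fold inner
## cross-validation. Outer test folds contribute one ROC curve each; curves
## are vertically averaged on a common 101-point FPR grid and the mean AUC
## is the arithmetic mean of fold AUCs.

#' Cross-validation configuration
#'
#' @param outer_k outer folds (default 5, stratified by group).
#' @param inner_k inner tuning folds (default 10).
#' @param budget random grid-search draws per outer fold (default 25).
#' @param seed integer seed driving fold assignment, grid draws and
#'   stochastic learners.
#' @return list of class `CVConfig`.
#' @export
cvConfig <- function(outer_k = 5, inner_k = 10, budget = 25, seed = 1) {
  stopifnot(outer_k >= 2, inner_k >= 2, budget >= 1)
  structure(list(outer_k = as.integer(outer_k), inner_k = as.integer(inner_k),
                 budget = as.integer(budget), seed = as.integer(seed)),
            class = "CVConfig")
}

#' All non-empty feature-set combinations
#'
#' The 15 non-empty subsets of \{RST, PRE, PST, DIF\}, ordered by subset
#' size and lexically within size (so the first is `DIF` alone and the last
#' is all four sets).
#'
#' @return list of character vectors.
#' @export
enumerateCombinations <- function() {
  sets <- sort(featureSets())
  out <- list()
  for (k in seq_along(sets)) {
    cmb <- utils::combn(sets, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Stratified fold assignment
#'
#' Assigns each subject to one of `k` folds, separately shuffling within
#' each class so every fold contains both groups.
#'
#' @param y factor of group labels.
#' @param k number of folds.
#' @param seed seed for the shuffle.
#' @return integer vector of fold ids (1..k).
#' @export
makeStratifiedFolds <- function(y, k, seed = 1) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(factor(y))) {
    idx <- which(y == cl)
    if (length(idx) < k) stop("class '", cl, "' has fewer members than folds")
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

## Rank-based AUC of MDD-oriented scores (equals U / (n1*n0); midrank ties).
aucFromScores <- function(scores, y) {
  pos <- y == "MDD"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## ROC step-curve points from scores (descending thresholds, ties grouped).
rocPoints <- function(scores, y) {
  pos <- y == "MDD"
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  list(fpr = c(0, fp[last] / sum(!pos)),
       tpr = c(0, tp[last] / sum(pos)),
       auc = aucFromScores(scores, y))
}

#' Vertically average ROC curves onto a common FPR grid
#'
#' Each fold's ROC curve is linearly interpolated onto a 101-point FPR grid
#' (taking the upper envelope at duplicated FPR values) and the TPR values
#' are averaged. The reported mean AUC is the arithmetic mean of the fold
#' AUCs (not the area under the averaged curve); its spread is the sample
#' standard deviation across folds.
#'
#' @param fold_curves list of `list(fpr, tpr, auc)` per fold.
#' @return list of class `ROCCurve` with `fpr_grid`, `mean_tpr`,
#'   `per_fold_tpr`, `fold_aucs`, `mean_auc`, `sd_auc`.
#' @export
averageRoc <- function(fold_curves) {
  stopifnot(length(fold_curves) >= 1)
  grid <- seq(0, 1, length.out = 101)
  tprs <- vapply(fold_curves, function(cv) {
    stats::approx(c(cv$fpr, 1), c(cv$tpr, 1), xout = grid,
                  ties = max, rule = 2)$y
  }, numeric(101))
  aucs <- vapply(fold_curves, `[[`, numeric(1), "auc")
  tprs[1, ] <- 0   # convention: tpr(0) = 0
  structure(list(fpr_grid = grid, mean_tpr = rowMeans(tprs),
                 per_fold_tpr = tprs, fold_aucs = aucs,
                 mean_auc = mean(aucs),
                 sd_auc = if (length(aucs) > 1) stats::sd(aucs) else 0),
            class = "ROCCurve")
}

## ---------------------------------------------------------------------------
## Model registry: nine classifiers, each exposing a hyperparameter grid and
## seeded fit/score closures. Scores are continuous and oriented so that
## larger means more MDD-like.

.asDf <- function(X) {
  df <- as.data.frame(X)
  colnames(df) <- paste0("V", seq_len(ncol(X)))
  df
}

#' The nine-classifier registry
#'
#' Logistic regression (LR, ridge-penalized), linear discriminant analysis
#' (LDA), RBF support vector machine (SVM), k-nearest neighbours (KNN),
#' Gaussian naive Bayes (NB), decision tree (DT), random forest (RF),
#' extremely randomized trees (ET) and gradient-boosted trees (LG). Each
#' entry carries a hyperparameter grid for the random search and seeded
#' `fit(X, y, params, seed)` / `score(model, X)` closures returning
#' MDD-oriented continuous scores.
#'
#' @param ids subset of the nine model ids to return.
#' @return named list of model specifications.
#' @export
modelRegistry <- function(ids = c("LR", "LDA", "SVM", "KNN", "NB",
                                  "DT", "RF", "ET", "LG")) {
  reg <- list(
    LR = list(
      grid = list(lambda = 10^seq(-4, 1, length.out = 8)),
      fit = function(X, y, params, seed) {
        glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                       lambda = params$lambda, standardize = FALSE)
      },
      score = function(m, X) as.numeric(predict(m, X, type = "response"))),
    LDA = list(
      ## linear discriminant with tunable covariance shrinkage toward a
      ## scaled identity; gamma = 0 is classical LDA (which is singular
      ## when DIF columns are exact PST - PRE combinations, hence the
      ## small floor)
      grid = list(gamma = c(0.01, 0.05, 0.15, 0.3, 0.6, 0.9)),
      fit = function(X, y, params, seed) {
        mu1 <- colMeans(X[y == "MDD", , drop = FALSE])
        mu0 <- colMeans(X[y == "HC", , drop = FALSE])
        Xc <- X
        Xc[y == "MDD", ] <- sweep(X[y == "MDD", , drop = FALSE], 2, mu1)
        Xc[y == "HC", ] <- sweep(X[y == "HC", , drop = FALSE], 2, mu0)
        S <- crossprod(Xc) / max(1, nrow(X) - 2)
        p <- ncol(X)
        Sg <- (1 - params$gamma) * S +
          diag(params$gamma * mean(diag(S)) + 1e-10, p)
        w <- solve(Sg, mu1 - mu0)
        list(w = w, mid = (mu1 + mu0) / 2)
      },
      score = function(m, X) {
        as.numeric(sweep(X, 2, m$mid) %*% m$w)
      }),
    SVM = list(
      grid = list(cost = 2^seq(-3, 7, by = 2),
                  gamma_scale = 2^seq(-6, 2, by = 2)),
      fit = function(X, y, params, seed) {
        set.seed(seed)
        e1071::svm(X, y, kernel = "radial", cost = params$cost,
                   gamma = params$gamma_scale / ncol(X), scale = FALSE)
      },
      score = function(m, X) {
        pr <- predict(m, X, decision.values = TRUE)
        dv <- attr(pr, "decision.values")
        firstClass <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1]
        if (firstClass == "MDD") as.numeric(dv) else -as.numeric(dv)
      }),
    KNN = list(
      grid = list(k = 3:15),
      fit = function(X, y, params, seed) {
        list(X = X, y = y, k = params$k, seed = seed)
      },
      score = function(m, X) {
        set.seed(m$seed)
        pr <- class::knn(m$X, X, m$y, k = min(m$k, nrow(m$X)), prob = TRUE)
        p <- attr(pr, "prob")
        ifelse(pr == "MDD", p, 1 - p)
      }),
    NB = list(
      grid = list(laplace = 0),
      fit = function(X, y, params, seed) {
        e1071::naiveBayes(X, y, laplace = params$laplace)
      },
      score = function(m, X) {
        predict(m, X, type = "raw")[, "MDD"]
      }),
    DT = list(
      grid = list(cp = c(0.001, 0.01, 0.05), maxdepth = c(2, 4, 8),
                  minbucket = c(3, 5, 10)),
      fit = function(X, y, params, seed) {
        df <- .asDf(X); df$.y <- y
        set.seed(seed)
        rpart::rpart(.y ~ ., data = df, method = "class",
                     control = rpart::rpart.control(
                       cp = params$cp, maxdepth = params$maxdepth,
                       minbucket = params$minbucket, xval = 0))
      },
      score = function(m, X) {
        predict(m, .asDf(X), type = "prob")[, "MDD"]
      }),
    RF = list(
      grid = list(ntree = c(100, 300), mtry_frac = c(0.5, 1, 2),
                  nodesize = c(1, 3, 5)),
      fit = function(X, y, params, seed) {
        set.seed(seed)
        mtry <- max(1, min(ncol(X), round(params$mtry_frac * sqrt(ncol(X)))))
        randomForest::randomForest(x = X, y = y, ntree = params$ntree,
                                   mtry = mtry, nodesize = params$nodesize)
      },
      score = function(m, X) {
        predict(m, X, type = "prob")[, "MDD"]
      }),
    ET = list(
      grid = list(num.trees = c(100, 300), mtry_frac = c(0.5, 1, 2),
                  min.node.size = c(1, 3, 5)),
      fit = function(X, y, params, seed) {
        mtry <- max(1, min(ncol(X), round(params$mtry_frac * sqrt(ncol(X)))))
        ranger::ranger(x = .asDf(X), y = y, probability = TRUE,
                       num.trees = params$num.trees, mtry = mtry,
                       min.node.size = params$min.node.size,
                       splitrule = "extratrees", num.random.splits = 1,
                       seed = seed, num.threads = 1)
      },
      score = function(m, X) {
        predict(m, data = .asDf(X), num.threads = 1)$predictions[, "MDD"]
      }),
    LG = list(
      grid = list(eta = c(0.05, 0.1, 0.3), max_depth = c(2, 3, 5),
                  nrounds = c(30, 60, 100), min_child_weight = c(1, 3)),
      fit = function(X, y, params, seed) {
        set.seed(seed)
        dtr <- xgboost::xgb.DMatrix(X, label = as.numeric(y == "MDD"))
        xgboost::xgb.train(
          params = list(objective = "binary:logistic", eta = params$eta,
                        max_depth = params$max_depth,
                        min_child_weight = params$min_child_weight,
                        subsample = 0.9, nthread = 1),
          data = dtr, nrounds = params$nrounds, verbose = 0)
      },
      score = function(m, X) {
        predict(m, xgboost::xgb.DMatrix(X))
      })
  )
  unknown <- setdiff(ids, names(reg))
  if (length(unknown)) stop("unknown model id(s): ", paste(unknown, collapse = ", "))
  for (id in names(reg)) reg[[id]]$id <- id
  reg[ids]
}

## Random grid-search draws: the full Cartesian grid when it is within
## budget, otherwise `budget` distinct rows sampled uniformly.
sampleGrid <- function(grid, budget, seed) {
  full <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(full) <= budget) return(full)
  set.seed(seed)
  full[sample.int(nrow(full), budget), , drop = FALSE]
}

## Mean inner-CV AUC of one hyperparameter draw.
.innerCvAuc <- function(X, y, model, params, k, seed) {
  folds <- makeStratifiedFolds(y, k, seed)
  aucs <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    m <- tryCatch(model$fit(X[tr, , drop = FALSE], y[tr], params,
                            seed = seed + f),
                  error = function(e) NULL)
    if (is.null(m)) return(NA_real_)
    sc <- tryCatch(model$score(m, X[!tr, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(sc)) return(NA_real_)
    aucFromScores(sc, y[!tr])
  }, numeric(1))
  if (all(is.na(aucs))) -Inf else mean(aucs, na.rm = TRUE)
}

#' Evaluation result of one (combination, model) cell
#'
#' @slot combination feature sets used.
#' @slot modelId one of the nine registry ids.
#' @slot foldAucs outer-fold test AUCs.
#' @slot meanAuc,sdAuc mean and sample SD of the fold AUCs.
#' @slot fprGrid,meanTpr,perFoldTpr vertically averaged ROC curve.
#' @slot selectedCounts features surviving screening per outer fold.
#' @slot placement selection placement used.
#' @slot fallbackFolds folds where fewer than 2 features passed screening
#'   and the top-2 smallest-p fallback was used.
#' @slot seed the driving seed.
#' @export
setClass("EvaluationResult",
  slots = c(combination = "character", modelId = "character",
            foldAucs = "numeric", meanAuc = "numeric", sdAuc = "numeric",
            fprGrid = "numeric", meanTpr = "numeric", perFoldTpr = "matrix",
            selectedCounts = "integer", placement = "character",
            fallbackFolds = "integer", seed = "integer"))

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf("EvaluationResult %s | %s: mean AUC %.3f +- %.3f (folds: %s)\n",
              paste(object@combination, collapse = "+"), object@modelId,
              object@meanAuc, object@sdAuc,
              paste(sprintf("%.3f", object@foldAucs), collapse = ", ")))
})

#' Nested double cross-validation of one model on one feature-set combination
#'
#' For each of the `outer_k` stratified outer folds: restrict to the
#' combination's columns, screen features on the outer-training subjects
#' (Mann-Whitney, `p < alpha`; with fewer than 2 survivors the top-2
#' smallest-p features are used), z-score using training means/SDs, tune
#' hyperparameters by random grid search scored with stratified `inner_k`
#' fold CV on the training subjects only, refit on the full training fold
#' and score the held-out test fold. Fully deterministic given the seed in
#' `cv`.
#'
#' @param table a [FeatureTable-class].
#' @param combo subset of `c("RST","PRE","PST","DIF")`.
#' @param model a single entry of [modelRegistry()] or a model id string.
#' @param cv a [cvConfig()] list.
#' @param alpha screening level (default 0.01).
#' @param placement `"per_fold"` (leakage-safe, default) or `"global"`
#'   (whole-sample screening).
#' @param keep_models also return the per-fold fitted models and fold
#'   indices (used for permutation importance).
#' @return an [EvaluationResult-class]; with `keep_models = TRUE`, a list
#'   `(result, fits)`.
#' @export
nestedCvEvaluate <- function(table, combo, model, cv = cvConfig(),
                             alpha = 0.01,
                             placement = c("per_fold", "global"),
                             keep_models = FALSE) {
  placement <- match.arg(placement)
  if (is.character(model)) {
    modelId <- model
    model <- modelRegistry(modelId)[[1]]
  } else {
    modelId <- if (!is.null(model$id)) model$id else "custom"
  }
  stopifnot(all(combo %in% featureSets()))
  ft <- subsetFeatureSets(table, combo)
  X <- featureValues(ft)
  y <- groupLabels(ft)
  folds <- makeStratifiedFolds(y, cv$outer_k, cv$seed)
  globalSel <- if (placement == "global") {
    selectFeatures(ft, alpha, placement = "global")
  } else NULL

  curves <- vector("list", cv$outer_k)
  selCounts <- integer(cv$outer_k)
  fallback <- integer(0)
  fits <- vector("list", cv$outer_k)
  for (f in seq_len(cv$outer_k)) {
    tr <- folds != f
    if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2) {
      stop("stratification failed: a fold contains a single class")
    }
    sel <- if (placement == "per_fold") {
      selectFeatures(ft, alpha, placement = "per_fold",
                     subjects = which(tr))
    } else globalSel
    selIdx <- which(sel$selected)
    if (length(selIdx) < 2) {
      selIdx <- order(sel$p)[1:2]
      fallback <- c(fallback, f)
    }
    selCounts[f] <- length(selIdx)
    Xtr <- X[tr, selIdx, drop = FALSE]
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Ztr <- scale(Xtr, center = mu, scale = sdv)
    Zte <- scale(X[!tr, selIdx, drop = FALSE], center = mu, scale = sdv)

    draws <- sampleGrid(model$grid, cv$budget, seed = cv$seed + 7919L * f)
    innerSeed <- cv$seed + 104729L * f
    tuneAuc <- vapply(seq_len(nrow(draws)), function(d) {
      .innerCvAuc(Ztr, y[tr], model, as.list(draws[d, , drop = FALSE]),
                  cv$inner_k, innerSeed)
    }, numeric(1))
    best <- as.list(draws[which.max(tuneAuc), , drop = FALSE])
    m <- model$fit(Ztr, y[tr], best, seed = innerSeed)
    sc <- model$score(m, Zte)
    curves[[f]] <- rocPoints(sc, y[!tr])
    fits[[f]] <- list(model = m, test = which(!tr), features = selIdx,
                      center = mu, scale = sdv, params = best)
  }
  roc <- averageRoc(curves)
  res <- new("EvaluationResult",
             combination = sort(combo), modelId = modelId,
             foldAucs = roc$fold_aucs, meanAuc = roc$mean_auc,
             sdAuc = roc$sd_auc, fprGrid = roc$fpr_grid,
             meanTpr = roc$mean_tpr, perFoldTpr = roc$per_fold_tpr,
             selectedCounts = selCounts, placement = placement,
             fallbackFolds = as.integer(fallback), seed = cv$seed)
  if (keep_models) list(result = res, fits = fits, model = model,
                        X = X, y = y) else res
}

#' Mean-AUC grid over all combinations and models
#'
#' @param results list of [EvaluationResult-class] objects covering the
#'   full 15 x 9 grid (or any subgrid).
#' @return matrix combinations x models of mean AUC with an `sd` attribute
#'   and an `argmax` attribute naming the best cell.
#' @export
rankModels <- function(results) {
  if (length(results) == 0) stop("no evaluation results supplied")
  comboLab <- vapply(results, function(r) paste(r@combination, collapse = "+"), "")
  modelLab <- vapply(results, function(r) r@modelId, "")
  combos <- unique(comboLab); models <- unique(modelLab)
  mAuc <- matrix(NA_real_, length(combos), length(models),
                 dimnames = list(combos, models))
  mSd <- mAuc
  for (i in seq_along(results)) {
    mAuc[comboLab[i], modelLab[i]] <- results[[i]]@meanAuc
    mSd[comboLab[i], modelLab[i]] <- results[[i]]@sdAuc
  }
  best <- which(mAuc == max(mAuc, na.rm = TRUE), arr.ind = TRUE)[1, ]
  attr(mAuc, "sd") <- mSd
  attr(mAuc, "argmax") <- c(combination = combos[best[1]],
                            model = models[best[2]])
  mAuc
}
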