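## Permutation feature importance on held-out outer folds, cross-model
## top-k intersection, and the post hoc statistics (age-adjusted ANCOVA and
## Spearman correlations against clinical scores).

#' Permutation importance of one fitted model on one test fold
#'
#' `importance(f) = baseline AUC - mean AUC over repeats with column f
#' permuted` within the test fold. A constant column gets importance 0 with
#' a warning.
#'
#' @param model fitted model object.
#' @param score scoring closure `score(model, X)` returning MDD-oriented
#'   scores.
#' @param X_test,y_test held-out fold (standardized like the training data).
#' @param n_repeats permutations per feature (default 10).
#' @param seed seed for the permutations.
#' @return named numeric vector of importances (one per column of
#'   `X_test`).
#' @export
permutationImportance <- function(model, score, X_test, y_test,
                                  n_repeats = 10, seed = 1) {
  base <- aucFromScores(score(model, X_test), y_test)
  set.seed(seed)
  n <- nrow(X_test)
  vapply(seq_len(ncol(X_test)), function(j) {
    if (stats::sd(X_test[, j]) == 0) {
      warning("constant column ", j, "; importance set to 0")
      return(0)
    }
    drop <- vapply(seq_len(n_repeats), function(r) {
      Xp <- X_test
      Xp[, j] <- Xp[sample.int(n), j]
      base - aucFromScores(score(model, Xp), y_test)
    }, numeric(1))
    mean(drop)
  }, numeric(1), USE.NAMES = FALSE) -> imp
  names(imp) <- colnames(X_test)
  imp
}

#' Cross-model permutation-importance report
#'
#' Runs nested CV for each requested model on the given feature-set
#' combination, computes permutation importance on every outer test fold
#' (features not screened into a fold contribute 0 for that fold), averages
#' over folds, and intersects the per-model top-`top_k` lists.
#'
#' @param table a [FeatureTable-class].
#' @param combo feature sets to use (default all four).
#' @param model_ids models to include (default the top three linear-ish
#'   models LDA, LR, SVM).
#' @param cv a [cvConfig()] list.
#' @param alpha screening level.
#' @param n_repeats permutation repeats per feature per fold.
#' @param top_k size of the per-model top list (default 20).
#' @return list with `importance` (named list of per-feature mean
#'   importance vectors, sorted descending), `top` (per-model top-k feature
#'   names), `intersection` (features common to every top-k list), and
#'   `evaluations` (per-model [EvaluationResult-class]).
#' @export
importanceReport <- function(table, combo = featureSets(),
                             model_ids = c("LDA", "LR", "SVM"),
                             cv = cvConfig(), alpha = 0.01,
                             n_repeats = 10, top_k = 20) {
  reg <- modelRegistry(model_ids)
  imps <- list(); evals <- list()
  allFeat <- colnames(featureValues(subsetFeatureSets(table, combo)))
  for (id in model_ids) {
    run <- nestedCvEvaluate(table, combo, reg[[id]], cv, alpha,
                            keep_models = TRUE)
    y <- run$y; X <- run$X
    acc <- stats::setNames(numeric(length(allFeat)), allFeat)
    for (f in seq_along(run$fits)) {
      ft <- run$fits[[f]]
      Zte <- scale(X[ft$test, ft$features, drop = FALSE],
                   center = ft$center, scale = ft$scale)
      imp <- permutationImportance(ft$model, run$model$score, Zte,
                                   y[ft$test], n_repeats = n_repeats,
                                   seed = cv$seed + 7L * f)
      acc[allFeat[ft$features]] <- acc[allFeat[ft$features]] + imp
    }
    imps[[id]] <- sort(acc / length(run$fits), decreasing = TRUE)
    evals[[id]] <- run$result
  }
  top <- lapply(imps, function(v) names(v)[seq_len(min(top_k, length(v)))])
  list(importance = imps, top = top,
       intersection = Reduce(intersect, top),
       evaluations = evals)
}

#' Age-adjusted group ANCOVA for one feature
#'
#' Linear model `value ~ age + group`; the reported F is the group effect
#' after the age covariate, on `(1, n - 3)` degrees of freedom.
#'
#' @param values numeric feature values.
#' @param group factor/character of `"MDD"`/`"HC"` labels.
#' @param age numeric covariate.
#' @return named vector `c(F, df1, df2, p)`.
#' @export
ancovaGroup <- function(values, group, age) {
  n <- length(values)
  stopifnot(n >= 4, length(group) == n, length(age) == n)
  group <- factor(group)
  if (nlevels(group) < 2) stop("both groups must be present")
  fit <- stats::lm(values ~ age + group)
  av <- stats::anova(fit)
  c(F = av["group", "F value"], df1 = av["group", "Df"],
    df2 = av["Residuals", "Df"], p = av["group", "Pr(>F)"])
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks; p-value from the t approximation.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return named vector `c(rho, p)`.
#' @export
spearmanCorr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  c(rho = unname(ct$estimate), p = ct$p.value)
}

#' Post hoc group statistics for a set of features
#'
#' For each feature: age-adjusted ANCOVA of the group effect, and per-group
#' Spearman correlations against MADRS, STAI (state/trait) and MMSE.
#'
#' @param table a [FeatureTable-class] with clinical covariates.
#' @param features feature names to analyse.
#' @return list with `ancova` (data.frame feature x F/df/p) and
#'   `correlations` (data.frame feature x group x score x rho/p).
#' @export
groupStatsReport <- function(table, features) {
  X <- featureValues(table)
  stopifnot(all(features %in% colnames(X)))
  y <- groupLabels(table)
  cd <- clinicalData(table)
  anc <- t(vapply(features, function(f) {
    ancovaGroup(X[, f], y, cd$age)
  }, numeric(4)))
  anc <- data.frame(feature = features, anc, row.names = NULL)
  scores <- intersect(c("MADRS", "STAI_state", "STAI_trait", "MMSE"),
                      colnames(cd))
  rows <- list()
  for (g in levels(y)) {
    idx <- y == g
    for (sc in scores) {
      for (f in features) {
        r <- spearmanCorr(X[idx, f], cd[idx, sc])
        rows[[length(rows) + 1]] <- data.frame(
          feature = f, group = g, score = sc,
          rho = r["rho"], p = r["p"], row.names = NULL)
      }
    }
  }
  list(ancova = anc, correlations = do.call(rbind, rows))
}
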