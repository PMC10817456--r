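## Mann-Whitney U feature screening at p < 0.01. No multiple-testing
## correction is applied: this is dimensionality reduction by screening,
## not inference, and every feature crossing the threshold enters the
## models. Default placement is per_fold (leakage-safe: the screen sees
## only the outer-training subjects); `global` reproduces whole-sample
## screening and is provided for comparison.

#' Mann-Whitney U test (two-sided)
#'
#' `U` counts the pairs with `x_i > y_j` (ties counting one half). The
#' p-value is exact (full enumeration) when `length(x) + length(y) <= 16`
#' and the data are tie-free, otherwise the normal approximation with tie
#' and continuity correction is used.
#'
#' @param x,y numeric samples (non-empty).
#' @return named vector `c(U, p)`.
#' @export
mannWhitneyU <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 16) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  c(U = unname(ht$statistic), p = ht$p.value)
}

## Cache of exact U-statistic CDFs, keyed by the group sizes.
.wilcoxCdfCache <- new.env(parent = emptyenv())

.wilcoxCdf <- function(n1, n2) {
  key <- paste(n1, n2, sep = "x")
  hit <- .wilcoxCdfCache[[key]]
  if (is.null(hit)) {
    u <- 0:(n1 * n2)
    ## both tails kept explicitly: 1 - lower CDF loses precision deep in
    ## the tail
    hit <- list(lo = stats::pwilcox(u, n1, n2),
                hi = stats::pwilcox(u, n1, n2, lower.tail = FALSE))
    .wilcoxCdfCache[[key]] <- hit
  }
  hit
}

## Vectorized U test over the columns of a matrix (the screening fast
## path). Tie-free columns use the exact null distribution of U; columns
## with ties fall back to the normal approximation with tie and continuity
## correction. Agreement with wilcox.test is asserted in the tests.
.uTestMatrix <- function(X, isA) {
  n1 <- sum(isA); n2 <- sum(!isA); n <- n1 + n2
  mu <- n1 * n2 / 2
  cdf <- .wilcoxCdf(n1, n2)
  U <- numeric(ncol(X)); p <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    r <- rank(X[, j])
    Uj <- sum(r[isA]) - n1 * (n1 + 1) / 2
    U[j] <- Uj
    if (anyDuplicated(X[, j])) {
      tab <- table(X[, j])
      tiecor <- sum(tab^3 - tab)
      s2 <- n1 * n2 / 12 * ((n + 1) - tiecor / (n * (n - 1)))
      z <- if (s2 > 0) (abs(Uj - mu) - 0.5) / sqrt(s2) else 0
      p[j] <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    } else {
      ## P(U >= u) = hi[u] (hi[i] = P(U > i - 1)); P(U <= u) = lo[u + 1]
      pj <- if (Uj > mu) cdf$hi[Uj] else cdf$lo[Uj + 1]
      p[j] <- min(1, 2 * pj)
    }
  }
  list(U = U, p = p)
}

#' Screen features by group difference
#'
#' Two-sided Mann-Whitney U test of MDD vs HC for every feature; features
#' with `p < alpha` are selected. With `placement = "per_fold"` the screen
#' is meant to be invoked on outer-training subjects only (as the nested-CV
#' engine does); `placement = "global"` screens the whole sample, which
#' leaks label information into the held-out folds and is provided to
#' reproduce whole-sample screening for comparison.
#'
#' @param table a [FeatureTable-class].
#' @param alpha selection level (default 0.01).
#' @param placement `"per_fold"` or `"global"` (recorded in the result).
#' @param subjects optional row indices restricting the screen (used for
#'   per-fold invocation).
#' @return data.frame (`feature`, `U`, `p`, `selected`) with attributes
#'   `alpha` and `placement`.
#' @export
selectFeatures <- function(table, alpha = 0.01,
                           placement = c("per_fold", "global"),
                           subjects = NULL) {
  placement <- match.arg(placement)
  X <- featureValues(table)
  y <- groupLabels(table)
  if (!is.null(subjects)) {
    X <- X[subjects, , drop = FALSE]
    y <- y[subjects]
  }
  if (min(table(y)) < 2) stop("at least 2 subjects per group required")
  res <- .uTestMatrix(X, y == "MDD")
  out <- data.frame(feature = colnames(X), U = res$U, p = res$p,
                    selected = res$p < alpha, stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "placement") <- placement
  out
}

#' Write a selection result as TSV
#' @param sel result of [selectFeatures()].
#' @param path output file.
#' @export
writeSelectionResult <- function(sel, path) {
  utils::write.table(sel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
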