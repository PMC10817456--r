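## Feature extraction: per modality, 68 band powers (17 channels x 4 bands),
## 544 wPLI values (136 channel pairs x 4 bands) and 2 region-averaged PAC
## modulation indices = 614 features, named `<SET>_<KIND>_<LOC>_<BAND>`.

## Analytic signal of every row of a real matrix (one FFT batch via mvfft).
.analyticRows <- function(M) {
  n <- ncol(M)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  X <- stats::mvfft(t(M)) * h
  t(stats::mvfft(X, inverse = TRUE) / n)
}

## Modulation index from precomputed phase and amplitude vectors.
.miFromPhaseAmp <- function(ph, am, n_bins = 18) {
  edges <- seq(-pi, pi, length.out = n_bins + 1L)
  idx <- findInterval(ph, edges, rightmost.closed = TRUE, left.open = TRUE)
  idx[idx < 1L] <- 1L
  m <- vapply(seq_len(n_bins), function(j) {
    v <- am[idx == j]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  m <- m[!is.na(m)]
  if (length(m) < 2 || sum(m) == 0) return(0)
  miFromDistribution(m)
}

## One-sided Welch PSD of every row of a matrix (batched FFTs).
.welchPsdRows <- function(M, fs, seg_s = 0.5, overlap = 0.5) {
  n <- ncol(M); nch <- nrow(M)
  nper <- round(seg_s * fs)
  if (nper > n) nper <- n
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, n - nper + 1L, by = step)
  nseg <- length(starts)
  idx <- outer(seq_len(nper) - 1L, starts, "+")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))
  big <- matrix(0, nper, nseg * nch)
  for (ch in seq_len(nch)) {
    S <- matrix(M[ch, idx], nper, nseg)
    S <- sweep(S, 2, colMeans(S)) * w
    big[, ((ch - 1) * nseg + 1):(ch * nseg)] <- S
  }
  P <- Mod(stats::mvfft(big))^2 / (fs * sum(w^2))
  nf <- floor(nper / 2) + 1L
  P <- P[seq_len(nf), , drop = FALSE]
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nper %% 2 == 0) dbl[nf] <- 1
  P <- P * dbl
  psd <- matrix(0, nch, nf)
  for (ch in seq_len(nch)) {
    psd[ch, ] <- rowMeans(P[, ((ch - 1) * nseg + 1):(ch * nseg),
                            drop = FALSE])
  }
  list(freq = (seq_len(nf) - 1L) * fs / nper, psd = psd)
}

## Band-filtered analytic signals of every channel, one complex matrix per
## band.
.bandAnalytic <- function(seg, fs) {
  bands <- eegBands()
  lapply(seq_len(nrow(bands)), function(b) {
    .fftFilterRows(seg, fs,
                   list(list(lo = bands$lo[b], hi = bands$hi[b],
                             order = 4, type = "pass")),
                   pad_s = 0.25, analytic = TRUE)
  })
}

## Band powers (channels x bands) from one Welch PSD per channel.
.powerFeatures <- function(seg, fs) {
  bands <- eegBands()
  ps <- .welchPsdRows(seg, fs)
  df <- ps$freq[2] - ps$freq[1]
  pw <- matrix(0, nrow(seg), nrow(bands))
  for (b in seq_len(nrow(bands))) {
    sel <- ps$freq >= bands$lo[b] & ps$freq <= bands$hi[b]
    pw[, b] <- rowSums(ps$psd[, sel, drop = FALSE]) * df
  }
  pw
}

## Accumulate the signed sum and absolute sum of the imaginary analytic
## cross-term for every channel pair and band (wPLI numerator/denominator
## contributions of one epoch). `keep` decimates the sample grid.
.wpliAccumulate <- function(An, keep, num, den) {
  nch <- nrow(An[[1]])
  npair <- nch * (nch - 1) / 2
  for (b in seq_along(An)) {
    Ab <- An[[b]][, keep, drop = FALSE]
    Ar <- Re(Ab); Ai <- Im(Ab)
    nt <- ncol(Ab)
    ## numerator for every pair at once: sum_t Im(a_i conj a_j) is the
    ## (i, j) entry of I R^T - R I^T
    Nm <- Ai %*% t(Ar) - Ar %*% t(Ai)
    tN <- t(Nm)
    num[, b] <- num[, b] + tN[lower.tri(tN)]  # row-major upper triangle
    if (nt <= 150) {
      ## short windows: per-sample outer products beat the pair loop
      D <- matrix(0, nch, nch)
      for (tt in seq_len(nt)) {
        M <- tcrossprod(Ai[, tt], Ar[, tt])
        D <- D + abs(M - t(M))
      }
      tD <- t(D)
      den[, b] <- den[, b] + tD[lower.tri(tD)]
    } else {
      k <- 0L
      for (i in seq_len(nch - 1)) {
        ri <- Ar[i, ]; ii <- Ai[i, ]
        for (j in (i + 1):nch) {
          k <- k + 1L
          den[k, b] <- den[k, b] + sum(abs(ii * Ar[j, ] - ri * Ai[j, ]))
        }
      }
    }
  }
  list(num = num, den = den)
}

## PAC MI per coupling, averaged over the left-DLPFC region.
.miFeatures <- function(An, channels) {
  bands <- eegBands()
  region <- match(dlpfcRegion(), channels)
  region <- region[!is.na(region)]
  cps <- pacCouplings()
  mi <- numeric(nrow(cps))
  for (ci in seq_len(nrow(cps))) {
    pb <- match(cps$phase[ci], bands$name)
    ab <- match(cps$amp[ci], bands$name)
    if (length(region) == 0) { mi[ci] <- NA_real_; next }
    mi[ci] <- mean(vapply(region, function(ch) {
      .miFromPhaseAmp(Arg(An[[pb]][ch, ]), Mod(An[[ab]][ch, ]))
    }, numeric(1)))
  }
  mi
}

## All 614 features of one epoch (channels x samples matrix). `wpli_dec`
## decimates the analytic sample grid used for the wPLI estimate; the
## band-limited (<= 45 Hz) analytic signal is fully represented on a
## >= 100 Hz grid, so decimation to that rate changes nothing in
## expectation and little in variance.
.epochFeatures <- function(seg, fs, channels, wpli_dec = 1L) {
  nch <- nrow(seg)
  nb <- nrow(eegBands())
  An <- .bandAnalytic(seg, fs)
  pw <- .powerFeatures(seg, fs)
  npair <- nch * (nch - 1) / 2
  keep <- seq(1L, ncol(seg), by = max(1L, as.integer(wpli_dec)))
  acc <- .wpliAccumulate(An, keep, matrix(0, npair, nb),
                         matrix(0, npair, nb))
  wp <- abs(acc$num) / acc$den         # npair x nb
  wp[acc$den == 0] <- 0
  wp[wp > 1] <- 1                      # guard float epsilon
  mi <- .miFeatures(An, channels)
  c(as.vector(t(pw)), as.vector(t(wp)), mi)
}

#' Resting-state features (RST)
#'
#' Computes all 614 features on every 6 s resting epoch and averages them
#' across epochs.
#'
#' @param epochs preprocessed resting [EpochSet-class] (at least 2 epochs).
#' @return named numeric vector of `RST_*` features.
#' @export
computeRstFeatures <- function(epochs) {
  nep <- dim(epochs@data)[1]
  if (nep < 2) stop("at least 2 resting epochs required")
  dec <- max(1L, floor(epochs@fs / 100))
  acc <- 0
  for (e in seq_len(nep)) {
    acc <- acc + .epochFeatures(epochs@data[e, , ], epochs@fs,
                                epochs@channelNames, wpli_dec = dec)
  }
  out <- acc / nep
  names(out) <- modalityFeatureNames("RST", epochs@channelNames)
  out
}

#' Pre- or post-stimulus window features (PRE / PST)
#'
#' Band powers and PAC MI are computed on the trial-averaged (evoked) trace
#' within the analysis window. wPLI is estimated over the time-sample
#' distribution of the analytic cross-term pooled across trials: phase
#' relations consistent over trials accumulate in the numerator, while the
#' short single-window estimate alone would be degenerate (a 500 ms
#' narrow-band window carries only a handful of independent phase samples).
#'
#' @param epochs windowed stimulus-locked [EpochSet-class]
#'   (see [extractWindows()]).
#' @param set_tag `"PRE"` or `"PST"`.
#' @return named numeric vector of `PRE_*` / `PST_*` features.
#' @export
computeWindowFeatures <- function(epochs, set_tag = c("PRE", "PST")) {
  set_tag <- match.arg(set_tag)
  fs <- epochs@fs
  nch <- length(epochs@channelNames)
  nb <- nrow(eegBands())
  evoked <- evokedAverage(epochs)
  pw <- .powerFeatures(evoked, fs)
  mi <- .miFeatures(.bandAnalytic(evoked, fs), epochs@channelNames)
  npair <- nch * (nch - 1) / 2
  num <- matrix(0, npair, nb); den <- matrix(0, npair, nb)
  keep <- seq(1L, dim(epochs@data)[3], by = max(1L, floor(fs / 100)))
  for (e in seq_len(dim(epochs@data)[1])) {
    An <- .bandAnalytic(epochs@data[e, , ], fs)
    acc <- .wpliAccumulate(An, keep, num, den)
    num <- acc$num; den <- acc$den
  }
  wp <- abs(num) / den
  wp[den == 0] <- 0
  wp[wp > 1] <- 1
  out <- c(as.vector(t(pw)), as.vector(t(wp)), mi)
  names(out) <- modalityFeatureNames(set_tag, epochs@channelNames)
  out
}

#' Post-minus-pre difference features (DIF)
#'
#' `DIF_x = PST_x - PRE_x` for every feature `x`.
#'
#' @param pre_vec named `PRE_*` feature vector.
#' @param pst_vec named `PST_*` feature vector.
#' @return named numeric vector of `DIF_*` features.
#' @export
computeDifFeatures <- function(pre_vec, pst_vec) {
  base_pre <- sub("^PRE_", "", names(pre_vec))
  base_pst <- sub("^PST_", "", names(pst_vec))
  if (!identical(base_pre, base_pst)) {
    stop("PRE and PST feature names must match up to the prefix")
  }
  out <- unname(pst_vec) - unname(pre_vec)
  names(out) <- paste0("DIF_", base_pre)
  out
}

#' Extract the full four-modality feature table from a cohort
#'
#' Runs the preprocessing chain on every subject's resting and TMS
#' recordings, computes RST, PRE, PST and DIF features (2456 in total) and
#' assembles them with the group labels and clinical covariates.
#'
#' @param cohort list of [SubjectRecord-class] objects
#'   (see [generateCohort()]).
#' @param cfg a [preprocConfig()] list.
#' @param seed seed for the ICA stages.
#' @param verbose print per-subject progress.
#' @return a [FeatureTable-class], subjects x 2456 features.
#' @export
buildFeatureTable <- function(cohort, cfg = preprocConfig(), seed = 1,
                              verbose = FALSE) {
  stopifnot(length(cohort) >= 1)
  channels <- cohort[[1]]@resting@channelNames
  allNames <- unlist(lapply(featureSets(), modalityFeatureNames,
                            channels = channels))
  vals <- matrix(NA_real_, length(cohort), length(allNames),
                 dimnames = list(vapply(cohort, function(s) s@subjectId, ""),
                                 allNames))
  for (k in seq_along(cohort)) {
    subj <- cohort[[k]]
    if (verbose) message("subject ", subj@subjectId)
    rest <- preprocessRecording(subj@resting, "resting", cfg, seed = seed)
    rst <- computeRstFeatures(rest$epochs)
    tms <- preprocessRecording(subj@tms, "tms", cfg, seed = seed)
    win <- extractWindows(tms$epochs)
    pre <- computeWindowFeatures(win$pre, "PRE")
    pst <- computeWindowFeatures(win$post, "PST")
    dif <- computeDifFeatures(pre, pst)
    feats <- c(rst, pre, pst, dif)
    vals[k, names(feats)] <- feats
  }
  if (anyNA(vals)) {
    warning("some features are missing (dropped channels); left as NA")
  }
  covars <- do.call(rbind, lapply(cohort, function(s) as.data.frame(t(s@clinical))))
  rownames(covars) <- rownames(vals)
  featureTable(vals, vapply(cohort, function(s) s@group, ""), covars)
}
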