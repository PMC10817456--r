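## Preprocessing chain: epoch -> baseline (TMS) -> artifact rejection ->
## ICA #1 (TMS decay) -> band-pass + notch filtering -> downsampling ->
## ICA #2. Every operation returns a new EpochSet with an appended
## provenance entry; inputs are never mutated.

#' Preprocessing configuration
#'
#' @param amp_reject_threshold epoch/channel rejection amplitude (uV,
#'   default 150).
#' @param flat_threshold peak-to-peak below which a channel is considered
#'   flat over the whole epoch set (uV).
#' @param bad_epoch_frac fraction of epochs over threshold above which a
#'   channel (rather than individual epochs) is dropped.
#' @param bandpass band-pass edges in Hz (default 0.5-100).
#' @param notch band-stop edges in Hz (default 48-52).
#' @param target_fs downsampling target in Hz (default 1000).
#' @param ica_tms_frac combined removal cap for the two TMS ICA stages, as a
#'   fraction of the component count (default 0.20).
#' @param ica_rest_frac removal cap for resting-state ICA (default 0.08).
#' @param baseline_window seconds relative to the pulse used for mean
#'   baseline correction (default the full pre-stimulus analysis window,
#'   -1.55 to -0.05 s).
#' @param exclusion_window seconds around the pulse excluded from analysis.
#' @param run_ica run the ICA stages (disable for artifact-free synthetic
#'   runs where the component scores have nothing to find).
#' @param decay_score_threshold first-stage ICA: minimum correlation with an
#'   exponential decay template for removal.
#' @param blink_score_threshold second-stage/resting ICA: minimum blink
#'   score (frontal topography x low-frequency power fraction) for removal.
#' @param line_score_threshold second-stage/resting ICA: minimum 50 Hz
#'   spectral peak ratio for removal.
#' @return a validated list of class `PreprocConfig`.
#' @export
preprocConfig <- function(amp_reject_threshold = 150, flat_threshold = 1,
                          bad_epoch_frac = 0.25,
                          bandpass = c(0.5, 100), notch = c(48, 52),
                          target_fs = 1000,
                          ica_tms_frac = 0.20, ica_rest_frac = 0.08,
                          baseline_window = c(-1.55, -0.05),
                          exclusion_window = c(-0.05, 0.05),
                          run_ica = TRUE,
                          decay_score_threshold = 0.8,
                          blink_score_threshold = 0.35,
                          line_score_threshold = 6) {
  stopifnot(bandpass[1] < bandpass[2],
            ica_tms_frac > 0, ica_tms_frac <= 1,
            ica_rest_frac > 0, ica_rest_frac <= 1,
            amp_reject_threshold > 0)
  structure(list(amp_reject_threshold = amp_reject_threshold,
                 flat_threshold = flat_threshold,
                 bad_epoch_frac = bad_epoch_frac,
                 bandpass = bandpass, notch = notch, target_fs = target_fs,
                 ica_tms_frac = ica_tms_frac, ica_rest_frac = ica_rest_frac,
                 baseline_window = baseline_window,
                 exclusion_window = exclusion_window,
                 run_ica = run_ica,
                 decay_score_threshold = decay_score_threshold,
                 blink_score_threshold = blink_score_threshold,
                 line_score_threshold = line_score_threshold),
            class = "PreprocConfig")
}

#' Epoch a resting-state recording into consecutive windows
#'
#' Cuts `floor(duration / dur_s)` consecutive non-overlapping epochs from
#' the start of the recording; any trailing remainder is discarded.
#'
#' @param rec an [EEGRecording-class].
#' @param dur_s epoch duration in seconds (default 6).
#' @return an [EpochSet-class] with window `(0, dur_s)`.
#' @export
epochResting <- function(rec, dur_s = 6) {
  nsamp <- round(dur_s * rec@fs)
  nep <- floor(ncol(rec@data) / nsamp)
  if (nep < 1) stop("recording shorter than one ", dur_s, " s epoch")
  nch <- nrow(rec@data)
  arr <- array(0, dim = c(nep, nch, nsamp))
  for (e in seq_len(nep)) {
    arr[e, , ] <- rec@data[, ((e - 1) * nsamp + 1):(e * nsamp)]
  }
  epochSet(arr, rec@fs, c(0, dur_s), rec@channelNames,
           provenance = sprintf("epoch_resting(%gs,n=%d)", dur_s, nep))
}

#' Epoch a TMS-EEG recording around each pulse
#'
#' Cuts one epoch per marker over `window` (default 2 s before to 2 s after
#' the pulse, half-open `[start, end)`) and mean-baseline-corrects each
#' channel using `baseline_window`. Markers too close to a recording edge
#' are dropped with a warning.
#'
#' @param rec an [EEGRecording-class] with pulse markers.
#' @param window epoch window in seconds relative to the pulse.
#' @param baseline_window baseline interval in seconds relative to the pulse.
#' @return an [EpochSet-class], one epoch per usable marker.
#' @export
epochTMS <- function(rec, window = c(-2, 2),
                     baseline_window = c(-1.55, -0.05)) {
  if (length(rec@markers) == 0) {
    stop("no markers: a TMS-EEG recording with pulse markers is required")
  }
  fs <- rec@fs
  nsamp <- round(diff(window) * fs)
  rel0 <- round(window[1] * fs)
  ok <- rec@markers + rel0 >= 1 &
    rec@markers + rel0 + nsamp - 1 <= ncol(rec@data)
  if (!all(ok)) {
    warning(sum(!ok), " marker(s) too close to a recording edge; dropped")
  }
  mk <- rec@markers[ok]
  if (length(mk) == 0) stop("no marker has the required margins")
  nch <- nrow(rec@data)
  arr <- array(0, dim = c(length(mk), nch, nsamp))
  ## baseline sample indices relative to epoch start (half-open window)
  b1 <- round((baseline_window[1] - window[1]) * fs) + 1
  b2 <- round((baseline_window[2] - window[1]) * fs)
  for (e in seq_along(mk)) {
    seg <- rec@data[, (mk[e] + rel0):(mk[e] + rel0 + nsamp - 1)]
    seg <- seg - rowMeans(seg[, b1:b2, drop = FALSE])
    arr[e, , ] <- seg
  }
  epochSet(arr, fs, window, rec@channelNames,
           keptEpochs = which(ok),
           provenance = sprintf("epoch_tms([%g,%g)s,baseline[%g,%g)s,n=%d)",
                                window[1], window[2], baseline_window[1],
                                baseline_window[2], length(mk)))
}

#' Reject noisy channels and epochs by amplitude thresholds
#'
#' Channels that are flat (peak-to-peak below `flat_threshold` over the
#' whole set) or exceed `amp_reject_threshold` in more than
#' `bad_epoch_frac` of epochs are dropped first; then any epoch in which a
#' remaining channel exceeds the threshold is dropped.
#'
#' @param epochs an [EpochSet-class].
#' @param cfg a [preprocConfig()] list.
#' @return list with `epochs` (cleaned [EpochSet-class]) and `report`
#'   (dropped channel names, dropped epoch ids).
#' @export
rejectBad <- function(epochs, cfg = preprocConfig()) {
  d <- epochs@data
  nep <- dim(d)[1]
  thr <- cfg$amp_reject_threshold
  ## per epoch x channel maximum absolute amplitude
  maxabs <- apply(abs(d), c(1, 2), max)
  ptp <- apply(d, 2, function(chdat) max(chdat) - min(chdat))
  flat <- ptp < cfg$flat_threshold
  noisy <- colMeans(maxabs > thr) > cfg$bad_epoch_frac
  dropCh <- flat | noisy
  keepCh <- which(!dropCh)
  if (length(keepCh) == 0) stop("all channels rejected")
  badEp <- apply(maxabs[, keepCh, drop = FALSE] > thr, 1, any)
  if (all(badEp)) stop("all epochs rejected")
  report <- list(
    channels_dropped = epochs@channelNames[dropCh],
    channels_flat = epochs@channelNames[flat],
    epochs_dropped = epochs@keptEpochs[badEp],
    threshold = thr)
  out <- epochSet(d[!badEp, keepCh, , drop = FALSE], epochs@fs,
                  epochs@window, epochs@channelNames[keepCh],
                  keptEpochs = epochs@keptEpochs[!badEp],
                  provenance = epochs@provenance)
  out <- addProvenance(out, sprintf("reject_bad(ch=%d,ep=%d)",
                                    sum(dropCh), sum(badEp)))
  list(epochs = out, report = report)
}

#' Band-pass and notch filter every channel of every epoch
#'
#' Zero-phase Butterworth band-pass (order 4) over `cfg$bandpass` followed
#' by a zero-phase band-stop (order 2) over `cfg$notch`.
#'
#' @param epochs an [EpochSet-class].
#' @param cfg a [preprocConfig()] list.
#' @return filtered [EpochSet-class].
#' @export
filterEpochs <- function(epochs, cfg = preprocConfig()) {
  fs <- epochs@fs
  if (fs <= 200) stop("filtering requires fs > 200 Hz")
  d <- epochs@data
  bp <- cfg$bandpass; nt <- cfg$notch
  designs <- list(list(lo = bp[1], hi = bp[2], order = 4, type = "pass"),
                  list(lo = nt[1], hi = nt[2], order = 2, type = "stop"))
  for (e in seq_len(dim(d)[1])) {
    d[e, , ] <- .fftFilterRows(d[e, , ], fs, designs, pad_s = 1)
  }
  out <- epochs; out@data <- d
  addProvenance(out, sprintf("filter(bp=%g-%gHz,notch=%g-%gHz)",
                             bp[1], bp[2], nt[1], nt[2]))
}

#' Downsample an epoch set
#'
#' Anti-alias low-pass (zero-phase Butterworth, order 6, cutoff 0.45 x
#' target rate) followed by integer decimation. The source rate must be an
#' integer multiple of the target; equal rates are the identity.
#'
#' @param epochs an [EpochSet-class].
#' @param target_fs target sampling rate in Hz.
#' @return downsampled [EpochSet-class].
#' @export
downsampleEpochs <- function(epochs, target_fs = 1000) {
  fs <- epochs@fs
  if (fs == target_fs) {
    return(addProvenance(epochs, sprintf("downsample(%gHz,identity)", fs)))
  }
  if (fs %% target_fs != 0) {
    stop("fs must be an integer multiple of target_fs")
  }
  k <- fs / target_fs
  d <- epochs@data
  nsamp <- dim(d)[3] / k
  if (nsamp != round(nsamp)) stop("epoch length not divisible by the decimation factor")
  keep <- seq(1, dim(d)[3], by = k)
  out <- array(0, dim = c(dim(d)[1], dim(d)[2], nsamp))
  aa <- list(list(lo = NULL, hi = 0.45 * target_fs, order = 6,
                  type = "pass"))
  for (e in seq_len(dim(d)[1])) {
    y <- .fftFilterRows(d[e, , ], fs, aa, pad_s = 0.5)
    out[e, , ] <- y[, keep]
  }
  res <- epochSet(out, target_fs, epochs@window, epochs@channelNames,
                  keptEpochs = epochs@keptEpochs,
                  provenance = epochs@provenance)
  addProvenance(res, sprintf("downsample(%g->%gHz)", fs, target_fs))
}

#' ICA cap arithmetic
#'
#' Maximum number of removable independent components:
#' `floor(fraction * n_components)`. With the 20% combined TMS-stage cap on
#' a 64-channel decomposition this evaluates to 12.
#'
#' @param fraction cap fraction in `(0, 1]`.
#' @param n_components component count of the decomposition.
#' @return integer cap.
#' @export
icaRemovalCap <- function(fraction, n_components) {
  stopifnot(fraction > 0, fraction <= 1, n_components >= 1)
  as.integer(floor(fraction * n_components))
}

#' ICA-based artifact component removal
#'
#' Decomposes the concatenated epochs with FastICA and removes components
#' flagged by stage-specific heuristics: the `first_tms` stage flags
#' components whose trial-averaged 10-500 ms post-stimulus time course
#' correlates with an exponential decay template; the `second` and
#' `resting` stages flag blink-like components (frontal-dominant topography
#' with dominant low-frequency power) and line-noise components (spectral
#' peak inside the notch band). The number of removals never exceeds
#' `floor(cap_fraction x n_components)`; for the TMS stages the cap is
#' shared across both stages via `prior_removed`.
#'
#' @param epochs an [EpochSet-class].
#' @param stage `"first_tms"`, `"second"`, or `"resting"`.
#' @param cfg a [preprocConfig()] list.
#' @param seed seed for the FastICA initialisation.
#' @param prior_removed components already removed by an earlier TMS stage
#'   (counts against the shared cap).
#' @return list with `epochs` (reconstructed [EpochSet-class]) and `report`
#'   (per-component scores, decisions, cap, truncation flag).
#' @export
icaClean <- function(epochs, stage = c("first_tms", "second", "resting"),
                     cfg = preprocConfig(), seed = 1, prior_removed = 0L) {
  stage <- match.arg(stage)
  d <- epochs@data
  nep <- dim(d)[1]; nch <- dim(d)[2]; nsamp <- dim(d)[3]
  if (nep * nsamp < 20 * nch^2) {
    warning("too few samples for a stable ICA decomposition; stage skipped")
    return(list(epochs = addProvenance(epochs, sprintf("ica_%s(skipped)", stage)),
                report = list(stage = stage, skipped = TRUE)))
  }
  ## channels x (epochs * samples) concatenation
  X <- matrix(aperm(d, c(2, 3, 1)), nch, nep * nsamp)
  mu <- rowMeans(X)
  ica <- .fastICA(X - mu, seed = seed)
  S <- ica$S      # components x samples
  A <- ica$A      # channels x components (mixing)

  frac <- if (stage == "resting") cfg$ica_rest_frac else cfg$ica_tms_frac
  cap <- icaRemovalCap(frac, nch)
  remaining <- max(0L, cap - as.integer(prior_removed))

  if (stage == "first_tms") {
    scores <- .decayScores(S, epochs, nep, nsamp)
    flagged <- which(scores > cfg$decay_score_threshold)
    kind <- rep("decay", length(flagged))
  } else {
    bs <- .blinkScores(S, A, epochs@channelNames, epochs@fs)
    ls <- .lineScores(S, epochs@fs, cfg$notch)
    scores <- pmax(bs / cfg$blink_score_threshold,
                   ls / cfg$line_score_threshold)
    flagged <- which(bs > cfg$blink_score_threshold |
                       ls > cfg$line_score_threshold)
    kind <- ifelse(bs[flagged] > cfg$blink_score_threshold, "blink", "line")
  }
  truncated <- length(flagged) > remaining
  if (truncated) {
    warning("ICA stage '", stage, "': ", length(flagged),
            " components flagged but cap allows ", remaining,
            "; keeping the highest-scoring ones")
    ord <- order(scores[flagged], decreasing = TRUE)
    flagged <- flagged[ord][seq_len(remaining)]
  }
  keep <- setdiff(seq_len(nrow(S)), flagged)
  Xc <- A[, keep, drop = FALSE] %*% S[keep, , drop = FALSE] + mu
  out <- epochs
  out@data <- aperm(array(Xc, dim = c(nch, nsamp, nep)), c(3, 1, 2))
  out <- addProvenance(out, sprintf("ica_%s(removed=%d/cap=%d)",
                                    stage, length(flagged), cap))
  list(epochs = out,
       report = list(stage = stage, scores = scores, removed = flagged,
                     removed_kind = kind, cap = cap,
                     prior_removed = as.integer(prior_removed),
                     truncated = truncated, skipped = FALSE))
}

## Correlation of each component's trial-averaged post-stimulus (10-500 ms)
## time course with exponential decay templates.
.decayScores <- function(S, epochs, nep, nsamp) {
  fs <- epochs@fs
  t0 <- round((0 - epochs@window[1]) * fs)   # sample index of the pulse
  i1 <- t0 + round(0.01 * fs); i2 <- min(nsamp, t0 + round(0.5 * fs))
  if (i1 >= i2 || i1 < 1) return(rep(0, nrow(S)))
  tt <- (seq(i1, i2) - t0) / fs
  templates <- lapply(c(0.05, 0.1, 0.2), function(tau) exp(-tt / tau))
  vapply(seq_len(nrow(S)), function(ci) {
    comp <- matrix(S[ci, ], nsamp, nep)      # samples x epochs
    evoked <- rowMeans(comp)[i1:i2]
    if (stats::sd(evoked) == 0) return(0)
    max(vapply(templates, function(tp) abs(stats::cor(evoked, tp)), numeric(1)))
  }, numeric(1))
}

## Blink score: fraction of topography magnitude on Fp/AF channels times
## fraction of component power below 4 Hz.
.blinkScores <- function(S, A, channels, fs) {
  frontal <- startsWith(channels, "Fp") | startsWith(channels, "AF")
  if (!any(frontal)) return(rep(0, nrow(S)))
  vapply(seq_len(nrow(S)), function(ci) {
    topo <- abs(A[, ci])
    topoFrac <- sum(topo[frontal]) / sum(topo)
    ps <- welchPsd(S[ci, ], fs, seg_s = min(1, length(S[ci, ]) / fs))
    tot <- sum(ps$psd)
    lfFrac <- if (tot > 0) sum(ps$psd[ps$freq < 4]) / tot else 0
    topoFrac * lfFrac
  }, numeric(1))
}

## Line-noise score: mean PSD inside the notch band over mean PSD in the
## flanking 10 Hz neighbourhoods.
.lineScores <- function(S, fs, notch = c(48, 52)) {
  if (fs / 2 <= notch[2]) return(rep(0, nrow(S)))
  vapply(seq_len(nrow(S)), function(ci) {
    ps <- welchPsd(S[ci, ], fs, seg_s = 1)
    inb <- ps$freq >= notch[1] & ps$freq <= notch[2]
    nb <- (ps$freq >= notch[1] - 10 & ps$freq < notch[1]) |
      (ps$freq > notch[2] & ps$freq <= notch[2] + 10)
    if (!any(inb) || !any(nb) || mean(ps$psd[nb]) == 0) return(0)
    mean(ps$psd[inb]) / mean(ps$psd[nb])
  }, numeric(1))
}

#' Extract the pre- and post-stimulus analysis windows
#'
#' Pre-stimulus window -1550 to -50 ms (1500 ms), post-stimulus window 50 to
#' 550 ms (500 ms), both half-open; the +-50 ms interval around the pulse
#' appears in neither.
#'
#' @param epochs stimulus-locked [EpochSet-class] spanning at least
#'   `[-1.55, 0.55]` s.
#' @param pre,post window definitions in seconds.
#' @return list with `pre` and `post` [EpochSet-class] objects.
#' @export
extractWindows <- function(epochs, pre = c(-1.55, -0.05),
                           post = c(0.05, 0.55)) {
  w <- epochs@window
  if (w[1] > pre[1] || w[2] < post[2]) {
    stop("epochs must span the pre- and post-stimulus analysis windows")
  }
  fs <- epochs@fs
  cut <- function(win) {
    i1 <- round((win[1] - w[1]) * fs) + 1
    n <- round(diff(win) * fs)
    d <- epochs@data[, , i1:(i1 + n - 1), drop = FALSE]
    res <- epochSet(d, fs, win, epochs@channelNames,
                    keptEpochs = epochs@keptEpochs,
                    provenance = epochs@provenance)
    addProvenance(res, sprintf("extract_window([%g,%g)s)", win[1], win[2]))
  }
  list(pre = cut(pre), post = cut(post))
}

#' Average an epoch set over trials
#'
#' Arithmetic mean across epochs, per channel and sample (the evoked
#' response for stimulus-locked data).
#'
#' @param epochs an [EpochSet-class] with at least one epoch.
#' @return channels x samples matrix.
#' @export
evokedAverage <- function(epochs) {
  d <- epochs@data
  if (dim(d)[1] < 1) stop("at least one epoch required")
  out <- colMeans(d, dims = 1)
  rownames(out) <- epochs@channelNames
  out
}

#' Run the full preprocessing chain on one recording
#'
#' Resting chain: epoch (6 s) -> reject -> filter -> downsample ->
#' ICA (resting). TMS chain: epoch (+-2 s, baseline-corrected) -> reject ->
#' ICA #1 (decay) -> filter -> downsample -> ICA #2, with the removal cap
#' shared across the two TMS ICA stages.
#'
#' @param rec an [EEGRecording-class].
#' @param type `"resting"` or `"tms"`.
#' @param cfg a [preprocConfig()] list.
#' @param seed seed for the ICA stages.
#' @return list with `epochs` (final [EpochSet-class]) and `reports`
#'   (rejection and ICA reports).
#' @export
preprocessRecording <- function(rec, type = c("resting", "tms"),
                                cfg = preprocConfig(), seed = 1) {
  type <- match.arg(type)
  reports <- list()
  if (type == "resting") {
    ep <- epochResting(rec)
    rb <- rejectBad(ep, cfg); ep <- rb$epochs
    reports$rejection <- rb$report
    ep <- filterEpochs(ep, cfg)
    if (rec@fs > cfg$target_fs) ep <- downsampleEpochs(ep, cfg$target_fs)
    if (cfg$run_ica) {
      ic <- icaClean(ep, "resting", cfg, seed = seed)
      ep <- ic$epochs; reports$ica <- ic$report
    }
  } else {
    ep <- epochTMS(rec, baseline_window = cfg$baseline_window)
    rb <- rejectBad(ep, cfg); ep <- rb$epochs
    reports$rejection <- rb$report
    removed1 <- 0L
    if (cfg$run_ica) {
      ic1 <- icaClean(ep, "first_tms", cfg, seed = seed)
      ep <- ic1$epochs; reports$ica_first <- ic1$report
      removed1 <- if (isTRUE(ic1$report$skipped)) 0L else length(ic1$report$removed)
    }
    ep <- filterEpochs(ep, cfg)
    if (rec@fs > cfg$target_fs) ep <- downsampleEpochs(ep, cfg$target_fs)
    if (cfg$run_ica) {
      ic2 <- icaClean(ep, "second", cfg, seed = seed + 1,
                      prior_removed = removed1)
      ep <- ic2$epochs; reports$ica_second <- ic2$report
    }
  }
  list(epochs = ep, reports = reports)
}
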