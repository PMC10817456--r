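## Core signal-processing primitives shared by the simulator, the
## preprocessing chain and the feature extractors. All functions operate on
## plain numeric vectors in microvolts, sampled at `fs` Hz.

## Cache of Butterworth squared-magnitude responses, keyed by design and
## FFT length (the same few designs recur thousands of times).
.mag2Cache <- new.env(parent = emptyenv())

## |H(e^{i w})|^2 of a Butterworth design evaluated on the length-L FFT
## grid. Applying it in the frequency domain implements the forward-
## backward (zero-phase) filter.
.butterMag2 <- function(fs, lo, hi, order, type, L) {
  key <- paste(fs, lo, hi, order, type, L, sep = "|")
  hit <- .mag2Cache[[key]]
  if (!is.null(hit)) return(hit)
  nyq <- fs / 2
  flt <- if (!is.null(lo) && !is.null(hi)) {
    signal::butter(order, c(lo, hi) / nyq, type = type)
  } else if (is.null(lo)) {
    signal::butter(order, hi / nyq, type = "low")
  } else {
    signal::butter(order, lo / nyq, type = "high")
  }
  w <- 2 * pi * (seq_len(L) - 1) / L
  eb <- exp(-1i * outer(w, seq_along(flt$b) - 1))
  ea <- exp(-1i * outer(w, seq_along(flt$a) - 1))
  H <- as.vector(eb %*% flt$b) / as.vector(ea %*% flt$a)
  out <- Mod(H)^2
  .mag2Cache[[key]] <- out
  out
}

## Odd-reflection padding of every row of a matrix; returns the padded
## matrix, padded to a 2-3-5-smooth FFT length with zeros on the right.
.reflectPadRows <- function(M, npad) {
  n <- ncol(M)
  npad <- min(npad, n - 1L)
  pre <- 2 * M[, 1] - M[, (npad + 1):2, drop = FALSE]
  post <- 2 * M[, n] - M[, (n - 1):(n - npad), drop = FALSE]
  Mp <- cbind(pre, M, post)
  L <- stats::nextn(ncol(Mp), c(2, 3, 5))
  if (L > ncol(Mp)) Mp <- cbind(Mp, matrix(0, nrow(M), L - ncol(Mp)))
  list(M = Mp, npad = npad, n = n)
}

## Frequency-domain zero-phase filtering of every row. `responses` is a
## list of design lists (fs/lo/hi/order/type) whose squared magnitudes are
## multiplied (so band-pass + notch compose into a single pass); with
## `analytic = TRUE` the analytic-signal weighting is folded in and a
## complex matrix is returned.
.fftFilterRows <- function(M, fs, responses, pad_s = 0.25,
                           analytic = FALSE) {
  pp <- .reflectPadRows(M, round(pad_s * fs))
  L <- ncol(pp$M)
  g <- rep(1, L)
  for (r in responses) {
    g <- g * .butterMag2(fs, r$lo, r$hi, r$order, r$type, L)
  }
  if (analytic) {
    h <- numeric(L)
    if (L %% 2 == 0) { h[1] <- 1; h[L / 2 + 1] <- 1; h[2:(L / 2)] <- 2 }
    else { h[1] <- 1; h[2:((L + 1) / 2)] <- 2 }
    g <- g * h
  }
  X <- stats::mvfft(t(pp$M)) * g
  Y <- t(stats::mvfft(X, inverse = TRUE) / L)
  Y <- Y[, (pp$npad + 1):(pp$npad + pp$n), drop = FALSE]
  if (analytic) Y else Re(Y)
}

#' Zero-phase Butterworth filtering with reflection padding
#'
#' Applies a Butterworth filter with zero net phase shift by multiplying
#' the spectrum with the design's squared magnitude response (the exact
#' frequency response of a forward-backward pass). The input is extended
#' at both ends by odd reflection so edge transients fall on the padding,
#' which is discarded.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param lo,hi band edges in Hz. Use `lo = NULL` for a low-pass, `hi = NULL`
#'   for a high-pass.
#' @param order filter order (of the underlying one-pass design).
#' @param type `"pass"` or `"stop"`.
#' @param pad_s padding duration in seconds on each side.
#' @return filtered vector, same length as `x`.
#' @keywords internal
zeroPhaseFilter <- function(x, fs, lo = NULL, hi = NULL, order = 4,
                            type = c("pass", "stop"), pad_s = 0.25) {
  type <- match.arg(type)
  nyq <- fs / 2
  if (!is.null(hi)) stopifnot(hi < nyq)
  if (!is.null(lo) && !is.null(hi)) stopifnot(lo < hi)
  as.vector(.fftFilterRows(matrix(x, 1), fs,
                           list(list(lo = lo, hi = hi, order = order,
                                     type = type)),
                           pad_s = pad_s))
}

#' Band-pass a signal to one oscillatory band
#' @inheritParams zeroPhaseFilter
#' @keywords internal
bandFilter <- function(x, fs, lo, hi, order = 4, pad_s = 0.25) {
  zeroPhaseFilter(x, fs, lo = lo, hi = hi, order = order, pad_s = pad_s)
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x real-valued numeric vector.
#' @return complex vector `x + i * H(x)`.
#' @keywords internal
analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

## Phase-shift a real band-limited signal by `deg` degrees (delaying the
## phase of every spectral component), used to plant lagged copies.
phaseShift <- function(x, deg) {
  Re(analyticSignal(x) * exp(-1i * deg * pi / 180))
}

#' Welch power spectral density
#'
#' One-sided Welch PSD with Hann-windowed segments and 50% overlap. Segments
#' are demeaned before windowing. When the requested segment is longer than
#' the signal, a single-segment periodogram is returned with a warning.
#'
#' @param x numeric vector (microvolts).
#' @param fs sampling rate in Hz.
#' @param seg_s segment length in seconds (default 0.5 s, two cycles of the
#'   4 Hz theta band edge).
#' @param overlap fractional overlap between consecutive segments.
#' @return list with `freq` (Hz) and `psd` (uV^2/Hz).
#' @export
welchPsd <- function(x, fs, seg_s = 0.5, overlap = 0.5) {
  n <- length(x)
  nper <- round(seg_s * fs)
  if (nper > n) {
    warning("segment longer than signal; using a single-segment periodogram")
    nper <- n
  }
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann
  scale <- fs * sum(w^2)
  nf <- floor(nper / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg))^2 / scale
    P <- P[seq_len(nf)]
    ## one-sided: double everything except DC (and Nyquist when nper even)
    dbl <- rep(2, nf); dbl[1] <- 1
    if (nper %% 2 == 0) dbl[nf] <- 1
    acc <- acc + P * dbl
  }
  list(freq = (seq_len(nf) - 1L) * fs / nper, psd = acc / length(starts))
}

#' Band power from the Welch PSD
#'
#' Integrated power (uV^2) of the one-sided Welch PSD over `[lo, hi]` Hz.
#'
#' @param x numeric signal.
#' @param lo,hi band edges in Hz.
#' @param fs sampling rate in Hz.
#' @param seg_s Welch segment length in seconds.
#' @return scalar band power in uV^2.
#' @examples
#' fs <- 500
#' x <- sin(2 * pi * 10 * seq(0, 4, by = 1 / fs))
#' bandPower(x, 8, 13, fs) > 100 * bandPower(x, 14, 30, fs)
#' @export
bandPower <- function(x, lo, hi, fs, seg_s = 0.5) {
  if (all(x == 0)) return(0)
  ps <- welchPsd(x, fs, seg_s = seg_s)
  sel <- ps$freq >= lo & ps$freq <= hi
  df <- ps$freq[2] - ps$freq[1]
  sum(ps$psd[sel]) * df
}

#' Weighted phase lag index between two signals
#'
#' Both signals are band-filtered, converted to analytic signals by the
#' Hilbert transform, and the wPLI is estimated over the time-sample
#' distribution of the imaginary part of the cross-term
#' \eqn{X_t = \tilde x_t \overline{\tilde y_t}}:
#' \deqn{wPLI = |\sum_t |Im X_t| sgn(Im X_t)| / \sum_t |Im X_t|.}
#' A zero denominator (no imaginary cross-spectrum at all) returns 0 by
#' convention. The estimator is insensitive to zero-lag (volume-conduction)
#' coupling and to amplitude scaling of either signal.
#'
#' @param x,y numeric signals of equal length.
#' @param lo,hi band edges in Hz.
#' @param fs sampling rate in Hz.
#' @return wPLI in `[0, 1]`.
#' @examples
#' fs <- 250; t <- seq(0, 4, by = 1 / fs)
#' x <- sin(2 * pi * 10 * t)
#' y <- sin(2 * pi * 10 * t - pi / 2)
#' round(wpli(x, y, 8, 13, fs), 6)  # quarter-cycle lag -> 1
#' @export
wpli <- function(x, y, lo, hi, fs) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  minlen <- 2 * fs / lo
  if (length(x) < minlen) {
    stop("signal shorter than two cycles of the band's low edge")
  }
  ax <- analyticSignal(bandFilter(x, fs, lo, hi))
  ay <- analyticSignal(bandFilter(y, fs, lo, hi))
  wpliFromImag(Im(ax * Conj(ay)))
}

#' wPLI from a sample of imaginary cross-spectrum values
#'
#' Evaluates the defining estimator
#' \eqn{|\sum_t |Im X_t| sgn(Im X_t)| / \sum_t |Im X_t|} on a vector of
#' imaginary cross-term samples (zero denominator returns 0 by convention).
#' Shared by [wpli()] and the multi-channel fast path.
#'
#' @param imx numeric vector of imaginary cross-spectrum samples.
#' @return wPLI in `[0, 1]`.
#' @examples
#' wpliFromImag(c(1, -0.5, 2, -0.5))  # 0.5
#' @export
wpliFromImag <- function(imx) {
  den <- sum(abs(imx))
  if (den == 0) return(0)
  abs(sum(imx)) / den
}

#' Normalized modulation index of a phase-binned amplitude distribution
#'
#' Kullback-Leibler divergence of `p` from the uniform distribution over its
#' `N` bins, normalized by `log(N)` so that MI lies in `[0, 1]`.
#'
#' @param p numeric vector of non-negative bin masses (normalized internally).
#' @return MI in `[0, 1]`.
#' @export
miFromDistribution <- function(p) {
  stopifnot(all(p >= 0), sum(p) > 0)
  p <- p / sum(p)
  nb <- length(p)
  if (nb < 2) return(1)
  plogp <- ifelse(p > 0, p * log(p), 0)
  (log(nb) + sum(plogp)) / log(nb)
}

#' Phase-amplitude coupling modulation index
#'
#' Extracts the instantaneous phase of the low-frequency band and the
#' instantaneous amplitude envelope of the high-frequency band (both via
#' band-pass filtering and the Hilbert transform), bins the amplitude by
#' phase into `n_bins` equal bins over \eqn{(-\pi, \pi]}, and computes the
#' normalized KL modulation index of the mean-amplitude distribution.
#' Empty phase bins are merged into their neighbours (equivalently dropped
#' from the distribution) with a warning.
#'
#' @param x numeric signal.
#' @param phase_lo,phase_hi phase-providing band edges in Hz.
#' @param amp_lo,amp_hi amplitude-providing band edges in Hz; the amplitude
#'   band must lie strictly above the phase band.
#' @param fs sampling rate in Hz.
#' @param n_bins number of phase bins (default 18).
#' @return MI in `[0, 1]`.
#' @export
pacMI <- function(x, phase_lo, phase_hi, amp_lo, amp_hi, fs, n_bins = 18) {
  if (amp_lo <= phase_hi) stop("amplitude band must lie above the phase band")
  minlen <- 2 * fs / phase_lo
  if (length(x) < minlen) {
    stop("signal shorter than two cycles of the phase band's low edge")
  }
  ph <- Arg(analyticSignal(bandFilter(x, fs, phase_lo, phase_hi)))
  am <- Mod(analyticSignal(bandFilter(x, fs, amp_lo, amp_hi)))
  edges <- seq(-pi, pi, length.out = n_bins + 1L)
  idx <- findInterval(ph, edges, rightmost.closed = TRUE, left.open = TRUE)
  idx[idx < 1L] <- 1L
  m <- vapply(seq_len(n_bins), function(j) {
    v <- am[idx == j]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  if (anyNA(m)) {
    warning("empty phase bin(s) merged with neighbours")
    m <- m[!is.na(m)]
  }
  if (sum(m) == 0) return(0)
  miFromDistribution(m)
}
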