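## Synthetic two-group cohort generator. Signals are 1/f background plus
## band-limited oscillatory components; group differences are planted in the
## signal domain through three mechanisms (band-power scaling, lagged shared
## sources for wPLI, modulation depth for PAC) so that the downstream feature
## pipeline recovers them with a controllable standardized effect size.

#' Default planted effect table
#'
#' The five group-difference analogues used as the generator's default:
#' resting AFz beta power and F6-F4 gamma wPLI elevated in MDD, and three
#' pre-to-post TMS wPLI changes (F5-AF3 alpha, AFz-F5 alpha, AF3-F8 theta)
#' reduced in MDD.
#'
#' @param magnitude standardized effect size planted for every effect
#'   (default 1.2).
#' @return data.frame with columns `feature`, `direction`, `magnitude`,
#'   `mechanism`.
#' @export
defaultEffectTable <- function(magnitude = 1.2) {
  data.frame(
    feature = c("RST_power_AFz_beta", "RST_wPLI_F6-F4_gamma",
                "DIF_wPLI_F5-AF3_alpha", "DIF_wPLI_AFz-F5_alpha",
                "DIF_wPLI_AF3-F8_theta"),
    direction = c("MDD_higher", "MDD_higher",
                  "MDD_lower", "MDD_lower", "MDD_lower"),
    magnitude = magnitude,
    mechanism = c("power_scale", "shared_source_lag",
                  "shared_source_lag", "shared_source_lag",
                  "shared_source_lag"),
    stringsAsFactors = FALSE)
}

#' Default clinical covariate model
#'
#' Per-group Gaussian mean/sd for age, MADRS, STAI (state and trait) and
#' MMSE, truncated to instrument ranges at draw time.
#'
#' @return nested list `list(MDD = ..., HC = ...)` of `c(mean, sd)` pairs.
#' @export
defaultClinicalModel <- function() {
  list(
    MDD = list(age = c(45.8, 12.2), MADRS = c(31.8, 7.8),
               STAI_trait = c(54.2, 20.1), STAI_state = c(55.4, 20.1),
               MMSE = c(29.1, 1.4)),
    HC = list(age = c(40.5, 12.2), MADRS = c(1.1, 2.0),
              STAI_trait = c(32.1, 9.2), STAI_state = c(34.2, 8.9),
              MMSE = c(28.5, 3.3)))
}

#' Specify a synthetic cohort
#'
#' @param nPerGroup subjects per group (default 60).
#' @param seed integer seed making the cohort fully reproducible.
#' @param fs generation sampling rate in Hz (default 3000; reduce for speed).
#' @param channels ordered channel names (default the 17-channel frontal
#'   montage).
#' @param restDuration resting recording length in seconds (default 300).
#' @param nPulses number of single TMS pulses (default 80).
#' @param interPulse mean inter-pulse interval in seconds (default 5,
#'   jittered +-10% per pulse).
#' @param effectTable planted effects (see [defaultEffectTable()]).
#' @param clinicalModel clinical covariate model
#'   (see [defaultClinicalModel()]).
#' @param artifactBlink inject blink-like frontal transients into the
#'   resting recording.
#' @param artifactDecay inject exponential TMS decay artifacts
#'   (time constant ~100 ms, frontal-weighted) after every pulse.
#' @param madrsCoupling target within-MDD Spearman correlation between the
#'   AFz-beta power effect and the MADRS score (default 0.28).
#' @return a [CohortSpec-class].
#' @export
cohortSpec <- function(nPerGroup = 60, seed = 1, fs = 3000,
                       channels = frontalMontage(), restDuration = 300,
                       nPulses = 80, interPulse = 5,
                       effectTable = defaultEffectTable(),
                       clinicalModel = defaultClinicalModel(),
                       artifactBlink = FALSE, artifactDecay = FALSE,
                       madrsCoupling = 0.28) {
  new("CohortSpec", nPerGroup = as.integer(nPerGroup),
      seed = as.integer(seed), fs = fs, channels = channels,
      restDuration = restDuration, nPulses = as.integer(nPulses),
      interPulse = interPulse, effectTable = effectTable,
      clinicalModel = clinicalModel, artifactBlink = artifactBlink,
      artifactDecay = artifactDecay, madrsCoupling = madrsCoupling)
}

#' Reduced-size cohort specification
#'
#' The evaluation profile used by the package's own test battery: a lower
#' sampling rate (which still resolves the gamma band with margin), a shorter
#' resting recording and fewer pulses, keeping everything else identical to
#' the defaults. Feature estimates are noisier at this scale; the planted
#' effect calibration is referenced to this profile (see the methods
#' vignette).
#'
#' @param nPerGroup subjects per group.
#' @param seed integer seed.
#' @param fs sampling rate in Hz.
#' @param restDuration resting recording seconds.
#' @param nPulses pulses.
#' @param ... further arguments passed to [cohortSpec()].
#' @return a [CohortSpec-class].
#' @export
fastCohortSpec <- function(nPerGroup = 12, seed = 1, fs = 1000,
                           restDuration = 30, nPulses = 20, ...) {
  cohortSpec(nPerGroup = nPerGroup, seed = seed, fs = fs,
             restDuration = restDuration, nPulses = nPulses, ...)
}

#' 1/f background signal
#'
#' Independent per-channel pink-like noise with power spectral density
#' proportional to \eqn{1/f^\beta}, produced by spectral shaping of white
#' Gaussian noise, plus independent white sensor noise.
#'
#' @param duration seconds.
#' @param fs sampling rate in Hz.
#' @param n_channels number of channels.
#' @param seed optional seed; `NULL` draws from the current RNG stream.
#' @param beta spectral exponent (1 = pink).
#' @param sd_pink standard deviation of the shaped component (uV).
#' @param sd_white standard deviation of the white sensor noise (uV).
#' @return matrix, channels x samples.
#' @export
synthBackground <- function(duration, fs, n_channels, seed = NULL,
                            beta = 1, sd_pink = 10, sd_white = 2) {
  n <- round(duration * fs)
  if (n < 1) stop("duration*fs must be at least one sample")
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(0, n_channels, n)
  L <- stats::nextn(n, c(2, 3, 5))   # smooth FFT length; excess discarded
  f <- c(0, seq_len(L - 1)) * fs / L
  f <- pmin(f, fs - f)              # two-sided frequency axis
  shape <- c(0, 1 / (f[-1]^(beta / 2)))
  for (ch in seq_len(n_channels)) {
    w <- stats::rnorm(L)
    x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE))[seq_len(n)] / L
    s <- stats::sd(x)
    if (s > 0) x <- x / s * sd_pink
    out[ch, ] <- x + stats::rnorm(n, sd = sd_white)
  }
  out
}

## Unit-sd band-limited Gaussian noise (oscillatory source material).
bandNoise <- function(n, fs, lo, hi) {
  x <- bandFilter(stats::rnorm(n), fs, lo, hi)
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Plant a lagged shared oscillatory source into two channels
#'
#' Adds a common band-limited source to channel `ch_i` and a copy
#' phase-delayed by `lag_deg` degrees to channel `ch_j`, both scaled by
#' `strength * amp` (uV sd). Against independent background noise the wPLI
#' between the two channels grows monotonically with `strength`; lags of 0
#' or 180 degrees produce a purely real cross-spectrum and leave wPLI at its
#' noise floor.
#'
#' @param signals channels x samples matrix with channel row names.
#' @param ch_i,ch_j channel names.
#' @param lo,hi band edges in Hz.
#' @param lag_deg phase lag applied to the `ch_j` copy, degrees.
#' @param strength coupling strength in `[0, 1]`.
#' @param fs sampling rate in Hz.
#' @param amp source amplitude (uV sd) at `strength = 1`.
#' @param source optional pre-generated source signal (length = samples);
#'   default draws band-limited Gaussian noise.
#' @return the modified signal matrix.
#' @export
plantPhaseCoupling <- function(signals, ch_i, ch_j, lo, hi, lag_deg,
                               strength, fs, amp = 1, source = NULL) {
  stopifnot(strength >= 0, strength <= 1)
  if (!all(c(ch_i, ch_j) %in% rownames(signals))) {
    stop("unknown channel: ",
         paste(setdiff(c(ch_i, ch_j), rownames(signals)), collapse = ", "))
  }
  if (strength == 0) return(signals)
  n <- ncol(signals)
  if (is.null(source)) source <- bandNoise(n, fs, lo, hi)
  src <- strength * amp * source
  signals[ch_i, ] <- signals[ch_i, ] + src
  signals[ch_j, ] <- signals[ch_j, ] + phaseShift(src, lag_deg)
  signals
}

#' Plant phase-amplitude coupling into a signal
#'
#' Modulates the amplitude of the signal's high-frequency band component as
#' \eqn{1 + depth \cos\phi} of the instantaneous phase \eqn{\phi} of its
#' low-frequency band component. `depth = 0` is the identity; the modulation
#' index grows monotonically with `depth`.
#'
#' @param x numeric signal.
#' @param phase_lo,phase_hi phase-providing band, Hz.
#' @param amp_lo,amp_hi amplitude-providing band, Hz (must lie above the
#'   phase band).
#' @param depth modulation depth in `[0, 1]`.
#' @param fs sampling rate in Hz.
#' @return the modulated signal.
#' @export
plantPAC <- function(x, phase_lo, phase_hi, amp_lo, amp_hi, depth, fs) {
  stopifnot(depth >= 0, depth <= 1)
  if (amp_lo <= phase_hi) stop("phase and amplitude bands must not overlap")
  if (depth == 0) return(x)
  ph <- Arg(analyticSignal(bandFilter(x, fs, phase_lo, phase_hi)))
  am <- bandFilter(x, fs, amp_lo, amp_hi)
  x + depth * am * cos(ph)
}

## ---------------------------------------------------------------------------
## Effect calibration. Signal-domain parameters are mapped to a target
## standardized effect size of the *realized feature* (after the full
## feature pipeline) via constants calibrated once by simulation at the
## reduced evaluation profile; see the methods vignette. `k` converts a
## requested effect size d into a group shift of the latent parameter;
## `sigma` is the between-subject sd of the latent.
## wPLI effects are planted as a shared band-limited source whose copy on
## the second channel is phase-delayed by a subject-specific lag angle
## theta = 90 * plogis(eta) degrees: zero lag is invisible to wPLI while
## larger lags raise it monotonically, and the added band power is the same
## for both groups (power features stay uninformative by construction).
.effectCalib <- list(
  power_scale       = list(A0 = 7, sigma = 0.22, k = 0.23),
  shared_source_lag = list(r = 1.2, l0 = -0.22, sigma = 0.4, k = 0.62),
  dif_coupling      = list(r = 1.5, l0 = -0.22, sigma_base = 0.6,
                           sigma = 0.25, k = 1.2),
  pac_depth         = list(d0 = 0.3, sigma = 0.10, k = 0.12)
)

## Frontal weighting of artifact topographies (blinks, decay) by row prefix.
.frontalWeight <- function(channels) {
  w <- rep(0.3, length(channels))
  w[startsWith(channels, "AF")] <- 0.6
  w[startsWith(channels, "Fp")] <- 1.0
  w
}

## Truncated-normal draw via clipping (instrument-range truncation).
.truncDraw <- function(mu, sd, z, lo, hi) pmin(hi, pmax(lo, mu + sd * z))

## Split the effect table by the modality it is planted in.
.restEffects <- function(et) et[grepl("^RST_", et$feature), , drop = FALSE]
.difEffects <- function(et) et[grepl("^DIF_", et$feature), , drop = FALSE]

## Per-subject latent draws for every planted effect. The AFz-beta power
## latent of MDD subjects mixes in the shared severity variable `u` so that
## the feature rank-correlates with MADRS/STAI.
.effectLatents <- function(et, group, u, rho_a) {
  if (nrow(et) == 0) return(numeric(0))
  vapply(seq_len(nrow(et)), function(i) {
    z <- stats::rnorm(1)
    couple <- group == "MDD" && et$mechanism[i] == "power_scale" &&
      grepl("AFz_beta$", et$feature[i])
    if (couple) rho_a * u + sqrt(1 - rho_a^2) * z else z
  }, numeric(1))
}

## Latent parameter value for effect row i: base + group shift + subject noise.
.latentValue <- function(effect, group, v, calib) {
  half <- calib$k * effect$magnitude / 2
  sgn <- if (effect$direction == "MDD_higher") 1 else -1
  shift <- if (group == "MDD") sgn * half else -sgn * half
  shift + calib$sigma * v
}

## Generate one subject's resting recording (planted REST effects applied).
.generateRestRecording <- function(spec, group, latents, subjectId) {
  chans <- spec@channels
  fs <- spec@fs
  x <- synthBackground(spec@restDuration, fs, length(chans))
  rownames(x) <- chans
  et <- spec@effectTable
  rest <- .restEffects(et)
  for (i in seq_len(nrow(rest))) {
    e <- rest[i, ]
    p <- parseFeatureName(e$feature)
    band <- bandByName(p$band)
    v <- latents[rownames(et) == rownames(rest)[i]]
    if (e$mechanism == "power_scale") {
      cal <- .effectCalib$power_scale
      a <- cal$A0 * exp(.latentValue(e, group, v, cal))
      osc <- bandNoise(ncol(x), fs, band$lo, band$hi) * a
      x[p$loc, ] <- x[p$loc, ] + osc
    } else if (e$mechanism == "shared_source_lag") {
      cal <- .effectCalib$shared_source_lag
      theta <- 90 * stats::plogis(cal$l0 + .latentValue(e, group, v, cal))
      sigb <- stats::sd(bandFilter(x[p$chans[1], seq_len(min(ncol(x), 6 * fs))],
                                   fs, band$lo, band$hi))
      x <- plantPhaseCoupling(x, p$chans[1], p$chans[2], band$lo, band$hi,
                              lag_deg = theta, strength = 1, fs = fs,
                              amp = cal$r * sigb)
    } else if (e$mechanism == "pac_depth") {
      cal <- .effectCalib$pac_depth
      depth <- min(1, max(0, cal$d0 + .latentValue(e, group, v, cal)))
      pc <- pacCouplings()
      cp <- pc[pc$tag == p$band, ]
      pb <- bandByName(cp$phase); ab <- bandByName(cp$amp)
      for (ch in dlpfcRegion()) {
        ## seed the two carriers, then modulate
        x[ch, ] <- x[ch, ] + 4 * bandNoise(ncol(x), fs, pb$lo, pb$hi) +
          3 * bandNoise(ncol(x), fs, ab$lo, ab$hi)
        x[ch, ] <- plantPAC(x[ch, ], pb$lo, pb$hi, ab$lo, ab$hi, depth, fs)
      }
    }
  }
  if (spec@artifactBlink) x <- .injectBlinks(x, fs)
  eegRecording(x, fs, chans, subjectId = subjectId)
}

## Blink-like transients: ~350 ms raised-cosine deflections, frontal-weighted,
## every ~4 s with jitter.
.injectBlinks <- function(x, fs, amp = 120) {
  n <- ncol(x)
  w <- .frontalWeight(rownames(x))
  blinkLen <- round(0.35 * fs)
  shape <- amp * 0.5 * (1 - cos(2 * pi * seq_len(blinkLen) / (blinkLen + 1)))
  t <- round(2 * fs)
  while (t + blinkLen < n) {
    x[, t:(t + blinkLen - 1)] <- x[, t:(t + blinkLen - 1)] +
      outer(w, shape)
    t <- t + round(fs * stats::runif(1, 3, 5))
  }
  x
}

#' Generate one subject's TMS-EEG recording
#'
#' Produces a continuous recording containing `nPulses` stimulation markers
#' at the specified inter-pulse interval (jittered +-10%), a deterministic
#' TMS-evoked response after each pulse, planted post-stimulus phase-coupled
#' components implementing the `DIF` effects (the pre-to-post change in wPLI
#' is smaller in the MDD group), and, optionally, exponential decay artifacts.
#'
#' @param spec a [CohortSpec-class].
#' @param group `"MDD"` or `"HC"`.
#' @param latents per-effect latent draws (internal; scalar noise is drawn
#'   when omitted).
#' @param subjectId subject identifier.
#' @return an [EEGRecording-class] with `nPulses` markers.
#' @export
generateTMSRecording <- function(spec, group = "HC", latents = NULL,
                                 subjectId = "synthetic") {
  if (spec@interPulse < 4) {
    stop("inter-pulse interval must be >= 4 s so 4 s epochs do not overlap")
  }
  et <- spec@effectTable
  if (is.null(latents)) latents <- stats::rnorm(nrow(et))
  chans <- spec@channels
  fs <- spec@fs
  isi <- spec@interPulse * (1 + stats::runif(spec@nPulses, -0.1, 0.1))
  onsets <- 3 + cumsum(isi) - isi[1]         # first pulse at t = 3 s
  duration <- onsets[length(onsets)] + 3
  markers <- round(onsets * fs)
  x <- synthBackground(duration, fs, length(chans))
  rownames(x) <- chans

  ## generic evoked response: damped 10 Hz oscillation, same on every trial
  tepLen <- round(0.5 * fs)
  tt <- seq_len(tepLen) / fs
  phi <- stats::runif(1, 0, 2 * pi)
  tep <- 8 * exp(-tt / 0.15) * sin(2 * pi * 10 * tt + phi)
  wch <- 0.4 + 0.6 * .frontalWeight(chans)

  ## planted induced (non-phase-locked) coupled components in the pre- and
  ## post-stimulus analysis windows: every trial draws a fresh shared
  ## band-limited source for each DIF effect, added to the channel pair at
  ## a fixed SNR relative to the background band noise, with a consistent
  ## within-pair phase lag. Each subject has a baseline lag (shared by the
  ## pre and post windows) plus a pre-to-post lag change whose size is
  ## smaller in MDD: the group difference lives in the *change*, with the
  ## subject baseline cancelling from DIF = PST - PRE. Because the source
  ## is redrawn per trial it cancels from the evoked average (band power
  ## stays group-invariant) and does not interfere deterministically with
  ## the evoked response or with other effects sharing a channel.
  pre0 <- round(-1.55 * fs); preLen <- round(1.5 * fs)
  post0 <- round(0.05 * fs); postLen <- round(0.5 * fs)
  taperPre <- .tukey(preLen, 0.25)
  taperPost <- .tukey(postLen, 0.25)
  dif <- .difEffects(et)
  cal <- .effectCalib$dif_coupling
  difPlan <- lapply(seq_len(nrow(dif)), function(i) {
    e <- dif[i, ]
    p <- parseFeatureName(e$feature)
    band <- bandByName(p$band)
    v <- latents[rownames(et) == rownames(dif)[i]]
    etaBase <- cal$l0 + cal$sigma_base * stats::rnorm(1)
    chg <- .latentValue(e, group, v, cal)
    sigb <- stats::sd(bandFilter(x[p$chans[1], seq_len(min(ncol(x), 4 * fs))],
                                 fs, band$lo, band$hi))
    list(chans = p$chans, lo = band$lo, hi = band$hi, amp = cal$r * sigb,
         thPre = 90 * stats::plogis(etaBase),
         thPost = 90 * stats::plogis(etaBase + chg))
  })

  decayLen <- round(0.6 * fs)
  decay <- if (spec@artifactDecay) {
    amp <- 120 * (0.3 + 0.7 * .frontalWeight(chans)) *
      sign(stats::rnorm(length(chans)))
    outer(amp, exp(-(seq_len(decayLen) / fs) / 0.1))
  } else NULL

  for (m in markers) {
    idx <- m:(m + tepLen - 1)
    x[, idx] <- x[, idx] + outer(wch, tep)
    for (pl in difPlan) {
      wpre <- pl$amp * taperPre * bandNoise(preLen, fs, pl$lo, pl$hi)
      wpost <- pl$amp * taperPost * bandNoise(postLen, fs, pl$lo, pl$hi)
      pidx <- (m + pre0):(m + pre0 + preLen - 1)
      x[pl$chans[1], pidx] <- x[pl$chans[1], pidx] + wpre
      x[pl$chans[2], pidx] <- x[pl$chans[2], pidx] +
        phaseShift(wpre, pl$thPre)
      qidx <- (m + post0):(m + post0 + postLen - 1)
      x[pl$chans[1], qidx] <- x[pl$chans[1], qidx] + wpost
      x[pl$chans[2], qidx] <- x[pl$chans[2], qidx] +
        phaseShift(wpost, pl$thPost)
    }
    if (!is.null(decay)) {
      didx <- m:(m + decayLen - 1)
      x[, didx] <- x[, didx] + decay
    }
  }
  eegRecording(x, fs, chans, markers = markers, subjectId = subjectId)
}

## Tukey (tapered cosine) window.
.tukey <- function(n, alpha = 0.25) {
  w <- rep(1, n)
  edge <- floor(alpha * n / 2)
  if (edge > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(edge) / edge))
    w[seq_len(edge)] <- ramp
    w[(n - edge + 1):n] <- rev(ramp)
  }
  w
}

## Clinical scores for one subject. `u` is the latent severity shared with
## the AFz-beta effect; rho_c mixes it into MADRS, rho_s into STAI.
.drawClinical <- function(model, group, u, rho_c, rho_s) {
  m <- model[[group]]
  mix <- function(rho) {
    if (group == "MDD") rho * u + sqrt(1 - rho^2) * stats::rnorm(1)
    else stats::rnorm(1)
  }
  c(age = .truncDraw(m$age[1], m$age[2], stats::rnorm(1), 18, 65),
    MADRS = .truncDraw(m$MADRS[1], m$MADRS[2], mix(rho_c), 0, 60),
    STAI_state = .truncDraw(m$STAI_state[1], m$STAI_state[2], mix(rho_s), 20, 80),
    STAI_trait = .truncDraw(m$STAI_trait[1], m$STAI_trait[2], mix(rho_s), 20, 80),
    MMSE = .truncDraw(m$MMSE[1], m$MMSE[2], stats::rnorm(1), 0, 30))
}

#' Generate a synthetic cohort
#'
#' Draws `2 * nPerGroup` subjects (MDD first, then HC), each with clinical
#' covariates, a resting-state recording and a TMS-EEG recording, with the
#' spec's planted effects realized per subject. The cohort is a deterministic
#' function of the spec (including its seed).
#'
#' @param spec a [CohortSpec-class].
#' @return list of [SubjectRecord-class] objects.
#' @examples
#' spec <- fastCohortSpec(nPerGroup = 2, seed = 1, restDuration = 12,
#'                        nPulses = 3)
#' cohort <- generateCohort(spec)
#' length(cohort)
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  n <- spec@nPerGroup
  groups <- rep(c("MDD", "HC"), each = n)
  ids <- sprintf("S%03d", seq_len(2 * n))
  set.seed(spec@seed)
  subjSeeds <- sample.int(.Machine$integer.max - 1, 2 * n)
  ## clinical coupling: the AFz-beta latent carries rho_a of the severity
  ## variable; MADRS carries rho_c, STAI rho_s. The products, attenuated by
  ## feature-estimation noise (factor calibrated by simulation), give the
  ## target Spearman correlations (MADRS 0.28, STAI ~0.36).
  rho_a <- 0.80
  atten <- 0.90
  rho_c <- min(1, spec@madrsCoupling / (rho_a * atten))
  rho_s <- min(1, 0.365 / (rho_a * atten))
  lapply(seq_len(2 * n), function(k) {
    set.seed(subjSeeds[k])
    u <- stats::rnorm(1)
    latents <- .effectLatents(spec@effectTable, groups[k], u, rho_a)
    clinical <- .drawClinical(spec@clinicalModel, groups[k], u, rho_c, rho_s)
    resting <- .generateRestRecording(spec, groups[k], latents, ids[k])
    tms <- generateTMSRecording(spec, groups[k], latents, ids[k])
    new("SubjectRecord", subjectId = ids[k], group = groups[k],
        clinical = clinical, resting = resting, tms = tms)
  })
}
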