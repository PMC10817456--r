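## Shared fixtures, built once per test run and cached. All synthetic data
## are generated in code at test time; sizes are kept small so the whole
## suite stays fast.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

## Reduced-scale evaluation profile used across tests: lower sampling rate
## (still resolving gamma), 3 resting epochs, 24 pulses, ICA off (no
## artifacts are injected).
testSpec <- function(nPerGroup, seed, fs = 400, restDuration = 18,
                     nPulses = 24, ...) {
  fastCohortSpec(nPerGroup = nPerGroup, seed = seed, fs = fs,
                 restDuration = restDuration, nPulses = nPulses, ...)
}

testPreproc <- function(...) {
  preprocConfig(run_ica = FALSE, target_fs = 400, ...)
}

## A small planted cohort and its feature table (shared by synthetic-data,
## feature and selection tests).
plantedTable <- function() {
  fixture("plantedTable", function() {
    coh <- generateCohort(testSpec(nPerGroup = 12, seed = 402))
    buildFeatureTable(coh, testPreproc())
  })
}

## The five planted feature names in canonical (montage-ordered) form.
plantedFeatures <- function() {
  vapply(defaultEffectTable()$feature, canonicalFeatureName, "",
         USE.NAMES = FALSE)
}

## Pure sinusoid helper.
sine <- function(freq, fs, dur, phase = 0) {
  sin(2 * pi * freq * seq(0, dur - 1 / fs, by = 1 / fs) + phase)
}

## A resting-style recording holding given channel data.
recordingOf <- function(data, fs, markers = integer(0)) {
  chn <- paste0("C", seq_len(nrow(data)))
  eegRecording(data, fs, chn, markers = markers, subjectId = "fixture")
}

## Minimal EDF writer used as an independent fixture generator for the EDF
## reader (constructs the byte layout directly from the format definition).
writeTestEdf <- function(path, signals, fs, annotations = NULL) {
  ## signals: channels x samples matrix; one data record per second
  nch <- nrow(signals)
  nrec <- ncol(signals) / fs
  stopifnot(nrec == round(nrec))
  hasAnn <- !is.null(annotations)
  ns <- nch + as.integer(hasAnn)
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(pad(x, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr("test patient", 80); wr("test recording", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 * (1 + ns), 8); wr(if (hasAnn) "EDF+C" else "", 44)
  wr(nrec, 8); wr(1, 8); wr(ns, 4)
  labs <- c(paste0("EEG C", seq_len(nch)), if (hasAnn) "EDF Annotations")
  for (l in labs) wr(l, 16)
  for (i in 1:ns) wr("", 80)               # transducer
  for (i in 1:ns) wr("uV", 8)              # dimension
  for (i in 1:ns) wr(-3277, 8)             # physical min (0.1 uV/bit)
  for (i in 1:ns) wr(3276.7, 8)            # physical max
  for (i in 1:ns) wr(-32770, 8)            # digital min
  for (i in 1:ns) wr(32767, 8)             # digital max
  for (i in 1:ns) wr("", 80)               # prefiltering
  nann <- 60                                # 2-byte samples per record
  for (i in 1:ns) wr(if (i <= nch) fs else nann, 8)
  for (i in 1:ns) wr("", 32)
  gain <- (3276.7 - (-3277)) / (32767 - (-32770))
  for (r in seq_len(nrec)) {
    for (i in seq_len(nch)) {
      seg <- signals[i, ((r - 1) * fs + 1):(r * fs)]
      dig <- as.integer(round((seg - (-3277)) / gain + (-32770)))
      writeBin(dig, con, size = 2, endian = "little")
    }
    if (hasAnn) {
      tal <- sprintf("+%d\x14\x14", r - 1)      # record time-keeping TAL
      for (on in annotations[annotations >= r - 1 & annotations < r]) {
        tal <- paste0(tal, sprintf("+%g\x15%g\x14TMS\x14", on, 0))
      }
      raw <- charToRaw(tal)
      raw <- c(raw, raw(2 * nann - length(raw)))
      writeBin(raw, con)
    }
  }
  invisible(path)
}
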