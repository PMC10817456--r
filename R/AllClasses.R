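#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Continuous multichannel EEG recording
#'
#' Holds a channels x samples matrix in microvolts together with the sampling
#' rate, ordered channel names and (for TMS-EEG) the sample indices of the
#' stimulation pulses.
#'
#' @slot data numeric matrix, channels x samples, microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelNames ordered, unique channel names (rows of `data`).
#' @slot markers strictly increasing pulse sample indices (empty for
#'   resting-state recordings).
#' @slot subjectId identifier of the recorded subject.
#' @export
setClass("EEGRecording",
  slots = c(data = "matrix", fs = "numeric", channelNames = "character",
            markers = "integer", subjectId = "character"))

setValidity("EEGRecording", function(object) {
  msg <- character(0)
  if (nrow(object@data) != length(object@channelNames)) {
    msg <- c(msg, "nrow(data) must equal length(channelNames)")
  }
  if (anyDuplicated(object@channelNames)) {
    msg <- c(msg, "channel names must be unique")
  }
  if (length(object@fs) != 1 || object@fs <= 0) {
    msg <- c(msg, "fs must be a positive scalar")
  }
  m <- object@markers
  if (length(m) > 0) {
    if (is.unsorted(m, strictly = TRUE)) {
      msg <- c(msg, "markers must be strictly increasing")
    }
    if (min(m) < 1 || max(m) > ncol(object@data)) {
      msg <- c(msg, "markers must lie within the recording")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate in Hz.
#' @param channelNames ordered channel names.
#' @param markers integer sample indices of TMS pulses.
#' @param subjectId subject identifier.
#' @return an [EEGRecording-class] object.
#' @export
eegRecording <- function(data, fs, channelNames = rownames(data),
                         markers = integer(0), subjectId = "unknown") {
  if (is.null(channelNames)) stop("channelNames are required")
  rownames(data) <- channelNames
  new("EEGRecording", data = data, fs = fs,
      channelNames = as.character(channelNames),
      markers = as.integer(markers), subjectId = subjectId)
}

#' Epoched EEG data
#'
#' A 3-D container (epochs x channels x samples) with the epoch window
#' definition relative to the epoch anchor (recording start for resting
#' epochs, the TMS pulse for stimulus-locked epochs) and an append-only
#' provenance trail of the preprocessing steps applied.
#'
#' @slot data numeric array, epochs x channels x samples.
#' @slot fs sampling rate in Hz.
#' @slot window numeric length-2, `(start_s, end_s)` relative to the anchor;
#'   half-open `[start, end)`.
#' @slot channelNames ordered channel names.
#' @slot keptEpochs identifiers of the surviving epochs (indices into the
#'   original epoch sequence).
#' @slot provenance ordered character vector naming each applied step.
#' @export
setClass("EpochSet",
  slots = c(data = "array", fs = "numeric", window = "numeric",
            channelNames = "character", keptEpochs = "integer",
            provenance = "character"))

setValidity("EpochSet", function(object) {
  msg <- character(0)
  d <- dim(object@data)
  if (length(d) != 3) msg <- c(msg, "data must be epochs x channels x samples")
  if (length(object@window) != 2 || diff(object@window) <= 0) {
    msg <- c(msg, "window must be (start_s, end_s) with start < end")
  } else if (length(d) == 3 &&
             d[3] != round(diff(object@window) * object@fs)) {
    msg <- c(msg, "sample count must equal round((end-start)*fs)")
  }
  if (length(d) == 3 && d[2] != length(object@channelNames)) {
    msg <- c(msg, "channel dimension must match channelNames")
  }
  if (length(d) == 3 && d[1] != length(object@keptEpochs)) {
    msg <- c(msg, "keptEpochs must identify every epoch")
  }
  if (length(msg)) msg else TRUE
})

epochSet <- function(data, fs, window, channelNames,
                     keptEpochs = seq_len(dim(data)[1]),
                     provenance = character(0)) {
  new("EpochSet", data = data, fs = fs, window = as.numeric(window),
      channelNames = as.character(channelNames),
      keptEpochs = as.integer(keptEpochs), provenance = provenance)
}

## Append a provenance entry, returning a modified copy.
addProvenance <- function(epochs, step) {
  epochs@provenance <- c(epochs@provenance, step)
  epochs
}

#' Subjects-by-features table with group labels and clinical covariates
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with one assay
#' (`features`, features x subjects) and clinical covariates in `colData`.
#' Feature names follow the grammar `<SET>_<KIND>_<LOC>_<BAND>`.
#'
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  msg <- character(0)
  cd <- colData(object)
  if (!"group" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain a 'group' column")
  } else if (!all(cd$group %in% c("MDD", "HC"))) {
    msg <- c(msg, "group labels must be 'MDD' or 'HC'")
  }
  if (anyDuplicated(rownames(object))) {
    msg <- c(msg, "feature names must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureTable
#'
#' @param values subjects x features numeric matrix with feature names as
#'   column names and subject ids as row names.
#' @param group character/factor of `"MDD"`/`"HC"` labels, one per subject.
#' @param covariates data.frame of clinical covariates (age, MADRS, STAI,
#'   MMSE, ...), one row per subject. Optional.
#' @return a [FeatureTable-class].
#' @export
featureTable <- function(values, group, covariates = NULL) {
  stopifnot(nrow(values) == length(group))
  cd <- DataFrame(group = as.character(group))
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == nrow(values))
    cd <- cbind(cd, DataFrame(covariates))
  }
  rownames(cd) <- rownames(values)
  se <- SummarizedExperiment(assays = list(features = t(values)), colData = cd)
  new("FeatureTable", se)
}

#' Specification of a synthetic two-group cohort
#'
#' Defaults reproduce the study protocol: 60 subjects per group, 3 kHz
#' acquisition over the 17-channel frontal montage, 5 min of eyes-closed
#' resting EEG and 80 single TMS pulses, with the five reported group
#' effects planted at standardized effect size 1.2 and clinical covariates
#' drawn from the reported per-group distributions.
#'
#' @slot nPerGroup subjects per group.
#' @slot seed integer seed; the cohort is a deterministic function of the
#'   full specification including the seed.
#' @slot fs generation sampling rate in Hz.
#' @slot channels ordered channel names.
#' @slot restDuration resting recording length in seconds.
#' @slot nPulses number of single TMS pulses.
#' @slot interPulse mean inter-pulse interval in seconds (jittered +-10%).
#' @slot effectTable data.frame of planted effects (columns `feature`,
#'   `direction`, `magnitude`, `mechanism`).
#' @slot clinicalModel per-group mean/sd of age, MADRS, STAI and MMSE.
#' @slot artifactBlink,artifactDecay inject blink-like transients / TMS
#'   decay artifacts.
#' @slot madrsCoupling target Spearman correlation, within the MDD group,
#'   between the AFz-beta power effect magnitude and the MADRS score.
#' @export
setClass("CohortSpec",
  slots = c(nPerGroup = "integer", seed = "integer", fs = "numeric",
            channels = "character", restDuration = "numeric",
            nPulses = "integer", interPulse = "numeric",
            effectTable = "data.frame", clinicalModel = "list",
            artifactBlink = "logical", artifactDecay = "logical",
            madrsCoupling = "numeric"))

setValidity("CohortSpec", function(object) {
  msg <- character(0)
  if (object@nPerGroup < 2) msg <- c(msg, "nPerGroup must be >= 2")
  if (object@fs < 200) msg <- c(msg, "fs must be >= 200 Hz to resolve gamma")
  if (object@restDuration < 12) {
    msg <- c(msg, "restDuration must cover at least two 6 s epochs (>= 12 s)")
  }
  if (object@nPulses < 1) msg <- c(msg, "nPulses must be >= 1")
  if (object@interPulse < 4) {
    msg <- c(msg, "interPulse must be >= 4 s so 4 s epochs do not overlap")
  }
  et <- object@effectTable
  if (nrow(et) > 0) {
    need <- c("feature", "direction", "magnitude", "mechanism")
    if (!all(need %in% colnames(et))) {
      msg <- c(msg, "effectTable needs columns feature/direction/magnitude/mechanism")
    } else {
      if (any(et$magnitude < 0)) msg <- c(msg, "effect magnitudes must be >= 0")
      if (!all(et$direction %in% c("MDD_higher", "MDD_lower"))) {
        msg <- c(msg, "effect direction must be MDD_higher or MDD_lower")
      }
      ok <- vapply(et$feature, function(f) {
        p <- tryCatch(parseFeatureName(f), error = function(e) NULL)
        if (is.null(p)) return(FALSE)
        chans <- if (p$kind == "wPLI") p$chans else if (p$kind == "MI") character(0) else p$loc
        all(chans %in% object@channels)
      }, logical(1))
      if (!all(ok)) {
        msg <- c(msg, paste0("effectTable features unparseable or naming unknown channels: ",
                             paste(et$feature[!ok], collapse = ", ")))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic subject: labels, clinical scores and both recordings
#'
#' @slot subjectId identifier.
#' @slot group `"MDD"` or `"HC"`.
#' @slot clinical named numeric vector (age, MADRS, STAI_state, STAI_trait,
#'   MMSE).
#' @slot resting resting-state [EEGRecording-class].
#' @slot tms TMS-EEG [EEGRecording-class] with one marker per pulse.
#' @export
setClass("SubjectRecord",
  slots = c(subjectId = "character", group = "character",
            clinical = "numeric", resting = "EEGRecording",
            tms = "EEGRecording"))

setValidity("SubjectRecord", function(object) {
  msg <- character(0)
  if (!object@group %in% c("MDD", "HC")) msg <- c(msg, "group must be MDD or HC")
  cl <- object@clinical
  if (!all(c("age", "MADRS", "STAI_state", "STAI_trait", "MMSE") %in% names(cl))) {
    msg <- c(msg, "clinical must contain age, MADRS, STAI_state, STAI_trait, MMSE")
  } else {
    if (cl["MADRS"] < 0 || cl["MADRS"] > 60) msg <- c(msg, "MADRS out of range 0-60")
    if (cl["MMSE"] < 0 || cl["MMSE"] > 30) msg <- c(msg, "MMSE out of range 0-30")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording '%s': %d channels x %d samples @ %g Hz (%.1f s), %d markers\n",
              object@subjectId, nrow(object@data), ncol(object@data),
              object@fs, ncol(object@data) / object@fs, length(object@markers)))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d epochs x %d channels x %d samples @ %g Hz, window [%g, %g) s\n",
              d[1], d[2], d[3], object@fs, object@window[1], object@window[2]))
  if (length(object@provenance)) {
    cat("  provenance:", paste(object@provenance, collapse = " -> "), "\n")
  }
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d+%d subjects, %d channels @ %g Hz, rest %g s, %d pulses, %d planted effects (seed %d)\n",
              object@nPerGroup, object@nPerGroup, length(object@channels),
              object@fs, object@restDuration, object@nPulses,
              nrow(object@effectTable), object@seed))
})

setMethod("show", "SubjectRecord", function(object) {
  cat(sprintf("SubjectRecord '%s' (%s): MADRS %.1f, age %.1f\n",
              object@subjectId, object@group,
              object@clinical["MADRS"], object@clinical["age"]))
})
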