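#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("pulseMarkers", function(x) standardGeneric("pulseMarkers"))
#' @rdname accessors
#' @export
setGeneric("recordingData", function(x) standardGeneric("recordingData"))
#' @rdname accessors
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setGeneric("epochWindow", function(x) standardGeneric("epochWindow"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))
#' @rdname accessors
#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))

#' Accessors for the pipeline's data classes
#'
#' `channelNames`, `samplingRate`, `pulseMarkers` and `recordingData` read
#' the corresponding slots of an [EEGRecording-class] (also available on an
#' [EpochSet-class] where they apply); `epochData`, `epochWindow`,
#' `provenance` and `nEpochs` read an [EpochSet-class]; `featureValues`
#' (subjects x features matrix), `groupLabels` and `clinicalData` read a
#' [FeatureTable-class].
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
setMethod("channelNames", "EEGRecording", function(x) x@channelNames)
#' @rdname accessors
setMethod("channelNames", "EpochSet", function(x) x@channelNames)
#' @rdname accessors
setMethod("samplingRate", "EEGRecording", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "EpochSet", function(x) x@fs)
#' @rdname accessors
setMethod("pulseMarkers", "EEGRecording", function(x) x@markers)
#' @rdname accessors
setMethod("recordingData", "EEGRecording", function(x) x@data)
#' @rdname accessors
setMethod("epochData", "EpochSet", function(x) x@data)
#' @rdname accessors
setMethod("epochWindow", "EpochSet", function(x) x@window)
#' @rdname accessors
setMethod("provenance", "EpochSet", function(x) x@provenance)
#' @rdname accessors
setMethod("nEpochs", "EpochSet", function(x) dim(x@data)[1])
#' @rdname accessors
setMethod("featureValues", "FeatureTable", function(x) t(assay(x, "features")))
#' @rdname accessors
setMethod("groupLabels", "FeatureTable",
          function(x) factor(colData(x)$group, levels = c("HC", "MDD")))
#' @rdname accessors
setMethod("clinicalData", "FeatureTable", function(x) {
  cd <- as.data.frame(colData(x))
  cd[, setdiff(colnames(cd), "group"), drop = FALSE]
})

#' Restrict a FeatureTable to some feature modalities
#'
#' @param x a [FeatureTable-class].
#' @param sets subset of `c("RST", "PRE", "PST", "DIF")`.
#' @return a [FeatureTable-class] with only the requested modalities.
#' @export
subsetFeatureSets <- function(x, sets) {
  stopifnot(all(sets %in% featureSets()))
  pref <- vapply(strsplit(rownames(x), "_", fixed = TRUE), `[`, "", 1)
  x[pref %in% sets, ]
}
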