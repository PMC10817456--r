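## Frontal montage, oscillatory band definitions and the feature-name
## grammar `<SET>_<KIND>_<LOC>_<BAND>` used across the pipeline.

#' The 17-electrode frontal montage
#'
#' The smallest standard 10-10 frontal electrode set of size 17 that contains
#' every electrode appearing in the group-difference findings (AFz, F6, F4,
#' F5, AF3, F8) and the left-DLPFC PAC region (F3, F5, AF3).
#'
#' @return character vector of 17 channel names, in montage order.
#' @export
frontalMontage <- function() {
  c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8")
}

#' Left-DLPFC electrode region used for phase-amplitude coupling
#' @return character vector of electrode names.
#' @export
dlpfcRegion <- function() c("F3", "F5", "AF3")

#' Oscillatory band definitions
#'
#' theta 4-7 Hz, alpha 8-13 Hz, beta 14-30 Hz, gamma 30-45 Hz.
#'
#' @return data.frame with columns `name`, `lo`, `hi`.
#' @export
eegBands <- function() {
  data.frame(name = c("theta", "alpha", "beta", "gamma"),
             lo = c(4, 8, 14, 30), hi = c(7, 13, 30, 45),
             stringsAsFactors = FALSE)
}

## Phase-amplitude couplings extracted as features: theta-gamma and
## alpha-gamma, averaged over the left-DLPFC region.
pacCouplings <- function() {
  data.frame(tag = c("thetagamma", "alphagamma"),
             phase = c("theta", "alpha"), amp = c("gamma", "gamma"),
             stringsAsFactors = FALSE)
}

#' The four feature modalities
#' @return `c("RST", "PRE", "PST", "DIF")`.
#' @export
featureSets <- function() c("RST", "PRE", "PST", "DIF")

#' Feature names of one modality
#'
#' Enumerates the 614 feature names of a single modality: 17 x 4 band powers,
#' C(17,2) = 136 channel pairs x 4 band wPLI values, and 2 region-averaged
#' PAC modulation indices. Channel pairs are named `<chA>-<chB>` with `chA`
#' preceding `chB` in montage order.
#'
#' @param set one of `"RST"`, `"PRE"`, `"PST"`, `"DIF"`.
#' @param channels channel names in montage order.
#' @return character vector of feature names.
#' @export
modalityFeatureNames <- function(set, channels = frontalMontage()) {
  stopifnot(set %in% featureSets())
  bands <- eegBands()$name
  power <- as.vector(t(outer(channels, bands,
                             function(ch, b) paste(set, "power", ch, b, sep = "_"))))
  nc <- length(channels)
  pairs <- character(0)
  for (i in seq_len(nc - 1)) {
    for (j in (i + 1):nc) {
      pairs <- c(pairs, paste0(channels[i], "-", channels[j]))
    }
  }
  wpli <- as.vector(t(outer(pairs, bands,
                            function(p, b) paste(set, "wPLI", p, b, sep = "_"))))
  mi <- paste(set, "MI", "lDLPFC", pacCouplings()$tag, sep = "_")
  c(power, wpli, mi)
}

#' Parse a feature name into its components
#'
#' @param name feature name following `<SET>_<KIND>_<LOC>_<BAND>`.
#' @return list with `set`, `kind`, `loc`, `band`, and for wPLI features the
#'   channel pair in `chans`.
#' @export
parseFeatureName <- function(name) {
  parts <- strsplit(name, "_", fixed = TRUE)[[1]]
  if (length(parts) != 4) stop("unparseable feature name: ", name)
  out <- list(set = parts[1], kind = parts[2], loc = parts[3], band = parts[4])
  if (!out$set %in% featureSets()) stop("unknown feature set in: ", name)
  if (!out$kind %in% c("power", "wPLI", "MI")) stop("unknown feature kind in: ", name)
  if (out$kind == "wPLI") out$chans <- strsplit(out$loc, "-", fixed = TRUE)[[1]]
  out
}

#' Canonicalize a feature name against a montage
#'
#' wPLI pair locations are reordered so the first channel precedes the second
#' in montage order (`F6-F4` and `F4-F6` refer to the same feature).
#'
#' @param name feature name.
#' @param channels montage, in order.
#' @return canonical feature name.
#' @export
canonicalFeatureName <- function(name, channels = frontalMontage()) {
  p <- parseFeatureName(name)
  if (p$kind != "wPLI") return(name)
  idx <- match(p$chans, channels)
  if (anyNA(idx)) stop("unknown channel in feature name: ", name)
  chans <- p$chans[order(idx)]
  paste(p$set, "wPLI", paste(chans, collapse = "-"), p$band, sep = "_")
}

## Look up a band definition by name.
bandByName <- function(name) {
  b <- eegBands()
  row <- b[b$name == name, ]
  if (nrow(row) != 1) stop("unknown band: ", name)
  row
}
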