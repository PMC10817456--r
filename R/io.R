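## Recording and table I/O. The internal container is a directory with a
## JSON sidecar header and a raw little-endian float64 payload (sample-
## multiplexed). BrainVision support covers the .vhdr/.vmrk/.eeg triplet
## (IEEE float32 and int16, multiplexed); EDF/EDF+ support is read-only
## with marker extraction from the annotations channel.

#' Write a recording to the internal container format
#'
#' @param rec an [EEGRecording-class].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writeRecordingInternal <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  header <- list(format = "tmseegdx-raw-v1", subject = rec@subjectId,
                 fs = rec@fs, channels = rec@channelNames,
                 n_samples = ncol(rec@data), markers = rec@markers,
                 dtype = "float64le", order = "multiplexed")
  jsonlite::write_json(header, file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(dir, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec@data), con, size = 8, endian = "little")
  invisible(dir)
}

#' Read a recording from the internal container format
#'
#' @param dir directory written by [writeRecordingInternal()].
#' @return an [EEGRecording-class]; the payload round-trips bit-identically.
#' @export
readRecordingInternal <- function(dir) {
  hpath <- file.path(dir, "header.json")
  if (!file.exists(hpath)) stop("not an internal recording container: ", dir)
  h <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  nch <- length(h$channels)
  con <- file(file.path(dir, "data.bin"), "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = nch * h$n_samples, size = 8,
               endian = "little")
  eegRecording(matrix(v, nch, h$n_samples), as.numeric(h$fs), h$channels,
               markers = as.integer(h$markers),
               subjectId = as.character(h$subject))
}

#' Export a recording as a BrainVision triplet
#'
#' Writes `<base>.vhdr`, `<base>.vmrk` and `<base>.eeg` (multiplexed IEEE
#' float32, 1 uV resolution). Markers are written as Stimulus entries.
#'
#' @param rec an [EEGRecording-class].
#' @param base path without extension.
#' @return `base`, invisibly.
#' @export
writeBrainVision <- function(rec, base) {
  nch <- nrow(rec@data)
  vhdr <- c("Brain Vision Data Exchange Header File Version 1.0",
            "", "[Common Infos]", "Codepage=UTF-8",
            paste0("DataFile=", basename(base), ".eeg"),
            paste0("MarkerFile=", basename(base), ".vmrk"),
            "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
            paste0("NumberOfChannels=", nch),
            paste0("SamplingInterval=", format(1e6 / rec@fs, digits = 12)),
            "", "[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32",
            "", "[Channel Infos]",
            sprintf("Ch%d=%s,,1,µV", seq_len(nch), rec@channelNames))
  writeLines(vhdr, paste0(base, ".vhdr"), useBytes = TRUE)
  vmrk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
            "", "[Common Infos]", "Codepage=UTF-8",
            paste0("DataFile=", basename(base), ".eeg"),
            "", "[Marker Infos]",
            "Mk1=New Segment,,1,1,0,00000000000000000000")
  if (length(rec@markers) > 0) {
    vmrk <- c(vmrk, sprintf("Mk%d=Stimulus,S  1,%d,1,0",
                            seq_along(rec@markers) + 1L, rec@markers))
  }
  writeLines(vmrk, paste0(base, ".vmrk"), useBytes = TRUE)
  con <- file(paste0(base, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec@data), con, size = 4, endian = "little")
  invisible(base)
}

## Parse a BrainVision INI-style section into key=value pairs.
.bvSection <- function(lines, section) {
  hdr <- grep(paste0("^\\[", section, "\\]"), lines)
  if (length(hdr) == 0) return(character(0))
  body <- lines[(hdr[1] + 1):length(lines)]
  nxt <- grep("^\\[", body)
  if (length(nxt) > 0) body <- body[seq_len(nxt[1] - 1)]
  body[grepl("=", body, fixed = TRUE)]
}

.bvValue <- function(kv, key) {
  hit <- grep(paste0("^", key, "="), kv, value = TRUE)
  if (length(hit) == 0) return(NA_character_)
  sub(paste0("^", key, "="), "", hit[1])
}

#' Read a BrainVision recording
#'
#' Supports multiplexed binary data in IEEE_FLOAT_32 or INT_16 (scaled by
#' the per-channel resolution) and extracts Stimulus markers from the
#' marker file.
#'
#' @param vhdr path to the `.vhdr` header file.
#' @return an [EEGRecording-class].
#' @export
readBrainVision <- function(vhdr) {
  if (!file.exists(vhdr)) stop("header file not found: ", vhdr)
  lines <- readLines(vhdr, warn = FALSE, encoding = "UTF-8")
  common <- .bvSection(lines, "Common Infos")
  binary <- .bvSection(lines, "Binary Infos")
  chinfo <- .bvSection(lines, "Channel Infos")
  orient <- .bvValue(common, "DataOrientation")
  if (!is.na(orient) && toupper(orient) != "MULTIPLEXED") {
    stop("only MULTIPLEXED BrainVision data are supported (", vhdr, ")")
  }
  nch <- as.integer(.bvValue(common, "NumberOfChannels"))
  sampint <- as.numeric(.bvValue(common, "SamplingInterval"))
  if (is.na(nch) || is.na(sampint)) {
    stop("malformed BrainVision header (NumberOfChannels/SamplingInterval): ",
         vhdr)
  }
  fs <- 1e6 / sampint
  fmt <- toupper(.bvValue(binary, "BinaryFormat"))
  parts <- strsplit(sub("^Ch[0-9]+=", "", chinfo), ",")
  chans <- vapply(parts, `[`, "", 1)
  res <- vapply(parts, function(p) {
    r <- suppressWarnings(as.numeric(p[3]))
    if (is.na(r)) 1 else r
  }, numeric(1))
  dataFile <- file.path(dirname(vhdr), .bvValue(common, "DataFile"))
  sz <- file.info(dataFile)$size
  con <- file(dataFile, "rb")
  on.exit(close(con))
  if (identical(fmt, "IEEE_FLOAT_32")) {
    v <- readBin(con, "double", n = sz / 4, size = 4, endian = "little")
  } else if (identical(fmt, "INT_16")) {
    v <- readBin(con, "integer", n = sz / 2, size = 2, signed = TRUE,
                 endian = "little")
  } else {
    stop("unsupported BinaryFormat '", fmt, "' in ", vhdr)
  }
  nsamp <- length(v) %/% nch
  M <- matrix(v[seq_len(nsamp * nch)], nch, nsamp)
  M <- M * res
  vmrk <- file.path(dirname(vhdr), .bvValue(common, "MarkerFile"))
  markers <- integer(0)
  if (!is.na(vmrk) && file.exists(vmrk)) {
    ml <- .bvSection(readLines(vmrk, warn = FALSE), "Marker Infos")
    stim <- grep("=Stimulus,", ml, value = TRUE, fixed = TRUE)
    markers <- vapply(strsplit(sub("^Mk[0-9]+=", "", stim), ","),
                      function(p) as.integer(p[3]), integer(1))
    markers <- sort(markers)
  }
  eegRecording(M, fs, chans, markers = markers,
               subjectId = sub("\\.vhdr$", "", basename(vhdr)))
}

#' Read an EDF/EDF+ recording
#'
#' Parses the EDF header and data records, scales digital values to
#' physical units, and extracts event markers from the `EDF Annotations`
#' channel when present (annotation onsets in seconds are converted to
#' sample indices at the signal sampling rate).
#'
#' @param path path to the `.edf` file.
#' @return an [EEGRecording-class] (annotation channels excluded).
#' @export
readEdf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rdStr <- function(n) {
    trimws(rawToChar(readBin(con, "raw", n)))
  }
  rdStr(8)                     # version
  rdStr(80); rdStr(80)         # patient, recording ids
  rdStr(8); rdStr(8)           # start date, time
  as.integer(rdStr(8))         # header bytes
  rdStr(44)                    # reserved
  nrec <- as.integer(rdStr(8))
  recdur <- as.numeric(rdStr(8))
  ns <- as.integer(rdStr(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header (signal count): ", path)
  labels <- vapply(seq_len(ns), function(i) rdStr(16), "")
  for (i in seq_len(ns)) rdStr(80)   # transducer
  for (i in seq_len(ns)) rdStr(8)    # dimension
  physMin <- vapply(seq_len(ns), function(i) as.numeric(rdStr(8)), 0)
  physMax <- vapply(seq_len(ns), function(i) as.numeric(rdStr(8)), 0)
  digMin <- vapply(seq_len(ns), function(i) as.numeric(rdStr(8)), 0)
  digMax <- vapply(seq_len(ns), function(i) as.numeric(rdStr(8)), 0)
  for (i in seq_len(ns)) rdStr(80)   # prefiltering
  nsampPer <- vapply(seq_len(ns), function(i) as.integer(rdStr(8)), 0L)
  for (i in seq_len(ns)) rdStr(32)   # reserved

  isAnn <- labels == "EDF Annotations"
  sig <- which(!isAnn)
  if (length(sig) == 0) stop("EDF file contains no signal channels: ", path)
  if (length(unique(nsampPer[sig])) != 1) {
    stop("EDF signals with heterogeneous sampling rates are not supported")
  }
  fs <- nsampPer[sig[1]] / recdur
  out <- matrix(0, length(sig), nrec * nsampPer[sig[1]])
  annRaw <- raw(0)
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      if (isAnn[i]) {
        annRaw <- c(annRaw, readBin(con, "raw", nsampPer[i] * 2))
      } else {
        v <- readBin(con, "integer", n = nsampPer[i], size = 2,
                     signed = TRUE, endian = "little")
        gain <- (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
        row <- match(i, sig)
        col0 <- (r - 1) * nsampPer[i]
        out[row, (col0 + 1):(col0 + nsampPer[i])] <-
          physMin[i] + (v - digMin[i]) * gain
      }
    }
  }
  markers <- integer(0)
  if (length(annRaw) > 0) {
    txt <- rawToChar(annRaw[annRaw != as.raw(0)])
    ## TALs: "+<onset>\x15<dur>\x14<text>\x14"; events carry non-empty text
    tals <- strsplit(txt, "\x14\x14", fixed = TRUE)[[1]]
    onsets <- unlist(lapply(tals, function(t) {
      fields <- strsplit(t, "\x14", fixed = TRUE)[[1]]
      if (length(fields) < 2) return(numeric(0))
      on <- suppressWarnings(as.numeric(sub("\x15.*$", "", fields[1])))
      if (is.na(on)) numeric(0) else on
    }))
    markers <- sort(unique(round(onsets * fs)))
    markers <- markers[markers >= 1 & markers <= ncol(out)]
  }
  eegRecording(out, fs, labels[sig], markers = as.integer(markers),
               subjectId = sub("\\.edf$", "", basename(path),
                               ignore.case = TRUE))
}

#' Read a recording in any supported format
#'
#' @param path file (`.vhdr`, `.edf`) or internal container directory.
#' @param format `"internal"`, `"brainvision"` or `"edf"`; guessed from the
#'   path by default.
#' @return an [EEGRecording-class].
#' @export
readRecording <- function(path, format = c("auto", "internal",
                                           "brainvision", "edf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "internal"
    else if (grepl("\\.vhdr$", path, ignore.case = TRUE)) "brainvision"
    else if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
    else stop("cannot guess the format of ", path)
  }
  switch(format,
         internal = readRecordingInternal(path),
         brainvision = readBrainVision(path),
         edf = readEdf(path))
}

#' Write a cohort to disk
#'
#' One internal-container directory pair per subject (`<id>/resting`,
#' `<id>/tms`) plus a cohort-level `clinical.tsv` of labels and covariates.
#'
#' @param cohort list of [SubjectRecord-class] objects.
#' @param dir output directory.
#' @param brainvision additionally export each recording as a BrainVision
#'   triplet.
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir, brainvision = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(s) {
    sd <- file.path(dir, s@subjectId)
    writeRecordingInternal(s@resting, file.path(sd, "resting"))
    writeRecordingInternal(s@tms, file.path(sd, "tms"))
    if (brainvision) {
      writeBrainVision(s@resting, file.path(sd, "resting"))
      writeBrainVision(s@tms, file.path(sd, "tms"))
    }
    data.frame(subject = s@subjectId, group = s@group,
               t(s@clinical), check.names = FALSE)
  })
  utils::write.table(do.call(rbind, rows), file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Serialize a FeatureTable as TSV plus a JSON sidecar
#'
#' @param table a [FeatureTable-class].
#' @param base path without extension; writes `<base>.tsv` (subjects x
#'   features) and `<base>.json` (labels and covariates).
#' @return `base`, invisibly.
#' @export
writeFeatureTable <- function(table, base) {
  X <- featureValues(table)
  df <- data.frame(subject = rownames(X), X, check.names = FALSE)
  utils::write.table(df, paste0(base, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- list(group = as.character(groupLabels(table)),
               covariates = clinicalData(table))
  jsonlite::write_json(side, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(base)
}

#' Read a FeatureTable written by [writeFeatureTable()]
#' @param base path without extension.
#' @return a [FeatureTable-class].
#' @export
readFeatureTable <- function(base) {
  df <- utils::read.table(paste0(base, ".tsv"), sep = "\t", header = TRUE,
                          check.names = FALSE)
  side <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df$subject
  featureTable(X, side$group, as.data.frame(side$covariates))
}
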