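## Plain-text (YAML) run configuration: one file drives simulation,
## preprocessing, screening, cross-validation and output. Validation is
## fail-fast: every referenced electrode must exist in the montage before
## any computation starts.

#' Read and validate a run configuration file
#'
#' The YAML file may contain the blocks `cohort` (arguments of
#' [cohortSpec()], with `effect_table` as a list of feature/direction/
#' magnitude/mechanism entries), `preproc` ([preprocConfig()] arguments),
#' `cv` ([cvConfig()] arguments), `selection` (`alpha`, `placement`),
#' `models` (subset of the nine ids), `combos` (`"all"`, `"singles"`, or a
#' list of feature-set vectors), and `out_dir`. Omitted blocks get the
#' package defaults, which reproduce the full-scale experiment.
#'
#' @param path YAML file.
#' @return list with validated `spec`, `cfg`, `cv`, `alpha`, `placement`,
#'   `models`, `combos`, `out_dir`.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  co <- y$cohort %||% list()
  if (!is.null(co$channels)) {
    unknown <- setdiff(co$channels, frontalMontage())
    ## custom montages are allowed, but names must look like 10-10 labels
    if (length(unknown) && any(!grepl("^(Fp|AF|F|C|T|P|O)[z0-9]+$", unknown))) {
      stop("config names unknown electrode(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  if (!is.null(co$effect_table)) {
    co$effectTable <- do.call(rbind, lapply(co$effect_table, as.data.frame))
    co$effect_table <- NULL
  }
  names(co) <- sub("^n_per_group$", "nPerGroup", names(co))
  names(co) <- sub("^rest_duration$", "restDuration", names(co))
  names(co) <- sub("^n_pulses$", "nPulses", names(co))
  names(co) <- sub("^inter_pulse$", "interPulse", names(co))
  spec <- do.call(cohortSpec, co)       # validity runs here (fail fast)
  cfg <- do.call(preprocConfig, y$preproc %||% list())
  cv <- do.call(cvConfig, y$cv %||% list())
  selAlpha <- (y$selection %||% list())$alpha %||% 0.01
  placement <- (y$selection %||% list())$placement %||% "per_fold"
  models <- y$models %||% names(modelRegistry())
  combos <- if (is.null(y$combos) || identical(y$combos, "all")) {
    enumerateCombinations()
  } else if (identical(y$combos, "singles")) {
    as.list(featureSets())
  } else {
    lapply(y$combos, unlist)
  }
  for (cmb in combos) stopifnot(all(cmb %in% featureSets()))
  list(spec = spec, cfg = cfg, cv = cv, alpha = selAlpha,
       placement = placement, models = models, combos = combos,
       out_dir = y$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full experiment from a configuration file
#'
#' Reads the configuration (validating it before any compute) and calls
#' [runExperiment()].
#'
#' @param path YAML configuration file.
#' @param ... overrides passed on to [runExperiment()].
#' @return see [runExperiment()].
#' @export
runFromConfig <- function(path, ...) {
  rc <- readRunConfig(path)
  args <- list(spec = rc$spec, cfg = rc$cfg, cv = rc$cv,
               combos = rc$combos, models = rc$models,
               out_dir = rc$out_dir, alpha = rc$alpha,
               placement = rc$placement)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(runExperiment, args)
}
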