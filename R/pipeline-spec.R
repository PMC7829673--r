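#' @include preprocess.R
NULL

#' Construct a preprocessing pipeline specification
#'
#' A pipeline is an ordered list of named steps with parameter maps, applied
#' left to right. Step order and parameters are fully user-configurable; the
#' conventional resting-state order is trim, detrend, motion correction,
#' filter, noise regression, resample.
#'
#' @param steps list of \code{list(name = , params = list(...))} entries, or
#'   a character vector of step names (empty params).
#' @param chromophores chromophore subset the pipeline applies to;
#'   \code{character(0)} (default) = all present.
#' @return a \code{PipelineSpec}.
#' @examples
#' ps <- pipelineSpec(list(
#'   list(name = "detrend", params = list(order = 1)),
#'   list(name = "filter", params = list(kind = "iir_butter", mode = "band",
#'                                       cutoffs = c(0.01, 0.08), order = 3))))
#' @export
pipelineSpec <- function(steps = list(), chromophores = character(0)) {
  if (is.character(steps))
    steps <- lapply(steps, function(s) list(name = s, params = list()))
  steps <- lapply(steps, function(s) {
    if (is.null(s$params)) s$params <- list()
    s[c("name", "params")]
  })
  new("PipelineSpec", steps = steps, chromophores = chromophores)
}

#' Default resting-state preprocessing pipeline
#'
#' trim (none) -> linear detrend -> TDDR motion correction -> third-order
#' Butterworth 0.01-0.08 Hz band-pass, the package's reference resting-state
#' chain.
#'
#' @param band band-pass cutoffs in Hz.
#' @return a \code{PipelineSpec}.
#' @export
defaultRestingPipeline <- function(band = c(0.01, 0.08)) {
  pipelineSpec(list(
    list(name = "detrend", params = list(order = 1)),
    list(name = "tddr", params = list()),
    list(name = "filter", params = list(kind = "iir_butter", mode = "band",
                                        cutoffs = band, order = 3))))
}

#' Serialize / deserialize a pipeline specification
#'
#' Pipelines round-trip losslessly through YAML text, so that a processing
#' protocol can be stored beside the data and re-run.
#'
#' @param spec a \code{PipelineSpec}.
#' @param path file path.
#' @return \code{readPipelineSpec} returns a \code{PipelineSpec}.
#' @export
writePipelineSpec <- function(spec, path) {
  yaml::write_yaml(list(chromophores = as.list(spec@chromophores),
                        steps = spec@steps),
                   path, precision = 15)
  invisible(path)
}

#' @rdname writePipelineSpec
#' @export
readPipelineSpec <- function(path) {
  y <- yaml::read_yaml(path)
  steps <- lapply(y$steps, function(s) {
    s$params <- lapply(s$params, function(p) if (is.list(p)) unlist(p) else p)
    s
  })
  pipelineSpec(steps, chromophores = as.character(unlist(y$chromophores)))
}

#' Apply a preprocessing pipeline to a recording
#'
#' Executes the steps left to right. Built-in steps dispatch to their
#' dedicated functions; any other name is looked up in the custom-step
#' registry. Each step appends exactly one history record, so re-running a
#' serialized pipeline reproduces the output exactly.
#'
#' @param rec a \code{NirsRecording}.
#' @param spec a \code{PipelineSpec}.
#' @return the processed recording.
#' @export
applyPipeline <- function(rec, spec) {
  stopifnot(is(rec, "NirsRecording"), is(spec, "PipelineSpec"))
  for (s in spec@steps) {
    p <- s$params
    rec <- switch(s$name,
      trim = trimRecording(rec,
                           dropStartS = p$drop_start_s %||% 0,
                           dropEndS = p$drop_end_s %||% 0),
      detrend = detrendRecording(rec, order = p$order %||% 1),
      cbsi = motionCorrectCBSI(rec),
      tddr = motionCorrectTDDR(rec),
      filter = applyFilter(rec,
        designFilter(kind = p$kind %||% "iir_butter",
                     mode = p$mode %||% "band",
                     cutoffs = as.numeric(unlist(p$cutoffs %||% c(0.01, 0.08))),
                     fs = samplingRate(rec), order = p$order,
                     keepDC = isTRUE(p$keepDC))),
      regress_noise = regressNoise(rec,
                                   regressorChannels = p$regressor_channels,
                                   external = p$external),
      resample = resampleRecording(rec, newFs = p$new_fs),
      {
        if (!exists(s$name, envir = .stepRegistry))
          stop("unknown pipeline step: '", s$name, "'")
        .applyCustomStep(rec, s$name, p)
      })
  }
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a
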