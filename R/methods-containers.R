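#' @include methods-NirsRecording.R
NULL

#' Construct a ProbeSetup
#'
#' @param sources,detectors data.frames with columns \code{label}, \code{x},
#'   \code{y}.
#' @param pairs two-column matrix of 1-based (source, detector) indices.
#' @return a \code{ProbeSetup}.
#' @export
ProbeSetup <- function(sources, detectors, pairs) {
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "integer"
  colnames(pairs) <- c("source", "detector")
  new("ProbeSetup", sources = sources, detectors = detectors, pairs = pairs)
}

setMethod("show", "ProbeSetup", function(object) {
  cat(sprintf("ProbeSetup: %d sources, %d detectors, %d channels\n",
              nrow(object@sources), nrow(object@detectors),
              nrow(object@pairs)))
})

#' Construct a TaskDesign
#'
#' @param conditions data.frame with columns \code{condition},
#'   \code{onset_s}, \code{duration_s}, or a named list of
#'   \code{list(onsets=, durations=)} entries.
#' @param covariates optional numeric matrix of per-timepoint nuisance series.
#' @param perSubject logical flag for subject-specific designs.
#' @return a \code{TaskDesign}.
#' @export
TaskDesign <- function(conditions, covariates = NULL, perSubject = FALSE) {
  if (is.list(conditions) && !is.data.frame(conditions)) {
    conditions <- do.call(rbind, lapply(names(conditions), function(nm) {
      e <- conditions[[nm]]
      data.frame(condition = nm, onset_s = e$onsets,
                 duration_s = rep_len(e$durations, length(e$onsets)))
    }))
  }
  if (is.null(covariates)) covariates <- matrix(numeric(0), 0, 0)
  new("TaskDesign", conditions = conditions,
      covariates = as.matrix(covariates), perSubject = perSubject)
}

#' @rdname accessors
#' @export
conditionNames <- function(x) unique(x@conditions$condition)

setMethod("show", "TaskDesign", function(object) {
  cat(sprintf("TaskDesign: %d conditions, %d events%s\n",
              length(unique(object@conditions$condition)),
              nrow(object@conditions),
              if (ncol(object@covariates)) sprintf(", %d covariates",
                                                   ncol(object@covariates)) else ""))
})

#' @rdname accessors
#' @export
setMethod("fcValues", "ConnectivityMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("thresholdState", "ConnectivityMatrix", function(x) x@thresholdState)

#' @rdname accessors
#' @export
setMethod("channelInfo", "ConnectivityMatrix", function(x) x@channelIds)

setMethod("show", "ConnectivityMatrix", function(object) {
  st <- object@thresholdState
  cat(sprintf("ConnectivityMatrix (%s): %d x %d, %s%s\n", object@mode,
              nrow(object@values), ncol(object@values),
              if (object@fisherZ) "Fisher z" else "Pearson r",
              if (identical(st$method, "none")) ""
              else sprintf(", thresholded (%s = %g)", st$method, st$value)))
})

#' @rdname accessors
#' @export
setMethod("alffTable", "ALFFResult", function(x) x@table)

setMethod("show", "ALFFResult", function(object) {
  cat(sprintf("ALFFResult: %d channels, band %.3g-%.3g Hz (%d bins)\n",
              nrow(object@table), object@band[1], object@band[2], object@Nk))
})

#' @rdname accessors
#' @export
setMethod("statValues", "ChannelStatMap", function(x) x@stat)

#' @rdname accessors
#' @export
setMethod("pValues", "ChannelStatMap", function(x) x@p)

#' @rdname accessors
#' @export
setMethod("significanceFlags", "ChannelStatMap", function(x) {
  fl <- x@corrected$flags
  if (is.null(fl)) rep(NA, length(x@channelIds)) else fl
})

#' @rdname accessors
#' @export
setMethod("channelInfo", "ChannelStatMap", function(x) x@channelIds)

setMethod("show", "ChannelStatMap", function(object) {
  cat(sprintf("ChannelStatMap (%s): %d channels, df = %s\n", object@model,
              length(object@channelIds),
              paste(signif(object@df, 4), collapse = ", ")))
  if (!identical(object@corrected$method, "none")) {
    cat(sprintf("  corrected: %s (q = %g), %d significant\n",
                object@corrected$method, object@corrected$q,
                sum(object@corrected$flags, na.rm = TRUE)))
  }
})

#' @rdname accessors
#' @export
setMethod("designMatrix", "DesignMatrix", function(x) x@X)

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf("DesignMatrix: %d x %d [%s]\n", nrow(object@X), ncol(object@X),
              paste(object@labels, collapse = ", ")))
})

#' @rdname accessors
#' @export
setMethod("glmBeta", "GLMResult", function(x) x@beta)

setMethod("show", "GLMResult", function(object) {
  cat(sprintf("GLMResult: %d regressors x %d columns, dof = %g\n",
              nrow(object@beta), ncol(object@beta), object@dof))
})

setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport: %d columns, %.4g s @ %.4g Hz\n",
              nrow(object@channelTable), object@durationS, object@fs))
})

setMethod("show", "ScenarioSpec", function(object) {
  cat(sprintf("ScenarioSpec: %d channels, %.4g s @ %.4g Hz, seed %d\n",
              object@nChannels, object@durationS, object@fs, object@seed))
})

setMethod("show", "PipelineSpec", function(object) {
  cat(sprintf("PipelineSpec: %d steps [%s]\n", length(object@steps),
              paste(vapply(object@steps, `[[`, "", "name"), collapse = " -> ")))
})
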