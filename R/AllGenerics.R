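#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Standard accessors for the package's S4 containers.
#'
#' @param x an object.
#' @param ... passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("recData", function(x, ...) standardGeneric("recData"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("signalKind", function(x) standardGeneric("signalKind"))

#' @rdname accessors
#' @export
setGeneric("chromophores", function(x) standardGeneric("chromophores"))

#' @rdname accessors
#' @export
setGeneric("channelInfo", function(x) standardGeneric("channelInfo"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' @rdname accessors
#' @export
setGeneric("processingHistory", function(x) standardGeneric("processingHistory"))

#' Extract one chromophore (or wavelength) block as a T x C matrix
#'
#' @param x a \code{NirsRecording}.
#' @param which chromophore name ("HbO", "HbR", "HbT") or wavelength block
#'   index for intensity/OD recordings.
#' @return numeric matrix, time points by channels.
#' @export
setGeneric("chromData", function(x, which) standardGeneric("chromData"))

#' @rdname accessors
#' @export
setGeneric("fcValues", function(x) standardGeneric("fcValues"))

#' @rdname accessors
#' @export
setGeneric("thresholdState", function(x) standardGeneric("thresholdState"))

#' @rdname accessors
#' @export
setGeneric("alffTable", function(x) standardGeneric("alffTable"))

#' @rdname accessors
#' @export
setGeneric("statValues", function(x) standardGeneric("statValues"))

#' @rdname accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname accessors
#' @export
setGeneric("significanceFlags", function(x) standardGeneric("significanceFlags"))

#' @rdname accessors
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))

#' @rdname accessors
#' @export
setGeneric("glmBeta", function(x) standardGeneric("glmBeta"))
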