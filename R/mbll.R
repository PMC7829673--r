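#' @include io-text.R
NULL

#' MBLL conversion parameters
#'
#' Bundles the quantities entering the modified Beer-Lambert law: the two
#' measurement wavelengths, the 2x2 molar extinction matrix
#' \eqn{\epsilon(\lambda, \mathrm{chromophore})} in mm^-1 mM^-1, the
#' differential pathlength factor per wavelength, and the source-detector
#' separation in mm.
#'
#' @slot wavelengths nm, length 2.
#' @slot extinction 2x2 matrix, rows = wavelengths, columns = (HbO, HbR).
#' @slot dpf differential pathlength factor per wavelength (dimensionless).
#' @slot distance source-detector separation in mm.
#' @export
setClass("MBLLParams",
  representation(wavelengths = "numeric", extinction = "matrix",
                 dpf = "numeric", distance = "numeric"))

setValidity("MBLLParams", function(object) {
  msg <- character(0)
  if (!all(dim(object@extinction) == c(2, 2)))
    msg <- c(msg, "extinction must be a 2x2 matrix")
  else if (!is.finite(kappa(object@extinction, exact = TRUE)) ||
           abs(det(object@extinction)) < 1e-12)
    msg <- c(msg, "extinction matrix is singular")
  if (any(object@dpf <= 0)) msg <- c(msg, "dpf must be positive")
  if (object@distance <= 0) msg <- c(msg, "distance must be positive")
  if (length(msg)) msg else TRUE
})

#' Extinction coefficients by nearest-nm lookup
#'
#' Returns molar extinction coefficients for HbO and HbR at the requested
#' wavelengths, from the compiled literature spectrum shipped with the
#' package (\code{inst/extdata/extinction_hb.tsv}, units mm^-1 mM^-1,
#' decadic). Lookup is nearest-nm.
#'
#' @param wavelengths numeric wavelengths in nm.
#' @return matrix with one row per wavelength and columns \code{eps_HbO},
#'   \code{eps_HbR}.
#' @examples
#' defaultExtinction(c(760, 850))
#' @export
defaultExtinction <- function(wavelengths) {
  tab <- utils::read.delim(system.file("extdata", "extinction_hb.tsv",
                                       package = "fnirsuite"))
  idx <- vapply(wavelengths, function(w) which.min(abs(tab$wavelength_nm - w)), 1L)
  out <- as.matrix(tab[idx, c("eps_HbO", "eps_HbR")])
  rownames(out) <- as.character(wavelengths)
  out
}

#' Construct MBLL parameters
#'
#' @param wavelengths nm, length 2 (default 760 and 850, a common CW-NIRS
#'   pairing bracketing the ~800 nm isosbestic point).
#' @param extinction optional 2x2 extinction matrix; nearest-nm lookup in the
#'   packaged table when omitted.
#' @param dpf differential pathlength factor, scalar or per wavelength
#'   (default 6.0, the conventional adult value).
#' @param distance source-detector separation in mm (default 30).
#' @return an \code{MBLLParams} object.
#' @export
mbllParams <- function(wavelengths = c(760, 850), extinction = NULL,
                       dpf = 6.0, distance = 30) {
  if (is.null(extinction)) extinction <- defaultExtinction(wavelengths)
  new("MBLLParams", wavelengths = wavelengths,
      extinction = as.matrix(extinction),
      dpf = rep_len(dpf, length(wavelengths)), distance = distance)
}

#' Optical intensity to optical density
#'
#' \eqn{OD(t,\lambda) = -\log_{10}(I(t,\lambda) / I_0(\lambda))}, with the
#' baseline \eqn{I_0} defaulting to the temporal mean per wavelength.
#'
#' @param I T x W matrix of positive intensities.
#' @param I0 baseline intensity per wavelength column; temporal mean when
#'   NULL.
#' @return T x W matrix of optical density changes.
#' @export
intensityToOD <- function(I, I0 = NULL) {
  I <- as.matrix(I)
  if (any(I <= 0, na.rm = TRUE)) {
    bad <- which(I <= 0, arr.ind = TRUE)
    stop("nonpositive intensity at (row, col): ",
         paste(apply(utils::head(bad, 5), 1, paste, collapse = ","),
               collapse = "; "))
  }
  if (is.null(I0)) I0 <- colMeans(I, na.rm = TRUE)
  -log10(sweep(I, 2, I0, "/"))
}

#' Optical density to hemoglobin concentration changes (MBLL)
#'
#' Inverts the modified Beer-Lambert law
#' \deqn{\Delta OD(\lambda) = [\epsilon(\lambda, HbO)\,\Delta HbO +
#'   \epsilon(\lambda, HbR)\,\Delta HbR] \; d \; DPF(\lambda)}
#' for the two chromophores by solving the 2x2 system per sample. With
#' extinction in mm^-1 mM^-1 and distance in mm the result is in mM.
#'
#' @param od T x 2 optical density matrix (one column per wavelength).
#' @param params an \code{MBLLParams}.
#' @return T x 2 matrix with columns \code{HbO}, \code{HbR}.
#' @export
odToHb <- function(od, params) {
  od <- as.matrix(od)
  if (ncol(od) != 2) stop("od must have exactly two wavelength columns")
  validObject(params)
  A <- diag(params@distance * params@dpf) %*% params@extinction
  hb <- t(solve(A, t(od)))
  colnames(hb) <- c("HbO", "HbR")
  hb
}

#' Forward MBLL: hemoglobin changes to optical density
#'
#' The forward counterpart of \code{\link{odToHb}}; used for simulation and
#' round-trip validation.
#'
#' @param hb T x 2 matrix (HbO, HbR) in mM.
#' @param params an \code{MBLLParams}.
#' @return T x 2 optical density matrix.
#' @export
hbToOD <- function(hb, params) {
  A <- diag(params@distance * params@dpf) %*% params@extinction
  t(A %*% t(as.matrix(hb)))
}

#' Convert an intensity or OD recording to hemoglobin concentrations
#'
#' Applies \code{\link{intensityToOD}} (when needed) and \code{\link{odToHb}}
#' channel by channel. The input recording must hold two wavelength blocks.
#'
#' @param rec a \code{NirsRecording} of kind "intensity" or
#'   "optical_density".
#' @param params an \code{MBLLParams}; built from the recording's
#'   wavelengths when NULL.
#' @return a \code{NirsRecording} of kind "hb" with chromophores HbO, HbR.
#' @export
beerLambert <- function(rec, params = NULL) {
  stopifnot(is(rec, "NirsRecording"))
  if (rec@signalKind == "hb") stop("recording already holds hemoglobin data")
  nw <- length(rec@wavelengths)
  if (nw != 2) stop("MBLL conversion needs exactly two wavelengths, got ", nw)
  if (is.null(params)) params <- mbllParams(rec@wavelengths)
  nch <- nChannels(rec)
  hbo <- hbr <- matrix(NA_real_, nTimepoints(rec), nch)
  for (i in seq_len(nch)) {
    raw <- cbind(chromData(rec, 1)[, i], chromData(rec, 2)[, i])
    od <- if (rec@signalKind == "intensity") intensityToOD(raw) else raw
    hb <- odToHb(od, params)
    hbo[, i] <- hb[, 1]; hbr[, i] <- hb[, 2]
  }
  out <- NirsRecording(cbind(hbo, hbr), fs = samplingRate(rec), kind = "hb",
                       chromophores = c("HbO", "HbR"),
                       channels = channelInfo(rec),
                       history = processingHistory(rec))
  appendHistory(out, "beer_lambert",
                list(wavelengths = params@wavelengths, dpf = params@dpf,
                     distance = params@distance))
}
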