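#' @include resting.R
NULL

#' Canonical double-gamma hemodynamic response function
#'
#' \deqn{h(t) = g(t; 6, 1) - g(t; 16, 1)/6,}
#' with \eqn{g} the gamma density (shape/scale in seconds): response peak
#' around 5 s, undershoot around 15 s, ratio 1/6. The kernel is sampled at
#' 1/fs from 0 to \code{durationS} (length \code{round(durationS*fs) + 1})
#' and peak-normalised to a maximum of 1.
#'
#' @param fs sampling rate in Hz.
#' @param durationS kernel length in seconds (default 32).
#' @param peakDelay,undershootDelay gamma shape parameters in seconds.
#' @param dispersion,undershootDispersion gamma scales.
#' @param undershootRatio relative undershoot amplitude (default 1/6).
#' @return numeric kernel vector; \code{h[1] = h(0) = 0}.
#' @examples
#' h <- canonicalHrf(10)
#' which.max(h)   # peak near 5 s
#' @export
canonicalHrf <- function(fs, durationS = 32, peakDelay = 6,
                         undershootDelay = 16, dispersion = 1,
                         undershootDispersion = 1, undershootRatio = 1/6) {
  t <- seq(0, durationS, by = 1 / fs)
  h <- stats::dgamma(t, shape = peakDelay, scale = dispersion) -
       stats::dgamma(t, shape = undershootDelay,
                     scale = undershootDispersion) * undershootRatio
  h / max(h)
}

#' Build a GLM design matrix from a task design
#'
#' Each condition contributes a unit boxcar over [onset, onset + duration)
#' (a single-sample impulse when the duration is 0), convolved with the
#' canonical HRF at acquisition resolution and truncated to T samples.
#' Onsets are rounded to the nearest sample. Covariate columns are z-scored
#' and appended; the constant column comes last. Overlapping events of one
#' condition sum their boxcars (with a warning).
#'
#' @param design a \code{TaskDesign}.
#' @param T number of time points.
#' @param fs sampling rate in Hz.
#' @param covariates optional T x K numeric matrix of nuisance series (e.g.
#'   short-channel signals); overrides covariates stored in the design.
#' @param hrfParams named list passed to \code{\link{canonicalHrf}}.
#' @return a \code{\link{DesignMatrix}} with columns
#'   [conditions..., covariates..., constant].
#' @export
buildDesign <- function(design, T, fs, covariates = NULL,
                        hrfParams = list()) {
  stopifnot(is(design, "TaskDesign"))
  cc <- design@conditions
  if (any(cc$onset_s + cc$duration_s >= T / fs))
    stop("events extend beyond the recording (", T / fs, " s)")
  conds <- unique(cc$condition)
  if (!length(conds)) stop("design has no conditions")
  h <- do.call(canonicalHrf, c(list(fs = fs), hrfParams))
  cols <- matrix(0, T, length(conds))
  for (ci in seq_along(conds)) {
    ev <- cc[cc$condition == conds[ci], , drop = FALSE]
    if (!nrow(ev)) stop("condition '", conds[ci], "' has no events")
    box <- numeric(T)
    for (r in seq_len(nrow(ev))) {
      i0 <- round(ev$onset_s[r] * fs) + 1
      i1 <- if (ev$duration_s[r] == 0) i0
            else min(round((ev$onset_s[r] + ev$duration_s[r]) * fs), T)
      box[i0:max(i0, i1)] <- box[i0:max(i0, i1)] + 1
    }
    if (any(box > 1))
      warning("overlapping events in condition '", conds[ci],
              "'; boxcars summed")
    conv <- stats::convolve(box, rev(h), type = "open")
    cols[, ci] <- conv[seq_len(T)]
  }
  labels <- conds
  if (is.null(covariates) && ncol(design@covariates)) {
    covariates <- design@covariates
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != T) stop("covariates must have T rows")
    covariates <- scale(covariates)
    covLabels <- colnames(covariates)
    if (is.null(covLabels)) covLabels <- sprintf("cov%d", seq_len(ncol(covariates)))
    cols <- cbind(cols, covariates)
    labels <- c(labels, covLabels)
  }
  cols <- cbind(cols, 1)
  labels <- c(labels, "constant")
  colnames(cols) <- labels
  new("DesignMatrix", X = cols, labels = labels, fs = fs,
      hrfParams = c(list(fs = fs), hrfParams))
}

#' Fit the channelwise GLM
#'
#' Ordinary least squares per data column:
#' \eqn{\hat\beta = (X'X)^{-1} X' y}. Rank-deficient designs are handled
#' with a pseudoinverse (warning; degrees of freedom use the actual rank).
#' No prewhitening is applied.
#'
#' @param rec a \code{NirsRecording} or T x C numeric matrix.
#' @param dm a \code{\link{DesignMatrix}}.
#' @param chromophore chromophore to fit when \code{rec} is a recording.
#' @return a \code{\link{GLMResult}}.
#' @export
fitGlm <- function(rec, dm, chromophore = "HbO") {
  Y <- if (is(rec, "NirsRecording")) chromData(rec, chromophore)
       else as.matrix(rec)
  X <- dm@X
  if (nrow(Y) != nrow(X)) stop("data and design have different T")
  P <- ncol(X)
  if (nrow(X) <= P) stop("T <= P: model is not estimable")
  qrX <- qr(X)
  rnk <- qrX$rank
  if (rnk < P) {
    warning("design is rank deficient (rank ", rnk, " < ", P,
            "); using pseudoinverse")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-12
    XtXinv <- sv$v[, pos, drop = FALSE] %*%
      diag(1 / sv$d[pos]^2, sum(pos)) %*% t(sv$v[, pos, drop = FALSE])
    beta <- XtXinv %*% t(X) %*% Y
  } else {
    XtXinv <- chol2inv(chol(crossprod(X)))
    beta <- XtXinv %*% crossprod(X, Y)
  }
  dof <- nrow(X) - rnk
  res <- Y - X %*% beta
  sigma2 <- colSums(res^2) / dof
  cn <- colnames(Y)
  if (is.null(cn)) cn <- sprintf("ch%d", seq_len(ncol(Y)))
  rownames(beta) <- dm@labels
  new("GLMResult", beta = beta, sigma2 = as.numeric(sigma2), dof = dof,
      XtXinv = XtXinv, labels = dm@labels, columnNames = cn)
}

#' Contrast of GLM effects
#'
#' Computes the per-channel contrast effect \eqn{c'\beta}, its variance
#' \eqn{\hat\sigma^2 c'(X'X)^{-1}c}, and the t statistic with the model's
#' residual degrees of freedom. These effects are the per-subject input to
#' group-level inference.
#'
#' @param res a \code{\link{GLMResult}}.
#' @param contrast numeric vector of length P, or a named vector over a
#'   subset of design labels (unnamed positions are 0).
#' @return data.frame with columns \code{channel}, \code{effect},
#'   \code{variance}, \code{t}, \code{p}, plus attribute \code{dof}.
#' @export
glmContrast <- function(res, contrast) {
  P <- nrow(res@beta)
  if (!is.null(names(contrast))) {
    cv <- numeric(P)
    idx <- match(names(contrast), res@labels)
    if (any(is.na(idx))) stop("unknown contrast label(s): ",
                              paste(names(contrast)[is.na(idx)], collapse = ", "))
    cv[idx] <- contrast
    contrast <- cv
  }
  if (length(contrast) != P)
    stop("contrast must have length ", P)
  eff <- as.numeric(crossprod(contrast, res@beta))
  cvc <- as.numeric(t(contrast) %*% res@XtXinv %*% contrast)
  if (cvc < 0 && cvc > -1e-15) cvc <- 0
  v <- res@sigma2 * cvc
  tstat <- eff / sqrt(v)
  p <- 2 * stats::pt(-abs(tstat), df = res@dof)
  out <- data.frame(channel = seq_along(eff), effect = eff, variance = v,
                    t = tstat, p = p)
  attr(out, "dof") <- res@dof
  out
}

#' Write per-subject beta / contrast maps as TSV keyed by channel
#'
#' @param res a \code{GLMResult}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGlmTable <- function(res, path) {
  tab <- as.data.frame(t(res@beta))
  names(tab) <- res@labels
  tab <- cbind(channel = seq_len(nrow(tab)), tab,
               residual_variance = res@sigma2, dof = res@dof)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
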