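#' @include taskglm.R
NULL

# per-channel linear-model t test of one coefficient, NA-tolerant
# (pairwise-complete rows per channel, per-channel df)
.lmTstat <- function(Y, X, coefIdx) {
  C <- ncol(Y)
  stat <- p <- df <- rep(NA_real_, C)
  anyNA <- anyNA(Y)
  if (!anyNA) {
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) stop("singular design")
    beta <- qr.coef(qrX, Y)
    res <- Y - X %*% beta
    dof <- nrow(X) - ncol(X)
    sigma2 <- colSums(res^2) / dof
    XtXinv <- chol2inv(qr.R(qrX))
    se <- sqrt(sigma2 * XtXinv[coefIdx, coefIdx])
    stat <- beta[coefIdx, ] / se
    df[] <- dof
    p <- 2 * stats::pt(-abs(stat), dof)
  } else {
    for (j in seq_len(C)) {
      ok <- stats::complete.cases(cbind(Y[, j], X))
      if (sum(ok) <= ncol(X)) next
      fit <- stats::lm.fit(X[ok, , drop = FALSE], Y[ok, j])
      if (fit$rank < ncol(X)) next
      dof <- sum(ok) - ncol(X)
      sigma2 <- sum(fit$residuals^2) / dof
      XtXinv <- chol2inv(qr.R(fit$qr))
      stat[j] <- fit$coefficients[coefIdx] /
        sqrt(sigma2 * XtXinv[coefIdx, coefIdx])
      df[j] <- dof
      p[j] <- 2 * stats::pt(-abs(stat[j]), dof)
    }
  }
  list(stat = stat, p = p, df = df)
}

# F test of a block of columns (full vs reduced), complete data
.lmFstat <- function(Y, Xfull, Xred) {
  fitF <- stats::lm.fit(Xfull, Y)
  fitR <- stats::lm.fit(Xred, Y)
  rssF <- colSums(as.matrix(fitF$residuals)^2)
  rssR <- colSums(as.matrix(fitR$residuals)^2)
  df1 <- fitF$rank - fitR$rank
  df2 <- nrow(Xfull) - fitF$rank
  Fst <- ((rssR - rssF) / df1) / (rssF / df2)
  list(stat = Fst, p = stats::pf(Fst, df1, df2, lower.tail = FALSE),
       df = c(df1, df2))
}

#' Group-level channelwise statistics
#'
#' Fits one of the supported population models independently per channel and
#' returns a \code{\link{ChannelStatMap}}. All models are expressed as
#' channelwise general linear models; covariates (e.g. age, gender, training
#' time; one value per subject) are partialled out after mean-centring.
#' Tests are two-sided.
#'
#' Models and their \code{data} argument:
#' \describe{
#'   \item{one_sample}{subjects x channels matrix; t test of the mean
#'     against \code{mu0}.}
#'   \item{two_sample}{subjects x channels matrix plus a two-level
#'     \code{groups} factor; t test of the group difference.}
#'   \item{paired}{list of two subjects x channels matrices (same subject
#'     order); one-sample t test on the paired differences.}
#'   \item{correlation}{subjects x channels matrix plus per-subject
#'     \code{x}; the (partial) Pearson correlation with its t-based p.}
#'   \item{anova_indep}{subjects x channels matrix plus a >= 2-level
#'     \code{groups} factor; F test of the factor.}
#'   \item{anova_rm}{list of L condition matrices (subjects x channels);
#'     one-way repeated-measures F with subject effects removed (no
#'     sphericity correction).}
#'   \item{mean_only}{subjects x channels matrix; group mean, no inference.}
#' }
#'
#' Missing values are handled pairwise-complete per channel with
#' per-channel degrees of freedom (t models on matrix input).
#'
#' @param data matrix or list of matrices, see above.
#' @param model model name.
#' @param groups factor for the two_sample / anova_indep models.
#' @param x per-subject regressor for the correlation model.
#' @param covariates optional subjects x K numeric matrix.
#' @param mu0 null mean for the one-sample model.
#' @return a \code{\link{ChannelStatMap}}.
#' @examples
#' m <- matrix(rnorm(50), 10, 5)
#' groupTest(m, "one_sample")
#' @export
groupTest <- function(data,
                      model = c("one_sample", "two_sample", "paired",
                                "correlation", "anova_indep", "anova_rm",
                                "mean_only"),
                      groups = NULL, x = NULL, covariates = NULL, mu0 = 0) {
  model <- match.arg(model)
  cov <- if (!is.null(covariates)) scale(as.matrix(covariates), scale = FALSE)
  mkMap <- function(stat, p, df, label, C) {
    dfOut <- if (length(unique(stats::na.omit(df))) == 1 && length(df) > 2)
      unique(stats::na.omit(df)) else df
    new("ChannelStatMap", channelIds = seq_len(C), stat = as.numeric(stat),
        p = as.numeric(p), df = as.numeric(dfOut), model = label,
        mask = rep(TRUE, C), corrected = list(method = "none"))
  }
  if (model %in% c("paired", "anova_rm")) {
    if (!is.list(data) || length(data) < 2)
      stop(model, " needs a list of condition matrices")
    dims <- vapply(data, dim, integer(2))
    if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1)
      stop("unequal condition matrix dimensions")
  }
  if (model == "paired") {
    if (length(data) != 2) stop("paired test needs exactly two matrices")
    data <- data[[1]] - data[[2]]
    model2 <- "one_sample"; mu0p <- 0
    return(initialize(groupTest(data, model2, covariates = covariates,
                                mu0 = mu0p), model = "paired"))
  }
  if (model == "anova_rm") {
    if (!is.null(cov)) stop("covariates are not supported for anova_rm")
    L <- length(data); S <- nrow(data[[1]]); C <- ncol(data[[1]])
    if (S < 3) stop("need at least 3 subjects")
    arr <- array(unlist(data), c(S, C, L))
    gm <- apply(arr, 2, mean)
    stat <- p <- rep(NA_real_, C)
    for (j in seq_len(C)) {
      y <- arr[, j, ]                       # S x L
      condMean <- colMeans(y); subjMean <- rowMeans(y); g <- mean(y)
      ssCond <- S * sum((condMean - g)^2)
      ssErr <- sum((y - outer(subjMean, rep(1, L)) -
                      outer(rep(1, S), condMean) + g)^2)
      df1 <- L - 1; df2 <- (S - 1) * (L - 1)
      stat[j] <- (ssCond / df1) / (ssErr / df2)
      p[j] <- stats::pf(stat[j], df1, df2, lower.tail = FALSE)
    }
    return(mkMap(stat, p, c(L - 1, (S - 1) * (L - 1)), "anova_rm", C))
  }
  Y <- as.matrix(data)
  S <- nrow(Y); C <- ncol(Y)
  if (model != "mean_only" && S < 3) stop("need at least 3 subjects")
  if (!is.null(cov) && nrow(cov) != S)
    stop("covariates must have one row per subject")
  switch(model,
    mean_only = mkMap(colMeans(Y, na.rm = TRUE), rep(NA_real_, C),
                      NA_real_, "mean_only", C),
    one_sample = {
      X <- cbind(intercept = rep(1, S), cov)
      r <- .lmTstat(Y - mu0, X, 1L)
      mkMap(r$stat, r$p, r$df, "one_sample", C)
    },
    two_sample = {
      g <- as.factor(groups)
      if (nlevels(g) != 2) stop("two_sample needs exactly two groups")
      if (min(table(g)) < 3) stop("need at least 3 subjects per group")
      X <- cbind(1, as.numeric(g == levels(g)[2]), cov)
      r <- .lmTstat(Y, X, 2L)
      mkMap(r$stat, r$p, r$df, "two_sample", C)
    },
    correlation = {
      if (is.null(x)) stop("correlation model needs x")
      X <- cbind(1, as.numeric(x), cov)
      r <- .lmTstat(Y, X, 2L)
      rho <- r$stat / sqrt(r$stat^2 + r$df)
      p <- r$p
      perfect <- !is.na(r$stat) & is.infinite(r$stat)
      rho[perfect] <- sign(r$stat[perfect]); p[perfect] <- 0
      mkMap(rho, p, r$df, "correlation", C)
    },
    anova_indep = {
      g <- as.factor(groups)
      if (nlevels(g) < 2) stop("anova_indep needs >= 2 groups")
      if (min(table(g)) < 3) stop("need at least 3 subjects per group")
      D <- stats::model.matrix(~g)[, -1, drop = FALSE]
      Xf <- cbind(1, D, cov)
      Xr <- cbind(matrix(1, S, 1), cov)
      r <- .lmFstat(Y, Xf, Xr)
      mkMap(r$stat, r$p, r$df, "anova_indep", C)
    })
}

#' Multiple-comparison correction within a mask
#'
#' Computes significance flags over the in-mask channels only (family size m
#' = mask size). \strong{bonferroni}: flag \eqn{p \le q/m}.
#' \strong{fdr_bh}: Benjamini-Hochberg step-up — sort in-mask p ascending
#' and flag all \eqn{p \le p_{(k^*)}} where \eqn{k^* = \max\{k : p_{(k)} \le
#' k q / m\}}.
#'
#' @param map a \code{\link{ChannelStatMap}}.
#' @param method "fdr_bh" or "bonferroni".
#' @param q significance level in (0, 1).
#' @param mask optional logical per channel (or integer channel ids);
#'   defaults to the map's mask.
#' @return the map with its \code{corrected} slot and \code{mask} updated.
#' @export
correctMultiple <- function(map, method = c("fdr_bh", "bonferroni"),
                            q = 0.05, mask = NULL) {
  method <- match.arg(method)
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  C <- length(map@channelIds)
  if (is.null(mask)) mask <- map@mask
  if (is.numeric(mask)) mask <- map@channelIds %in% mask
  if (!any(mask)) stop("empty mask")
  pm <- map@p[mask]
  m <- sum(mask)
  flagsIn <- if (method == "bonferroni") {
    !is.na(pm) & pm <= q / m
  } else {
    ps <- sort(pm[!is.na(pm)])
    kStar <- suppressWarnings(max(which(ps <= seq_along(ps) * q / m)))
    if (is.finite(kStar)) !is.na(pm) & pm <= ps[kStar]
    else rep(FALSE, length(pm))
  }
  flags <- rep(FALSE, C)
  flags[mask] <- flagsIn
  initialize(map, mask = mask,
             corrected = list(method = method, q = q, flags = flags,
                              threshold = if (method == "bonferroni") q / m
                                          else NA_real_))
}

#' Write a group statistics table
#'
#' @param map a \code{ChannelStatMap}.
#' @param path TSV output path.
#' @return \code{path}, invisibly.
#' @export
writeStatMap <- function(map, path) {
  tab <- data.frame(channel = map@channelIds, stat = map@stat, p = map@p,
                    mask = map@mask)
  if (!is.null(map@corrected$flags)) tab$flag <- map@corrected$flags
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
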