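# Precision-weighted two-group differential expression with
# empirical-Bayes moderated t statistics.
#
# The mean-variance trend is estimated voom-style: gene-wise square-root
# residual standard deviations from an ordinary two-group fit are
# regressed on average logCPM by lowess (span 0.5), the trend is
# evaluated at each observation's fitted logCPM, and the inverse fourth
# power becomes the observation weight. The moderated t follows the
# canonical empirical-Bayes treatment: gene-wise variances are shrunk
# toward a common prior estimated by moment matching of the
# log-variances (digamma/trigamma matching to a scaled F distribution).
# limma implements the same machinery and serves as an independent
# cross-check in the test-suite; this implementation additionally lets
# the prior degrees of freedom be forced (d0 = 0 or Inf) to expose the
# ordinary-t and pooled-variance limiting cases.

#' Voom-style precision weights
#'
#' @param counts filtered \linkS4class{ExpressionMatrix} on the counts
#'   scale (>= 10 genes).
#' @param factors TMM factors from \code{\link{tmmFactors}} (default all 1).
#' @param labels two-group labels over the samples (>= 2 per group).
#' @param span lowess span for the mean-variance trend (default 0.5).
#' @param prior logCPM pseudocount (default 0.5).
#' @return list with \code{logcpm} (\linkS4class{ExpressionMatrix}) and
#'   \code{weights} (genes x samples matrix, clipped to [1e-6, 1e6]).
#' @export
voomTransform <- function(counts, factors = NULL, labels, span = 0.5,
                          prior = 0.5) {
  stopifnot(is(counts, "ExpressionMatrix"))
  m <- exprValues(counts)
  if (nrow(m) < 10L) stop("mean-variance trend unestimable with < 10 genes")
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L || any(table(labels) < 2L))
    stop("need two groups with >= 2 samples each")
  lc <- logCPM(counts, factors = factors, prior = prior)
  y <- exprValues(lc)
  grpIdx <- lapply(levels(labels), function(l) which(labels == l))
  fitted <- y
  for (idx in grpIdx)
    fitted[, idx] <- rowMeans(y[, idx, drop = FALSE])
  resid <- y - fitted
  df <- ncol(y) - 2L
  s <- sqrt(rowSums(resid^2) / df)
  sqrtSd <- sqrt(s)
  aveLogCPM <- rowMeans(y)
  trend <- lowess(aveLogCPM, sqrtSd, f = span)
  ok <- is.finite(trend$x) & is.finite(trend$y)
  predFun <- if (length(unique(trend$x[ok])) < 2L) {
    flat <- mean(trend$y[ok])  # degenerate trend: constant prediction
    function(v) rep(flat, length(v))
  } else {
    stats::approxfun(trend$x[ok], trend$y[ok], rule = 2, ties = mean)
  }
  pred <- matrix(predFun(fitted), nrow(y), ncol(y))
  w <- pred^(-4)
  nClip <- sum(w > 1e6 | w < 1e-6)
  if (nClip > 0)
    warning(nClip, " weight(s) clipped to [1e-6, 1e6]")
  w <- pmin(pmax(w, 1e-6), 1e6)
  dimnames(w) <- dimnames(y)
  list(logcpm = lc, weights = w)
}

# Newton solve of trigamma(y) = x (x > 0); standard inversion used by
# the moment-matching variance-prior estimator.
trigammaInverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi)) return(NA_real_)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif / y) < 1e-10) break
    }
    y
  }, 0)
}

# Moment-matching estimate of the variance prior (d0, s0^2) from
# gene-wise sample variances s2 on df degrees of freedom.
estimatePrior <- function(s2, df) {
  ok <- s2 > 0
  if (sum(ok) < 2L) return(list(d0 = Inf, s02 = mean(s2)))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0)
    return(list(d0 = Inf, s02 = exp(ebar + digamma(df / 2) - log(df / 2))))
  d0 <- 2 * trigammaInverse(evar)
  s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Moderated-t differential expression fit
#'
#' Per-gene weighted least squares for the two-group contrast, followed
#' by empirical-Bayes variance moderation: the posterior variance is
#' \code{(d0*s0^2 + df*s^2) / (d0 + df)} and the moderated t has
#' \code{d0 + df} degrees of freedom. BH adjustment is applied to the
#' two-sided p-values.
#'
#' @param logcpm \linkS4class{ExpressionMatrix} of logCPM values (from
#'   \code{\link{voomTransform}}).
#' @param weights genes-by-samples precision weights (default: all 1).
#' @param labels two-group labels; the contrast is level 2 minus level 1
#'   ... positive logFC means higher in the second level.
#' @param d0 force the prior degrees of freedom: \code{NULL} (default)
#'   estimates it by moment matching; \code{0} reduces to the ordinary
#'   weighted t; \code{Inf} pools all gene variances to the prior.
#' @return A data.frame (one row per gene): \code{gene}, \code{logFC},
#'   \code{aveExpr}, \code{t}, \code{p}, \code{adjp}.
#' @export
fitModerated <- function(logcpm, weights = NULL, labels, d0 = NULL) {
  stopifnot(is(logcpm, "ExpressionMatrix"))
  y <- exprValues(logcpm)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L || any(table(labels) < 2L))
    stop("need two groups with >= 2 samples each")
  if (is.null(weights)) weights <- matrix(1, nrow(y), ncol(y))
  g2 <- labels == levels(labels)[2L]
  # WLS for design [intercept, group2]: per-gene closed form
  w1 <- weights[, !g2, drop = FALSE]; y1 <- y[, !g2, drop = FALSE]
  w2 <- weights[, g2, drop = FALSE];  y2 <- y[, g2, drop = FALSE]
  sw1 <- rowSums(w1); sw2 <- rowSums(w2)
  mu1 <- rowSums(w1 * y1) / sw1
  mu2 <- rowSums(w2 * y2) / sw2
  beta <- mu2 - mu1
  rss <- rowSums(w1 * (y1 - mu1)^2) + rowSums(w2 * (y2 - mu2)^2)
  df <- ncol(y) - 2L
  s2 <- rss / df
  u2 <- 1 / sw1 + 1 / sw2   # unscaled variance of the contrast
  if (is.null(d0)) {
    pr <- estimatePrior(s2, df)
    d0 <- pr$d0; s02 <- pr$s02
    if (!is.finite(d0)) {
      warning("variance prior df non-finite; falling back to pooled ",
              "variance (d0 = Inf)")
      d0 <- Inf
    }
  } else {
    s02 <- if (is.finite(d0) && d0 == 0) NA_real_ else
      estimatePrior(s2, df)$s02
  }
  if (is.infinite(d0)) {
    s2post <- rep(s02, length(s2))
    dfTotal <- rep(Inf, length(s2))
  } else if (d0 == 0) {
    s2post <- s2
    dfTotal <- rep(df, length(s2))
  } else {
    s2post <- (d0 * s02 + df * s2) / (d0 + df)
    dfTotal <- rep(d0 + df, length(s2))
  }
  tstat <- beta / sqrt(s2post * u2)
  p <- 2 * pt(-abs(tstat), df = dfTotal)
  data.frame(gene = rownames(y), logFC = beta,
             aveExpr = rowMeans(y), t = tstat, p = p,
             adjp = bhAdjust(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in [0, 1].
#' @return Adjusted p-values (monotone after sorting, capped at 1).
#' @export
bhAdjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Select differentially expressed genes at threshold
#'
#' Keeps genes with linear fold change strictly greater than
#' \code{fcMin} in either direction (|logFC| > log2(fcMin)) and
#' BH-adjusted p strictly below \code{fdrMax}.
#'
#' @param table a DEG table from \code{\link{fitModerated}}.
#' @param fcMin linear fold-change cutoff, > 1 (default 3).
#' @param fdrMax adjusted-p cutoff in (0, 1) (default 0.05).
#' @param name name for the resulting signature.
#' @return A \linkS4class{GeneSignature}, or \code{NULL} if no gene
#'   passes.
#' @export
selectDegs <- function(table, fcMin = 3, fdrMax = 0.05, name = "DEGs") {
  stopifnot(all(c("gene", "logFC", "adjp") %in% names(table)))
  if (fcMin <= 1) stop("fcMin must exceed 1")
  if (fdrMax <= 0 || fdrMax >= 1) stop("fdrMax must lie in (0, 1)")
  hit <- abs(table$logFC) > log2(fcMin) & table$adjp < fdrMax
  if (!any(hit)) return(NULL)
  GeneSignature(name, table$gene[hit])
}
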