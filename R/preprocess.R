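#' Filter low-count genes
#'
#' Removes genes too weakly expressed to support inference, using the
#' \code{edgeR::filterByExpr} rule: keep gene g iff its CPM exceeds
#' \code{minCount / median(library size) * 1e6} in at least S samples
#' (S shrinks from the smallest group size via \code{largeN} /
#' \code{minProp}) and its total count is at least \code{minTotalCount}.
#' With no \code{groups}, all samples form one group.
#'
#' @param counts an \linkS4class{ExpressionMatrix} on the counts scale
#'   with at least 2 samples.
#' @param minCount minimum count in the CPM cutoff (default 10).
#' @param minProp proportion of the smallest group that must pass once
#'   the group is larger than \code{largeN} (default 0.5).
#' @param largeN group-size pivot for the proportion rule (default 5).
#' @param minTotalCount minimum total count across samples (default 15).
#' @param groups optional sample group labels (e.g. cluster labels).
#' @param keepGenes optional gene whitelist applied before filtering
#'   (e.g. the protein-coding / polymorphic-pseudogene annotation subset
#'   used for human cohorts); genes absent from the matrix are ignored.
#' @return The filtered \linkS4class{ExpressionMatrix} (row order
#'   preserved).
#' @export
filterLowCounts <- function(counts, minCount = 10, minProp = 0.5,
                            largeN = 5, minTotalCount = 15,
                            groups = NULL, keepGenes = NULL) {
  stopifnot(is(counts, "ExpressionMatrix"))
  if (exprScale(counts) != "counts")
    stop("filterLowCounts requires the counts scale, got ",
         exprScale(counts))
  m <- exprValues(counts)
  if (nrow(m) == 0L || ncol(m) < 2L)
    stop("need a non-empty matrix with >= 2 samples")
  if (!is.null(keepGenes)) {
    sel <- rownames(m) %in% toupper(keepGenes) |
      rownames(m) %in% keepGenes
    m <- m[sel, , drop = FALSE]
  }
  if (is.null(groups)) groups <- rep(1L, ncol(m))
  keep <- edgeR::filterByExpr(m, group = groups, min.count = minCount,
                              min.prop = minProp, large.n = largeN,
                              min.total.count = minTotalCount)
  if (!any(keep))
    stop("all genes removed by the low-count filter (retained count 0)")
  message(sprintf("low-count filter: %d of %d genes retained",
                  sum(keep), nrow(m)))
  ExpressionMatrix(m[keep, , drop = FALSE], scale = "counts")
}

#' Collapse duplicate gene symbols by averaging
#'
#' Rows sharing a symbol (multiple probes mapped to one gene) are
#' replaced by their arithmetic mean; rows with empty, \code{"NA"} or
#' missing symbols are dropped (count reported). Output symbols are
#' unique; first-occurrence row order is preserved.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @return An \linkS4class{ExpressionMatrix} with unique gene symbols.
#' @export
collapseDuplicateGenes <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  m <- exprValues(x)
  g <- rownames(m)
  bad <- is.na(g) | !nzchar(trimws(g)) | toupper(trimws(g)) == "NA"
  if (any(bad)) {
    message(sprintf("dropping %d unnamed/ambiguous gene rows", sum(bad)))
    m <- m[!bad, , drop = FALSE]
    g <- g[!bad]
  }
  if (!nrow(m)) stop("no named genes left after dropping ambiguous rows")
  if (!anyDuplicated(g)) {
    out <- m
  } else {
    first <- !duplicated(g)
    sums <- rowsum(m, group = g, reorder = FALSE)
    n <- as.vector(rowsum(rep(1, length(g)), group = g, reorder = FALSE))
    out <- sums / n
    # rowsum(reorder = FALSE) keeps first-occurrence order already
    rownames(out) <- g[first]
  }
  ExpressionMatrix(out, scale = exprScale(x))
}

#' Quantile normalization
#'
#' Forces every sample (column) onto the identical empirical
#' distribution: the per-rank mean of the sorted columns. Ties within a
#' column receive the mean of the reference values at their tied ranks
#' (the "average ties" dialect). Delegates to
#' \code{limma::normalizeQuantiles(ties = TRUE)}.
#'
#' @param x an \linkS4class{ExpressionMatrix} with >= 2 samples.
#' @return An \linkS4class{ExpressionMatrix} with scale
#'   \code{"quantile_normalized"}.
#' @export
quantileNormalize <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  m <- exprValues(x)
  if (ncol(m) < 2L)
    stop("quantile normalization needs >= 2 samples")
  q <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(q) <- dimnames(m)
  ExpressionMatrix(q, scale = "quantile_normalized")
}

#' TMM scaling factors
#'
#' Trimmed mean of M-values between-sample normalization
#' (\code{edgeR::calcNormFactors}): the reference sample is the column
#' whose upper quartile is closest to the mean upper quartile; each
#' sample's factor is 2 to the weighted trimmed mean of M-values (30
#' percent M-trim, 5 percent A-trim, inverse asymptotic-variance
#' weights), rescaled so the factors have geometric mean 1.
#'
#' @param counts an \linkS4class{ExpressionMatrix} on the counts scale.
#' @return Named numeric vector of positive scaling factors (geometric
#'   mean 1).
#' @export
tmmFactors <- function(counts) {
  stopifnot(is(counts, "ExpressionMatrix"))
  if (exprScale(counts) != "counts")
    stop("tmmFactors requires the counts scale")
  m <- exprValues(counts)
  if (ncol(m) < 2L) stop("TMM needs >= 2 samples")
  lib <- colSums(m)
  if (any(lib == 0))
    stop("sample(s) with zero total count: ",
         paste(colnames(m)[lib == 0], collapse = ", "))
  f <- edgeR::calcNormFactors(m, method = "TMM")
  setNames(as.numeric(f), colnames(m))
}

#' Log2 counts-per-million
#'
#' \code{log2((count + prior) / (libsize * factor + 2 * prior) * 1e6)},
#' the standard prior-damped logCPM transform.
#'
#' @param counts an \linkS4class{ExpressionMatrix} on the counts scale.
#' @param factors optional named TMM factors from \code{\link{tmmFactors}}
#'   (default: all 1).
#' @param prior pseudocount (default 0.5); must be non-negative.
#' @return An \linkS4class{ExpressionMatrix} with scale \code{"logcpm"}.
#' @export
logCPM <- function(counts, factors = NULL, prior = 0.5) {
  stopifnot(is(counts, "ExpressionMatrix"))
  if (exprScale(counts) != "counts")
    stop("logCPM requires the counts scale")
  if (prior < 0) stop("prior must be non-negative")
  m <- exprValues(counts)
  lib <- colSums(m)
  if (is.null(factors)) factors <- setNames(rep(1, ncol(m)), colnames(m))
  f <- factors[colnames(m)]
  if (anyNA(f)) stop("factors must be named for every sample")
  eff <- lib * f
  out <- log2(sweep(m + prior, 2L, eff + 2 * prior, "/") * 1e6)
  ExpressionMatrix(out, scale = "logcpm")
}
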