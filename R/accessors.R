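#' Accessors for crossOncoSig S4 classes
#'
#' Small accessor layer so user code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @return \code{exprValues}: the numeric genes-by-samples matrix;
#'   \code{exprScale}: the scale tag; \code{geneIds}/\code{sampleIds}:
#'   character vectors; \code{signatureGenes}: the gene symbols of a
#'   signature; \code{geneSets}: the named list of sets;
#'   \code{enrichmentScores}: the samples-by-sets score matrix;
#'   \code{clusterLabels}: named integer labels; \code{selectedK}: the
#'   silhouette-selected k; \code{silhouetteByK}: mean silhouette per k;
#'   \code{prognosisLabels}: cluster -> FP/PP map (possibly empty);
#'   \code{biclusterGenes}/\code{biclusterSamples}: member IDs;
#'   \code{biclusterSupport}: consensus support fraction;
#'   \code{kmMedian}: the median survival time of a \code{KMCurve}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
exprValues <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  SummarizedExperiment::assay(x, "exprs")
}

#' @rdname accessors
#' @export
exprScale <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  x@scale
}

#' @rdname accessors
#' @export
geneIds <- function(x) {
  if (is(x, "ExpressionMatrix")) return(rownames(x))
  if (is(x, "GeneSignature")) return(x@genes)
  stop("no geneIds method for class ", class(x))
}

#' @rdname accessors
#' @export
sampleIds <- function(x) {
  if (is(x, "ExpressionMatrix")) return(colnames(x))
  if (is(x, "ClusteringResult")) return(names(x@labels))
  stop("no sampleIds method for class ", class(x))
}

#' @rdname accessors
#' @export
signatureName <- function(x) {
  stopifnot(is(x, "GeneSignature") || is(x, "GeneSetCollection"))
  x@name
}

#' @rdname accessors
#' @export
signatureGenes <- function(x) {
  stopifnot(is(x, "GeneSignature"))
  x@genes
}

#' @rdname accessors
#' @export
geneSets <- function(x) {
  stopifnot(is(x, "GeneSetCollection"))
  x@sets
}

#' @rdname accessors
#' @export
enrichmentScores <- function(x) {
  stopifnot(is(x, "EnrichmentProfile"))
  x@scores
}

#' @rdname accessors
#' @export
clusterLabels <- function(x) {
  stopifnot(is(x, "ClusteringResult"))
  x@labels
}

#' @rdname accessors
#' @export
selectedK <- function(x) {
  stopifnot(is(x, "ClusteringResult"))
  x@kSelected
}

#' @rdname accessors
#' @export
silhouetteByK <- function(x) {
  stopifnot(is(x, "ClusteringResult"))
  x@silhouetteByK
}

#' @rdname accessors
#' @export
prognosisLabels <- function(x) {
  stopifnot(is(x, "ClusteringResult"))
  x@prognosisLabels
}

#' @rdname accessors
#' @export
biclusterGenes <- function(x) {
  stopifnot(is(x, "Bicluster"))
  x@genes
}

#' @rdname accessors
#' @export
biclusterSamples <- function(x) {
  stopifnot(is(x, "Bicluster"))
  x@samples
}

#' @rdname accessors
#' @export
biclusterSupport <- function(x) {
  stopifnot(is(x, "Bicluster"))
  x@support
}

#' @rdname accessors
#' @export
kmMedian <- function(x) {
  stopifnot(is(x, "KMCurve"))
  x@median
}

#' @rdname accessors
#' @export
testStatistic <- function(x) {
  stopifnot(is(x, "TestResult"))
  setNames(x@statistic, x@statisticName)
}

#' @rdname accessors
#' @export
testPValue <- function(x) {
  stopifnot(is(x, "TestResult"))
  x@p
}

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [scale: %s]\n",
              nrow(object), ncol(object), object@scale))
  callNextMethod()
})

setMethod("show", "GeneSignature", function(object) {
  cat(sprintf("GeneSignature '%s': %d genes\n", object@name,
              length(object@genes)))
  cat("  ", paste(head(object@genes, 8), collapse = ", "),
      if (length(object@genes) > 8) ", ..." else "", "\n", sep = "")
})

setMethod("show", "GeneSetCollection", function(object) {
  sizes <- vapply(object@sets, length, 1L)
  cat(sprintf("GeneSetCollection '%s': %d sets (sizes %d-%d)\n",
              object@name, length(object@sets), min(sizes), max(sizes)))
})

setMethod("show", "EnrichmentProfile", function(object) {
  cat(sprintf(
    "EnrichmentProfile: %d samples x %d sets (alpha = %g, %s)\n",
    nrow(object@scores), ncol(object@scores), object@alpha,
    if (object@normalized) "range-normalized" else "raw"))
})

setMethod("show", "ClusteringResult", function(object) {
  cat(sprintf("ClusteringResult on %s: k = %d selected from {%s}\n",
              object@featureSpace, object@kSelected,
              paste(names(object@silhouetteByK), collapse = ",")))
  cat("  mean silhouette by k: ",
      paste(sprintf("%s=%.3f", names(object@silhouetteByK),
                    object@silhouetteByK), collapse = "  "), "\n", sep = "")
  cat("  cluster sizes: ",
      paste(table(object@labels), collapse = ", "), "\n", sep = "")
  if (length(object@prognosisLabels))
    cat("  prognosis: ",
        paste(names(object@prognosisLabels), object@prognosisLabels,
              sep = "->", collapse = "  "), "\n", sep = "")
})

setMethod("show", "Bicluster", function(object) {
  cat(sprintf(
    "Bicluster: %d genes x %d samples (support %.2f%s)\n",
    length(object@genes), length(object@samples), object@support,
    if (object@converged) "" else ", NON-CONVERGED"))
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("TestResult [%s]: statistic = %.4g", object@statisticName,
              object@statistic))
  if (!is.na(object@df)) cat(sprintf(", df = %g", object@df))
  cat(sprintf(", p = %.4g", object@p))
  if (!is.na(object@estimate))
    cat(sprintf(", estimate = %.4g", object@estimate))
  cat("\n")
})

setMethod("show", "KMCurve", function(object) {
  cat(sprintf(
    "KMCurve: %d time points, median = %s\n", length(object@time),
    if (is.na(object@median)) "not reached" else
      format(object@median)))
})
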