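#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom stats approx coef cutree dist hclust kmeans lowess mad
#'   median p.adjust pchisq pt quantile rbinom rexp rlnorm rnbinom rnorm
#'   rpois runif sd setNames uniroot var wilcox.test weighted.mean
#' @importFrom utils head read.delim write.table
NULL

.EXPR_SCALES <- c("counts", "tpm", "logcpm", "quantile_normalized")

#' ExpressionMatrix: a genes-by-samples expression container
#'
#' Thin extension of \linkS4class{SummarizedExperiment} holding one dense
#' assay (\code{"exprs"}) plus a scale tag recording what the values are
#' (raw counts, TPM, log2-CPM, or quantile-normalized intensities).
#' Row names are gene symbols (duplicates allowed until
#' \code{\link{collapseDuplicateGenes}} is applied); column names are
#' sample identifiers and must be unique.
#'
#' @slot scale character(1), one of \code{"counts"}, \code{"tpm"},
#'   \code{"logcpm"}, \code{"quantile_normalized"}.
#' @seealso \code{\link{ExpressionMatrix}}, \code{\link{exprValues}},
#'   \code{\link{exprScale}}
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  representation(scale = "character")
)

setValidity("ExpressionMatrix", function(object) {
  msg <- NULL
  if (length(object@scale) != 1L || !object@scale %in% .EXPR_SCALES)
    msg <- c(msg, sprintf("scale must be one of: %s",
                          paste(.EXPR_SCALES, collapse = ", ")))
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    return(c(msg, "assay 'exprs' is required"))
  m <- SummarizedExperiment::assay(object, "exprs")
  if (!is.numeric(m))
    msg <- c(msg, "expression values must be numeric")
  if (anyNA(m) || any(!is.finite(m)))
    msg <- c(msg, "expression values must be finite (no NA/NaN/Inf)")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    msg <- c(msg, "sample IDs must be present and unique")
  if (is.null(rownames(m)))
    msg <- c(msg, "gene IDs (row names) are required")
  if (length(object@scale) == 1L && object@scale %in% c("counts", "tpm") &&
      length(m) && !anyNA(m) && all(is.finite(m)) && min(m) < 0)
    msg <- c(msg, sprintf("negative values not allowed on scale '%s'",
                          object@scale))
  if (is.null(msg)) TRUE else msg
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes in rows (row names = gene symbols),
#'   samples in columns (column names = unique sample IDs).
#' @param scale character(1); what the values are: \code{"counts"},
#'   \code{"tpm"}, \code{"logcpm"} or \code{"quantile_normalized"}.
#' @return An \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(rpois(6, 20), 3, 2,
#'             dimnames = list(c("TP53", "RB1", "MYC"), c("s1", "s2")))
#' ExpressionMatrix(m, scale = "counts")
#' @export
ExpressionMatrix <- function(values, scale = c("counts", "tpm", "logcpm",
                                               "quantile_normalized")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values))
  new("ExpressionMatrix", se, scale = scale)
}

#' GeneSignature: a named set of gene symbols
#'
#' @slot name character(1) signature name.
#' @slot genes character vector of unique, uppercase gene symbols.
#' @exportClass GeneSignature
setClass("GeneSignature",
  representation(name = "character", genes = "character"))

setValidity("GeneSignature", function(object) {
  msg <- NULL
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "name must be a non-empty string")
  if (length(object@genes) == 0L)
    msg <- c(msg, "signature must contain at least one gene")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "gene symbols must be unique")
  if (length(object@genes) && !identical(object@genes, toupper(object@genes)))
    msg <- c(msg, "gene symbols must be uppercase-harmonized")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GeneSignature
#'
#' Symbols are uppercased and deduplicated (harmonized symbol space: the
#' cross-species transfer in the underlying design matches canine and
#' human genes by shared symbol).
#'
#' @param name signature name.
#' @param genes character vector of gene symbols.
#' @return A \linkS4class{GeneSignature}.
#' @export
GeneSignature <- function(name, genes) {
  new("GeneSignature", name = as.character(name),
      genes = unique(toupper(as.character(genes))))
}

#' GeneSetCollection: named gene-symbol sets (hallmark-style)
#'
#' @slot name character(1) collection name.
#' @slot sets named list of character vectors (unique uppercase symbols).
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
  representation(name = "character", sets = "list"))

setValidity("GeneSetCollection", function(object) {
  msg <- NULL
  if (length(object@name) != 1L)
    msg <- c(msg, "name must be a single string")
  if (length(object@sets) == 0L)
    msg <- c(msg, "collection must contain at least one set")
  nm <- names(object@sets)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    msg <- c(msg, "set names must be present and unique")
  if (any(vapply(object@sets, length, 1L) == 0L))
    msg <- c(msg, "every set must be non-empty")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GeneSetCollection
#'
#' @param name collection name.
#' @param sets named list of character vectors of gene symbols; symbols are
#'   uppercased and deduplicated per set.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
GeneSetCollection <- function(name, sets) {
  sets <- lapply(sets, function(g) unique(toupper(as.character(g))))
  new("GeneSetCollection", name = as.character(name), sets = sets)
}

#' EnrichmentProfile: per-sample gene-set scores
#'
#' @slot scores numeric matrix, samples in rows, gene sets in columns.
#' @slot alpha rank-weight exponent used by the ssGSEA scorer.
#' @slot normalized logical; TRUE if scores were rescaled by the global
#'   score range.
#' @exportClass EnrichmentProfile
setClass("EnrichmentProfile",
  representation(scores = "matrix", alpha = "numeric",
                 normalized = "logical"))

setValidity("EnrichmentProfile", function(object) {
  msg <- NULL
  if (any(!is.finite(object@scores)))
    msg <- c(msg, "scores must be finite")
  if (is.null(rownames(object@scores)) || is.null(colnames(object@scores)))
    msg <- c(msg, "scores must carry sample (row) and set (column) names")
  if (is.null(msg)) TRUE else msg
})

#' ClusteringResult: outcome-blind sample partition with model selection
#'
#' @slot labels named integer vector, sample -> cluster (1-based, clusters
#'   numbered by decreasing size).
#' @slot kSelected integer, the silhouette-selected number of clusters.
#' @slot silhouetteByK named numeric vector of mean silhouette widths.
#' @slot featureSpace character tag, e.g. \code{"signature-genes"} or
#'   \code{"ssgsea-scores"}.
#' @slot prognosisLabels named character vector mapping cluster id to
#'   \code{"FP"}/\code{"PP"} (empty until survival labeling is applied;
#'   labeling is post hoc and never alters the partition).
#' @exportClass ClusteringResult
setClass("ClusteringResult",
  representation(labels = "integer", kSelected = "integer",
                 silhouetteByK = "numeric", featureSpace = "character",
                 prognosisLabels = "character"))

setValidity("ClusteringResult", function(object) {
  msg <- NULL
  k <- object@kSelected
  if (length(k) != 1L || is.na(k))
    msg <- c(msg, "kSelected must be a single integer")
  if (is.null(names(object@labels)))
    msg <- c(msg, "labels must be named by sample ID")
  tab <- tabulate(object@labels)
  if (length(k) == 1L && !is.na(k) &&
      (length(unique(object@labels)) != k || any(tab[seq_len(k)] == 0L)))
    msg <- c(msg, "labels must cover exactly kSelected non-empty clusters")
  if (length(object@silhouetteByK) &&
      any(object@silhouetteByK < -1 - 1e-12 | object@silhouetteByK > 1 + 1e-12))
    msg <- c(msg, "silhouette values must lie in [-1, 1]")
  if (length(object@prognosisLabels) &&
      !all(object@prognosisLabels %in% c("FP", "PP")))
    msg <- c(msg, "prognosis labels must be 'FP' or 'PP'")
  if (is.null(msg)) TRUE else msg
})

#' Bicluster: a joint gene-set / sample-set module
#'
#' @slot genes character vector of member gene symbols.
#' @slot samples character vector of member sample IDs.
#' @slot geneScores named numeric z-scores of member genes.
#' @slot sampleScores named numeric z-scores of member samples.
#' @slot support fraction of stochastic ISA runs containing a matching
#'   bi-cluster (in (0, 1]; 1 for a single-run result).
#' @slot converged logical; FALSE if iteration hit the cap without a
#'   fixed point.
#' @exportClass Bicluster
setClass("Bicluster",
  representation(genes = "character", samples = "character",
                 geneScores = "numeric", sampleScores = "numeric",
                 support = "numeric", converged = "logical"))

setValidity("Bicluster", function(object) {
  msg <- NULL
  if (length(object@genes) == 0L || length(object@samples) == 0L)
    msg <- c(msg, "gene and sample sets must be non-empty")
  if (length(object@support) != 1L || object@support <= 0 ||
      object@support > 1)
    msg <- c(msg, "support must lie in (0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' TestResult: a statistic + p-value container
#'
#' @slot statisticName one of \code{"logrank_chi2"}, \code{"pearson_chi2"},
#'   \code{"mannwhitney_U"}, \code{"cox_wald"}.
#' @slot statistic numeric test statistic.
#' @slot df degrees of freedom (NA where not applicable).
#' @slot p two-sided p-value.
#' @slot estimate effect estimate (hazard ratio for Cox, rank-biserial for
#'   Mann-Whitney; NA otherwise).
#' @slot extra list of method-specific extras (e.g. beta/SE for Cox).
#' @exportClass TestResult
setClass("TestResult",
  representation(statisticName = "character", statistic = "numeric",
                 df = "numeric", p = "numeric", estimate = "numeric",
                 extra = "list"))

setValidity("TestResult", function(object) {
  msg <- NULL
  if (!object@statisticName %in%
      c("logrank_chi2", "pearson_chi2", "mannwhitney_U", "cox_wald"))
    msg <- c(msg, "unknown statisticName")
  if (!is.finite(object@statistic))
    msg <- c(msg, "statistic must be finite")
  if (is.na(object@p) || object@p < 0 || object@p > 1)
    msg <- c(msg, "p must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

TestResult <- function(statisticName, statistic, df = NA_real_, p,
                       estimate = NA_real_, extra = list()) {
  new("TestResult", statisticName = statisticName,
      statistic = as.numeric(statistic), df = as.numeric(df),
      p = as.numeric(p), estimate = as.numeric(estimate), extra = extra)
}

#' KMCurve: Kaplan-Meier product-limit estimate
#'
#' @slot time sorted distinct observed times (days).
#' @slot surv survival probabilities S(t) at those times.
#' @slot nRisk numbers at risk just before each time.
#' @slot nEvent events at each time.
#' @slot median smallest time with S(t) <= 0.5, or NA if never reached.
#' @exportClass KMCurve
setClass("KMCurve",
  representation(time = "numeric", surv = "numeric", nRisk = "numeric",
                 nEvent = "numeric", median = "numeric"))

setValidity("KMCurve", function(object) {
  msg <- NULL
  if (is.unsorted(object@time))
    msg <- c(msg, "times must be sorted")
  if (any(object@surv < -1e-12 | object@surv > 1 + 1e-12))
    msg <- c(msg, "S(t) must lie in [0, 1]")
  if (any(diff(object@surv) > 1e-12))
    msg <- c(msg, "S(t) must be non-increasing")
  if (is.null(msg)) TRUE else msg
})
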