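#' Outcome-blind K-means with silhouette model selection
#'
#' For each k in \code{kRange}, runs best-of-\code{nInit} K-means
#' (within-cluster sum of squares criterion) and computes the mean
#' Euclidean silhouette width; the k with maximal mean silhouette is
#' selected (ties go to the smaller k). Clusters are relabeled
#' canonically by decreasing size. Clustering is strictly outcome-blind:
#' this function never sees survival data (prognosis labels are attached
#' post hoc by \code{\link{assignPrognosisLabels}}).
#'
#' @param x numeric matrix, samples in rows, features in columns (e.g. a
#'   samples-by-genes signature submatrix or an ssGSEA score matrix).
#' @param kRange candidate cluster numbers (default 2:6).
#' @param nInit K-means restarts per k (default 50).
#' @param seed RNG seed for the stochastic restarts.
#' @param featureSpace descriptive tag recorded in the result.
#' @return A \linkS4class{ClusteringResult}.
#' @export
kmeansSelectK <- function(x, kRange = 2:6, nInit = 50, seed = NULL,
                          featureSpace = "features") {
  x <- as.matrix(x)
  if (is.null(rownames(x)))
    rownames(x) <- paste0("sample", seq_len(nrow(x)))
  if (any(!is.finite(x))) stop("feature matrix must be finite")
  if (nrow(x) < max(kRange) + 1L)
    stop("need at least max(kRange)+1 samples")
  if (all(apply(x, 2L, function(col) diff(range(col)) == 0)))
    stop("constant feature matrix: silhouette undefined")
  d <- dist(x)
  fits <- with_seed(seed, lapply(kRange, function(k) {
    km <- kmeans(x, centers = k, nstart = nInit, iter.max = 100L)
    sil <- cluster::silhouette(km$cluster, d)
    list(k = k, labels = km$cluster, sil = mean(sil[, 3L]))
  }))
  silByK <- setNames(vapply(fits, `[[`, 0, "sil"),
                     as.character(kRange))
  best <- fits[[which.max(silByK)]]  # which.max takes first => smaller k
  lab <- best$labels
  sizeOrder <- order(-tabulate(lab, nbins = best$k), seq_len(best$k))
  relab <- match(lab, sizeOrder)
  new("ClusteringResult",
      labels = setNames(as.integer(relab), rownames(x)),
      kSelected = as.integer(best$k), silhouetteByK = silByK,
      featureSpace = featureSpace, prognosisLabels = character(0))
}

#' Attach favorable/poor prognosis labels to a two-cluster partition
#'
#' Post hoc labeling of an outcome-blind two-cluster partition: the
#' cluster with the longer Kaplan-Meier median survival is labeled FP
#' (favorable prognosis), the other PP (poor prognosis). An undefined
#' median (curve never falls to 0.5) counts as the longest survival. If
#' both medians are equal or both undefined, cluster 1 is labeled FP and
#' a warning is emitted. The partition itself is never altered.
#'
#' @param clust a \linkS4class{ClusteringResult} with \code{kSelected == 2}.
#' @param clinical a clinical table (see \code{\link{clinicalTable}});
#'   at least 80 percent of clustered samples must have survival rows.
#' @param endpoint which endpoint rows to use (default first present).
#' @return The \linkS4class{ClusteringResult} with
#'   \code{prognosisLabels} filled in.
#' @export
assignPrognosisLabels <- function(clust, clinical, endpoint = NULL) {
  stopifnot(is(clust, "ClusteringResult"))
  clinical <- validateClinical(clinical)
  if (selectedK(clust) != 2L)
    stop("prognosis labeling requires k = 2; ",
         "use pairwise analyses for k > 2")
  if (is.null(endpoint)) endpoint <- clinical$endpoint[1L]
  cl <- clinical[clinical$endpoint == endpoint, , drop = FALSE]
  lab <- clusterLabels(clust)
  common <- intersect(names(lab), cl$sample_id)
  if (length(common) < 0.8 * length(lab))
    stop("survival available for < 80% of clustered samples")
  cl <- cl[match(common, cl$sample_id), , drop = FALSE]
  g <- lab[common]
  med <- vapply(1:2, function(k) {
    km <- kmEstimate(cl$time_days[g == k], cl$event[g == k])
    kmMedian(km)
  }, 0)
  fp <- if (is.na(med[1L]) && is.na(med[2L])) {
    warning("both cluster medians undefined; labeling cluster 1 as FP")
    1L
  } else if (is.na(med[1L])) 1L
  else if (is.na(med[2L])) 2L
  else if (med[1L] == med[2L]) {
    warning("identical median survival; labeling cluster 1 as FP")
    1L
  } else which.max(med)
  pl <- c("PP", "PP"); pl[fp] <- "FP"
  clust@prognosisLabels <- setNames(pl, c("1", "2"))
  validObject(clust)
  clust
}

#' Ward hierarchical clustering of genes and samples
#'
#' Agglomerative clustering with the classic Ward criterion
#' (\code{hclust} method \code{"ward.D"} on Euclidean distances), cutting
#' the gene (row) tree and the sample (column) tree independently. Used
#' to seed the ISA bi-clustering (10 gene clusters and 7 sample clusters
#' by default).
#'
#' @param x an \linkS4class{ExpressionMatrix} or genes-by-samples matrix.
#' @param nGeneClusters number of gene clusters (default 10).
#' @param nSampleClusters number of sample clusters (default 7).
#' @return list with integer partitions \code{genes} and \code{samples}
#'   (named by gene/sample ID).
#' @export
wardClusters <- function(x, nGeneClusters = 10, nSampleClusters = 7) {
  m <- as_expr_matrix(x)
  if (any(!is.finite(m))) stop("matrix must be finite")
  if (nGeneClusters > nrow(m) || nSampleClusters > ncol(m))
    stop("requested more clusters than items")
  gp <- cutree(hclust(dist(m), method = "ward.D"), k = nGeneClusters)
  sp <- cutree(hclust(dist(t(m)), method = "ward.D"),
               k = nSampleClusters)
  list(genes = gp, samples = sp)
}
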