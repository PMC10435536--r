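# The two published workflow shapes, end to end.
#
# Workflow A (signature application): filter -> collapse -> quantile
# normalize -> harmonize the supplied signature -> subset -> per-gene
# z-score -> outcome-blind K-means with silhouette selection ->
# post-hoc FP/PP labeling -> Kaplan-Meier + log-rank per endpoint ->
# optional two-class GSEA and moderated-t DEG between the clusters.
#
# Workflow B (signature discovery): filter -> TMM -> logCPM ->
# collapse -> ssGSEA over a hallmark-style collection -> K-means on the
# enrichment profile -> voom/moderated-t DEG between the clusters ->
# consensus ISA bi-clustering on the DEG-restricted matrix -> one
# exported gene signature per consensus bi-cluster -> each signature
# re-applied via workflow A to a second (held-out or cross-species)
# cohort.
#
# Outcome blindness is structural: no clustering function receives the
# clinical table; survival enters only after the partition is fixed.

#' Run the signature-application workflow
#'
#' @param counts \linkS4class{ExpressionMatrix} of raw counts.
#' @param clinical clinical table (see \code{\link{clinicalTable}}).
#' @param signature a \linkS4class{GeneSignature} to apply.
#' @param seed root RNG seed (stages draw derived sub-seeds, so each
#'   stage is independently reproducible).
#' @param kRange,nInit clustering controls (see
#'   \code{\link{kmeansSelectK}}).
#' @param gseaSets optional \linkS4class{GeneSetCollection} for the
#'   between-cluster GSEA stage (skipped if NULL).
#' @param nPerm GSEA permutations (default 200).
#' @param fcMin,fdrMax DEG thresholds (defaults 3 and 0.05).
#' @param runDeg run the DEG stage (default TRUE; the transfer
#'   re-application of discovered signatures turns it off).
#' @param zscoreGenes z-score each signature gene before K-means
#'   (default TRUE; heat-map-style standardized expression).
#' @return A named list report: \code{clustering}, \code{km} (per
#'   cluster), \code{logrank} (per endpoint), \code{gsea}, \code{degs},
#'   \code{deg_table}, \code{harmonization}, \code{params}, \code{seed}.
#'   Pass it to \code{\link{writeReportBundle}} to serialize.
#' @export
runSignatureWorkflow <- function(counts, clinical, signature,
                                 seed = NULL, kRange = 2:6, nInit = 50,
                                 gseaSets = NULL, nPerm = 200,
                                 fcMin = 3, fdrMax = 0.05,
                                 runDeg = TRUE, zscoreGenes = TRUE) {
  stopifnot(is(counts, "ExpressionMatrix"), is(signature, "GeneSignature"))
  clinical <- validateClinical(clinical)
  filtered <- filterLowCounts(counts)
  collapsed <- collapseDuplicateGenes(filtered)
  normalized <- quantileNormalize(collapsed)
  harm <- harmonizeSymbols(signature, geneIds(normalized))
  if (is.null(harm$mapped) || length(signatureGenes(harm$mapped)) < 2L)
    stop("fewer than 2 signature genes survive harmonization; aborting")
  sub <- exprValues(normalized)[signatureGenes(harm$mapped), ,
                                drop = FALSE]
  feat <- t(sub)
  if (zscoreGenes) feat <- scale(feat)
  feat <- feat[, apply(feat, 2L, function(v) all(is.finite(v))),
               drop = FALSE]
  clust <- kmeansSelectK(feat, kRange = kRange, nInit = nInit,
                         seed = derive_seed(seed, 1L),
                         featureSpace = "signature-genes")
  report <- list(params = list(signature = signatureName(signature),
                               n_signature_genes =
                                 length(signatureGenes(harm$mapped)),
                               kRange = kRange, nInit = nInit,
                               fcMin = fcMin, fdrMax = fdrMax,
                               nPerm = nPerm, zscoreGenes = zscoreGenes,
                               filter = list(minCount = 10, minProp = 0.5,
                                             largeN = 5,
                                             minTotalCount = 15),
                               normalization = "quantile"),
                 seed = seed,
                 harmonization = list(
                   mapped = signatureGenes(harm$mapped),
                   dropped = harm$dropped))
  if (selectedK(clust) == 2L)
    clust <- assignPrognosisLabels(clust, clinical)
  report$clustering <- clust
  lab <- clusterLabels(clust)
  km <- list(); lr <- list()
  for (ep in unique(clinical$endpoint)) {
    cl <- clinical[clinical$endpoint == ep, , drop = FALSE]
    common <- intersect(names(lab), cl$sample_id)
    cl <- cl[match(common, cl$sample_id), , drop = FALSE]
    g <- lab[common]
    for (k in sort(unique(g)))
      km[[paste0(ep, "_cluster", k)]] <-
        kmEstimate(cl$time_days[g == k], cl$event[g == k])
    if (length(unique(g)) == 2L)
      lr[[ep]] <- logrankTest(cl$time_days, cl$event, g)
  }
  report$km <- km
  report$logrank <- lr
  if (selectedK(clust) == 2L) {
    grp <- factor(ifelse(lab == 1L, "cluster1", "cluster2"),
                  levels = c("cluster1", "cluster2"))
    if (!is.null(gseaSets)) {
      collapsedExpr <- collapseDuplicateGenes(filtered)
      lcAll <- logCPM(collapsedExpr, tmmFactors(collapsedExpr))
      report$gsea <- gseaTwoClass(lcAll, grp[match(colnames(lcAll),
                                                   names(lab))],
                                  gseaSets, nPerm = nPerm,
                                  seed = derive_seed(seed, 2L))
    }
    if (runDeg) {
      fac <- tmmFactors(collapsed)
      vm <- voomTransform(collapsed, fac, grp)
      tab <- fitModerated(vm$logcpm, vm$weights, grp)
      report$deg_table <- tab
      report$degs <- selectDegs(tab, fcMin = fcMin, fdrMax = fdrMax,
                                name = paste0(signatureName(signature),
                                              "-cluster-DEGs"))
    }
  }
  report
}

#' Run the signature-discovery workflow
#'
#' @inheritParams runSignatureWorkflow
#' @param sets a hallmark-style \linkS4class{GeneSetCollection} for the
#'   ssGSEA stage.
#' @param alpha ssGSEA rank-weight exponent (default 0.25).
#' @param params ISA parameters (see \code{\link{isaParams}}).
#' @param secondCohort optional list with \code{counts} and
#'   \code{clinical}: every exported bi-cluster signature is re-applied
#'   to it via \code{\link{runSignatureWorkflow}} (transfer testing).
#' @return A named list report: \code{ssgsea_clustering}, \code{degs},
#'   \code{deg_table}, \code{biclusters}, \code{signatures},
#'   \code{transfer} (per signature: the workflow-A report on the
#'   second cohort), \code{params}, \code{seed}. A run with zero DEGs
#'   or zero consensus bi-clusters returns cleanly with the stages that
#'   exist and \code{status} explaining the early exit.
#' @export
runDiscoveryWorkflow <- function(counts, clinical, sets, seed = NULL,
                                 alpha = 0.25, kRange = 2:6, nInit = 50,
                                 fcMin = 3, fdrMax = 0.05,
                                 params = isaParams(),
                                 secondCohort = NULL) {
  stopifnot(is(counts, "ExpressionMatrix"), is(sets, "GeneSetCollection"))
  clinical <- validateClinical(clinical)
  filtered <- filterLowCounts(counts)
  fac <- tmmFactors(filtered)
  lc <- logCPM(filtered, fac)
  lc <- collapseDuplicateGenes(lc)
  profile <- ssgseaScore(lc, sets, alpha = alpha)
  clust <- kmeansSelectK(enrichmentScores(profile), kRange = kRange,
                         nInit = nInit, seed = derive_seed(seed, 11L),
                         featureSpace = "ssgsea-scores")
  report <- list(params = list(alpha = alpha, kRange = kRange,
                               nInit = nInit, fcMin = fcMin,
                               fdrMax = fdrMax, isa = unclass(params),
                               filter = list(minCount = 10, minProp = 0.5,
                                             largeN = 5,
                                             minTotalCount = 15),
                               normalization = "tmm-logcpm"),
                 seed = seed,
                 ssgsea_clustering = clust,
                 status = "complete")
  lab <- clusterLabels(clust)
  if (selectedK(clust) != 2L) {
    # fall back to the two-cluster partition for the DEG contrast
    km2 <- with_seed(derive_seed(seed, 12L),
                     kmeans(enrichmentScores(profile), centers = 2L,
                            nstart = nInit))
    lab <- setNames(km2$cluster, rownames(enrichmentScores(profile)))
    report$status <- paste0("silhouette selected k=", selectedK(clust),
                            "; DEG contrast uses the k=2 partition")
  }
  grp <- factor(ifelse(lab == 1L, "cluster1", "cluster2"))
  collapsedCounts <- collapseDuplicateGenes(filtered)
  vm <- voomTransform(collapsedCounts, tmmFactors(collapsedCounts), grp)
  tab <- fitModerated(vm$logcpm, vm$weights, grp)
  report$deg_table <- tab
  degs <- selectDegs(tab, fcMin = fcMin, fdrMax = fdrMax,
                     name = "discovery-DEGs")
  report$degs <- degs
  if (is.null(degs)) {
    report$status <- "no genes passed the DEG thresholds; ISA skipped"
    return(report)
  }
  degExpr <- exprValues(lc)[intersect(geneIds(lc),
                                      signatureGenes(degs)), ,
                            drop = FALSE]
  biclusters <- isaConsensus(degExpr, params = params,
                             seed = derive_seed(seed, 13L))
  report$biclusters <- biclusters
  if (!length(biclusters)) {
    report$status <- "no consensus bi-clusters; signature export skipped"
    return(report)
  }
  sigs <- lapply(seq_along(biclusters), function(i)
    GeneSignature(sprintf("ISA-signature-%d", i),
                  biclusterGenes(biclusters[[i]])))
  sigs <- c(sigs, degs)  # the DEG-derived signature transfers as well
  names(sigs) <- vapply(sigs, signatureName, "")
  report$signatures <- sigs
  if (!is.null(secondCohort)) {
    report$transfer <- lapply(sigs, function(sg) {
      tryCatch(
        runSignatureWorkflow(secondCohort$counts, secondCohort$clinical,
                             sg, seed = derive_seed(seed, 14L),
                             kRange = kRange, nInit = nInit,
                             runDeg = FALSE),
        error = function(e) list(status = conditionMessage(e)))
    })
  }
  report
}
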