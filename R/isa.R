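# Iterative Signature Algorithm (ISA) consensus bi-clustering.
#
# ISA alternates between scoring samples over the current gene set (on
# the column-standardized matrix) and scoring genes over the current
# sample set (on the row-standardized matrix), thresholding each score
# vector at a z-cutoff, until the gene and sample sets reach a fixed
# point. Because the result depends on the (random) seeds, the full
# seeded procedure is repeated n_runs times; bi-clusters are matched
# across runs by gene-set Jaccard, and only groups present in strictly
# more than consensus_frac of the runs survive ("25 runs, > 75%": at
# least 19 of 25).

#' ISA parameter bundle
#'
#' @param tGene gene z-score threshold (default 2.0).
#' @param tSample sample z-score threshold (default 1.5).
#' @param direction \code{"signed"} keeps |z| exceedances (up- and
#'   down-coherent members), \code{"up"} keeps positive exceedances only.
#' @param maxIter iteration cap per seed (default 50).
#' @param nRuns stochastic repetitions of the seeded algorithm
#'   (default 25).
#' @param consensusFrac strict consensus fraction; a bi-cluster is kept
#'   iff its match group spans MORE than this fraction of runs
#'   (default 0.75).
#' @param matchJaccard gene-set Jaccard threshold for matching
#'   bi-clusters across runs (default 0.66).
#' @param seedsPerCluster members drawn per Ward cluster when building
#'   seeds (default 3).
#' @return A validated parameter list of class \code{isaParams}.
#' @export
isaParams <- function(tGene = 2.0, tSample = 1.5,
                      direction = c("signed", "up"), maxIter = 50L,
                      nRuns = 25L, consensusFrac = 0.75,
                      matchJaccard = 0.66, seedsPerCluster = 3L) {
  direction <- match.arg(direction)
  stopifnot(tGene > 0, tSample > 0, nRuns >= 1,
            consensusFrac > 0, consensusFrac < 1,
            matchJaccard > 0, matchJaccard <= 1, seedsPerCluster >= 1)
  structure(list(tGene = tGene, tSample = tSample, direction = direction,
                 maxIter = as.integer(maxIter), nRuns = as.integer(nRuns),
                 consensusFrac = consensusFrac,
                 matchJaccard = matchJaccard,
                 seedsPerCluster = as.integer(seedsPerCluster)),
            class = "isaParams")
}

#' Row- and column-standardize a matrix for ISA
#'
#' @param x an \linkS4class{ExpressionMatrix} or genes-by-samples matrix
#'   with at least 2 rows and columns. Constant rows/columns are dropped
#'   with a warning (fewer than 2 non-constant rows is an error).
#' @return list with \code{rowStd} (each gene mean 0 / SD 1 across
#'   samples) and \code{colStd} (each sample mean 0 / SD 1 across genes).
#' @export
isaNormalize <- function(x) {
  m <- as_expr_matrix(x)
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need >= 2 rows and columns")
  constRow <- apply(m, 1L, function(v) sd(v) == 0)
  constCol <- apply(m, 2L, function(v) sd(v) == 0)
  if (any(constRow) || any(constCol)) {
    warning(sprintf("dropping %d constant row(s), %d constant column(s)",
                    sum(constRow), sum(constCol)))
    m <- m[!constRow, !constCol, drop = FALSE]
  }
  if (nrow(m) < 2L)
    stop("fewer than 2 non-constant rows: cannot standardize")
  rowStd <- t(scale(t(m)))
  colStd <- scale(m)
  attr(rowStd, "scaled:center") <- attr(rowStd, "scaled:scale") <- NULL
  attr(colStd, "scaled:center") <- attr(colStd, "scaled:scale") <- NULL
  list(rowStd = rowStd, colStd = colStd)
}

# z-score a vector across its entries.
.zscore <- function(v) {
  s <- sd(v)
  if (s == 0) return(rep(0, length(v)))
  (v - mean(v)) / s
}

.threshold <- function(z, t, direction) {
  if (direction == "up") z > t else abs(z) > t
}

#' One seeded ISA iteration to a fixed point
#'
#' Alternates sample scoring (mean of the column-standardized values
#' over the current gene set, z-scored across samples, thresholded at
#' \code{tSample}) and gene scoring (mean of the row-standardized
#' values over the current sample set, z-scored across genes,
#' thresholded at \code{tGene}) until two consecutive iterations give
#' identical gene and sample sets, an empty set appears, or
#' \code{maxIter} is reached.
#'
#' @param norm output of \code{\link{isaNormalize}}.
#' @param geneSeed,sampleSeed character vector of seed gene symbols /
#'   sample IDs (exactly one of the two).
#' @param params an \code{\link{isaParams}} bundle.
#' @return A \linkS4class{Bicluster} (with \code{converged} flag), or
#'   \code{NULL} if the iteration emptied out.
#' @export
isaIterate <- function(norm, geneSeed = NULL, sampleSeed = NULL,
                       params = isaParams()) {
  rowStd <- norm$rowStd; colStd <- norm$colStd
  genes <- rownames(rowStd); samples <- colnames(rowStd)
  if (is.null(geneSeed) == is.null(sampleSeed))
    stop("provide exactly one of geneSeed / sampleSeed")
  gSet <- intersect(geneSeed, genes)
  sSet <- intersect(sampleSeed, samples)
  if (is.null(geneSeed)) {
    if (!length(sSet)) stop("empty sample seed")
    gz <- .zscore(rowMeans(rowStd[, sSet, drop = FALSE]))
    gSet <- genes[.threshold(gz, params$tGene, params$direction)]
    if (!length(gSet)) return(NULL)
  } else if (!length(gSet)) stop("empty gene seed")

  prevG <- character(0); prevS <- character(0)
  converged <- FALSE
  gz <- sz <- NULL
  for (it in seq_len(params$maxIter)) {
    sz <- .zscore(colMeans(colStd[gSet, , drop = FALSE]))
    sSet <- samples[.threshold(sz, params$tSample, params$direction)]
    if (!length(sSet)) return(NULL)
    gz <- .zscore(rowMeans(rowStd[, sSet, drop = FALSE]))
    gSet <- genes[.threshold(gz, params$tGene, params$direction)]
    if (!length(gSet)) return(NULL)
    if (setequal(gSet, prevG) && setequal(sSet, prevS)) {
      converged <- TRUE
      break
    }
    prevG <- gSet; prevS <- sSet
  }
  names(gz) <- genes; names(sz) <- samples
  new("Bicluster", genes = sort(gSet), samples = sort(sSet),
      geneScores = gz[sort(gSet)], sampleScores = sz[sort(sSet)],
      support = 1, converged = converged)
}

#' Build ISA seed sets from Ward partitions
#'
#' For every sample cluster, draws \code{seedsPerCluster} members
#' uniformly at random (all members if the cluster is smaller, with a
#' warning) to form one sample seed; likewise one gene seed per gene
#' cluster. With the default 10 gene and 7 sample clusters this yields
#' 17 seeds per run.
#'
#' @param genePartition,samplePartition named integer partitions from
#'   \code{\link{wardClusters}}.
#' @param seedsPerCluster members per seed (default 3).
#' @param seed RNG seed fixing the draw order.
#' @return list with \code{geneSeeds} and \code{sampleSeeds} (lists of
#'   character vectors).
#' @export
makeSeeds <- function(genePartition, samplePartition,
                      seedsPerCluster = 3, seed = NULL) {
  if (!length(genePartition) || !length(samplePartition))
    stop("empty partition")
  drawFrom <- function(partition) {
    lapply(sort(unique(partition)), function(k) {
      members <- names(partition)[partition == k]
      if (length(members) < seedsPerCluster) {
        warning(sprintf("cluster %d has only %d member(s); using all",
                        k, length(members)))
        members
      } else {
        sample(members, seedsPerCluster)
      }
    })
  }
  with_seed(seed, {
    list(geneSeeds = drawFrom(genePartition),
         sampleSeeds = drawFrom(samplePartition))
  })
}

#' Consensus ISA bi-clustering
#'
#' Runs the fully seeded ISA \code{nRuns} times with distinct derived
#' RNG streams (fresh random seed draws from the Ward partitions each
#' run), pools the converged bi-clusters, and keeps only those that
#' recur - matched greedily, largest gene set first, by gene-set Jaccard
#' at \code{matchJaccard} - in strictly more than
#' \code{consensusFrac} of the runs. Consensus membership is the set of
#' genes (samples) present in at least half of the matched instances.
#'
#' @param x \linkS4class{ExpressionMatrix} or matrix, typically the
#'   DEG-restricted expression matrix of the discovery workflow.
#' @param params an \code{\link{isaParams}} bundle.
#' @param seed root RNG seed.
#' @param partitions optional precomputed \code{\link{wardClusters}}
#'   output (computed from \code{x} with 10 gene / 7 sample clusters if
#'   absent; cluster counts are clamped to the matrix dimensions).
#' @return list of consensus \linkS4class{Bicluster} objects, sorted by
#'   decreasing gene-set size (possibly empty).
#' @export
isaConsensus <- function(x, params = isaParams(), seed = NULL,
                         partitions = NULL) {
  m <- as_expr_matrix(x)
  norm <- isaNormalize(m)
  if (is.null(partitions))
    partitions <- wardClusters(norm$rowStd,
                               nGeneClusters = min(10L, nrow(norm$rowStd)),
                               nSampleClusters = min(7L, ncol(norm$rowStd)))
  runs <- vector("list", params$nRuns)
  for (r in seq_len(params$nRuns)) {
    seeds <- makeSeeds(partitions$genes, partitions$samples,
                       seedsPerCluster = params$seedsPerCluster,
                       seed = derive_seed(seed, r))
    found <- list()
    for (gs in seeds$geneSeeds) {
      bc <- isaIterate(norm, geneSeed = gs, params = params)
      if (!is.null(bc) && bc@converged) found <- c(found, bc)
    }
    for (ss in seeds$sampleSeeds) {
      bc <- isaIterate(norm, sampleSeed = ss, params = params)
      if (!is.null(bc) && bc@converged) found <- c(found, bc)
    }
    # de-duplicate identical fixed points within the run
    if (length(found)) {
      key <- vapply(found, function(b)
        paste(c(biclusterGenes(b), "|", biclusterSamples(b)),
              collapse = ","), "")
      found <- found[!duplicated(key)]
    }
    runs[[r]] <- found
  }
  isaConsensusFromRuns(runs, params)
}

#' Consensus filter over per-run bi-cluster lists
#'
#' Exposed separately so the strict >consensusFrac boundary can be
#' exercised directly: with 25 runs and consensusFrac 0.75, a
#' bi-cluster recurring in 18 runs is rejected and one recurring in 19
#' is accepted.
#'
#' @param runs list (one element per run) of lists of
#'   \linkS4class{Bicluster} objects.
#' @param params an \code{\link{isaParams}} bundle; \code{nRuns} is
#'   taken as \code{length(runs)}.
#' @return list of consensus \linkS4class{Bicluster} objects.
#' @export
isaConsensusFromRuns <- function(runs, params = isaParams()) {
  nRuns <- length(runs)
  all <- unlist(runs, recursive = FALSE)
  if (!length(all)) return(list())
  runOf <- rep(seq_len(nRuns), vapply(runs, length, 1L))
  sizes <- vapply(all, function(b) length(biclusterGenes(b)), 1L)
  ord <- order(-sizes)
  assigned <- logical(length(all))
  out <- list()
  for (i in ord) {
    if (assigned[i]) next
    proto <- biclusterGenes(all[[i]])
    match <- which(!assigned & vapply(all, function(b)
      jaccard(biclusterGenes(b), proto), 0) >= params$matchJaccard)
    assigned[match] <- TRUE
    nRunsSpanned <- length(unique(runOf[match]))
    if (nRunsSpanned <= params$consensusFrac * nRuns) next  # strict >
    inst <- all[match]
    geneTab <- table(unlist(lapply(inst, biclusterGenes)))
    sampTab <- table(unlist(lapply(inst, biclusterSamples)))
    genes <- sort(names(geneTab)[geneTab >= length(inst) / 2])
    samples <- sort(names(sampTab)[sampTab >= length(inst) / 2])
    if (!length(genes) || !length(samples)) next
    gScores <- rowMeans(matrix(vapply(inst, function(b) {
      v <- b@geneScores[genes]; v[is.na(v)] <- 0; v
    }, numeric(length(genes))), nrow = length(genes)))
    sScores <- rowMeans(matrix(vapply(inst, function(b) {
      v <- b@sampleScores[samples]; v[is.na(v)] <- 0; v
    }, numeric(length(samples))), nrow = length(samples)))
    names(gScores) <- genes; names(sScores) <- samples
    out <- c(out, new("Bicluster", genes = genes, samples = samples,
                      geneScores = gScores, sampleScores = sScores,
                      support = nRunsSpanned / nRuns, converged = TRUE))
  }
  out[order(-vapply(out, function(b) length(biclusterGenes(b)), 1L))]
}
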