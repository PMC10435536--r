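# Single-sample GSEA and two-class GSEA with permutation FDR.
#
# Both scorers are rank-based. ssGSEA integrates, over the descending
# expression ranking of one sample, the difference between the weighted
# in-set empirical CDF (weights proportional to rank^alpha) and the
# uniform out-of-set CDF. Two-class GSEA ranks genes by signal-to-noise
# between two phenotype groups and takes the maximum deviation of the
# weighted Kolmogorov-Smirnov running sum.

#' Single-sample GSEA enrichment scores
#'
#' For each sample, genes are ranked by expression (descending; tied
#' expression receives average ranks for the weights). For each gene set
#' the enrichment score is the sum over all ranked positions of the
#' difference between the weighted in-set ECDF (in-set weight
#' proportional to rank^\code{alpha}) and the uniform out-of-set ECDF.
#' With \code{normalize = TRUE} the whole score matrix is divided by its
#' global range (max - min), the customary ssGSEA output normalization.
#'
#' @param expr an \linkS4class{ExpressionMatrix} with unique gene
#'   symbols (collapse duplicates first).
#' @param sets a \linkS4class{GeneSetCollection}. Sets with no gene in
#'   the matrix are skipped with a warning; a set covering every gene in
#'   the matrix is an error (empty out-set).
#' @param alpha rank-weight exponent (default 0.25).
#' @param normalize divide by the global score range (default TRUE).
#' @return An \linkS4class{EnrichmentProfile} (samples x sets).
#' @export
ssgseaScore <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
  stopifnot(is(expr, "ExpressionMatrix"), is(sets, "GeneSetCollection"))
  m <- exprValues(expr)
  genes <- rownames(m)
  if (anyDuplicated(genes))
    stop("ssGSEA requires unique gene symbols; run collapseDuplicateGenes")
  setsL <- lapply(geneSets(sets), intersect, x = genes)
  setsL <- Filter(function(g) TRUE, setsL)
  empty <- vapply(setsL, length, 1L) == 0L
  if (any(empty)) {
    warning("skipping set(s) with empty intersection: ",
            paste(names(setsL)[empty], collapse = ", "))
    setsL <- setsL[!empty]
  }
  if (!length(setsL)) stop("no gene set overlaps the expression matrix")
  full <- vapply(setsL, length, 1L) == length(genes)
  if (any(full))
    stop("set(s) covering all genes (empty out-set): ",
         paste(names(setsL)[full], collapse = ", "))
  N <- length(genes)
  ind <- vapply(setsL, function(g) genes %in% g, logical(N))  # N x S
  sizes <- colSums(ind)
  scores <- matrix(NA_real_, ncol(m), length(setsL),
                   dimnames = list(colnames(m), names(setsL)))
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    ord <- order(x, decreasing = TRUE)
    w <- rank(x, ties.method = "average")^alpha   # top gene largest
    indO <- ind[ord, , drop = FALSE]
    wO <- w[ord]
    hitCum <- apply(indO * wO, 2L, cumsum)
    hitCum <- sweep(hitCum, 2L, colSums(indO * wO), "/")
    missCum <- apply(!indO, 2L, cumsum)
    missCum <- sweep(missCum, 2L, N - sizes, "/")
    scores[j, ] <- colSums(hitCum - missCum)
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  new("EnrichmentProfile", scores = scores, alpha = alpha,
      normalized = normalize)
}

# Signal-to-noise metric between two groups of columns, with the
# customary small-SD floor sd >= 0.2 * |mean| (+ eps against 0/0).
signal2noise <- function(m, idxA, idxB) {
  mA <- rowMeans(m[, idxA, drop = FALSE])
  mB <- rowMeans(m[, idxB, drop = FALSE])
  sA <- apply(m[, idxA, drop = FALSE], 1L, sd)
  sB <- apply(m[, idxB, drop = FALSE], 1L, sd)
  sA <- pmax(sA, 0.2 * abs(mA) + 1e-8)
  sB <- pmax(sB, 0.2 * abs(mB) + 1e-8)
  (mA - mB) / (sA + sB)
}

# Weighted KS enrichment score from a descending-sorted metric.
# hitPos: sorted positions of set members in the ranking; w: |metric|^p
# at those positions. Returns the running-sum value of maximum absolute
# deviation, evaluated in O(set size).
esMaxDeviation <- function(hitPos, w, N) {
  mSize <- length(hitPos)
  if (sum(w) == 0) w <- rep(1, mSize)  # all-zero metric inside the set
  cumw <- cumsum(w) / sum(w)
  miss <- 1 / (N - mSize)
  k <- seq_len(mSize)
  after <- cumw - (hitPos - k) * miss               # just after each hit
  before <- c(0, cumw[-mSize]) - (hitPos - k) * miss  # just before each hit
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

esForSets <- function(metric, ind, weight) {
  ord <- order(metric, decreasing = TRUE)
  wAbs <- abs(metric[ord])^weight
  N <- length(metric)
  vapply(seq_len(ncol(ind)), function(s) {
    hp <- which(ind[ord, s])
    esMaxDeviation(hp, wAbs[hp], N)
  }, 0)
}

#' Two-class GSEA with permutation-based FDR
#'
#' Genes are ranked by signal-to-noise ratio between the two phenotype
#' groups (group mean difference over summed, floor-adjusted SDs); the
#' enrichment score of a set is the maximum deviation of the weighted
#' Kolmogorov-Smirnov running sum (hit increments proportional to
#' |metric|^\code{weight}). The null distribution comes from phenotype
#' label permutations when both groups have at least 7 samples, and from
#' gene-set (size-matched random set) permutations otherwise. NES
#' divides each ES by the mean absolute null ES of the same sign;
#' nominal p is the same-sign null exceedance fraction; FDR q follows
#' the positive/negative pool ratio rule.
#'
#' @param expr \linkS4class{ExpressionMatrix} (typically logCPM or
#'   normalized values) with unique gene symbols.
#' @param labels a two-level factor/character vector over the samples;
#'   the first level is the "enriched-in" direction of positive ES.
#' @param sets a \linkS4class{GeneSetCollection}.
#' @param nPerm number of permutations (default 1000; < 100 warns).
#' @param weight hit-increment exponent (default 1).
#' @param seed RNG seed for reproducible permutations.
#' @return A data.frame with one row per set: \code{set}, \code{size},
#'   \code{ES}, \code{NES}, \code{p}, \code{q}, \code{direction};
#'   sorted by decreasing NES.
#' @export
gseaTwoClass <- function(expr, labels, sets, nPerm = 1000, weight = 1,
                         seed = NULL) {
  stopifnot(is(expr, "ExpressionMatrix"), is(sets, "GeneSetCollection"))
  m <- exprValues(expr)
  if (anyDuplicated(rownames(m)))
    stop("gseaTwoClass requires unique gene symbols")
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L)
    stop("labels must define exactly two groups")
  if (length(labels) != ncol(m))
    stop("labels length must match sample count")
  nA <- sum(labels == levels(labels)[1L])
  nB <- sum(labels == levels(labels)[2L])
  if (min(nA, nB) < 3L) stop("both groups need >= 3 samples")
  if (nPerm < 100) warning("nPerm < 100 gives unstable p/q estimates")
  genes <- rownames(m)
  setsL <- lapply(geneSets(sets), intersect, x = genes)
  keep <- vapply(setsL, length, 1L) >= 2L &
    vapply(setsL, length, 1L) < length(genes)
  if (any(!keep))
    warning("skipping ", sum(!keep), " set(s) with <2 or all genes present")
  setsL <- setsL[keep]
  if (!length(setsL)) stop("no usable gene sets")
  ind <- vapply(setsL, function(g) genes %in% g, logical(length(genes)))
  sizes <- colSums(ind)
  idxA <- which(labels == levels(labels)[1L])
  idxB <- which(labels == levels(labels)[2L])

  metric <- signal2noise(m, idxA, idxB)
  es <- esForSets(metric, ind, weight)

  phenoPerm <- min(nA, nB) >= 7L
  nullES <- with_seed(seed, {
    if (phenoPerm) {
      vapply(seq_len(nPerm), function(p) {
        pa <- sample(ncol(m), nA)
        esForSets(signal2noise(m, pa, setdiff(seq_len(ncol(m)), pa)),
                  ind, weight)
      }, numeric(ncol(ind)))
    } else {
      ord <- order(metric, decreasing = TRUE)
      wAbs <- abs(metric[ord])^weight
      N <- length(metric)
      vapply(seq_len(nPerm), function(p) {
        vapply(sizes, function(sz) {
          hp <- sort(sample.int(N, sz))
          esMaxDeviation(hp, wAbs[hp], N)
        }, 0)
      }, numeric(ncol(ind)))
    }
  })
  if (is.null(dim(nullES))) nullES <- matrix(nullES, nrow = 1L)

  S <- length(setsL)
  nes <- p <- numeric(S)
  nullNES <- matrix(NA_real_, S, nPerm)
  for (s in seq_len(S)) {
    nl <- nullES[s, ]
    posMean <- mean(nl[nl >= 0]); negMean <- mean(abs(nl[nl < 0]))
    norm1 <- function(e) {
      ifelse(e >= 0,
             if (is.finite(posMean) && posMean > 0) e / posMean else NA,
             if (is.finite(negMean) && negMean > 0) e / negMean else NA)
    }
    nes[s] <- norm1(es[s])
    nullNES[s, ] <- norm1(nl)
    same <- if (es[s] >= 0) nl[nl >= 0] else nl[nl < 0]
    p[s] <- if (length(same)) mean(abs(same) >= abs(es[s])) else 1
  }
  pooled <- as.vector(nullNES)
  pooled <- pooled[is.finite(pooled)]
  q <- vapply(seq_len(S), function(s) {
    v <- nes[s]
    if (!is.finite(v)) return(NA_real_)
    if (v >= 0) {
      num <- mean(pooled[pooled >= 0] >= v)
      den <- sum(nes >= v & is.finite(nes)) / sum(nes >= 0 & is.finite(nes))
    } else {
      num <- mean(pooled[pooled < 0] <= v)
      den <- sum(nes <= v & is.finite(nes)) / sum(nes < 0 & is.finite(nes))
    }
    min(1, max(0, num / max(den, .Machine$double.eps)))
  }, 0)
  out <- data.frame(set = names(setsL), size = sizes, ES = es, NES = nes,
                    p = p, q = q,
                    direction = ifelse(es >= 0, levels(labels)[1L],
                                       levels(labels)[2L]),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$NES), , drop = FALSE]
}
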