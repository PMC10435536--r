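# Programmatic fixtures and independent oracles shared across tests.

# Small counts matrix with named genes/samples.
makeCounts <- function(nGenes = 50, nSamples = 6, seed = 1, lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(nGenes * nSamples, lambda), nGenes, nSamples,
              dimnames = list(sprintf("G%03d", seq_len(nGenes)),
                              sprintf("s%02d", seq_len(nSamples))))
  ExpressionMatrix(m, scale = "counts")
}

# Independent brute-force ssGSEA enrichment score: explicit loop over
# ranked positions, recomputing both ECDFs at every step.
ssgseaOracle <- function(x, set, alpha) {
  g <- names(x)
  N <- length(x)
  ord <- order(x, decreasing = TRUE)
  r <- rank(x, ties.method = "average")
  inSet <- g %in% set
  m <- sum(inSet)
  sumw <- sum((r^alpha)[inSet])
  total <- 0
  Pin <- 0
  Pout <- 0
  for (i in seq_len(N)) {
    gi <- ord[i]
    if (inSet[gi]) Pin <- Pin + r[gi]^alpha / sumw
    else Pout <- Pout + 1 / (N - m)
    total <- total + (Pin - Pout)
  }
  unname(total)
}

# Independent full running-sum GSEA ES (O(N) vector walk, max
# deviation), used to check the O(set size) implementation.
gseaEsOracle <- function(metric, inSet, weight = 1) {
  ord <- order(metric, decreasing = TRUE)
  hit <- inSet[ord]
  w <- abs(metric[ord])^weight
  w[!hit] <- 0
  if (sum(w) == 0) w[hit] <- 1
  run <- cumsum(w / sum(w)) - cumsum(!hit) / sum(!hit)
  run[which.max(abs(run))]
}

# Direct evaluation of the low-count filter rule (CPM cutoff from the
# median library size; group-size shrinkage; total-count floor).
filterOracle <- function(m, minCount = 10, minProp = 0.5, largeN = 5,
                         minTotalCount = 15, groups = NULL) {
  lib <- colSums(m)
  if (is.null(groups)) groups <- rep(1L, ncol(m))
  nMin <- min(table(groups))
  S <- if (nMin > largeN) largeN + (nMin - largeN) * minProp else nMin
  cutoff <- minCount / median(lib) * 1e6
  cpm <- sweep(m, 2L, lib, "/") * 1e6
  tol <- 1e-14
  keepCpm <- rowSums(cpm >= cutoff * (1 - tol)) >= S - 1e-10
  keepTotal <- rowSums(m) >= minTotalCount - 1e-10
  keepCpm & keepTotal
}

# Hand product-limit estimator (no censoring adjustments beyond risk-set
# bookkeeping; events before censorings at ties).
kmOracle <- function(time, event) {
  ord <- order(time, -event)
  time <- time[ord]; event <- event[ord]
  ut <- sort(unique(time[event == 1]))
  S <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    atRisk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / atRisk)
    S[i] <- s
  }
  list(time = ut, surv = S)
}

# Two-group log-rank statistic from the hypergeometric-margins formula.
logrankOracle <- function(time, event, group) {
  g <- as.integer(as.factor(group)) == 1L
  ut <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ut) {
    atRisk <- time >= t
    n <- sum(atRisk); n1 <- sum(atRisk & g)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Breslow partial log-likelihood for one covariate (used as a
# grid-search oracle for the Cox fit).
coxLogLik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Tiny synthetic cohort config used where full scale is not needed.
smallSimConfig <- function(...) {
  simConfig(nSamples = 60, nGenes = 400, moduleSize = 60,
            biclusters = list(list(nGenes = 20L, nSamples = 16L,
                                   shiftSd = 1.5)), ...)
}

# Plain Jaccard index used in recovery assertions.
jaccardSets <- function(a, b) length(intersect(a, b)) / length(union(a, b))
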