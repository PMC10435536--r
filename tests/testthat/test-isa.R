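plantedMatrix <- function(nGenes = 500, nSamples = 150, blocksG = list(),
                          blocksS = list(), shift = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(nGenes * nSamples), nGenes, nSamples,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              sprintf("s%03d", seq_len(nSamples))))
  for (i in seq_along(blocksG))
    X[blocksG[[i]], blocksS[[i]]] <- X[blocksG[[i]], blocksS[[i]]] + shift
  X
}

test_that("ISA standardization matches the direct (x - mu) / sigma form", {
  set.seed(101)
  X <- matrix(rnorm(16, 3, 2), 4, 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  nrm <- isaNormalize(X)
  for (i in 1:4) {
    expect_equal(unname(nrm$rowStd[i, ]),
                 unname((X[i, ] - mean(X[i, ])) / sd(X[i, ])),
                 tolerance = 1e-12)
    expect_equal(unname(nrm$colStd[, i]),
                 unname((X[, i] - mean(X[, i])) / sd(X[, i])),
                 tolerance = 1e-12)
  }
  expect_true(all(abs(rowMeans(nrm$rowStd)) < 1e-12))
  # pre-standardized input is a fixed point
  again <- isaNormalize(nrm$rowStd)
  expect_equal(again$rowStd, nrm$rowStd, tolerance = 1e-12)
  # constant rows dropped with warning; too few left is an error
  Xc <- rbind(X, gconst = rep(1, 4))
  expect_warning(nc <- isaNormalize(Xc), "constant")
  expect_false("gconst" %in% rownames(nc$rowStd))
  expect_error(suppressWarnings(isaNormalize(
    matrix(1, 3, 3, dimnames = list(paste0("g", 1:3),
                                    paste0("s", 1:3))))),
    "non-constant|constant")
})

test_that("seeded iteration converges onto a planted block", {
  X <- plantedMatrix(blocksG = list(1:30), blocksS = list(1:40),
                     shift = 2, seed = 102)
  nrm <- isaNormalize(X)
  bc <- isaIterate(nrm, geneSeed = sprintf("g%03d", c(2, 9, 17)))
  expect_s4_class(bc, "Bicluster")
  expect_true(bc@converged)
  expect_gte(jaccardSets(biclusterGenes(bc), sprintf("g%03d", 1:30)),
             0.9)
  # re-applying one update step to the fixed point returns it unchanged
  bc2 <- isaIterate(nrm, geneSeed = biclusterGenes(bc))
  expect_identical(biclusterGenes(bc2), biclusterGenes(bc))
  expect_identical(biclusterSamples(bc2), biclusterSamples(bc))
  # sample-seeded entry reaches the same module
  bc3 <- isaIterate(nrm, sampleSeed = sprintf("s%03d", c(3, 11, 25)))
  expect_gte(jaccardSets(biclusterGenes(bc3), biclusterGenes(bc)), 0.9)
  expect_error(isaIterate(nrm), "exactly one")
  expect_error(isaIterate(nrm, geneSeed = "nope"), "empty gene seed")
})

test_that("on pure noise most runs end empty or non-converged", {
  set.seed(103)
  X <- plantedMatrix(nGenes = 300, nSamples = 100, seed = 103)
  nrm <- isaNormalize(X)
  outcomes <- vapply(1:20, function(i) {
    r <- isaIterate(nrm, geneSeed = sample(rownames(X), 3))
    is.null(r) || !r@converged
  }, TRUE)
  expect_gte(mean(outcomes), 0.8)
})

test_that("seed construction follows the Ward partitions", {
  part <- list(genes = setNames(rep(1:10, each = 12),
                                sprintf("g%03d", 1:120)),
               samples = setNames(rep(1:7, each = 10),
                                  sprintf("s%03d", 1:70)))
  seeds <- makeSeeds(part$genes, part$samples, seed = 104)
  expect_length(seeds$geneSeeds, 10L)
  expect_length(seeds$sampleSeeds, 7L)   # 17 seeds total
  expect_true(all(vapply(seeds$geneSeeds, length, 1L) == 3L))
  for (k in 1:7)
    expect_true(all(part$samples[seeds$sampleSeeds[[k]]] == k))
  # clamp rule for undersized clusters
  tiny <- setNames(c(1L, 1L, 2L, 2L, 2L), paste0("g", 1:5))
  expect_warning(s2 <- makeSeeds(tiny, part$samples, seed = 1),
                 "only 2")
  expect_length(s2$geneSeeds[[1L]], 2L)
  # determinism
  expect_identical(makeSeeds(part$genes, part$samples, seed = 104),
                   seeds)
  expect_error(makeSeeds(integer(0), part$samples), "empty")
})

test_that("consensus keeps recurrent modules and drops weak plants", {
  X <- plantedMatrix(blocksG = list(1:30, 31:60, 61:100, 101:115),
                     blocksS = list(1:40, 41:75, 76:110, 111:135),
                     shift = 2, seed = 105)
  cons <- isaConsensus(X, seed = 106)
  expect_length(cons, 4L)
  truthG <- list(1:30, 31:60, 61:100, 101:115)
  for (b in cons) {
    best <- max(vapply(truthG, function(tg)
      jaccardSets(biclusterGenes(b), sprintf("g%03d", tg)), 0))
    expect_gte(best, 0.8)
    expect_gt(biclusterSupport(b), 0.75)
  }
  # sorted by decreasing gene-set size
  sizes <- vapply(cons, function(b) length(biclusterGenes(b)), 1L)
  expect_false(is.unsorted(rev(sizes)))

  # sub-threshold plant (+0.2 SD) is absent
  Xweak <- plantedMatrix(blocksG = list(1:30), blocksS = list(1:40),
                         shift = 0.2, seed = 107)
  consW <- isaConsensus(Xweak, seed = 108)
  for (b in consW)
    expect_lt(jaccardSets(biclusterGenes(b), sprintf("g%03d", 1:30)),
              0.5)

  # reproducibility: identical seed, identical consensus
  cons2 <- isaConsensus(X, seed = 106)
  expect_equal(cons, cons2)
})

test_that("the >75% consensus boundary is strict (19/25 in, 18/25 out)", {
  mk <- function(genes) new("Bicluster", genes = genes,
                            samples = c("s1", "s2"),
                            geneScores = setNames(rep(2.5,
                                                      length(genes)),
                                                  genes),
                            sampleScores = c(s1 = 2, s2 = 2),
                            support = 1, converged = TRUE)
  stable <- paste0("g", 1:20)
  runsWith <- function(n) {
    runs <- replicate(25, list(), simplify = FALSE)
    for (r in seq_len(n)) runs[[r]] <- list(mk(stable))
    runs
  }
  expect_length(isaConsensusFromRuns(runsWith(18)), 0L)
  got <- isaConsensusFromRuns(runsWith(19))
  expect_length(got, 1L)
  expect_equal(biclusterSupport(got[[1L]]), 19 / 25)
  expect_setequal(biclusterGenes(got[[1L]]), stable)
})

test_that("consensus is equivariant and monotone in the gene threshold", {
  X <- plantedMatrix(nGenes = 250, nSamples = 90,
                     blocksG = list(1:25), blocksS = list(1:30),
                     shift = 2, seed = 109)
  cons <- isaConsensus(X, seed = 110)
  # permuting genes and samples permutes the output, nothing else
  set.seed(111)
  gp <- sample(nrow(X)); sp <- sample(ncol(X))
  consP <- isaConsensus(X[gp, sp], seed = 110)
  expect_identical(lapply(consP, biclusterGenes),
                   lapply(cons, biclusterGenes))
  expect_identical(lapply(consP, biclusterSamples),
                   lapply(cons, biclusterSamples))
  # raising tGene never grows consensus gene sets
  consHi <- isaConsensus(X, params = isaParams(tGene = 2.6),
                         seed = 110)
  if (length(cons) && length(consHi)) {
    expect_lte(length(biclusterGenes(consHi[[1L]])),
               length(biclusterGenes(cons[[1L]])))
    expect_true(all(biclusterGenes(consHi[[1L]]) %in%
                      biclusterGenes(cons[[1L]])))
  }
})
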