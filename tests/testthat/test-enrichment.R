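test_that("ssGSEA agrees with the brute-force running-sum oracle", {
  set.seed(21)
  ng <- 30
  m <- matrix(rnorm(ng * 4, 6, 2), ng, 4,
              dimnames = list(sprintf("G%02d", 1:ng), paste0("s", 1:4)))
  m[5, 2] <- m[6, 2]  # introduce a tie
  em <- ExpressionMatrix(m, "logcpm")
  sets <- GeneSetCollection("toy", list(A = sprintf("G%02d", 1:8),
                                        B = sprintf("G%02d", 15:25)))
  pr <- ssgseaScore(em, sets, alpha = 0.25, normalize = FALSE)
  for (j in 1:4) for (s in c("A", "B")) {
    expect_equal(enrichmentScores(pr)[j, s],
                 ssgseaOracle(m[, j], geneSets(sets)[[s]], 0.25),
                 tolerance = 1e-12)
  }
})

test_that("ssGSEA symmetry, determinism and rank-only dependence", {
  set.seed(22)
  m <- matrix(rnorm(40 * 3, 5), 40, 3,
              dimnames = list(sprintf("G%02d", 1:40), paste0("s", 1:3)))
  m[, 3] <- m[, 1]  # duplicate sample
  em <- ExpressionMatrix(m, "logcpm")
  sets <- GeneSetCollection("c", list(A = sprintf("G%02d", 3:12)))
  pr <- ssgseaScore(em, sets, normalize = FALSE)
  expect_equal(enrichmentScores(pr)["s1", ], enrichmentScores(pr)["s3", ])

  # consistent gene relabeling leaves the profile unchanged
  perm <- sample(40)
  m2 <- m[perm, ]
  pr2 <- ssgseaScore(ExpressionMatrix(m2, "logcpm"), sets,
                     normalize = FALSE)
  expect_equal(enrichmentScores(pr2), enrichmentScores(pr))

  # rank-preserving monotone transform leaves scores unchanged
  pr3 <- ssgseaScore(ExpressionMatrix(m * 3 + 10, "logcpm"), sets,
                     normalize = FALSE)
  expect_equal(enrichmentScores(pr3), enrichmentScores(pr),
               tolerance = 1e-9)

  # with alpha = 0 any strictly monotone transform works (rank-only)
  pr4 <- ssgseaScore(em, sets, alpha = 0, normalize = FALSE)
  pr5 <- ssgseaScore(ExpressionMatrix(exp(m / 4), "logcpm"), sets,
                     alpha = 0, normalize = FALSE)
  expect_equal(enrichmentScores(pr5), enrichmentScores(pr4),
               tolerance = 1e-9)

  # degenerate sets
  expect_warning(ssgseaScore(em, GeneSetCollection("c", list(
    A = sprintf("G%02d", 3:12), NOPE = "ABSENT")), normalize = FALSE),
    "empty intersection")
  expect_error(suppressWarnings(ssgseaScore(em, GeneSetCollection("c",
    list(ALL = sprintf("G%02d", 1:40))))), "all genes")
})

test_that("GSEA enrichment score matches the full running-sum walk and
           an independent implementation", {
  set.seed(23)
  metric <- rnorm(200)
  for (sz in c(3, 20, 60)) {
    inSet <- rep(FALSE, 200)
    inSet[sample(200, sz)] <- TRUE
    ours <- crossOncoSig:::esForSets(
      metric, matrix(inSet, ncol = 1), weight = 1)
    expect_equal(ours, gseaEsOracle(metric, inSet, 1), tolerance = 1e-12)
    # cross-check against fgsea's ES on the identical ranked input
    ord <- order(metric, decreasing = TRUE)
    fES <- fgsea::calcGseaStat(metric[ord], which(inSet[ord]),
                               gseaParam = 1)
    expect_equal(ours, fES, tolerance = 1e-9)
  }
  # singleton set holding the top-ranked gene always scores positive
  top <- which.max(metric)
  inSet <- seq_along(metric) == top
  expect_gt(crossOncoSig:::esForSets(metric,
                                     matrix(inSet, ncol = 1), 1), 0)
})

test_that("two-class GSEA recovers a planted up-shifted set", {
  set.seed(24)
  ng <- 400; nA <- 20; nB <- 20
  m <- matrix(rnorm(ng * (nA + nB), 6), ng, nA + nB,
              dimnames = list(sprintf("G%03d", 1:ng),
                              sprintf("s%02d", 1:(nA + nB))))
  planted <- sprintf("G%03d", 1:30)
  m[planted, 1:nA] <- m[planted, 1:nA] + 2
  em <- ExpressionMatrix(m, "logcpm")
  sets <- simulateGenesets(nSets = 19, sizeRange = c(20, 50),
                           genes = rownames(m), seed = 25)
  sets <- GeneSetCollection("c", c(list(PLANTED = planted),
                                  geneSets(sets)))
  labels <- rep(c("grpA", "grpB"), c(nA, nB))
  res <- gseaTwoClass(em, labels, sets, nPerm = 1000, seed = 26)
  expect_identical(res$set[1L], "PLANTED")
  expect_lt(res$q[res$set == "PLANTED"], 0.05)
  expect_identical(res$direction[1L], "grpA")

  # label swap negates the planted ES (antisymmetry)
  swapped <- gseaTwoClass(em, rep(c("grpB", "grpA"), c(nA, nB)), sets,
                          nPerm = 200, seed = 26)
  expect_equal(swapped$ES[swapped$set == "PLANTED"],
               -res$ES[res$set == "PLANTED"], tolerance = 1e-12)

  # same seed reproduces bit-identically
  res2 <- gseaTwoClass(em, labels, sets, nPerm = 200, seed = 26)
  res3 <- gseaTwoClass(em, labels, sets, nPerm = 200, seed = 26)
  expect_identical(res2, res3)
})

test_that("two-class GSEA p-values are calibrated under the null", {
  set.seed(27)
  ng <- 300
  m <- matrix(rnorm(ng * 24, 6), ng, 24,
              dimnames = list(sprintf("G%03d", 1:ng),
                              sprintf("s%02d", 1:24)))
  em <- ExpressionMatrix(m, "logcpm")
  sets <- simulateGenesets(nSets = 50, sizeRange = c(15, 60),
                           genes = rownames(m), seed = 28)
  labels <- sample(rep(c("x", "y"), 12))   # no signal
  res <- gseaTwoClass(em, labels, sets, nPerm = 500, seed = 29)
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("gene-set permutation fallback engages for small groups", {
  set.seed(30)
  m <- matrix(rnorm(200 * 10, 6), 200, 10,
              dimnames = list(sprintf("G%03d", 1:200),
                              sprintf("s%02d", 1:10)))
  em <- ExpressionMatrix(m, "logcpm")
  sets <- simulateGenesets(nSets = 5, sizeRange = c(10, 30),
                           genes = rownames(m), seed = 31)
  labels <- rep(c("x", "y"), c(5, 5))   # min group 5 < 7
  res <- gseaTwoClass(em, labels, sets, nPerm = 200, seed = 32)
  expect_identical(nrow(res), 5L)
  expect_true(all(res$q >= 0 & res$q <= 1, na.rm = TRUE))
  expect_error(gseaTwoClass(em, rep(c("x", "y"), c(2, 8)), sets,
                            nPerm = 200), ">= 3 samples")
  expect_warning(gseaTwoClass(em, labels, sets, nPerm = 50, seed = 1),
                 "nPerm")
})
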