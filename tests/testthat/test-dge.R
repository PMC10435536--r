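test_that("voom-style weights track the mean-variance trend", {
  # homoscedastic Gaussian fixture: flat trend, near-constant weights
  set.seed(71)
  y <- matrix(rnorm(200 * 12, 8, 1), 200, 12,
              dimnames = list(sprintf("G%03d", 1:200),
                              sprintf("s%02d", 1:12)))
  counts <- ExpressionMatrix(round(2^y), "counts")
  labels <- rep(c("a", "b"), each = 6)
  vm <- voomTransform(counts, labels = labels)
  w <- vm$weights
  expect_lt(sd(w) / mean(w), 0.10)

  # NB counts spanning a genuine low-count regime (means 0.5-512):
  # the Poisson term dominates the dispersion at the low end, so
  # precision weights must rise with expression there
  set.seed(72)
  mu <- 2^runif(800, -1, 9)
  nb <- matrix(rnbinom(800 * 24, mu = mu, size = 1 / 0.2), 800, 24,
               dimnames = list(sprintf("G%03d", 1:800),
                               sprintf("s%02d", 1:24)))
  nb <- nb[rowSums(nb) > 0, ]
  vm2 <- voomTransform(ExpressionMatrix(nb, "counts"),
                       labels = rep(c("a", "b"), each = 12))
  mn <- rowMeans(exprValues(vm2$logcpm))
  wt <- rowMeans(vm2$weights)
  low <- mn <= quantile(mn, 1 / 3)
  expect_gt(cor(mn[low], wt[low], method = "spearman"), 0)

  # degenerate zero-residual genes push weights to the clip ceiling
  z <- matrix(rep(c(100, 200), each = 2), 12, 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:12), paste0("s", 1:4)))
  expect_warning(vz <- voomTransform(ExpressionMatrix(z, "counts"),
                                     labels = c("a", "a", "b", "b")),
                 "clipped")
  expect_true(any(vz$weights == 1e6))
  expect_error(voomTransform(makeCounts(5, 4), labels = c(1, 1, 2, 2)),
               "10 genes")
})

test_that("moderated t matches limma and its analytic limits", {
  sim <- simulateCohort(simConfig(nSamples = 30, nGenes = 500,
                                  moduleSize = 50,
                                  biclusters = list()), seed = 73)
  f <- suppressMessages(filterLowCounts(sim$counts))
  grp <- factor(sim$truth$cluster)
  vm <- voomTransform(f, tmmFactors(f), grp)
  tab <- fitModerated(vm$logcpm, vm$weights, grp)

  # independent oracle: limma's lmFit/eBayes on the identical inputs
  fit <- limma::eBayes(limma::lmFit(exprValues(vm$logcpm),
                                    stats::model.matrix(~grp),
                                    weights = vm$weights))
  expect_equal(tab$logFC, unname(fit$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(tab$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(tab$p, unname(fit$p.value[, 2]), tolerance = 1e-8)

  # d0 = 0: ordinary weighted t
  t0 <- fitModerated(vm$logcpm, vm$weights, grp, d0 = 0)
  y <- exprValues(vm$logcpm)
  for (g in c(1, 250, 500)) {
    lmfit <- stats::lm(y[g, ] ~ grp, weights = vm$weights[g, ])
    expect_equal(t0$t[g], summary(lmfit)$coefficients[2, 3],
                 tolerance = 1e-10)
  }
  # d0 = Inf: every gene shares the pooled prior variance
  tinf <- fitModerated(vm$logcpm, vm$weights, grp, d0 = Inf)
  sw <- rowSums(vm$weights[, grp == levels(grp)[1]])
  sw2 <- rowSums(vm$weights[, grp == levels(grp)[2]])
  s2post <- (tab$logFC / tab$t)^2 / (1 / sw + 1 / sw2)
  s2inf <- (tinf$logFC / tinf$t)^2 / (1 / sw + 1 / sw2)
  expect_lt(diff(range(s2inf)), 1e-8)      # pooled: all equal
  expect_gt(diff(range(s2post)), 1e-6)     # moderated: gene-specific

  # label swap negates logFC, preserves |t| and p
  swapped <- fitModerated(vm$logcpm, vm$weights,
                          factor(grp, levels = rev(levels(grp))))
  expect_equal(swapped$logFC, -tab$logFC, tolerance = 1e-12)
  expect_equal(abs(swapped$t), abs(tab$t), tolerance = 1e-12)
  expect_equal(swapped$p, tab$p, tolerance = 1e-12)

  # gene-order permutation equivariance
  set.seed(74)
  perm <- sample(nrow(y))
  lcP <- ExpressionMatrix(y[perm, ], "logcpm")
  tabP <- fitModerated(lcP, vm$weights[perm, ], grp)
  expect_equal(tabP$t, tab$t[perm], tolerance = 1e-12)
})

test_that("DE simulation attains nominal error control and power", {
  # NB counts, 10% DE at |log2FC| = 2 with balanced signs, 20 vs 20:
  # with one-directional DE a composition shift would bias the
  # normalization itself, so the calibration check plants both signs
  simDE <- function(seed, nGenes = 1000, n = 20, fracDE = 0.1,
                    lfc = 2, phi = 0.15) {
    set.seed(seed)
    base <- rnorm(nGenes, 5, 2)
    de <- sample(nGenes, fracDE * nGenes)
    sgn <- rep(c(1, -1), length.out = length(de))
    log2mu <- matrix(base, nGenes, 2 * n)
    log2mu[de, 1:n] <- log2mu[de, 1:n] + sgn * lfc
    rel <- sweep(2^log2mu, 2L, colSums(2^log2mu), "/")
    lib <- rlnorm(2 * n, log(2e7), 0.15)
    mu <- sweep(rel, 2L, lib, "*")
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / phi),
                     nGenes, 2 * n,
                     dimnames = list(sprintf("G%04d", 1:nGenes),
                                     sprintf("s%02d", 1:(2 * n))))
    list(counts = ExpressionMatrix(counts, "counts"),
         de = rownames(counts)[de])
  }
  nSeeds <- 10
  fdrs <- powers <- numeric(nSeeds)
  for (i in seq_len(nSeeds)) {
    s <- simDE(80 + i)
    f <- suppressMessages(filterLowCounts(s$counts))
    grp <- factor(rep(c("A", "B"), each = 20))
    vm <- voomTransform(f, tmmFactors(f), grp)
    tab <- fitModerated(vm$logcpm, vm$weights, grp)
    called <- tab$gene[tab$adjp < 0.05]
    fdrs[i] <- if (length(called)) mean(!called %in% s$de) else 0
    powers[i] <- mean(s$de %in% called)
  }
  expect_lte(mean(fdrs), 0.10)
  expect_gte(mean(powers), 0.7)
})

test_that("global-null adjusted discoveries stay near zero", {
  hits <- numeric(20)
  for (i in 1:20) {
    set.seed(90 + i)
    y <- matrix(rnorm(300 * 16, 8), 300, 16,
                dimnames = list(sprintf("G%03d", 1:300),
                                sprintf("s%02d", 1:16)))
    lc <- ExpressionMatrix(y, "logcpm")
    # equal-variance Gaussian genes can push the prior-df estimate to
    # its pooled-variance fallback, which warns by design
    tab <- suppressWarnings(
      fitModerated(lc, labels = rep(c("a", "b"), each = 8)))
    hits[i] <- mean(tab$adjp < 0.05)
  }
  expect_lte(mean(hits), 0.05 + 2 * sd(hits) / sqrt(20) + 0.01)
})

test_that("BH step-up and DEG threshold rules are exact", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone step-up property over a random vector
  set.seed(95)
  p <- runif(50)
  adj <- bhAdjust(p)
  expect_true(all(adj >= p - 1e-15))
  expect_false(is.unsorted(adj[order(p)]))

  tab <- data.frame(gene = paste0("g", 1:5),
                    logFC = c(log2(3), log2(4), -log2(5), 0.1, 3),
                    adjp = c(0.01, 0.01, 0.04, 0.001, 0.5))
  sel <- selectDegs(tab)
  # FC exactly 3 is excluded (strict), adj p 0.5 excluded, both signs kept
  expect_setequal(signatureGenes(sel), c("G2", "G3"))
  # brute-force agreement
  brute <- toupper(tab$gene[2^abs(tab$logFC) > 3 & tab$adjp < 0.05])
  expect_setequal(signatureGenes(sel), brute)
  expect_null(selectDegs(tab, fcMin = 100))
  expect_error(selectDegs(tab, fcMin = 1), "exceed 1")
})
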