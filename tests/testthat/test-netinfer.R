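# Pearson and shrinkage partial-correlation networks, significance, masking
# and consensus.

labelled <- function(x, subclass = "IgG1") {
  structs <- c("G0", "G0F", "G0N", "G1", "G1F", "G2", "G2F", "G1S1", "G2S1",
               "G0FN", "G1N", "G2N")
  colnames(x) <- glycoformLabel(subclass, structs[seq_len(ncol(x))])
  x
}

test_that("pearsonNetwork flags perfectly correlated columns", {
  set.seed(5)
  x <- labelled(matrix(rnorm(50 * 3), 50, 3))
  x[, 2] <- x[, 1]
  net <- pearsonNetwork(x)
  expect_equal(estimates(net)[1, 2], 1)
  expect_true(significanceMask(net)[1, 2])
  expect_true(all(abs(estimates(net)) <= 1))
  expect_equal(estimates(net), t(estimates(net)))
  expect_equal(unname(diag(estimates(net))), rep(1, 3))
  x[, 3] <- 5
  expect_error(pearsonNetwork(x), "zero-variance")
})

test_that("no edges are called on independent data", {
  set.seed(6)
  x <- labelled(matrix(rnorm(1000 * 10), 1000, 10))
  net <- pearsonNetwork(x, alpha = 0.01)
  expect_lte(sum(significanceMask(net)[upper.tri(estimates(net))]), 1L)
})

test_that("BH masking equals the hand step-up oracle", {
  set.seed(7)
  x <- labelled(matrix(rnorm(40 * 4), 40, 4))
  x[, 2] <- x[, 1] + rnorm(40, 0, 0.4)
  net <- pearsonNetwork(x, alpha = 0.05)
  p <- pvalues(net)[upper.tri(pvalues(net))]
  # step-up rule by hand
  ord <- order(p)
  m <- length(p)
  passes <- p[ord] <= 0.05 * seq_len(m) / m
  kmax <- if (any(passes)) max(which(passes)) else 0L
  oracle <- logical(m)
  if (kmax > 0) oracle[ord[seq_len(kmax)]] <- TRUE
  expect_equal(significanceMask(net)[upper.tri(pvalues(net))], oracle)
})

test_that("partial correlations separate direct from mediated dependence", {
  set.seed(8)
  n <- 2000
  x <- rnorm(n)
  y <- 0.7 * x + rnorm(n, 0, sqrt(1 - 0.49))
  z <- 0.7 * y + rnorm(n, 0, sqrt(1 - 0.49))
  m <- labelled(cbind(x, y, z))
  net <- partialCorrelation(m)
  e <- estimates(net)
  expect_lt(abs(e[1, 3]), 0.05)     # conditional independence X _||_ Z | Y
  expect_gt(e[1, 2], 0.3)
  expect_gt(e[2, 3], 0.3)
  # marginal correlation of X and Z is nevertheless strong
  expect_gt(cor(x, z), 0.3)
})

test_that("lambda = 0 partial correlations equal plain matrix inversion", {
  set.seed(9)
  x <- labelled(matrix(rnorm(200 * 5), 200, 5))
  pc <- glyconet:::.shrinkPcor(x, lambda = 0)$pcor
  # oracle: invert the sample correlation matrix directly
  om <- solve(cor(x))
  oracle <- -om / sqrt(tcrossprod(diag(om)))
  diag(oracle) <- 1
  expect_equal(pc, oracle, tolerance = 1e-10)
})

test_that("with two variables the partial correlation is the shrunken r", {
  set.seed(10)
  x <- labelled(matrix(rnorm(100 * 2), 100, 2))
  x[, 2] <- x[, 1] * 0.5 + x[, 2]
  net <- partialCorrelation(x)
  lam <- shrinkageLambda(net)
  expect_gt(lam, 0)
  expect_equal(estimates(net)[1, 2], (1 - lam) * cor(x)[1, 2],
               tolerance = 1e-10)
})

test_that("pcor significance is calibrated and powered", {
  # pcor ~ 0 yields p ~ 1
  set.seed(12)
  n <- 400
  x <- labelled(matrix(rnorm(n * 4), n, 4))
  net <- partialCorrelation(x)
  hi <- which.max(abs(pvalues(net)[upper.tri(diag(4))]))
  expect_gt(max(pvalues(net)[upper.tri(diag(4))], na.rm = TRUE), 0.5)
  # planted edges (pcor 0.3) at n = 700 are recovered with sensitivity >= .9
  set.seed(13)
  p <- 20
  om <- diag(p)
  planted <- cbind(seq(1, 19, by = 2), seq(2, 20, by = 2))
  om[planted] <- om[planted[, 2:1]] <- -0.3
  xs <- matrix(rnorm(700 * p), 700, p) %*% chol(solve(om))
  structs <- c("G0", "G0F", "G0N", "G1", "G1F", "G2", "G2F", "G1S1", "G2S1",
               "G0FN")
  colnames(xs) <- c(glycoformLabel("IgG1", structs),
                    glycoformLabel("IgG2", structs))
  net <- partialCorrelation(xs, alpha = 0.01)
  sens <- mean(significanceMask(net)[planted])
  expect_gte(sens, 0.9)
  # permuted-rows null: empirical edge rate stays near the nominal level
  set.seed(14)
  hits <- 0L; tests <- 0L
  base <- labelled(matrix(rnorm(150 * 6), 150, 6))
  for (b in 1:100) {
    perm <- apply(base, 2, sample)
    colnames(perm) <- colnames(base)
    netp <- partialCorrelation(perm, alpha = 0.01)
    hits <- hits + sum(significanceMask(netp)[upper.tri(diag(6))])
    tests <- tests + 15L
  }
  expect_lte(hits / tests, 2 * 0.01)
})

test_that("the empirical-null significance mode is selectable and sane", {
  set.seed(15)
  x <- labelled(matrix(rnorm(300 * 8), 300, 8))
  x[, 2] <- x[, 1] + rnorm(300, 0, 0.8)
  netF <- partialCorrelation(x, method = "fisher")
  netE <- partialCorrelation(x, method = "empirical")
  expect_identical(estimates(netF), estimates(netE))
  # p-values decrease with |coefficient| under the fitted null
  ut <- upper.tri(diag(8))
  ordE <- order(abs(estimates(netE)[ut]))
  expect_true(all(diff(pvalues(netE)[ut][ordE]) <= 1e-12))
  expect_error(partialCorrelation(x, method = "nosuch"))
})

test_that("the GGM applies the Pearson significance mask", {
  nodes <- glycoformLabel("IgG1", c("G0", "G1", "G2"))
  pearson <- makeTestNetwork(nodes, list(c(1, 2)), kind = "pearson")
  partial <- makeTestNetwork(nodes, list(c(1, 2), c(2, 3)), kind = "partial")
  ggm <- buildGGM(pearson, partial)
  expect_true(significanceMask(ggm)[1, 2])     # both significant
  expect_false(significanceMask(ggm)[2, 3])    # Pearson not significant
  expect_equal(networkKind(ggm), "ggm")
  # empty partial mask yields an empty GGM
  emptyPartial <- makeTestNetwork(nodes, list(), kind = "partial")
  expect_equal(sum(significanceMask(buildGGM(pearson, emptyPartial))), 0L)
  other <- makeTestNetwork(glycoformLabel("IgG2", c("G0", "G1", "G2")),
                           list(), kind = "partial")
  expect_error(buildGGM(pearson, other), "different glycoform sets")
})

test_that("consensus replication counts follow set algebra", {
  nodes <- glycoformLabel("IgG1", c("G0", "G1", "G2", "G2S1"))
  nets <- list(
    makeTestNetwork(nodes, list(c(1, 2), c(2, 3), c(3, 4))),
    makeTestNetwork(nodes, list(c(1, 2), c(2, 3))),
    makeTestNetwork(nodes, list(c(1, 2), c(2, 3), c(1, 4))),
    makeTestNetwork(nodes, list(c(1, 2))))
  cons <- consensusNetwork(nets)
  counts <- replicationCounts(cons)
  expect_equal(counts[1, 2], 4)        # replicated in all
  expect_equal(counts[2, 3], 3)        # in three of four only
  expect_equal(counts[3, 4], 1)
  expect_equal(counts[1, 3], 0)
  # oracle via explicit set algebra
  keys <- lapply(nets, function(nw) {
    ed <- networkEdges(nw, TRUE); paste(ed$node1, ed$node2)
  })
  expect_equal(counts[1, 2], sum(vapply(keys, function(k) "IgG1_G0 IgG1_G1" %in% k, TRUE)))
  allIdentical <- consensusNetwork(nets[c(1, 1, 1)])
  expect_true(all(replicationCounts(allIdentical)[upper.tri(counts)] %in% c(0, 3)))
})

test_that("estimated GGM signs agree with the generating precision matrix", {
  set.seed(16)
  kp <- knownPathway()
  cfg <- simulationConfig(kp, nSamples = 1000, dilutionSd = 0, seed = 16)
  se <- simulateCohort(cfg)
  truth <- S4Vectors::metadata(se)$truth$edges
  pre <- preprocessCohort(se, pqn = FALSE)
  net <- partialCorrelation(pre, confounders = cohortConfounders(se))
  est <- estimates(net)
  strong <- truth[truth$pcor >= 0.2, ]
  idx <- cbind(match(strong$node1, rownames(est)),
               match(strong$node2, rownames(est)))
  expect_true(all(sign(est[idx]) == 1))
  # structural invariants of the estimate
  expect_equal(est, t(est))
  expect_true(all(abs(est) <= 1))
  ggm <- buildGGM(pearsonNetwork(pre), net)
  expect_true(all(which(significanceMask(ggm)) %in% which(significanceMask(net))))
})
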