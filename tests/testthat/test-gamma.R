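test_that("GLS gamma reproduces the hand example and trivial cases", {
  # two unrelated genotyped founders of one MF, A22 = I, Q = 1:
  # p_hat = (1, 0, 0.5, 0.5); centered at 0.5 -> gamma = 8 * 0.5/4 = 1
  gm <- genotypeMatrix(rbind(c(2, 0, 2, 1), c(2, 0, 0, 1)),
                       ids = c("a", "b"))
  a22 <- relationshipMatrix(diag(2), c("a", "b"), "A")
  q <- matrix(1, 2, 1, dimnames = list(c("a", "b"), "MF1"))
  expect_equal(unname(gammaValues(estimateGamma(gm, a22, q))),
               matrix(1, 1, 1))

  # everyone heterozygous everywhere: p_hat = 0.5, Gamma = 0
  gh <- genotypeMatrix(matrix(1, 3, 6), ids = c("a", "b", "c"))
  a22h <- relationshipMatrix(diag(3), c("a", "b", "c"), "A")
  qh <- matrix(1, 3, 1, dimnames = list(c("a", "b", "c"), "MF1"))
  expect_equal(max(abs(gammaValues(estimateGamma(gh, a22h, qh)))), 0)

  # a metafounder without genotyped descendants is a named error
  q2 <- cbind(MF1 = c(1, 1), MF2 = c(0, 0))
  rownames(q2) <- c("a", "b")
  expect_error(estimateGamma(gm, a22, q2), "MF2")
})

test_that("GLS reduces to simple frequency estimation for A22 = I, Q = 1", {
  set.seed(15)
  n <- 40; m <- 200
  M <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.9)), n, m)
  ids <- sprintf("i%02d", 1:n)
  gm <- genotypeMatrix(M, ids = ids)
  a22 <- relationshipMatrix(diag(n), ids, "A")
  q <- matrix(1, n, 1, dimnames = list(ids, "MF1"))
  gam <- estimateGamma(gm, a22, q)
  p <- colMeans(M) / 2
  expect_equal(unname(gammaValues(gam)[1, 1]), 8 * mean((p - 0.5)^2))
})

test_that("gamma estimate is invariant to marker and individual order", {
  set.seed(22)
  base <- simBasePopulations(K = 3, m = 400, nPerPop = 30)
  ids <- genoIds(base$founders)
  ped <- Pedigree(data.frame(id = ids, sire = NA, dam = NA,
                             sire_group = base$founderPop,
                             dam_group = base$founderPop))
  Q <- upgMatrix(ped)[ids, ]
  a22 <- aMatrix(ped, ids)
  g0 <- estimateGamma(base$founders, a22, Q)

  pm <- sample(ncol(genoValues(base$founders)))
  gmPerm <- genotypeMatrix(genoValues(base$founders)[, pm], ids = ids)
  expect_equal(gammaValues(estimateGamma(gmPerm, a22, Q)), gammaValues(g0))

  pi <- sample(length(ids))
  gmI <- subsetGenotypes(base$founders, ids[pi])
  expect_equal(gammaValues(estimateGamma(gmI, aMatrix(ped, ids[pi]),
                                         Q[pi, ])),
               gammaValues(g0))
})

test_that("k scalar is the Gamma moment combination and permutation-invariant", {
  g <- gammaMatrix(rbind(c(0.5, 0.2), c(0.2, 0.5)), c("X", "Y"))
  expect_equal(kScalar(g), 0.90)
  expect_equal(kScalar(gammaMatrix(matrix(0, 3, 3))), 1)
  set.seed(2)
  gr <- randomGamma(5)
  pm <- sample(5)
  expect_equal(kScalar(gammaMatrix(gammaValues(gr)[pm, pm])), kScalar(gr))
})

test_that("gamma diversity summary reports inbreeding and partners", {
  gI <- gammaMatrix(diag(3))
  expect_equal(unname(gammaSummary(gI)$inbreeding), rep(0, 3))

  # uniform base frequencies give the 2/3 diagonal expectation
  set.seed(10)
  p <- runif(50000)
  expect_lt(abs(8 * mean((p - 0.5)^2) - 2 / 3), 0.02)

  g <- gammaMatrix(rbind(c(0.5, 0.2), c(0.2, 0.4)), c("X", "Y"))
  s <- gammaSummary(g)
  expect_equal(s$partners$partner, c("Y", "X"))
  expect_equal(s$partners$value, c(0.2, 0.2))
  expect_equal(s$meanInbreeding, mean(c(0.5, 0.4) - 1))
  expect_equal(unname(s$diagonal["mean"]), 0.45)
})

test_that("UPGMA tree from Gamma is ultrametric and groups similar MFs", {
  # two metafounders: a single cherry at height d12 / 2
  g2 <- gammaMatrix(rbind(c(0.6, 0.2), c(0.2, 0.4)), c("X", "Y"))
  tr <- gammaTree(g2)
  d12 <- (0.6 + 0.4) / 2 - 0.2
  expect_equal(sort(tr$tip.label), c("X", "Y"))
  expect_equal(unname(tr$edge.length), rep(d12 / 2, 2))

  # two well-separated 2-MF blocks come out as sister pairs
  v <- rbind(c(0.6, 0.5, 0.1, 0.1),
             c(0.5, 0.6, 0.1, 0.1),
             c(0.1, 0.1, 0.6, 0.45),
             c(0.1, 0.1, 0.45, 0.6))
  labs <- c("A1", "A2", "B1", "B2")
  tr4 <- gammaTree(gammaMatrix(v, labs))
  expect_true(ape::is.monophyletic(tr4, c("A1", "A2")))
  expect_true(ape::is.monophyletic(tr4, c("B1", "B2")))

  # ultrametric: all tips equidistant from the root
  set.seed(30)
  tr5 <- gammaTree(randomGamma(6))
  depths <- ape::node.depth.edgelength(tr5)[seq_len(6)]
  expect_lt(diff(range(depths)), 1e-10)

  expect_error(gammaTree(gammaMatrix(matrix(0.4, 1, 1), "A")), "at least 2")
})

test_that("gamma recovery from simulated founder populations is accurate", {
  set.seed(55)
  base <- simBasePopulations(K = 4, m = 2000, nPerPop = 100)
  ids <- genoIds(base$founders)
  ped <- Pedigree(data.frame(id = ids, sire = NA, dam = NA,
                             sire_group = base$founderPop,
                             dam_group = base$founderPop))
  gam <- estimateGamma(base$founders, aMatrix(ped, ids),
                       upgMatrix(ped)[ids, ])
  expect_lt(maxAbs(gammaValues(gam) - gammaValues(base$gammaTrue)), 0.05)
})
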