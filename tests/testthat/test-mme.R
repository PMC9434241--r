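# shared small dataset for solver tests
mmeFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    pop <- smallDataset(101)
    vc <- pop$truth$varComp
    cache <<- list(pop = pop, vc = vc, Ainv = aInverse(pop$ped),
                   Q = upgMatrix(pop$ped))
    cache
  }
})

test_that("direct solutions match a dense solve and satisfy the residual bound", {
  fx <- mmeFixture()
  mod <- blupModel("ABLUP", fx$vc[1], fx$vc[2], fx$vc[3])
  sys <- buildMME(fx$pop$phenotypes, mod, fx$Ainv)
  sol <- solveMME(sys)
  expect_lt(sol@meta$relResidual, 1e-10)
  xDense <- solve(as.matrix(sys$C), sys$rhs)
  expect_lt(maxAbs(c(sol@fixed, sol@additive, sol@family) - xDense), 1e-8)

  # conjugate gradients reach the same solutions
  solCG <- solveMME(sys, method = "cg", tol = 1e-10)
  expect_lt(maxAbs(solCG@additive - sol@additive), 1e-6)
  expect_error(solveMME(sys, method = "cg", maxIter = 3L), "converge")
})

test_that("shrinkage behaves as the single-record algebra predicts", {
  # two founders, two records at one site: BLUP shrinks the contrast by
  # the usual variance ratio (hand-derived from the 4x4 system)
  ped <- Pedigree(data.frame(id = c("A", "B"), sire = NA, dam = NA))
  phen <- data.frame(id = c("A", "B"), site = "S1",
                     family = c("f1", "f2"), value = c(1, -1))
  mod <- blupModel("ABLUP", sigmaA2 = 0.25, sigmaF2 = 0.25, sigmaE2 = 0.5)
  sol <- fitBlup(phen, mod, aInverse(ped))
  # independent oracle: a_hat = sigmaA2/(sigmaA2+sigmaF2+sigmaE2) * y_dev
  expect_equal(unname(sol@additive["A"]), 0.25 / 1 * 1, tolerance = 1e-8)
  expect_equal(unname(sol@additive["B"]), -0.25, tolerance = 1e-8)
  expect_equal(unname(sol@family), c(0.25, -0.25), tolerance = 1e-8)
})

test_that("applying k = 1 leaves the system unchanged", {
  fx <- mmeFixture()
  gam1 <- gammaMatrix(matrix(0, 2, 2),
                      gammaLabels(fx$pop$truth$gammaTrue))  # k = 1
  # identical penalty: compare a gamma model with k applied (k = 1)
  AGi <- aGammaInverse(fx$pop$ped, gammaMatrix(
    diag(2) * 1e-8 + gammaValues(gam1), gammaLabels(gam1)))
  modK <- blupModel("ABLUP_MF", fx$vc[1], fx$vc[2], fx$vc[3], applyK = TRUE)
  modNoK <- blupModel("ABLUP_MF", fx$vc[1], fx$vc[2], fx$vc[3],
                      applyK = FALSE)
  sK <- buildMME(fx$pop$phenotypes, modK, AGi, gamma = gam1)
  sN <- buildMME(fx$pop$phenotypes, modNoK, AGi)
  expect_equal(sK$k, 1)
  expect_lt(maxAbs(sK$C - sN$C), 1e-12)
})

test_that("UPG solutions equal the explicit group-covariate formulation", {
  fx <- mmeFixture()
  mod <- blupModel("ABLUP_UPG", fx$vc[1], fx$vc[2], fx$vc[3])
  sol <- fitBlup(fx$pop$phenotypes, mod, fx$Ainv, q = fx$Q)

  # oracle: groups as unpenalized covariates (last column dropped),
  # dense normal equations
  phen <- fx$pop$phenotypes
  ents <- entityIds(fx$Ainv)
  Qr <- fx$Q[, -ncol(fx$Q), drop = FALSE]
  X <- stats::model.matrix(~ 0 + factor(phen$site))
  Xf <- cbind(X, Qr[match(phen$id, rownames(fx$Q)), , drop = FALSE])
  n <- nrow(phen)
  Z1 <- matrix(0, n, length(ents))
  Z1[cbind(seq_len(n), match(phen$id, ents))] <- 1
  Z2 <- stats::model.matrix(~ 0 + factor(phen$family))
  lamA <- fx$vc[3] / fx$vc[1]; lamF <- fx$vc[3] / fx$vc[2]
  W <- cbind(Xf, Z1, Z2)
  C <- crossprod(W)
  ia <- ncol(Xf) + seq_along(ents)
  im <- ncol(Xf) + length(ents) + seq_len(ncol(Z2))
  C[ia, ia] <- C[ia, ia] + as.matrix(fx$Ainv@values) * lamA
  C[im, im] <- C[im, im] + diag(ncol(Z2)) * lamF
  x <- solve(C, crossprod(W, phen$value))
  ghat <- x[ncol(X) + seq_len(ncol(Qr))]
  total <- x[ia] + as.vector(fx$Q %*% c(ghat, 0))
  expect_lt(maxAbs(total - unname(sol@additive)), 1e-8)
  expect_lt(maxAbs(c(ghat, 0) - unname(sol@groups)), 1e-8)
})

test_that("solutions are invariant to record order and to residual-scaled duplication", {
  fx <- mmeFixture()
  mod <- blupModel("ABLUP", fx$vc[1], fx$vc[2], fx$vc[3])
  phen <- fx$pop$phenotypes
  sol <- fitBlup(phen, mod, fx$Ainv)

  set.seed(1)
  solPerm <- fitBlup(phen[sample(nrow(phen)), ], mod, fx$Ainv)
  expect_lt(maxAbs(solPerm@additive - sol@additive), 1e-9)

  # duplicating every record while doubling the residual variance leaves
  # the normal equations proportional, hence the solutions unchanged
  mod2 <- blupModel("ABLUP", fx$vc[1], fx$vc[2], 2 * fx$vc[3])
  solDup <- fitBlup(rbind(phen, phen), mod2, fx$Ainv)
  expect_lt(maxAbs(solDup@additive - sol@additive), 1e-9)
})

test_that("HBLUP with G = A22 reproduces ABLUP solutions", {
  fx <- mmeFixture()
  gids <- fx$pop$genotypedIds
  A22 <- aMatrix(fx$pop$ped, gids)
  Gfake <- relationshipMatrix(as.matrix(A22), gids, "G_blend")
  Hinv <- hInverse(fx$Ainv, A22, Gfake, gids)
  modA <- blupModel("ABLUP", fx$vc[1], fx$vc[2], fx$vc[3])
  modH <- blupModel("HBLUP", fx$vc[1], fx$vc[2], fx$vc[3])
  sA <- fitBlup(fx$pop$phenotypes, modA, fx$Ainv)
  sH <- fitBlup(fx$pop$phenotypes, modH, Hinv)
  expect_lt(maxAbs(sH@additive - sA@additive), 1e-8)
})

test_that("metafounder effects are shrunk to zero as Gamma vanishes", {
  fx <- mmeFixture()
  gam <- gammaMatrix(diag(2) * 1e-8,
                     gammaLabels(fx$pop$truth$gammaTrue))
  AGi <- aGammaInverse(fx$pop$ped, gam)
  mod <- blupModel("ABLUP_MF", fx$vc[1], fx$vc[2], fx$vc[3],
                   applyK = FALSE)
  sMF <- fitBlup(fx$pop$phenotypes, mod, AGi)
  modA <- blupModel("ABLUP", fx$vc[1], fx$vc[2], fx$vc[3])
  sA <- fitBlup(fx$pop$phenotypes, modA, fx$Ainv)
  mfIds <- gammaLabels(gam)
  expect_lt(maxAbs(sMF@additive[mfIds]), 1e-6)
  indIds <- entityIds(fx$Ainv)
  expect_lt(maxAbs(sMF@additive[indIds] - sA@additive[indIds]), 1e-6)
})

test_that("per-site residual variances weight the records", {
  fx <- mmeFixture()
  sites <- unique(fx$pop$phenotypes$site)
  se <- setNames(rep(fx$vc[3], length(sites)), sites)
  modP <- blupModel("ABLUP", fx$vc[1], fx$vc[2], se,
                    residualMode = "per-site")
  modH <- blupModel("ABLUP", fx$vc[1], fx$vc[2], fx$vc[3])
  sP <- fitBlup(fx$pop$phenotypes, modP, fx$Ainv)
  sH <- fitBlup(fx$pop$phenotypes, modH, fx$Ainv)
  expect_lt(maxAbs(sP@additive - sH@additive), 1e-9)
  seBad <- setNames(se, rev(paste0("X", seq_along(se))))
  expect_error(fitBlup(fx$pop$phenotypes,
                       blupModel("ABLUP", fx$vc[1], fx$vc[2], seBad,
                                 residualMode = "per-site"), fx$Ainv),
               "per-site")
})

test_that("unknown ids, sites or variance misuse raise informative errors", {
  fx <- mmeFixture()
  mod <- blupModel("ABLUP", fx$vc[1], fx$vc[2], fx$vc[3])
  phenBad <- fx$pop$phenotypes
  phenBad$id[1] <- "nobody"
  expect_error(buildMME(phenBad, mod, fx$Ainv), "nobody")
  expect_error(buildMME(fx$pop$phenotypes, mod,
                        relationshipMatrix(diag(2), c("a", "b"), "A")),
               "kind")
  expect_error(blupModel("ABLUP", -1, 0.1, 0.8), "positive|> 0")
  expect_error(blupModel("ABLUP", 0.1, 0.1, 0.8, applyK = TRUE),
               "metafounder")
})

test_that("EM-REML recovers components on a small correctly-specified fixture", {
  pop <- simPopulation("desk", seed = 7, K = 2, m = 120, nPerPop = 30,
                       fst = 0.01, nGenerations = 2L, familiesPerGen = 20L,
                       progenyPerFamily = 15L, nSites = 3L,
                       varComp = c(sigmaA2 = 0.25, sigmaF2 = 0.1,
                                   sigmaE2 = 0.65))
  est <- emREML(pop$phenotypes, aInverse(pop$ped), maxIter = 1200L)
  expect_true(est$converged)
  expect_lt(abs(est$sigmaA2 - 0.25), 0.15)
  expect_lt(abs(est$sigmaE2 - 0.65), 0.15)
  expect_equal(est$h2,
               est$sigmaA2 / (est$sigmaA2 + est$sigmaF2 + est$sigmaE2))
})

test_that("EM-REML pins a zero family variance at its floor", {
  pop <- simPopulation("desk", seed = 8, K = 2, m = 120, nPerPop = 20,
                       fst = 0.01, nGenerations = 2L, familiesPerGen = 15L,
                       progenyPerFamily = 10L, nSites = 2L,
                       varComp = c(sigmaA2 = 0.3, sigmaF2 = 1e-9,
                                   sigmaE2 = 0.7))
  # rebuild phenotypes without any family signal
  est <- emREML(pop$phenotypes, aInverse(pop$ped), maxIter = 400L,
                init = c(0.3, 1e-6, 0.7))
  expect_lt(est$sigmaF2, 1e-3)
})
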