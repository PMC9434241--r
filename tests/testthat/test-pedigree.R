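test_that("pedigree construction sorts, materializes phantoms, rejects cycles", {
  # child listed first is reordered after its parents
  ped <- Pedigree(data.frame(id = c("C", "A", "B"),
                             sire = c("A", NA, NA), dam = c("B", NA, NA)))
  expect_equal(entityIds(ped), c("A", "B", "C"))

  # referenced-but-unlisted parent becomes a founder and is reported
  ped2 <- Pedigree(data.frame(id = c("X"), sire = c("P"), dam = c("0")))
  expect_setequal(ped2@phantoms, "P")
  expect_true(all(c("P", "X") %in% entityIds(ped2)))

  # parent loop is a cycle error naming an individual on it
  expect_error(Pedigree(data.frame(id = c("A", "B"), sire = c("B", "A"),
                                   dam = c(NA, NA))),
               "cycle")
  expect_error(Pedigree(data.frame(id = c("A", "A"), sire = NA, dam = NA)),
               "duplicate")
})

test_that("aMatrix reproduces hand-computed relationship coefficients", {
  A <- as.matrix(aMatrix(trioPed()))
  expect_equal(unname(A), rbind(c(1, 0, 0.5), c(0, 1, 0.5), c(0.5, 0.5, 1)))

  # full sibs: a(D,E) = 0.5, no inbreeding
  ped <- Pedigree(data.frame(id = c("A", "B", "D", "E"),
                             sire = c(NA, NA, "A", "A"),
                             dam = c(NA, NA, "B", "B")))
  A <- as.matrix(aMatrix(ped))
  expect_equal(A["D", "E"], 0.5)
  expect_equal(A["D", "D"], 1)

  # parent-offspring mating: F(F) = 0.25 by the tabular recursion
  A <- as.matrix(aMatrix(inbredPed()))
  expect_equal(A["F", "F"], 1.25)

  expect_error(aMatrix(trioPed(), subset = c("A", "nope")), "subset")
  expect_equal(rownames(as.matrix(aMatrix(trioPed(), subset = c("C", "A")))),
               c("C", "A"))
})

test_that("aInverse matches known trio inverse and the dense oracle", {
  Ai <- as.matrix(aInverse(trioPed()))
  expect_equal(unname(Ai),
               rbind(c(1.5, 0.5, -1), c(0.5, 1.5, -1), c(-1, -1, 2)))

  foundersOnly <- Pedigree(data.frame(id = c("A", "B"), sire = NA, dam = NA))
  expect_equal(unname(as.matrix(aInverse(foundersOnly))), diag(2))

  # dense-inverse oracle on a random 200-individual pedigree
  set.seed(31)
  ped <- Pedigree(randomPedigreeDF(200))
  A <- as.matrix(aMatrix(ped))
  Ai <- as.matrix(aInverse(ped))
  expect_lt(maxAbs(Ai %*% A - diag(200)), 1e-8)
})

test_that("aGammaMatrix follows the single-MF closed form and two-MF recursion", {
  # single metafounder: AGamma = (1 - g/2) A + g on the individual block
  ped <- Pedigree(data.frame(id = c("A", "B"), sire = NA, dam = NA,
                             sire_group = "MF1", dam_group = "MF1"))
  AG <- as.matrix(aGammaMatrix(ped, gammaMatrix(matrix(0.5, 1, 1), "MF1")))
  expect_equal(AG["A", "A"], 1.25)
  expect_equal(AG["A", "B"], 0.5)

  # zero Gamma reduces to classical A
  set.seed(5)
  pedR <- Pedigree(randomPedigreeDF(60, withGroups = TRUE, K = 1))
  g0 <- gammaMatrix(matrix(0, 1, 1), "g1")
  expect_lt(maxAbs(as.matrix(aGammaMatrix(pedR, g0))[1:60, 1:60] -
                     as.matrix(aMatrix(pedR))), 1e-12)

  # two MFs: cross-founder relationship equals Gamma_12
  g2 <- gammaMatrix(rbind(c(0.5, 0.2), c(0.2, 0.5)), c("g1", "g2"))
  ped2 <- Pedigree(data.frame(id = c("A", "B"), sire = NA, dam = NA,
                              sire_group = c("g1", "g2"),
                              dam_group = c("g1", "g2")))
  AG2 <- as.matrix(aGammaMatrix(ped2, g2))
  expect_equal(AG2["A", "B"], 0.2)
  expect_equal(unname(diag(AG2)[1:2]), c(1.25, 1.25))

  expect_error(aGammaMatrix(trioPed(), g2), "without metafounder label")
})

test_that("single-MF closed form holds for any gamma on a random pedigree", {
  set.seed(77)
  ped <- Pedigree(randomPedigreeDF(80, withGroups = TRUE, K = 1))
  A <- as.matrix(aMatrix(ped))
  for (g in c(0, 0.25, 0.5, 1)) {
    AG <- as.matrix(aGammaMatrix(ped, gammaMatrix(matrix(g, 1, 1), "g1")))
    expect_lt(maxAbs(AG[1:80, 1:80] - ((1 - g / 2) * A + g)), 1e-10)
  }
})

test_that("aGammaInverse equals the dense inverse of aGammaMatrix", {
  set.seed(13)
  ped <- Pedigree(randomPedigreeDF(300, withGroups = TRUE, K = 3))
  gam <- randomGamma(3)
  AG <- as.matrix(aGammaMatrix(ped, gam))
  AGi <- as.matrix(aGammaInverse(ped, gam))
  expect_lt(maxAbs(AGi %*% AG - diag(nrow(AG))), 1e-8)

  # diag(AGamma) >= diag(A) when Gamma is nonnegative
  expect_true(all(diag(AG)[1:300] >= diag(as.matrix(aMatrix(ped))) - 1e-12))

  # hand-inverted 2x2: single founder, one MF, gamma 0.5
  ped1 <- Pedigree(data.frame(id = "A", sire = NA, dam = NA,
                              sire_group = "MF1", dam_group = "MF1"))
  AGi1 <- as.matrix(aGammaInverse(ped1,
                                  gammaMatrix(matrix(0.5, 1, 1), "MF1")))
  M <- rbind(c(1.25, 0.5), c(0.5, 0.5))   # [individual, MF] block by hand
  expect_lt(maxAbs(AGi1 - solve(M)), 1e-12)

  # ridge limit: individual block approaches plain A-inverse
  gR <- gammaMatrix(matrix(1e-8, 1, 1), "g1")
  pedS <- Pedigree(randomPedigreeDF(50, withGroups = TRUE, K = 1))
  AiG <- as.matrix(aGammaInverse(pedS, gR))[1:50, 1:50]
  expect_lt(maxAbs(AiG - as.matrix(aInverse(pedS))), 1e-6)

  expect_error(aGammaInverse(ped1, gammaMatrix(matrix(0, 1, 1), "MF1")),
               "singular")
})

test_that("upgMatrix rows are expected group contributions summing to one", {
  df <- data.frame(
    id = c("F1", "F2", "F3", "C1", "C2"),
    sire = c(NA, NA, NA, "F1", "C1"),
    dam = c(NA, NA, NA, "F2", "F3"),
    sire_group = c("g1", "g2", "g2", NA, NA),
    dam_group = c("g1", "g2", "g2", NA, NA))
  Q <- upgMatrix(Pedigree(df))
  expect_equal(Q["F1", ], c(g1 = 1, g2 = 0))
  expect_equal(Q["C1", ], c(g1 = 0.5, g2 = 0.5))          # g1 x g2 founders
  expect_equal(Q["C2", ], c(g1 = 0.25, g2 = 0.75))        # (g1xg2) x g2
  set.seed(3)
  Qr <- upgMatrix(Pedigree(randomPedigreeDF(150, withGroups = TRUE, K = 4)))
  expect_equal(unname(rowSums(Qr)), rep(1, 150))
})

test_that("opposing-homozygote screen separates true pairs from errors", {
  set.seed(9)
  m <- 1000
  pA <- rbinom(m, 2, 0.5); pB <- rbinom(m, 2, 0.5)
  kid <- (pA == 2) + (pA == 1) * rbinom(m, 1, 0.5) +
    (pB == 2) + (pB == 1) * rbinom(m, 1, 0.5)
  unrel <- rbinom(m, 2, 0.5)
  geno <- genotypeMatrix(rbind(A = pA, B = pB, K = kid, U = unrel),
                         ids = c("A", "B", "K", "U"))

  # true parent-offspring pair: rate exactly 0
  pedTrue <- Pedigree(data.frame(id = c("A", "B", "K"),
                                 sire = c(NA, NA, "A"), dam = c(NA, NA, "B")))
  cf <- genotypeConflicts(pedTrue, geno)
  expect_true(all(cf$rate == 0))

  # unrelated declared pair at p = 0.5: rate near 2 * 0.25 * 0.25 = 0.125
  pedWrong <- Pedigree(data.frame(id = c("U", "K"), sire = c(NA, "U"),
                                  dam = c(NA, NA)))
  cfW <- genotypeConflicts(pedWrong, geno, threshold = 0.01)
  se <- sqrt(0.125 * 0.875 / m)
  expect_lt(abs(cfW$rate - 0.125), 3 * se)
  expect_true(cfW$flagged)

  pedNo <- Pedigree(data.frame(id = "Z", sire = NA, dam = NA))
  expect_error(genotypeConflicts(pedNo, geno), "no ids shared")
})
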