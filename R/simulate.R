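## Seed-deterministic population simulator: divergent base populations
## drifting along a bifurcating tree, a multi-generation two-program
## pedigree with per-locus gene dropping, and multi-site standardized
## phenotypes with additive + full-sib-family + residual structure.
## Full truth (base frequencies, Gamma, TBV, components) is returned for
## recovery tests.

#' Simulate divergent base populations
#'
#' Ancestral allele frequencies are drawn uniform on \[0.05, 0.95\] and
#' drift along a balanced bifurcating tree by Balding-Nichols steps
#' (Beta(p(1-F)/F, (1-p)(1-F)/F) at each branch). K populations are
#' assigned to distinct leaves; founder genotypes are Binomial(2, p).
#' The true Gamma is 8 times the second moment about 0.5 of the realized
#' base frequencies.
#'
#' @param K number of base populations (>= 2).
#' @param m number of biallelic markers (>= 100).
#' @param nPerPop founders per population.
#' @param fst per-level divergence, scalar or vector recycled over tree
#'   levels, each value in (0, 0.5).
#' @param treeDepth bifurcation levels (raised automatically when
#'   2^treeDepth < K).
#' @param seed optional integer seed (`set.seed` on entry).
#' @return List: `freq` (K x m realized base frequencies), `founders`
#'   ([GenotypeMatrix-class]), `founderPop` (named pop labels),
#'   `gammaTrue` ([GammaMatrix-class]), `treeDistance` (K x K branch
#'   distance between the populations' leaves), `popLabels`.
#' @export
simBasePopulations <- function(K, m, nPerPop = 100L, fst = 0.05,
                               treeDepth = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (K < 2L) stop("K must be at least 2")
  if (m < 100L) stop("need at least 100 markers")
  if (any(fst <= 0 | fst >= 0.5)) stop("fst values must be in (0, 0.5)")
  depth <- max(treeDepth, ceiling(log2(K)))
  fstv <- rep_len(fst, depth)
  p0 <- runif(m, 0.05, 0.95)
  freqs <- list(p0)
  paths <- list(integer(0))                 # branch choices from the root
  for (lev in seq_len(depth)) {
    Fd <- fstv[lev]
    nf <- list(); np <- list()
    for (l in seq_along(freqs)) {
      p <- freqs[[l]]
      for (side in 0:1) {
        child <- if (Fd < 1e-8) p else
          rbeta(m, p * (1 - Fd) / Fd, (1 - p) * (1 - Fd) / Fd)
        nf[[length(nf) + 1L]] <- child
        np[[length(np) + 1L]] <- c(paths[[l]], side)
      }
    }
    freqs <- nf; paths <- np
  }
  leaf <- sample(length(freqs), K)
  P <- do.call(rbind, freqs[leaf])
  popLabels <- paste0("P", seq_len(K))
  rownames(P) <- popLabels
  ## pairwise tree distance: branches since the most recent common branch
  td <- matrix(0, K, K, dimnames = list(popLabels, popLabels))
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
    a <- paths[[leaf[i]]]; b <- paths[[leaf[j]]]
    shared <- 0L
    while (shared < depth && a[shared + 1L] == b[shared + 1L])
      shared <- shared + 1L
    td[i, j] <- td[j, i] <- 2L * (depth - shared)
  }
  ids <- character(0); pop <- character(0)
  geno <- matrix(0L, K * nPerPop, m)
  for (k in seq_len(K)) {
    rows <- (k - 1L) * nPerPop + seq_len(nPerPop)
    geno[rows, ] <- matrix(
      rbinom(nPerPop * m, 2L, rep(P[k, ], each = nPerPop)), nPerPop, m)
    ids <- c(ids, sprintf("%s_F%03d", popLabels[k], seq_len(nPerPop)))
    pop <- c(pop, rep(popLabels[k], nPerPop))
  }
  markers <- sprintf("M%04d", seq_len(m))
  gammaTrue <- gammaMatrix(8 * tcrossprod(P - 0.5) / m, popLabels,
                           meta = list(truth = TRUE, markers = m))
  list(freq = P,
       founders = genotypeMatrix(geno, ids, markers),
       founderPop = setNames(pop, ids),
       gammaTrue = gammaTrue,
       treeDistance = td,
       popLabels = popLabels)
}

## one gamete from a parent's gene-content vector
.gamete <- function(g, m) {
  (g == 2L) + (g == 1L) * rbinom(m, 1L, 0.5)
}

#' Simulate a multi-generation pedigree with gene dropping
#'
#' Founders (with their base-population labels as metafounder groups)
#' are split across breeding programs; each generation mates random
#' within-program parent pairs (with occasional cross-program parents)
#' into full-sib families and drops genes locus by locus. The genotyped
#' subset emulates operational panels: every individual used as a parent
#' plus a random fraction of the remaining progeny.
#'
#' @param base output of [simBasePopulations()].
#' @param nGenerations number of progeny generations.
#' @param familiesPerGen full-sib families per generation.
#' @param progenyPerFamily progeny per family.
#' @param nPrograms number of breeding programs (populations are split
#'   among them round-robin).
#' @param crossProgramProb probability a family takes its second parent
#'   from another program.
#' @param genoPropProgeny fraction of non-parent progeny genotyped.
#' @param seed optional integer seed.
#' @return List: `ped` ([Pedigree-class]), `geno` (all individuals,
#'   [GenotypeMatrix-class]), `genotypedIds`, `family` (named full-sib
#'   family of each progeny), `generation`, `program`, `base`.
#' @export
simPedigree <- function(base, nGenerations = 3L, familiesPerGen = 40L,
                        progenyPerFamily = 25L, nPrograms = 2L,
                        crossProgramProb = 0.05, genoPropProgeny = 0.3,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  founders <- genoIds(base$founders)
  m <- length(base$founders@markers)
  K <- length(base$popLabels)
  popProgram <- setNames(((seq_len(K) - 1L) %% nPrograms) + 1L,
                         base$popLabels)
  program <- popProgram[base$founderPop]
  names(program) <- founders
  if (min(table(factor(program, levels = seq_len(nPrograms)))) < 2L)
    stop("insufficient founders in a program to form families")
  id <- founders
  sire <- rep(NA_character_, length(founders))
  dam <- rep(NA_character_, length(founders))
  sg <- dg <- unname(base$founderPop)
  family <- character(0)
  generation <- setNames(rep(0L, length(founders)), founders)
  pool <- split(founders, program[founders])
  usedAsParent <- character(0)
  G <- genoValues(base$founders)
  allGeno <- matrix(0L,
                    length(founders) +
                      nGenerations * familiesPerGen * progenyPerFamily, m)
  allGeno[seq_len(nrow(G)), ] <- G
  nrows <- nrow(G)
  rowIdx <- setNames(seq_len(nrow(G)), founders)
  famOf <- character(0)
  for (g in seq_len(nGenerations)) {
    newIds <- character(0)
    for (f in seq_len(familiesPerGen)) {
      prog <- ((f - 1L) %% nPrograms) + 1L
      pp <- pool[[as.character(prog)]]
      s <- sample(pp, 1L)
      other <- if (nPrograms > 1L && runif(1L) < crossProgramProb) {
        unlist(pool[setdiff(names(pool), as.character(prog))])
      } else setdiff(pp, s)
      d <- sample(other, 1L)
      usedAsParent <- c(usedAsParent, s, d)
      famId <- sprintf("FAM_G%d_%03d", g, f)
      gs <- allGeno[rowIdx[[s]], ]
      gd <- allGeno[rowIdx[[d]], ]
      for (pgy in seq_len(progenyPerFamily)) {
        child <- sprintf("G%d_%03d_%02d", g, f, pgy)
        cg <- .gamete(gs, m) + .gamete(gd, m)
        nrows <- nrows + 1L
        allGeno[nrows, ] <- cg
        rowIdx[[child]] <- nrows
        id <- c(id, child)
        sire <- c(sire, s); dam <- c(dam, d)
        sg <- c(sg, NA_character_); dg <- c(dg, NA_character_)
        famOf[child] <- famId
        generation[child] <- g
        newIds <- c(newIds, child)
      }
    }
    ## progeny inherit the program of their family (sire's program)
    program[newIds] <- program[sire[match(newIds, id)]]
    pool <- split(newIds, program[newIds])
  }
  allGeno <- allGeno[seq_len(nrows), , drop = FALSE]
  geno <- genotypeMatrix(allGeno[rowIdx[id], , drop = FALSE], id,
                         base$founders@markers)
  ped <- Pedigree(data.frame(id = id, sire = sire, dam = dam,
                             sire_group = sg, dam_group = dg,
                             stringsAsFactors = FALSE))
  usedAsParent <- unique(usedAsParent)
  nonParents <- setdiff(id, c(founders, usedAsParent))
  extra <- sort(sample(nonParents,
                       round(genoPropProgeny * length(nonParents))))
  genotypedIds <- ped@id[ped@id %in%
                           unique(c(founders, usedAsParent, extra))]
  list(ped = ped, geno = geno, genotypedIds = genotypedIds,
       family = famOf, generation = generation, program = program,
       base = base)
}

#' Simulate multi-site standardized phenotypes
#'
#' True breeding values are built from marker effects on 0.5-centered
#' gene content (`alpha ~ N(0, sigmaA2/(m/2))`, then rescaled so the
#' realized TBV variance equals sigmaA2 exactly), so base-population
#' means diverge naturally with allele frequencies and genomic models
#' have real signal to exploit. Every non-founder is phenotyped once;
#' full-sib family effects and residuals are added, records are spread
#' over sites within family, and each site is standardized to mean 0,
#' SD 1 (n-1 divisor).
#'
#' @param sim output of [simPedigree()].
#' @param nSites number of trial sites (>= 1).
#' @param varComp numeric `c(sigmaA2, sigmaF2, sigmaE2)` on the
#'   standardized-phenotype scale.
#' @param seed optional integer seed.
#' @return List: `phenotypes` (data frame `id`, `site`, `family`,
#'   `value`), `truth` (named TBV for all individuals, the components,
#'   marker-effect scale), `focalCandidates` (parents with phenotyped
#'   progeny).
#' @export
simPhenotypes <- function(sim, nSites = 4L,
                          varComp = c(sigmaA2 = 0.171, sigmaF2 = 0.043,
                                      sigmaE2 = 0.805),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nSites < 1L) stop("need at least one site")
  if (any(varComp <= 0)) stop("variance components must be positive")
  sa <- varComp[[1L]]; sf <- varComp[[2L]]; se <- varComp[[3L]]
  M <- genoValues(sim$geno)
  m <- ncol(M)
  alpha <- rnorm(m, 0, sqrt(sa / (m / 2)))
  tbvRaw <- as.vector((M - 1) %*% alpha)
  scl <- sqrt(sa / var(tbvRaw))
  tbv <- setNames(tbvRaw * scl, genoIds(sim$geno))
  phenoIds <- names(sim$family)
  fam <- sim$family[phenoIds]
  famLevels <- unique(fam)
  famEff <- setNames(rnorm(length(famLevels), 0, sqrt(sf)), famLevels)
  siteOf <- character(length(phenoIds))
  names(siteOf) <- phenoIds
  for (fl in famLevels) {
    members <- phenoIds[fam == fl]
    siteOf[members] <- sample(sprintf("S%d", rep_len(seq_len(nSites),
                                                     length(members))))
  }
  y <- tbv[phenoIds] + famEff[fam] + rnorm(length(phenoIds), 0, sqrt(se))
  ph <- data.frame(id = phenoIds, site = unname(siteOf),
                   family = unname(fam), value = unname(y),
                   stringsAsFactors = FALSE)
  ph <- standardizeByTrial(ph)
  parents <- unique(c(sim$ped@sire, sim$ped@dam))
  parents <- parents[!is.na(parents)]
  hasPhenoKid <- vapply(parents, function(p)
    any((sim$ped@sire %in% p | sim$ped@dam %in% p) &
          sim$ped@id %in% phenoIds), logical(1L))
  list(phenotypes = ph,
       truth = list(tbv = tbv, varComp = c(sigmaA2 = sa, sigmaF2 = sf,
                                           sigmaE2 = se),
                    alphaScale = scl),
       focalCandidates = parents[hasPhenoKid])
}

#' One-call desk-scale population simulation
#'
#' Bundles base populations, pedigree + gene dropping, and phenotypes
#' with full truth. The `"desk"` preset (6 base populations in 2
#' programs, 3 generations of 40 x 25 full-sib families, 2,000 markers,
#' 30% of non-parent progeny genotyped, 4 sites) finishes the whole
#' pipeline in minutes on one CPU while keeping family and provenance
#' structure estimable; `"large"` doubles the family count and sites.
#'
#' @param preset `"desk"` or `"large"`.
#' @param seed integer seed driving every stochastic step.
#' @param ... overrides passed to the component simulators
#'   (`K`, `m`, `nPerPop`, `fst`, `nGenerations`, `familiesPerGen`,
#'   `progenyPerFamily`, `genoPropProgeny`, `nSites`, `varComp`).
#' @return List combining the component outputs: `ped`, `geno`,
#'   `genotypedIds`, `phenotypes`, `truth` (incl. `gammaTrue`),
#'   `family`, `program`, `focalCandidates`, `base`.
#' @export
simPopulation <- function(preset = c("desk", "large"), seed = NULL, ...) {
  preset <- match.arg(preset)
  defaults <- list(K = 6L, m = 2000L, nPerPop = 20L, fst = 0.05,
                   treeDepth = 3L, nGenerations = 3L, familiesPerGen = 40L,
                   progenyPerFamily = 25L, nPrograms = 2L,
                   crossProgramProb = 0.05, genoPropProgeny = 0.3,
                   nSites = 4L,
                   varComp = c(sigmaA2 = 0.171, sigmaF2 = 0.043,
                               sigmaE2 = 0.805))
  if (preset == "large") {
    defaults$familiesPerGen <- 80L
    defaults$nSites <- 8L
    defaults$nPerPop <- 40L
  }
  args <- utils::modifyList(defaults, list(...))
  if (!is.null(seed)) set.seed(seed)
  base <- simBasePopulations(K = args$K, m = args$m,
                             nPerPop = args$nPerPop, fst = args$fst,
                             treeDepth = args$treeDepth)
  sim <- simPedigree(base, nGenerations = args$nGenerations,
                     familiesPerGen = args$familiesPerGen,
                     progenyPerFamily = args$progenyPerFamily,
                     nPrograms = args$nPrograms,
                     crossProgramProb = args$crossProgramProb,
                     genoPropProgeny = args$genoPropProgeny)
  phe <- simPhenotypes(sim, nSites = args$nSites, varComp = args$varComp)
  list(ped = sim$ped, geno = sim$geno, genotypedIds = sim$genotypedIds,
       phenotypes = phe$phenotypes,
       truth = c(phe$truth, list(gammaTrue = base$gammaTrue,
                                 baseFreq = base$freq)),
       family = sim$family, program = sim$program,
       focalCandidates = phe$focalCandidates, base = base)
}
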