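## Mixed-model equations for the site + additive + full-sib-family model
## y = Xb + Z1 a + Z2 f + e, assembled in precision form
## C = W' R^-1 W + Sigma^-1 for the five variants, solved directly or by
## preconditioned conjugate gradients, plus a small-scale EM-REML.

.VARIANT_KIND <- c(ABLUP = "A_inv", ABLUP_UPG = "A_inv",
                   ABLUP_MF = "A_gamma_inv", HBLUP = "H_inv",
                   HBLUP_MF = "H_gamma_inv")

.checkPhenotypes <- function(phenotypes) {
  need <- c("id", "site", "family", "value")
  if (!all(need %in% names(phenotypes)))
    stop("phenotypes need columns id, site, family, value")
  if (!nrow(phenotypes)) stop("no phenotype records")
  invisible(TRUE)
}

#' Assemble the mixed-model equations
#'
#' Builds the symmetric sparse system for one model variant. Sites enter
#' as a full fixed-effect indicator block (no intercept, which fixes
#' identifiability the same way as dropping a reference level); the
#' additive block is penalized by the supplied inverse relationship
#' matrix at precision `k / sigmaA2` (k = 1 unless the model applies the
#' Gamma-derived scalar); families by `1 / sigmaF2`. The ABLUP_UPG
#' variant appends unknown-parent-group equations by the Quaas-Pollak
#' device (no penalty on groups, last group constrained to zero), so its
#' additive solutions are total merit including expected group
#' contribution.
#'
#' @param phenotypes data frame with columns `id`, `site`, `family`,
#'   `value` (pre-adjusted, per-trial-standardized trait).
#' @param model a [BlupModel-class].
#' @param kinv inverse relationship [RelationshipMatrix-class] whose kind
#'   matches the variant (`A_inv`, `A_gamma_inv`, `H_inv`,
#'   `H_gamma_inv`).
#' @param gamma [GammaMatrix-class], required when `model@applyK`.
#' @param q group-contribution matrix over the individuals of `kinv`
#'   (ABLUP_UPG only).
#' @return A list of class `"mmeSystem"`: coefficient matrix `C`, `rhs`,
#'   index `blocks`, level names, and bookkeeping for the solver.
#' @export
buildMME <- function(phenotypes, model, kinv, gamma = NULL, q = NULL) {
  .checkPhenotypes(phenotypes)
  variant <- model@variant
  wantKind <- .VARIANT_KIND[[variant]]
  if (relKind(kinv) != wantKind)
    stop("variant ", variant, " needs a kinv of kind ", wantKind,
         ", got ", relKind(kinv))
  ents <- entityIds(kinv)
  ridx <- match(phenotypes$id, ents)
  if (anyNA(ridx)) {
    bad <- unique(phenotypes$id[is.na(ridx)])
    stop("phenotyped ids absent from relationship structure: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  nrec <- nrow(phenotypes)
  site <- factor(phenotypes$site, levels = unique(phenotypes$site))
  fam <- factor(phenotypes$family, levels = unique(phenotypes$family))
  S <- nlevels(site); nEnt <- length(ents); nFam <- nlevels(fam)
  y <- as.numeric(phenotypes$value)

  ## residual precision per record
  if (model@residualMode == "per-site") {
    se2 <- model@sigmaE2[levels(site)]
    if (anyNA(se2))
      stop("per-site sigmaE2 must be named for every site")
    rvec <- 1 / se2[as.integer(site)]
  } else {
    rvec <- rep(1 / model@sigmaE2, nrec)
  }

  X <- Matrix::sparseMatrix(i = seq_len(nrec), j = as.integer(site),
                            x = 1, dims = c(nrec, S))
  Z1 <- Matrix::sparseMatrix(i = seq_len(nrec), j = ridx, x = 1,
                             dims = c(nrec, nEnt))
  Z2 <- Matrix::sparseMatrix(i = seq_len(nrec), j = as.integer(fam),
                             x = 1, dims = c(nrec, nFam))
  W <- cbind(X, Z1, Z2)
  Wr <- W * rvec                       # R^-1 W (rowwise scaling)
  C <- Matrix::t(W) %*% Wr
  rhs <- as.vector(Matrix::t(W) %*% (rvec * y))

  kval <- 1
  if (model@applyK) {
    if (is.null(gamma)) stop("applyK requires the Gamma matrix")
    kval <- kScalar(gamma)
  }
  precA <- kval / model@sigmaA2
  aBlock <- S + seq_len(nEnt)
  fBlock <- S + nEnt + seq_len(nFam)
  Kv <- kinv@values
  C <- C + Matrix::bdiag(Matrix::Diagonal(S, 0), Kv * precA,
                         Matrix::Diagonal(nFam, 1 / model@sigmaF2))

  gBlock <- integer(0)
  groupLevels <- character(0)
  Qfull <- NULL
  if (variant == "ABLUP_UPG") {
    if (is.null(q)) stop("ABLUP_UPG requires the group-contribution matrix q")
    Qfull <- as.matrix(q)
    if (nrow(Qfull) != nEnt || !identical(rownames(Qfull), ents))
      stop("q rows must match the kinv entities, same order")
    groupLevels <- colnames(Qfull)
    K <- ncol(Qfull)
    if (K < 2L) stop("need at least 2 groups for ABLUP_UPG")
    Qr <- Qfull[, -K, drop = FALSE]     # last group constrained to zero
    KQ <- (Kv %*% Qr) * precA
    QKQ <- crossprod(Qr, Kv %*% Qr) * precA
    nG <- K - 1L
    N0 <- nrow(C)
    C <- rbind(cbind(C, Matrix::Matrix(0, N0, nG, sparse = TRUE)),
               cbind(Matrix::Matrix(0, nG, N0, sparse = TRUE),
                     Matrix::Matrix(QKQ, sparse = TRUE)))
    C[aBlock, N0 + seq_len(nG)] <- -KQ
    C[N0 + seq_len(nG), aBlock] <- Matrix::t(-KQ)
    rhs <- c(rhs, numeric(nG))
    gBlock <- N0 + seq_len(nG)
  }

  structure(list(
    C = Matrix::forceSymmetric(C), rhs = rhs,
    blocks = list(b = seq_len(S), a = aBlock, f = fBlock, g = gBlock),
    siteLevels = levels(site), famLevels = levels(fam),
    groupLevels = groupLevels, entityIds = ents,
    model = model, k = kval, n = nrec,
    yty = sum(rvec * y^2)), class = "mmeSystem")
}

#' Solve assembled mixed-model equations
#'
#' @param system an `"mmeSystem"` from [buildMME()].
#' @param method `"direct"` (sparse Cholesky) or `"cg"`
#'   (Jacobi-preconditioned conjugate gradients from a zero start).
#' @param tol relative-residual tolerance for CG (default 1e-10).
#' @param maxIter CG iteration cap.
#' @return A [BlupSolutions-class]; `meta$relResidual` records the
#'   achieved relative residual.
#' @export
solveMME <- function(system, method = c("direct", "cg"), tol = 1e-10,
                     maxIter = 20000L) {
  method <- match.arg(method)
  C <- system$C; rhs <- system$rhs
  if (method == "direct") {
    x <- as.vector(Matrix::solve(C, rhs))
  } else {
    x <- .cgSolve(C, rhs, tol = tol, maxIter = maxIter)
  }
  rr <- sqrt(sum((as.vector(C %*% x) - rhs)^2)) / sqrt(sum(rhs^2))
  b <- system$blocks
  groups <- if (length(b$g))
    setNames(c(x[b$g], 0), system$groupLevels) else numeric(0)
  new("BlupSolutions",
      fixed = setNames(x[b$b], system$siteLevels),
      additive = setNames(x[b$a], system$entityIds),
      groups = groups,
      family = setNames(x[b$f], system$famLevels),
      meta = list(variant = system$model@variant, method = method,
                  relResidual = rr, k = system$k))
}

.cgSolve <- function(C, rhs, tol, maxIter) {
  dg <- Matrix::diag(C)
  dg[dg <= 0] <- 1
  x <- numeric(length(rhs))
  r <- rhs
  z <- r / dg
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(rhs^2))
  hist <- numeric(0)
  for (it in seq_len(maxIter)) {
    Cp <- as.vector(C %*% p)
    alpha <- rz / sum(p * Cp)
    x <- x + alpha * p
    r <- r - alpha * Cp
    res <- sqrt(sum(r^2)) / bnorm
    hist <- c(hist, res)
    if (res < tol) return(x)
    z <- r / dg
    rzNew <- sum(r * z)
    p <- z + (rzNew / rz) * p
    rz <- rzNew
  }
  stop("conjugate gradients did not converge in ", maxIter,
       " iterations; last relative residuals: ",
       paste(signif(utils::tail(hist, 5L), 3), collapse = ", "))
}

#' Build and solve in one call
#'
#' @inheritParams buildMME
#' @param ... passed to [solveMME()] (`method`, `tol`).
#' @return A [BlupSolutions-class].
#' @export
fitBlup <- function(phenotypes, model, kinv, gamma = NULL, q = NULL, ...) {
  solveMME(buildMME(phenotypes, model, kinv, gamma = gamma, q = q), ...)
}

#' EM-REML variance components for the base model
#'
#' Expectation-maximisation REML for (sigmaA2, sigmaF2, sigmaE2) in the
#' site + additive + family model with a pedigree (or combined) inverse
#' relationship matrix. The E-step traces `tr(K^-1 C^aa)` and `tr(C^ff)`
#' are exact (dense) for systems up to `denseLimit` unknowns and
#' estimated with a fixed set of Hutchinson probe vectors above that, so
#' a run is deterministic given the RNG state on entry. A family variance
#' collapsing to zero is held at 1e-8 and reported.
#'
#' @param phenotypes data frame `id`, `site`, `family`, `value`.
#' @param kinv inverse relationship matrix (usually kind `"A_inv"`).
#' @param init starting values `c(sigmaA2, sigmaF2, sigmaE2)`.
#' @param maxIter iteration cap (default 2000; EM steps are cheap and
#'   convergence near the optimum is slow).
#' @param tol convergence: max relative change across components
#'   (default 1e-5).
#' @param nProbes Hutchinson probes per trace for large systems.
#' @param denseLimit switch-over size for exact traces.
#' @return List: the three components, `h2` (cross-site narrow-sense
#'   heritability sigmaA2 / (sigmaA2 + sigmaF2 + sigmaE2)), iterations,
#'   convergence flag, and the iteration history.
#' @export
emREML <- function(phenotypes, kinv, init = c(0.3, 0.1, 0.6),
                   maxIter = 2000L, tol = 1e-5, nProbes = 64L,
                   denseLimit = 1500L) {
  .checkPhenotypes(phenotypes)
  ents <- entityIds(kinv)
  ridx <- match(phenotypes$id, ents)
  if (anyNA(ridx))
    stop("phenotyped ids absent from relationship structure: ",
         paste(utils::head(unique(phenotypes$id[is.na(ridx)]), 10L),
               collapse = ", "))
  nrec <- nrow(phenotypes)
  site <- factor(phenotypes$site, levels = unique(phenotypes$site))
  fam <- factor(phenotypes$family, levels = unique(phenotypes$family))
  S <- nlevels(site); nEnt <- length(ents); nFam <- nlevels(fam)
  y <- as.numeric(phenotypes$value)
  X <- Matrix::sparseMatrix(i = seq_len(nrec), j = as.integer(site),
                            x = 1, dims = c(nrec, S))
  Z1 <- Matrix::sparseMatrix(i = seq_len(nrec), j = ridx, x = 1,
                             dims = c(nrec, nEnt))
  Z2 <- Matrix::sparseMatrix(i = seq_len(nrec), j = as.integer(fam),
                             x = 1, dims = c(nrec, nFam))
  W <- cbind(X, Z1, Z2)
  WtW <- Matrix::t(W) %*% W
  Wty <- as.vector(Matrix::t(W) %*% y)
  yty <- sum(y^2)
  Kv <- kinv@values
  aBlock <- S + seq_len(nEnt)
  fBlock <- S + nEnt + seq_len(nFam)
  N <- S + nEnt + nFam
  dense <- N <= denseLimit
  if (!dense) {
    ## fixed probe set, +-1 entries on each random-effect block
    Pa <- matrix(sample(c(-1, 1), nEnt * nProbes, replace = TRUE),
                 nEnt, nProbes)
    Pf <- matrix(sample(c(-1, 1), nFam * nProbes, replace = TRUE),
                 nFam, nProbes)
    Emb <- matrix(0, N, 2L * nProbes)
    Emb[aBlock, seq_len(nProbes)] <- Pa
    Emb[fBlock, nProbes + seq_len(nProbes)] <- Pf
    KPa <- as.matrix(Kv %*% Pa)
  }
  sa <- init[1L]; sf <- init[2L]; se <- init[3L]
  hist <- matrix(NA_real_, maxIter, 3L,
                 dimnames = list(NULL, c("sigmaA2", "sigmaF2", "sigmaE2")))
  converged <- FALSE
  floorHit <- FALSE
  it <- 0L
  for (it in seq_len(maxIter)) {
    C <- WtW / se +
      Matrix::bdiag(Matrix::Diagonal(S, 0), Kv / sa,
                    Matrix::Diagonal(nFam, 1 / sf))
    C <- Matrix::forceSymmetric(C)
    ch <- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
    theta <- as.vector(Matrix::solve(ch, Wty / se, system = "A"))
    ah <- theta[aBlock]; fh <- theta[fBlock]
    seNew <- (yty - sum(theta * Wty)) / (nrec - S)
    if (dense) {
      Cinv <- as.matrix(Matrix::solve(C))
      trA <- sum(as.matrix(Kv) * Cinv[aBlock, aBlock])
      trF <- sum(diag(Cinv)[fBlock])
    } else {
      Xs <- as.matrix(Matrix::solve(ch, Emb, system = "A"))
      trA <- mean(colSums(KPa * Xs[aBlock, seq_len(nProbes), drop = FALSE]))
      trF <- mean(colSums(Pf *
        Xs[fBlock, nProbes + seq_len(nProbes), drop = FALSE]))
    }
    saNew <- (sum(ah * as.vector(Kv %*% ah)) + trA) / nEnt
    sfNew <- (sum(fh^2) + trF) / nFam
    if (sfNew < 1e-8) { sfNew <- 1e-8; floorHit <- TRUE }
    hist[it, ] <- c(saNew, sfNew, seNew)
    delta <- max(abs(c(saNew - sa, sfNew - sf, seNew - se)) /
                   pmax(abs(c(sa, sf, se)), 1e-12))
    sa <- saNew; sf <- sfNew; se <- seNew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (any(!is.finite(c(sa, sf, se))) || se <= 0)
    stop("EM-REML produced a non-positive-definite system")
  list(sigmaA2 = sa, sigmaF2 = sf, sigmaE2 = se,
       h2 = sa / (sa + sf + se), iterations = it, converged = converged,
       familyFloor = floorHit, history = hist[seq_len(it), , drop = FALSE])
}
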