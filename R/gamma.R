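## Estimation and summary of the metafounder relationship matrix Gamma:
## GLS estimation of base-population allele frequencies from descendant
## genotypes, the k variance scalar, diversity summaries, and the UPGMA
## tree of among-population similarity.

#' Estimate Gamma from descendant genotypes by GLS
#'
#' Base-population allele frequencies are estimated per marker by
#' generalized least squares on gene content,
#' `p_hat = (Q' A22^-1 Q)^-1 Q' A22^-1 m / 2`,
#' where `Q` holds expected group contributions of the genotyped
#' individuals and `A22` is the plain pedigree relationship matrix among
#' them (no Gamma augmentation: Gamma is the quantity being estimated).
#' Then `Gamma = 8 * mean_j (p_hat_j - c)(p_hat_j - c)'` across markers.
#'
#' The default centering `c = 0.5` is the second moment about one half,
#' the convention under which the 0.5-frequency G05 matrix and Gamma
#' share a base and a uniformly distributed base frequency gives an
#' expected diagonal of 2/3. `center = "mean"` instead centers each
#' population's frequencies at its own across-marker mean (a covariance
#' proper). If the estimate is indefinite its negative eigenvalues are
#' clipped at 1e-6 (always with a warning unless `psdRepair = TRUE` was
#' requested).
#'
#' @param geno [GenotypeMatrix-class] of the genotyped individuals.
#' @param a22 pedigree [RelationshipMatrix-class] over exactly those
#'   individuals, same order (kind `"A"`).
#' @param q group-contribution matrix (genotyped individuals x K), e.g.
#'   `upgMatrix(ped)[ids, ]`.
#' @param center `"half"` (default) or `"mean"`.
#' @param psdRepair logical; request eigenvalue clipping up front.
#' @return A [GammaMatrix-class]; `meta` records markers, centering and
#'   whether a repair was applied.
#' @export
estimateGamma <- function(geno, a22, q, center = c("half", "mean"),
                          psdRepair = FALSE) {
  center <- match.arg(center)
  q <- as.matrix(q)
  ids <- genoIds(geno)
  if (!identical(entityIds(a22), ids))
    stop("a22 entities must match genotyped ids, same order")
  if (nrow(q) != length(ids))
    stop("q must have one row per genotyped individual")
  labels <- colnames(q)
  if (is.null(labels)) labels <- paste0("MF", seq_len(ncol(q)))
  empty <- colSums(abs(q)) == 0
  if (any(empty))
    stop("metafounder with no genotyped descendant contribution: ",
         paste(labels[empty], collapse = ", "))
  A <- as.matrix(a22)
  ch <- tryCatch(chol(A), error = function(e)
    stop("A22 is singular or not positive definite"))
  M <- .imputeMean(genoValues(geno))
  W <- chol2inv(ch) %*% q                    # A22^-1 Q
  S <- crossprod(q, W)                       # Q' A22^-1 Q
  P <- solve(S, crossprod(W, M)) / 2         # K x m base frequencies
  m <- ncol(M)
  ctr <- if (center == "half") matrix(0.5, nrow(P), m) else
    matrix(rowMeans(P), nrow(P), m)
  D <- P - ctr
  G <- 8 * tcrossprod(D) / m
  G <- (G + t(G)) / 2
  repaired <- FALSE
  ev <- eigen(G, symmetric = TRUE)
  if (min(ev$values) < 0 || psdRepair) {
    if (min(ev$values) < 0) {
      if (!psdRepair)
        warning("Gamma estimate indefinite (min eigenvalue ",
                signif(min(ev$values), 3), "); clipping to 1e-6")
      G <- ev$vectors %*% (pmax(ev$values, 1e-6) * t(ev$vectors))
      G <- (G + t(G)) / 2
      repaired <- TRUE
    }
  }
  dimnames(G) <- list(labels, labels)
  gammaMatrix(G, labels,
              meta = list(markers = m, centering = center,
                          psdRepaired = repaired))
}

#' Variance scalar k for metafounder models
#'
#' `k = 1 + mean(diag(Gamma))/2 - mean(Gamma)`; the additive variance of
#' a metafounder model is divided by k so it is comparable to the
#' classical parameterization (k = 1 when Gamma = 0).
#'
#' @param gamma a [GammaMatrix-class] (or plain symmetric matrix).
#' @return Single numeric k.
#' @export
kScalar <- function(gamma) {
  v <- if (is(gamma, "GammaMatrix")) gammaValues(gamma) else as.matrix(gamma)
  1 + mean(diag(v)) / 2 - mean(v)
}

#' Diversity summary of a Gamma matrix
#'
#' Diagonal range and mean, the implied within-metafounder inbreeding
#' `F_g = Gamma_gg - 1` (negative for diverse base populations) with its
#' mean, and each metafounder's most-related partner (largest
#' off-diagonal in its row).
#'
#' @param gamma a [GammaMatrix-class].
#' @return List with `diagonal` (min/mean/max), `inbreeding` (per-MF),
#'   `meanInbreeding`, and a `partners` data frame.
#' @export
gammaSummary <- function(gamma) {
  v <- gammaValues(gamma)
  labels <- gammaLabels(gamma)
  d <- diag(v)
  Fg <- d - 1
  partners <- if (length(labels) >= 2L) {
    off <- v; diag(off) <- -Inf
    j <- apply(off, 1L, which.max)
    data.frame(label = labels, partner = labels[j],
               value = off[cbind(seq_along(labels), j)],
               stringsAsFactors = FALSE)
  } else {
    data.frame(label = labels, partner = NA_character_, value = NA_real_)
  }
  list(diagonal = c(min = min(d), mean = mean(d), max = max(d)),
       inbreeding = setNames(Fg, labels),
       meanInbreeding = mean(Fg),
       partners = partners)
}

#' UPGMA tree of metafounder similarity
#'
#' Converts Gamma to the distance `d_ij = (Gamma_ii + Gamma_jj)/2 -
#' Gamma_ij` (clipped at zero), then agglomerates by average linkage.
#' The result is ultrametric with node heights at half the cophenetic
#' distance.
#'
#' @param gamma a [GammaMatrix-class] with K >= 2 distinct labels.
#' @return An [ape::as.phylo] `phylo` tree; write it with
#'   [writeNewickTree()].
#' @export
gammaTree <- function(gamma) {
  labels <- gammaLabels(gamma)
  if (length(labels) < 2L) stop("need at least 2 metafounders for a tree")
  if (anyDuplicated(labels)) stop("duplicate metafounder labels")
  v <- gammaValues(gamma)
  D <- (outer(diag(v), diag(v), "+")) / 2 - v
  D <- pmax(D, 0)
  diag(D) <- 0
  dimnames(D) <- list(labels, labels)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  ape::as.phylo(hc)
}
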