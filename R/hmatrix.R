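## Single-step combined relationship matrices: sparse H-inverse
## assemblies (plain and Gamma-augmented) and the dense direct H for
## inspection, plus inbreeding coefficients read off the H diagonal.

## shared core: add (G^-1 - Aref22^-1) on the genotyped block of a
## sparse pedigree inverse
.hInverseCore <- function(aInv, aRef22, gBlend, genotypedIds, kind) {
  ents <- entityIds(aInv)
  idx <- match(genotypedIds, ents)
  if (anyNA(idx))
    stop("genotyped ids absent from the pedigree inverse: ",
         paste(utils::head(genotypedIds[is.na(idx)], 5L), collapse = ", "))
  if (!identical(entityIds(aRef22), genotypedIds) ||
      !identical(entityIds(gBlend), genotypedIds))
    stop("a22 and G must cover exactly the genotyped ids, same order")
  G <- as.matrix(gBlend)
  A22 <- as.matrix(aRef22)
  chG <- tryCatch(chol(G), error = function(e)
    stop("G is singular; blend with the pedigree reference ",
         "(blendG with weight < 1) before the single-step assembly"))
  chA <- tryCatch(chol(A22), error = function(e)
    stop("A22 block is singular"))
  corr <- chol2inv(chG) - chol2inv(chA)
  corr <- (corr + t(corr)) / 2
  N <- length(ents)
  ij <- expand.grid(idx, idx)
  corrSp <- Matrix::sparseMatrix(i = ij[[1L]], j = ij[[2L]],
                                 x = as.vector(corr), dims = c(N, N))
  Hinv <- Matrix::forceSymmetric(aInv@values + corrSp)
  relationshipMatrix(Hinv, ents, kind)
}

#' Single-step H-inverse (no base-population structure)
#'
#' `H^-1 = A^-1 + [0 0; 0 G^-1 - A22^-1]`, the correction placed on the
#' genotyped block only.
#'
#' @param aInv sparse [RelationshipMatrix-class] of kind `"A_inv"` over
#'   all individuals.
#' @param a22 pedigree relationships among the genotyped individuals
#'   (kind `"A"`), same order as `genotypedIds`.
#' @param gBlend blended genomic matrix over the genotyped individuals.
#' @param genotypedIds ids of the genotyped individuals.
#' @return Sparse [RelationshipMatrix-class] of kind `"H_inv"`.
#' @export
hInverse <- function(aInv, a22, gBlend, genotypedIds) {
  if (relKind(aInv) != "A_inv")
    stop("aInv must be of kind A_inv (see hGammaInverse for metafounders)")
  .hInverseCore(aInv, a22, gBlend, genotypedIds, "H_inv")
}

#' Gamma-augmented single-step H-inverse
#'
#' `HGamma^-1 = AGamma^-1 + correction` with the
#' `G05^-1 - AGamma22^-1` correction zero-padded so it never touches the
#' metafounder rows/columns.
#'
#' @param aGammaInv sparse kind `"A_gamma_inv"` over individuals +
#'   metafounders.
#' @param aGamma22 Gamma-augmented pedigree relationships among the
#'   genotyped individuals (kind `"A_gamma"` restricted to them).
#' @param g05Blend blended 0.5-frequency genomic matrix over the
#'   genotyped individuals.
#' @param genotypedIds ids of the genotyped individuals (no metafounder
#'   labels).
#' @return Sparse [RelationshipMatrix-class] of kind `"H_gamma_inv"`.
#' @export
hGammaInverse <- function(aGammaInv, aGamma22, g05Blend, genotypedIds) {
  if (relKind(aGammaInv) != "A_gamma_inv")
    stop("aGammaInv must be of kind A_gamma_inv")
  .hInverseCore(aGammaInv, aGamma22, g05Blend, genotypedIds, "H_gamma_inv")
}

#' Direct (dense) combined relationship matrix H
#'
#' Standard identity consistent with the single-step inverse:
#' `H11 = A11 + A12 A22^-1 (G - A22) A22^-1 A21`,
#' `H12 = A12 A22^-1 G`, `H22 = G`, where block 2 is the genotyped
#' individuals and block 1 everything else (including metafounders when
#' `a` is Gamma-augmented). An inspection and testing tool; the solver
#' consumes the sparse inverses.
#'
#' @param a dense [RelationshipMatrix-class] over all entities (kind
#'   `"A"` or `"A_gamma"`).
#' @param g (blended) genomic matrix over the genotyped individuals.
#' @param genotypedIds ids of the genotyped individuals.
#' @return Dense [RelationshipMatrix-class] of kind `"H_direct"`, same
#'   entity order as `a`.
#' @export
hMatrix <- function(a, g, genotypedIds) {
  ents <- entityIds(a)
  if (length(ents) > 20000L)
    stop("refusing to build a dense H over more than 20,000 entities")
  idx2 <- match(genotypedIds, ents)
  if (anyNA(idx2))
    stop("genotyped ids absent from a: ",
         paste(utils::head(genotypedIds[is.na(idx2)], 5L), collapse = ", "))
  if (length(genotypedIds) && !identical(entityIds(g), genotypedIds))
    stop("g must cover exactly the genotyped ids, same order")
  A <- as.matrix(a)
  G <- as.matrix(g)
  idx1 <- setdiff(seq_along(ents), idx2)
  H <- A
  if (length(idx2)) {
    A22 <- A[idx2, idx2, drop = FALSE]
    A22i <- chol2inv(chol(A22))
    if (length(idx1)) {
      T12 <- A[idx1, idx2, drop = FALSE] %*% A22i
      H[idx1, idx1] <- A[idx1, idx1] + T12 %*% (G - A22) %*% t(T12)
      H12 <- T12 %*% G
      H[idx1, idx2] <- H12
      H[idx2, idx1] <- t(H12)
    }
    H[idx2, idx2] <- G
  }
  H <- (H + t(H)) / 2
  relationshipMatrix(H, ents, "H_direct")
}

#' Inbreeding coefficients from a relationship matrix diagonal
#'
#' `F_i = H_ii - 1` for the requested ids, plus their mean (the quantity
#' the LR accuracy formula needs for the focal group).
#'
#' @param h a relationship-kind [RelationshipMatrix-class] (H, A, ...).
#' @param ids ids to report; default all entities.
#' @return List with named `F` and `mean`.
#' @export
inbreedingFromH <- function(h, ids = NULL) {
  ents <- entityIds(h)
  if (is.null(ids)) ids <- ents
  idx <- match(ids, ents)
  if (anyNA(idx))
    stop("ids absent from matrix: ",
         paste(utils::head(ids[is.na(idx)], 5L), collapse = ", "))
  Fi <- Matrix::diag(h@values)[idx] - 1
  names(Fi) <- ids
  list(F = Fi, mean = mean(Fi))
}
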