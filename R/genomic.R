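## Gene-content genotypes and VanRaden genomic relationship matrices
## (observed and 0.5 allele frequencies), compatibility rescaling,
## blending, and matrix-comparison summaries.

#' Gene-content genotype matrix
#'
#' Individuals x markers matrix of biallelic gene content (0/1/2, `NA`
#' for missing). Markers that are entirely missing are rejected.
#'
#' @slot ids character, individual ids (rows).
#' @slot markers character, marker ids (columns).
#' @slot values integer-valued matrix in \{0,1,2,NA\}.
#' @export
setClass("GenotypeMatrix", slots = c(
  ids = "character", markers = "character", values = "matrix"))

setValidity("GenotypeMatrix", function(object) {
  v <- object@values
  if (nrow(v) != length(object@ids) || ncol(v) != length(object@markers))
    return("values dimensions do not match ids/markers")
  if (anyDuplicated(object@ids)) return("duplicate individual ids")
  vv <- v[!is.na(v)]
  if (length(vv) && !all(vv %in% c(0, 1, 2)))
    return("gene content must be 0, 1, 2 or NA")
  if (ncol(v) && any(colSums(!is.na(v)) == 0L))
    return("a marker is entirely missing")
  TRUE
})

#' Create a genotype matrix object
#'
#' @param values individuals x markers matrix with entries 0/1/2/NA.
#' @param ids individual ids; defaults to rownames.
#' @param markers marker ids; defaults to colnames, else `M1..Mm`.
#' @return A [GenotypeMatrix-class] object.
#' @export
genotypeMatrix <- function(values, ids = rownames(values),
                           markers = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(ids)) stop("individual ids required")
  if (is.null(markers)) markers <- paste0("M", seq_len(ncol(values)))
  dimnames(values) <- list(ids, markers)
  new("GenotypeMatrix", ids = as.character(ids),
      markers = as.character(markers), values = values)
}

#' Gene-content values of a genotype matrix
#' @param x a GenotypeMatrix.
#' @return Individuals x markers numeric matrix (NA = missing).
#' @export
setGeneric("genoValues", function(x) standardGeneric("genoValues"))

#' @rdname genoValues
#' @export
setMethod("genoValues", "GenotypeMatrix", function(x) x@values)

#' Individual ids of a genotype matrix
#' @param x a GenotypeMatrix.
#' @return Character vector of ids.
#' @export
setGeneric("genoIds", function(x) standardGeneric("genoIds"))

#' @rdname genoIds
#' @export
setMethod("genoIds", "GenotypeMatrix", function(x) x@ids)

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d individuals x %d markers (%.2f%% missing)\n",
              length(object@ids), length(object@markers),
              100 * mean(is.na(object@values))))
})

#' Subset a genotype matrix by individual ids
#'
#' @param x a [GenotypeMatrix-class].
#' @param ids individual ids to keep, in the requested order.
#' @return A [GenotypeMatrix-class] over `ids`.
#' @export
subsetGenotypes <- function(x, ids) {
  idx <- match(ids, x@ids)
  if (anyNA(idx))
    stop("ids not genotyped: ",
         paste(utils::head(ids[is.na(idx)], 5L), collapse = ", "))
  genotypeMatrix(x@values[idx, , drop = FALSE], ids, x@markers)
}

#' Observed allele frequencies
#'
#' Per-marker frequency of the counted allele: mean non-missing gene
#' content divided by 2.
#'
#' @param geno a [GenotypeMatrix-class].
#' @return Named numeric vector of frequencies in \[0, 1\].
#' @export
alleleFrequencies <- function(geno) {
  colMeans(genoValues(geno), na.rm = TRUE) / 2
}

## mean-impute missing gene content per marker (deterministic fallback
## for the upstream imputation this pipeline does not perform)
.imputeMean <- function(M) {
  miss <- which(is.na(M), arr.ind = TRUE)
  if (nrow(miss)) {
    cm <- colMeans(M, na.rm = TRUE)
    M[miss] <- cm[miss[, 2L]]
  }
  M
}

#' VanRaden genomic relationship matrix
#'
#' First-method G: `G = Z Z' / c` with `Z` the per-marker centered gene
#' content and `c = 2 * sum(p (1 - p))`. `center = "observed"` centers at
#' observed frequencies (monomorphic markers dropped, since they carry no
#' weight); `center = "half"` uses p = 0.5 for every marker so `c = m/2`
#' (monomorphic markers retained), the metafounder-compatible G05.
#' Missing genotypes are mean-imputed per marker first.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param center `"observed"` or `"half"`.
#' @return [RelationshipMatrix-class] of kind `"G_obs"` or `"G05"`.
#' @export
genomicRelationship <- function(geno, center = c("observed", "half")) {
  center <- match.arg(center)
  M <- .imputeMean(genoValues(geno))
  if (center == "observed") {
    p <- colMeans(M) / 2
    poly <- p > 0 & p < 1
    if (!any(poly))
      stop("all markers monomorphic: scaling constant is zero under ",
           "observed-frequency centering")
    M <- M[, poly, drop = FALSE]
    p <- p[poly]
    cc <- 2 * sum(p * (1 - p))
    kind <- "G_obs"
  } else {
    p <- rep(0.5, ncol(M))
    cc <- ncol(M) / 2
    kind <- "G05"
  }
  Z <- sweep(M, 2L, 2 * p)
  G <- tcrossprod(Z) / cc
  G <- (G + t(G)) / 2
  relationshipMatrix(G, genoIds(geno), kind)
}

#' Rescale G to match pedigree moments
#'
#' `Gscaled = alpha + beta * Gobs`, with alpha and beta chosen so that
#' the mean diagonal and the overall mean of the result equal those of
#' the pedigree reference A22 (the standard single-step compatibility
#' tuning).
#'
#' @param g a genomic [RelationshipMatrix-class].
#' @param a22 pedigree relationship matrix over the same entities, same
#'   order.
#' @return [RelationshipMatrix-class] of kind `"G_scaled"`, with the
#'   coefficients in `attr(, "coefficients")`.
#' @export
rescaleG <- function(g, a22) {
  .checkSameEntities(g, a22)
  Gm <- as.matrix(g)
  Am <- as.matrix(a22)
  mdG <- mean(diag(Gm)); mG <- mean(Gm)
  mdA <- mean(diag(Am)); mA <- mean(Am)
  den <- mdG - mG
  if (abs(den) < 1e-12)
    stop("degenerate rescaling system: mean diagonal equals overall mean in G")
  beta <- (mdA - mA) / den
  alpha <- mA - beta * mG
  out <- relationshipMatrix(alpha + beta * Gm, entityIds(g), "G_scaled")
  attr(out, "coefficients") <- c(alpha = alpha, beta = beta)
  out
}

#' Blend a genomic matrix with its pedigree reference
#'
#' `weight * G + (1 - weight) * Aref`; the default 0.95/0.05 blend keeps
#' G invertible for the single-step correction.
#'
#' @param g genomic [RelationshipMatrix-class].
#' @param aRef pedigree reference over the same entities (A22, or the
#'   Gamma-augmented A22 for the 0.5-frequency G).
#' @param weight weight on G, in (0, 1\]; default 0.95.
#' @return [RelationshipMatrix-class] of kind `"G_blend"`.
#' @export
blendG <- function(g, aRef, weight = 0.95) {
  if (weight <= 0 || weight > 1) stop("weight must be in (0, 1]")
  .checkSameEntities(g, aRef)
  V <- weight * as.matrix(g) + (1 - weight) * as.matrix(aRef)
  relationshipMatrix(V, entityIds(g), "G_blend")
}

.checkSameEntities <- function(x, y) {
  if (!identical(entityIds(x), entityIds(y)))
    stop("entity ids/order differ between matrices")
  invisible(TRUE)
}

#' Compare two relationship matrices element-wise
#'
#' Pearson correlations of the diagonals and of the strict lower-triangle
#' off-diagonals, plus per-matrix mean/min/max summaries of both element
#' classes (the standard pedigree-vs-genomic compatibility diagnostics).
#' A correlation over elements with zero variance is reported as `NA`.
#'
#' @param m1,m2 [RelationshipMatrix-class] objects over identical
#'   entities in identical order.
#' @return List with `diagCor`, `offdiagCor`, and a `summary` data frame.
#' @export
compareRelMatrices <- function(m1, m2) {
  .checkSameEntities(m1, m2)
  if (length(entityIds(m1)) < 3L)
    stop("need at least 3 entities to compare matrices")
  A <- as.matrix(m1); B <- as.matrix(m2)
  lt <- lower.tri(A)
  safeCor <- function(x, y)
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  summ <- function(name, M) {
    d <- diag(M); o <- M[lt]
    data.frame(matrix = name,
               element = c("diagonal", "off-diagonal"),
               mean = c(mean(d), mean(o)),
               min = c(min(d), min(o)),
               max = c(max(d), max(o)),
               stringsAsFactors = FALSE)
  }
  list(diagCor = safeCor(diag(A), diag(B)),
       offdiagCor = safeCor(A[lt], B[lt]),
       summary = rbind(summ(relKind(m1), A), summ(relKind(m2), B)))
}
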