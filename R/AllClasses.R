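## Central S4 containers. Validity methods enforce the structural
## invariants every downstream operation relies on.

.REL_KINDS <- c("A", "A_inv", "A_gamma", "A_gamma_inv", "A_star_inv",
                "G_obs", "G_scaled", "G_blend", "G05",
                "H_inv", "H_gamma_inv", "H_direct")

## kinds that are relationship (not precision) matrices: diagonals >= 0
.REL_KINDS_DIAG <- c("A", "A_gamma", "G_obs", "G_scaled", "G_blend",
                     "G05", "H_direct")

#' Pedigree with optional metafounder labels
#'
#' An ordered pedigree: each individual appears once, parents precede
#' offspring (topological order), and missing parent slots may carry a
#' metafounder (genetic-group) label. Build one with [Pedigree()] or
#' [readPedigree()]; both sort and validate.
#'
#' @slot id character, unique individual ids in topological order.
#' @slot sire,dam character, parent ids or `NA` when unknown.
#' @slot sireGroup,damGroup character, metafounder label of a missing
#'   parent slot (`NA` when the parent is known or unlabelled).
#' @slot groups character, ordered metafounder labels (may be empty).
#' @slot phantoms character, ids of parents that were referenced but not
#'   listed and were materialized as founders.
#' @export
setClass("Pedigree", slots = c(
  id = "character", sire = "character", dam = "character",
  sireGroup = "character", damGroup = "character",
  groups = "character", phantoms = "character"))

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  if (n == 0L) return("pedigree has no records")
  if (anyDuplicated(object@id))
    return(paste0("duplicate id: ", object@id[duplicated(object@id)][1L]))
  lens <- c(length(object@sire), length(object@dam),
            length(object@sireGroup), length(object@damGroup))
  if (any(lens != n)) return("slot lengths differ")
  pos <- seq_len(n)
  si <- match(object@sire, object@id)
  di <- match(object@dam, object@id)
  if (any(!is.na(object@sire) & is.na(si)))
    return("sire referenced but not present")
  if (any(!is.na(object@dam) & is.na(di)))
    return("dam referenced but not present")
  if (any(si >= pos, na.rm = TRUE) || any(di >= pos, na.rm = TRUE))
    return("pedigree is not topologically sorted (a parent follows its offspring)")
  bad <- c(object@sireGroup[!is.na(object@sireGroup)],
           object@damGroup[!is.na(object@damGroup)])
  if (length(bad) && length(object@groups) && !all(bad %in% object@groups))
    return("group label used that is absent from the groups slot")
  TRUE
})

#' Relationship matrix over an ordered entity list
#'
#' Symmetric (to 1e-10) relationship or precision matrix tagged with its
#' kind (`A`, `A_inv`, `A_gamma`, `G_obs`, `H_inv`, ...). Entities are
#' individuals, optionally followed by metafounders. Dense `matrix` or a
#' sparse symmetric `Matrix` are both accepted as storage.
#'
#' @slot entityIds character, ordered entity labels.
#' @slot values square symmetric matrix (base or Matrix).
#' @slot kind one of the recognised matrix kinds (see `relKinds()`).
#' @export
setClass("RelationshipMatrix", slots = c(
  entityIds = "character", values = "ANY", kind = "character"))

setValidity("RelationshipMatrix", function(object) {
  v <- object@values
  n <- length(object@entityIds)
  if (is.null(dim(v)) || nrow(v) != n || ncol(v) != n)
    return("values must be a square matrix matching entityIds")
  if (!(object@kind %in% .REL_KINDS))
    return(paste0("unknown kind '", object@kind, "'"))
  asym <- max(abs(v - Matrix::t(v)))
  if (asym > 1e-10)
    return(sprintf("matrix not symmetric (max asymmetry %.3g)", asym))
  if (object@kind %in% .REL_KINDS_DIAG && any(Matrix::diag(v) < 0))
    return("relationship-kind matrix has a negative diagonal element")
  TRUE
})

#' Metafounder relationship matrix (Gamma)
#'
#' K x K symmetric matrix of metafounder self- and cross-relationships,
#' defined as 8 times the covariance of base-population allele
#' frequencies. Estimated from descendant genotypes by [estimateGamma()].
#'
#' @slot labels character, metafounder names.
#' @slot values K x K symmetric numeric matrix.
#' @slot meta list with estimation metadata (marker count, centering,
#'   whether a positive-semidefinite repair was applied).
#' @export
setClass("GammaMatrix", slots = c(
  labels = "character", values = "matrix", meta = "list"))

setValidity("GammaMatrix", function(object) {
  K <- length(object@labels)
  v <- object@values
  if (nrow(v) != K || ncol(v) != K) return("values must be K x K")
  if (anyDuplicated(object@labels)) return("duplicate metafounder labels")
  if (max(abs(v - t(v))) > 1e-10) return("Gamma not symmetric")
  if (any(diag(v) < 0)) return("Gamma has a negative diagonal element")
  TRUE
})

#' Mixed-model specification
#'
#' Variant plus variance components for the site + additive +
#' full-sib-family model. Variances are on the per-trial-standardized
#' phenotype scale (phenotypic SD^2 units).
#'
#' @slot variant one of ABLUP, ABLUP_UPG, ABLUP_MF, HBLUP, HBLUP_MF.
#' @slot sigmaA2,sigmaF2 additive and family variances.
#' @slot sigmaE2 residual variance; a named per-site vector when
#'   `residualMode` is "per-site".
#' @slot applyK logical; divide the additive variance by the k scalar
#'   (metafounder variants only).
#' @slot residualMode "homogeneous" or "per-site".
#' @export
setClass("BlupModel", slots = c(
  variant = "character", sigmaA2 = "numeric", sigmaF2 = "numeric",
  sigmaE2 = "numeric", applyK = "logical", residualMode = "character"))

.MODEL_VARIANTS <- c("ABLUP", "ABLUP_UPG", "ABLUP_MF", "HBLUP", "HBLUP_MF")

setValidity("BlupModel", function(object) {
  if (!(object@variant %in% .MODEL_VARIANTS))
    return(paste0("unknown variant '", object@variant, "'"))
  if (object@sigmaA2 <= 0 || object@sigmaF2 <= 0 || any(object@sigmaE2 <= 0))
    return("all variance components must be > 0")
  if (object@applyK && !(object@variant %in% c("ABLUP_MF", "HBLUP_MF")))
    return("applyK is only meaningful for metafounder variants")
  if (!(object@residualMode %in% c("homogeneous", "per-site")))
    return("residualMode must be 'homogeneous' or 'per-site'")
  if (object@residualMode == "homogeneous" && length(object@sigmaE2) != 1L)
    return("homogeneous residual needs a single sigmaE2")
  TRUE
})

#' Solutions of the mixed-model equations
#'
#' @slot fixed named numeric, per-site fixed-effect estimates.
#' @slot additive named numeric over the entities of the relationship
#'   structure (individuals and, for metafounder variants, metafounder
#'   effects at the end). For ABLUP_UPG these are total solutions
#'   (individual deviation plus expected group contribution).
#' @slot groups named numeric, unknown-parent-group effects (ABLUP_UPG
#'   only; last group constrained to zero), length 0 otherwise.
#' @slot family named numeric, full-sib family effects.
#' @slot meta list: solver, relative residual, variant, shrinkage used.
#' @export
setClass("BlupSolutions", slots = c(
  fixed = "numeric", additive = "numeric", groups = "numeric",
  family = "numeric", meta = "list"))

setValidity("BlupSolutions", function(object) {
  if (is.null(names(object@additive))) return("additive must be named")
  TRUE
})

## ---- constructors -------------------------------------------------

#' Create a relationship matrix object
#'
#' @param values square symmetric matrix (dense or sparse Matrix).
#' @param entityIds entity labels; defaults to rownames.
#' @param kind matrix kind tag, one of `relKinds()`.
#' @return A [RelationshipMatrix-class] object.
#' @export
relationshipMatrix <- function(values, entityIds = rownames(values), kind) {
  if (is.null(entityIds)) stop("entityIds required (no rownames found)")
  new("RelationshipMatrix", entityIds = as.character(entityIds),
      values = values, kind = kind)
}

#' Recognised relationship-matrix kinds
#' @return Character vector of valid `kind` tags.
#' @export
relKinds <- function() .REL_KINDS

#' Create a Gamma matrix object
#'
#' @param values K x K symmetric matrix.
#' @param labels metafounder names; defaults to rownames.
#' @param meta optional metadata list.
#' @return A [GammaMatrix-class] object.
#' @export
gammaMatrix <- function(values, labels = rownames(values), meta = list()) {
  values <- as.matrix(values)
  if (is.null(labels)) labels <- paste0("MF", seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  new("GammaMatrix", labels = as.character(labels), values = values,
      meta = meta)
}

#' Specify a BLUP model variant
#'
#' @param variant one of `"ABLUP"`, `"ABLUP_UPG"`, `"ABLUP_MF"`,
#'   `"HBLUP"`, `"HBLUP_MF"`.
#' @param sigmaA2,sigmaF2,sigmaE2 variance components (additive, full-sib
#'   family, residual). `sigmaE2` may be a named per-site vector together
#'   with `residualMode = "per-site"`.
#' @param applyK divide the additive variance by the Gamma-derived k
#'   scalar; defaults to `TRUE` for metafounder variants.
#' @param residualMode `"homogeneous"` (default) or `"per-site"`.
#' @return A [BlupModel-class] object.
#' @export
blupModel <- function(variant, sigmaA2, sigmaF2, sigmaE2,
                      applyK = variant %in% c("ABLUP_MF", "HBLUP_MF"),
                      residualMode = "homogeneous") {
  new("BlupModel", variant = variant, sigmaA2 = sigmaA2, sigmaF2 = sigmaF2,
      sigmaE2 = sigmaE2, applyK = applyK, residualMode = residualMode)
}

## ---- accessors & show ---------------------------------------------

#' Entity labels of a relationship structure
#' @param x a RelationshipMatrix or Pedigree.
#' @return Character vector of entity (individual/metafounder) labels.
#' @export
setGeneric("entityIds", function(x) standardGeneric("entityIds"))

#' @rdname entityIds
#' @export
setMethod("entityIds", "RelationshipMatrix", function(x) x@entityIds)

#' @rdname entityIds
#' @export
setMethod("entityIds", "Pedigree", function(x) x@id)

#' Kind tag of a relationship matrix
#' @param x a RelationshipMatrix.
#' @return Single character kind tag (see `relKinds()`).
#' @export
setGeneric("relKind", function(x) standardGeneric("relKind"))

#' @rdname relKind
#' @export
setMethod("relKind", "RelationshipMatrix", function(x) x@kind)

#' @export
#' @describeIn relationshipMatrix dense base-matrix view.
setMethod("as.matrix", "RelationshipMatrix", function(x, ...) {
  m <- as.matrix(x@values)
  dimnames(m) <- list(x@entityIds, x@entityIds)
  m
})

#' Numeric values of a Gamma matrix
#' @param x a GammaMatrix.
#' @return Labelled K x K numeric matrix.
#' @export
setGeneric("gammaValues", function(x) standardGeneric("gammaValues"))

#' @rdname gammaValues
#' @export
setMethod("gammaValues", "GammaMatrix", function(x) x@values)

#' Metafounder labels of a Gamma matrix
#' @param x a GammaMatrix.
#' @return Character vector of metafounder names.
#' @export
setGeneric("gammaLabels", function(x) standardGeneric("gammaLabels"))

#' @rdname gammaLabels
#' @export
setMethod("gammaLabels", "GammaMatrix", function(x) x@labels)

setMethod("show", "Pedigree", function(object) {
  cat("Pedigree with", length(object@id), "individuals\n")
  nf <- sum(is.na(object@sire) & is.na(object@dam))
  cat("  founders:", nf, "| metafounder labels:",
      if (length(object@groups)) paste(object@groups, collapse = ", ")
      else "(none)", "\n")
  if (length(object@phantoms))
    cat("  phantom parents materialized:", length(object@phantoms), "\n")
})

setMethod("show", "RelationshipMatrix", function(object) {
  cat(sprintf("RelationshipMatrix [%s] over %d entities (%s storage)\n",
              object@kind, length(object@entityIds),
              if (is(object@values, "sparseMatrix")) "sparse" else "dense"))
})

setMethod("show", "GammaMatrix", function(object) {
  cat("GammaMatrix over", length(object@labels), "metafounders\n")
  print(round(object@values, 3))
})

setMethod("show", "BlupModel", function(object) {
  cat(sprintf("BlupModel %s: sigmaA2=%g sigmaF2=%g sigmaE2=%s applyK=%s\n",
              object@variant, object@sigmaA2, object@sigmaF2,
              paste(signif(object@sigmaE2, 4), collapse = "/"),
              object@applyK))
})

setMethod("show", "BlupSolutions", function(object) {
  cat(sprintf("BlupSolutions (%s): %d fixed, %d additive, %d family\n",
              object@meta$variant %||% "?", length(object@fixed),
              length(object@additive), length(object@family)))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
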