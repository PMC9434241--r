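## Pedigree parsing, ordering, and numerator relationship matrices
## (plain A and the metafounder-augmented A-Gamma), plus the
## unknown-parent-group expected-contribution matrix Q.

.MISSING_CODES <- c("0", "", "NA", "na", ".")

.cleanIds <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% .MISSING_CODES] <- NA_character_
  x
}

#' Build (sort and validate) a pedigree
#'
#' Accepts a data frame with columns `id`, `sire`, `dam` and optionally
#' `sire_group`, `dam_group`. Missing parents may be coded `0`, empty, or
#' `NA`. Parents referenced but never listed are materialized as founders
#' (phantom parents); the result is topologically sorted so that every
#' parent precedes its offspring. Cycles and duplicate ids are errors.
#'
#' @param x data frame (or object coercible to one) of pedigree records.
#' @return A sorted, validated [Pedigree-class] object; the ids of any
#'   materialized phantom parents are in the `phantoms` slot.
#' @examples
#' ped <- Pedigree(data.frame(id = c("C", "A", "B"),
#'                            sire = c("A", NA, NA),
#'                            dam  = c("B", NA, NA)))
#' entityIds(ped)  # parents reordered before child
#' @export
Pedigree <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  nm <- tolower(names(x))
  need <- c("id", "sire", "dam")
  if (!all(need %in% nm))
    stop("pedigree needs columns id, sire, dam")
  names(x) <- nm
  id <- trimws(as.character(x$id))
  if (any(id %in% .MISSING_CODES | is.na(id)))
    stop("missing or invalid individual id in pedigree")
  if (anyDuplicated(id))
    stop("duplicate id in pedigree: ", id[duplicated(id)][1L])
  sire <- .cleanIds(x$sire)
  dam <- .cleanIds(x$dam)
  sg <- if ("sire_group" %in% nm) .cleanIds(x$sire_group) else
    rep(NA_character_, length(id))
  dg <- if ("dam_group" %in% nm) .cleanIds(x$dam_group) else
    rep(NA_character_, length(id))
  ## group labels only attach to missing parent slots
  sg[!is.na(sire)] <- NA_character_
  dg[!is.na(dam)] <- NA_character_

  ## materialize phantom parents as founders
  phantom <- setdiff(c(sire, dam), c(id, NA_character_))
  if (length(phantom)) {
    id <- c(id, phantom)
    sire <- c(sire, rep(NA_character_, length(phantom)))
    dam <- c(dam, rep(NA_character_, length(phantom)))
    sg <- c(sg, rep(NA_character_, length(phantom)))
    dg <- c(dg, rep(NA_character_, length(phantom)))
  }

  n <- length(id)
  si <- match(sire, id, nomatch = 0L)
  di <- match(dam, id, nomatch = 0L)
  ## Kahn topological sort over parent -> child edges
  indeg <- (si > 0L) + (di > 0L)
  kids <- vector("list", n)
  for (t in seq_len(n)) {
    if (si[t] > 0L) kids[[si[t]]] <- c(kids[[si[t]]], t)
    if (di[t] > 0L) kids[[di[t]]] <- c(kids[[di[t]]], t)
  }
  queue <- integer(n)
  nq <- 0L
  for (t in which(indeg == 0L)) { nq <- nq + 1L; queue[nq] <- t }
  ord <- integer(n)
  done <- 0L
  pos <- 1L
  while (pos <= nq) {
    t <- queue[pos]; pos <- pos + 1L
    done <- done + 1L; ord[done] <- t
    for (k in kids[[t]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) { nq <- nq + 1L; queue[nq] <- k }
    }
  }
  if (done < n) {
    stuck <- setdiff(seq_len(n), ord[seq_len(done)])
    stop("pedigree cycle detected involving individual '", id[stuck[1L]], "'")
  }
  ord <- ord[seq_len(n)]

  groups <- unique(c(sg[ord], dg[ord]))
  groups <- groups[!is.na(groups)]
  new("Pedigree", id = id[ord], sire = sire[ord], dam = dam[ord],
      sireGroup = sg[ord], damGroup = dg[ord], groups = groups,
      phantoms = phantom)
}

#' @rdname Pedigree
#' @export
sortPedigree <- function(x) {
  if (is(x, "Pedigree")) x <- as.data.frame(x)
  Pedigree(x)
}

#' @export
#' @describeIn Pedigree data-frame view (id, sire, dam, groups).
setMethod("as.data.frame", "Pedigree", function(x, ...) {
  data.frame(id = x@id, sire = x@sire, dam = x@dam,
             sire_group = x@sireGroup, dam_group = x@damGroup,
             stringsAsFactors = FALSE)
})

## integer parent indices (0 = missing), in sorted order
.parentIndex <- function(ped) {
  list(si = match(ped@sire, ped@id, nomatch = 0L),
       di = match(ped@dam, ped@id, nomatch = 0L))
}

## ---- tabular relationship matrix ----------------------------------

## Recursion over [MF block | individuals] with MFs first. gammaVals NULL
## gives the classical A (missing parents unrelated). Individuals must be
## in topological order; parent codes are already offset into this index
## space (MF g -> g, individual t -> K + t, missing -> 0).
.tabularRel <- function(p1, p2, K = 0L, gammaVals = NULL) {
  n <- length(p1)
  N <- K + n
  M <- matrix(0, N, N)
  if (K > 0L) M[seq_len(K), seq_len(K)] <- gammaVals
  for (t in seq_len(n)) {
    r <- K + t
    a <- p1[t]; b <- p2[t]
    if (r > 1L) {
      idx <- seq_len(r - 1L)
      row <- numeric(r - 1L)
      if (a > 0L) row <- row + 0.5 * M[a, idx]
      if (b > 0L) row <- row + 0.5 * M[b, idx]
      M[r, idx] <- row
      M[idx, r] <- row
    }
    M[r, r] <- 1 + if (a > 0L && b > 0L) 0.5 * M[a, b] else 0
  }
  M
}

## parent codes in the [MF | individuals] index space; gamma mode
## requires every missing slot to carry a label present in `labels`
.parentCodes <- function(ped, labels = NULL) {
  pi <- .parentIndex(ped)
  K <- length(labels)
  if (is.null(labels)) {
    list(p1 = ifelse(pi$si > 0L, pi$si, 0L),
         p2 = ifelse(pi$di > 0L, pi$di, 0L), K = 0L)
  } else {
    sgi <- match(ped@sireGroup, labels, nomatch = 0L)
    dgi <- match(ped@damGroup, labels, nomatch = 0L)
    badS <- pi$si == 0L & sgi == 0L
    badD <- pi$di == 0L & dgi == 0L
    if (any(badS | badD))
      stop("missing parent slot without metafounder label for individual '",
           ped@id[which(badS | badD)[1L]], "'")
    list(p1 = ifelse(pi$si > 0L, K + pi$si, sgi),
         p2 = ifelse(pi$di > 0L, K + pi$di, dgi), K = K)
  }
}

#' Pedigree numerator relationship matrix A
#'
#' Tabular-method A over all individuals (diagonal 1 + F with F the
#' pedigree inbreeding coefficient), optionally restricted to a subset
#' after the full recursion.
#'
#' @param ped a sorted [Pedigree-class].
#' @param subset optional ids to restrict the returned matrix to.
#' @return [RelationshipMatrix-class] of kind `"A"`.
#' @export
aMatrix <- function(ped, subset = NULL) {
  pc <- .parentCodes(ped)
  M <- .tabularRel(pc$p1, pc$p2)
  ids <- ped@id
  if (!is.null(subset)) {
    idx <- match(subset, ids)
    if (anyNA(idx))
      stop("subset ids not in pedigree: ",
           paste(utils::head(subset[is.na(idx)], 5L), collapse = ", "))
    M <- M[idx, idx, drop = FALSE]
    ids <- subset
  }
  relationshipMatrix(M, ids, "A")
}

#' Gamma-augmented relationship matrix A-Gamma
#'
#' Tabular recursion treating metafounders as founder pseudo-individuals
#' whose mutual relationships are Gamma; every missing parent slot must
#' carry a metafounder label. Entities are the pedigree individuals
#' followed by the K metafounders.
#'
#' @param ped a sorted [Pedigree-class] with group labels on all missing
#'   parent slots.
#' @param gamma a [GammaMatrix-class] covering all labels used.
#' @param subset optional entity ids (individuals and/or metafounders).
#' @return [RelationshipMatrix-class] of kind `"A_gamma"`.
#' @export
aGammaMatrix <- function(ped, gamma, subset = NULL) {
  labels <- gammaLabels(gamma)
  pc <- .parentCodes(ped, labels)
  K <- pc$K
  M <- .tabularRel(pc$p1, pc$p2, K, gammaValues(gamma))
  n <- length(ped@id)
  ## reorder to [individuals, metafounders]
  perm <- c(K + seq_len(n), seq_len(K))
  M <- M[perm, perm, drop = FALSE]
  ids <- c(ped@id, labels)
  if (!is.null(subset)) {
    idx <- match(subset, ids)
    if (anyNA(idx))
      stop("subset ids not among entities: ",
           paste(utils::head(subset[is.na(idx)], 5L), collapse = ", "))
    M <- M[idx, idx, drop = FALSE]
    ids <- subset
  }
  relationshipMatrix(M, ids, "A_gamma")
}

## ---- memoized pairwise relationships ------------------------------

## Closure computing individual relationship coefficients on demand in
## the [MF | individuals] index space. Used for the Mendelian-sampling
## variances of the sparse inverses without forming the dense matrix.
.relFun <- function(p1, p2, K = 0L, gammaVals = NULL) {
  memo <- new.env(hash = TRUE, parent = emptyenv())
  rel <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i <= K && j <= K) return(gammaVals[i, j])
    key <- if (i <= j) paste0(i, ":", j) else paste0(j, ":", i)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    if (i == j) {
      t <- i - K
      a <- p1[t]; b <- p2[t]
      v <- 1 + if (a > 0L && b > 0L) 0.5 * rel(a, b) else 0
    } else {
      ## recurse on the later entity (individuals follow all MFs and
      ## are topologically ordered, so max index is safe)
      k <- max(i, j); l <- min(i, j)
      t <- k - K
      v <- 0
      if (p1[t] > 0L) v <- v + 0.5 * rel(p1[t], l)
      if (p2[t] > 0L) v <- v + 0.5 * rel(p2[t], l)
    }
    memo[[key]] <- v
    v
  }
  rel
}

## Henderson-rule triplets for the inverse; shared by aInverse and
## aGammaInverse. Returns the assembled sparse symmetric inverse in the
## [MF | individuals] index space.
.hendersonInverse <- function(p1, p2, K, gammaVals) {
  n <- length(p1)
  N <- K + n
  rel <- .relFun(p1, p2, K, gammaVals)
  ti <- tj <- tx <- vector("list", n + 1L)
  for (t in seq_len(n)) {
    r <- K + t
    a <- p1[t]; b <- p2[t]
    aa <- if (a > 0L) rel(a, a) else 0
    bb <- if (b > 0L) rel(b, b) else 0
    ab <- if (a > 0L && b > 0L) rel(a, b) else 0
    ## Mendelian-sampling variance consistent with the recursion
    d <- (1 + 0.5 * ab) - 0.25 * (aa + bb + 2 * ab)
    w <- c(r, if (a > 0L) a, if (b > 0L) b)
    cf <- c(1, if (a > 0L) -0.5, if (b > 0L) -0.5)
    op <- outer(cf, cf) / d
    ti[[t]] <- rep(w, each = length(w))
    tj[[t]] <- rep(w, times = length(w))
    tx[[t]] <- as.vector(op)
  }
  if (K > 0L) {
    Ginv <- tryCatch(chol2inv(chol(gammaVals)),
                     error = function(e)
                       stop("Gamma is singular; apply a PSD repair ",
                            "(estimateGamma(..., psdRepair = TRUE)) first"))
    ij <- expand.grid(seq_len(K), seq_len(K))
    ti[[n + 1L]] <- ij[[1L]]
    tj[[n + 1L]] <- ij[[2L]]
    tx[[n + 1L]] <- as.vector(Ginv)
  }
  Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                       dims = c(N, N))
}

#' Sparse inverse of the pedigree relationship matrix
#'
#' Henderson's rules with Mendelian-sampling variances from the
#' inbreeding-aware recursion, so `aInverse(ped)` is the exact inverse of
#' `aMatrix(ped)` (to numerical precision) on inbred pedigrees too.
#'
#' @param ped a sorted [Pedigree-class].
#' @return Sparse [RelationshipMatrix-class] of kind `"A_inv"`.
#' @export
aInverse <- function(ped) {
  pc <- .parentCodes(ped)
  Minv <- .hendersonInverse(pc$p1, pc$p2, 0L, NULL)
  relationshipMatrix(Matrix::forceSymmetric(Minv), ped@id, "A_inv")
}

#' Sparse inverse of the Gamma-augmented relationship matrix
#'
#' Assembles the inverse by Henderson-style rules in which metafounders
#' act as founder pseudo-individuals, with the inverse Gamma added on the
#' metafounder block. Equals the dense inverse of [aGammaMatrix()].
#'
#' @inheritParams aGammaMatrix
#' @return Sparse [RelationshipMatrix-class] of kind `"A_gamma_inv"`,
#'   entities ordered individuals first, metafounders last.
#' @export
aGammaInverse <- function(ped, gamma) {
  labels <- gammaLabels(gamma)
  pc <- .parentCodes(ped, labels)
  K <- pc$K
  Minv <- .hendersonInverse(pc$p1, pc$p2, K, gammaValues(gamma))
  n <- length(ped@id)
  perm <- c(K + seq_len(n), seq_len(K))
  Minv <- Minv[perm, perm, drop = FALSE]
  relationshipMatrix(Matrix::forceSymmetric(Minv), c(ped@id, labels),
                     "A_gamma_inv")
}

## ---- unknown-parent-group machinery -------------------------------

#' Expected group-contribution matrix Q
#'
#' Each row gives the expected fractional contribution of every
#' metafounder/genetic group to one individual: founders are indicators
#' of their group(s), offspring rows are the mean of their parents' rows
#' (a known parent contributes half its row, a missing labelled parent
#' half an indicator). Rows sum to 1 exactly.
#'
#' @param ped a sorted [Pedigree-class] with labels on all missing parent
#'   slots.
#' @return Numeric matrix (individuals x K groups) with dimnames.
#' @export
upgMatrix <- function(ped) {
  labels <- ped@groups
  if (!length(labels)) stop("pedigree has no group labels")
  n <- length(ped@id)
  K <- length(labels)
  pi <- .parentIndex(ped)
  sgi <- match(ped@sireGroup, labels, nomatch = 0L)
  dgi <- match(ped@damGroup, labels, nomatch = 0L)
  Q <- matrix(0, n, K, dimnames = list(ped@id, labels))
  for (t in seq_len(n)) {
    row <- numeric(K)
    if (pi$si[t] > 0L) row <- row + 0.5 * Q[pi$si[t], ]
    else if (sgi[t] > 0L) row[sgi[t]] <- row[sgi[t]] + 0.5
    else stop("missing parent slot without group label for individual '",
              ped@id[t], "'")
    if (pi$di[t] > 0L) row <- row + 0.5 * Q[pi$di[t], ]
    else if (dgi[t] > 0L) row[dgi[t]] <- row[dgi[t]] + 0.5
    else stop("missing parent slot without group label for individual '",
              ped@id[t], "'")
    Q[t, ] <- row
  }
  Q
}

## ---- genotype/pedigree consistency --------------------------------

#' Opposing-homozygote screen of declared parent-offspring pairs
#'
#' For every declared parent-offspring pair where both members are
#' genotyped, counts loci at which the two are opposite homozygotes
#' (0 vs 2). A true parent-offspring pair has rate 0 up to genotyping
#' error; pairs above `threshold` are flagged as probable pedigree
#' errors.
#'
#' @param ped a sorted [Pedigree-class].
#' @param geno a [GenotypeMatrix-class].
#' @param threshold flag rate, default 0.02 of shared non-missing loci.
#' @return data frame: id, parent, slot, nLoci, nOpposing, rate, flagged.
#' @export
genotypeConflicts <- function(ped, geno, threshold = 0.02) {
  gids <- genoIds(geno)
  if (!length(intersect(ped@id, gids)))
    stop("no ids shared between pedigree and genotypes")
  M <- genoValues(geno)
  pi <- .parentIndex(ped)
  out <- list()
  for (slot in c("sire", "dam")) {
    par <- if (slot == "sire") ped@sire else ped@dam
    keep <- which(!is.na(par) & ped@id %in% gids & par %in% gids)
    for (t in keep) {
      x <- M[match(ped@id[t], gids), ]
      y <- M[match(par[t], gids), ]
      ok <- !is.na(x) & !is.na(y)
      opp <- sum((x == 0L & y == 2L) | (x == 2L & y == 0L), na.rm = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        id = ped@id[t], parent = par[t], slot = slot,
        nLoci = sum(ok), nOpposing = opp,
        rate = if (sum(ok)) opp / sum(ok) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(id = character(), parent = character(), slot = character(),
               nLoci = integer(), nOpposing = integer(), rate = numeric())
  res$flagged <- !is.na(res$rate) & res$rate > threshold
  res
}
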