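## LR-method cross-validation: delete the phenotypes of a focal group
## (all progeny of chosen parents), refit, and compare whole vs partial
## solutions through accuracy, stability, dispersion and bias.

#' Form the partial dataset for LR validation
#'
#' Removes the phenotype records of every phenotyped progeny of any
#' focal parent; the removed ids form the focal group. Overlapping
#' progeny of two focal parents are counted once; a listed id that is
#' not a parent contributes nothing (with a warning).
#'
#' @param phenotypes data frame `id`, `site`, `family`, `value`.
#' @param focalParents ids of the focal parents.
#' @param ped a sorted [Pedigree-class].
#' @return List: `phenotypes` (partial data), `focalIds` (removed ids).
#' @export
dropFocalPhenotypes <- function(phenotypes, focalParents, ped) {
  .checkPhenotypes(phenotypes)
  focalParents <- unique(as.character(focalParents))
  isProgeny <- (!is.na(ped@sire) & ped@sire %in% focalParents) |
    (!is.na(ped@dam) & ped@dam %in% focalParents)
  progeny <- ped@id[isProgeny]
  noKids <- setdiff(focalParents,
                    unique(c(ped@sire[isProgeny], ped@dam[isProgeny])))
  if (length(noKids))
    warning("focal parent(s) with no progeny in the pedigree: ",
            paste(utils::head(noKids, 5L), collapse = ", "))
  focalIds <- unique(intersect(phenotypes$id, progeny))
  if (!length(focalIds))
    stop("focal group is empty: no phenotyped progeny of the focal parents")
  list(phenotypes = phenotypes[!(phenotypes$id %in% focalIds), ,
                               drop = FALSE],
       focalIds = focalIds)
}

#' Stratified focal-parent sample
#'
#' Draws an (approximately) equal number of focal parents from each
#' stratum (e.g. breeding program or base population), emulating focal
#' groups whose progeny represent a diversity of origins. Seed the RNG
#' before calling for reproducibility.
#'
#' @param candidates parent ids eligible as focal parents (parents with
#'   phenotyped progeny).
#' @param strata named character/integer vector giving the stratum of
#'   each candidate (names are ids), or a vector aligned to
#'   `candidates`.
#' @param n total number of focal parents to draw.
#' @return Character vector of focal parent ids.
#' @export
sampleFocalParents <- function(candidates, strata, n = 20L) {
  st <- if (!is.null(names(strata))) strata[candidates] else strata
  groups <- split(candidates, st)
  per <- ceiling(n / length(groups))
  picked <- unlist(lapply(groups, function(x) sample(x, min(per, length(x)))))
  if (length(picked) > n) picked <- sample(picked, n)
  unname(picked)
}

#' LR validation statistics for one model
#'
#' Over the focal group, with `aw`/`ap` the whole- and partial-data
#' solutions:
#' accuracy `ACC = sqrt(cov(aw, ap) / ((1 - Fbar) * sigmaA2))`,
#' stability `STAB = cor(aw, ap)`, dispersion
#' `DISP = cov(aw, ap) / var(ap)` (1 = none), and
#' `BIAS = mean(ap) - mean(aw)` (0 = none), using n-1 divisors.
#' A negative covariance makes ACC undefined; it is returned as `NA`
#' with the raw ratio still reported.
#'
#' @param whole,partial [BlupSolutions-class] from the whole and partial
#'   fits of the same model.
#' @param focalIds ids of the focal group.
#' @param fBar mean inbreeding coefficient of the focal group, from the
#'   group-free H matrix (see [inbreedingFromH()]).
#' @param sigmaA2 additive variance estimate used by the model.
#' @return One-row data frame: `acc`, `accRatio` (the raw ratio under
#'   the square root), `stab`, `disp`, `bias`, `biasSD` (bias in genetic
#'   SD units), `fBar`, `sigmaA2`, `n`.
#' @export
lrStatistics <- function(whole, partial, focalIds, fBar, sigmaA2) {
  if (sigmaA2 <= 0) stop("sigmaA2 must be positive")
  if (fBar >= 1) stop("fBar must be below 1")
  aw <- whole@additive[focalIds]
  ap <- partial@additive[focalIds]
  if (anyNA(aw) || anyNA(ap))
    stop("focal ids missing from the solution vectors")
  cv <- cov(aw, ap)
  vp <- var(ap)
  if (vp == 0) stop("partial-data solutions have zero variance over the ",
                    "focal group: dispersion undefined")
  ratio <- cv / ((1 - fBar) * sigmaA2)
  acc <- if (ratio >= 0) sqrt(ratio) else NA_real_
  bias <- mean(ap) - mean(aw)
  data.frame(acc = acc, accRatio = ratio,
             stab = cor(aw, ap), disp = cv / vp,
             bias = bias, biasSD = bias / sqrt(sigmaA2),
             fBar = fBar, sigmaA2 = sigmaA2, n = length(focalIds))
}

#' Run the LR validation across model variants
#'
#' Fits every configured variant on the whole and on the partial data
#' (same focal group and same mean inbreeding for all variants, the
#' latter taken from the group-free H per standard practice) and tabulates
#' the LR statistics.
#'
#' @param phenotypes data frame `id`, `site`, `family`, `value`.
#' @param configs named list; each element a list with components
#'   `model` ([BlupModel-class]), `kinv`, and optionally `gamma` and
#'   `q`, as for [buildMME()].
#' @param focalParents ids whose progeny form the focal group.
#' @param ped a sorted [Pedigree-class].
#' @param fBar shared mean focal-group inbreeding coefficient.
#' @param method solver passed to [solveMME()].
#' @return Data frame, one row per variant, Table-style columns
#'   (variant, acc, stab, disp, bias, biasSD, ...), with the fitted
#'   solutions in `attr(, "fits")`.
#' @export
runLRSuite <- function(phenotypes, configs, focalParents, ped, fBar,
                       method = "direct") {
  if (!length(configs)) stop("no model variants configured")
  if (is.null(names(configs)) || any(!nzchar(names(configs))))
    stop("configs must be a named list")
  part <- dropFocalPhenotypes(phenotypes, focalParents, ped)
  rows <- vector("list", length(configs))
  fits <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cf <- configs[[i]]
    whole <- fitBlup(phenotypes, cf$model, cf$kinv, gamma = cf$gamma,
                     q = cf$q, method = method)
    partial <- fitBlup(part$phenotypes, cf$model, cf$kinv,
                       gamma = cf$gamma, q = cf$q, method = method)
    st <- lrStatistics(whole, partial, part$focalIds, fBar,
                       cf$model@sigmaA2)
    rows[[i]] <- cbind(data.frame(variant = names(configs)[i],
                                  stringsAsFactors = FALSE), st)
    fits[[i]] <- list(whole = whole, partial = partial)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "focalIds") <- part$focalIds
  attr(out, "fits") <- setNames(fits, names(configs))
  out
}
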