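## Delimited-text readers/writers for pedigrees, genotypes, phenotypes,
## relationship and Gamma matrices, Newick trees, and the per-trial
## phenotype standardization. Numeric output uses 17 significant digits
## so write -> read -> write round-trips are byte-stable.

.fmtNum <- function(x) sprintf("%.17g", x)

.detectDelim <- function(file) {
  line <- readLines(file, n = 1L)
  hasC <- grepl(",", line, fixed = TRUE)
  hasT <- grepl("\t", line, fixed = TRUE)
  if (hasC && hasT)
    stop("ambiguous delimiter in ", file, ": both comma and tab present")
  if (hasC) "," else if (hasT) "\t" else ""
}

#' Read a pedigree file
#'
#' Delimited text (comma/tab/whitespace auto-detected) with header
#' `id,sire,dam[,sire_group,dam_group]`; missing parents coded `0`,
#' empty or `NA`. The result is sorted and validated (see [Pedigree()]).
#'
#' @param file path.
#' @return A [Pedigree-class].
#' @export
readPedigree <- function(file) {
  sep <- .detectDelim(file)
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  Pedigree(df)
}

#' Write a pedigree file
#'
#' @param ped a [Pedigree-class].
#' @param file path; comma-delimited, missing parents written as `0`.
#' @return `file`, invisibly.
#' @export
writePedigree <- function(ped, file) {
  df <- as.data.frame(ped)
  df$sire[is.na(df$sire)] <- "0"
  df$dam[is.na(df$dam)] <- "0"
  df$sire_group[is.na(df$sire_group)] <- ""
  df$dam_group[is.na(df$dam_group)] <- ""
  utils::write.table(df, file, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a gene-content genotype file
#'
#' One row per individual: id then the marker codes `0/1/2` (`NA` or `5`
#' for missing), with an optional marker-id header line. Any other code
#' is a parse error reported with its line and column.
#'
#' @param file path.
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypes <- function(file) {
  sep <- .detectDelim(file)
  lines <- readLines(file)
  if (!length(lines)) stop("empty genotype file")
  splitLine <- function(x)
    if (sep == "") strsplit(trimws(x), "[ \t]+")[[1L]] else
      strsplit(x, sep, fixed = TRUE)[[1L]]
  first <- splitLine(lines[1L])
  codes <- c("0", "1", "2", "5", "NA", "")
  hasHeader <- length(first) > 1L && !all(first[-1L] %in% codes)
  markers <- if (hasHeader) first[-1L] else NULL
  body <- lines[(1L + hasHeader):length(lines)]
  body <- body[nzchar(trimws(body))]
  ids <- character(length(body))
  rows <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- splitLine(body[i])
    ids[i] <- f[1L]
    v <- f[-1L]
    bad <- which(!(v %in% codes))
    if (length(bad))
      stop("invalid genotype code '", v[bad[1L]], "' at line ",
           i + hasHeader, ", column ", bad[1L] + 1L)
    x <- suppressWarnings(as.integer(v))
    x[v %in% c("5", "NA", "")] <- NA_integer_
    rows[[i]] <- x
  }
  m <- unique(lengths(rows))
  if (length(m) != 1L)
    stop("rows have differing marker counts")
  M <- do.call(rbind, rows)
  if (is.null(markers)) markers <- paste0("M", seq_len(ncol(M)))
  genotypeMatrix(M, ids, markers)
}

#' Write a gene-content genotype file
#'
#' @param geno a [GenotypeMatrix-class].
#' @param file path; comma-delimited with a marker header, missing as
#'   `NA`.
#' @return `file`, invisibly.
#' @export
writeGenotypes <- function(geno, file) {
  M <- genoValues(geno)
  header <- paste(c("id", geno@markers), collapse = ",")
  rows <- vapply(seq_len(nrow(M)), function(i)
    paste(c(genoIds(geno)[i], ifelse(is.na(M[i, ]), "NA", M[i, ])),
          collapse = ","), character(1L))
  writeLines(c(header, rows), file)
  invisible(file)
}

#' Read a phenotype file
#'
#' Delimited text with header `id,site,family,value`.
#'
#' @param file path.
#' @return Data frame with those columns, `value` numeric.
#' @export
readPhenotypes <- function(file) {
  sep <- .detectDelim(file)
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  need <- c("id", "site", "family", "value")
  if (!all(need %in% names(df)))
    stop("phenotype file needs columns id, site, family, value")
  df$value <- as.numeric(df$value)
  if (anyNA(df$value)) stop("non-numeric phenotype value")
  df[need]
}

#' Write a phenotype file
#'
#' @param phenotypes data frame `id`, `site`, `family`, `value`.
#' @param file path; comma-delimited, full numeric precision.
#' @return `file`, invisibly.
#' @export
writePhenotypes <- function(phenotypes, file) {
  .checkPhenotypes(phenotypes)
  out <- phenotypes
  out$value <- .fmtNum(out$value)
  utils::write.table(out, file, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write a relationship matrix
#'
#' `format = "dense"`: labelled dense CSV; `format = "long"`: lower
#' triangle (including the diagonal) as `id_i,id_j,value`. The kind tag
#' is stored in a leading `#kind=` comment so reading restores the
#' object exactly.
#'
#' @param x a [RelationshipMatrix-class].
#' @param file path.
#' @param format `"dense"` or `"long"`.
#' @return `file`, invisibly.
#' @export
writeRelMatrix <- function(x, file, format = c("dense", "long")) {
  format <- match.arg(format)
  M <- as.matrix(x)
  ids <- entityIds(x)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("#kind=", relKind(x)), con)
  if (format == "dense") {
    writeLines(paste(c("id", ids), collapse = ","), con)
    for (i in seq_along(ids))
      writeLines(paste(c(ids[i], .fmtNum(M[i, ])), collapse = ","), con)
  } else {
    writeLines("id_i,id_j,value", con)
    for (i in seq_along(ids)) {
      j <- seq_len(i)
      writeLines(paste(ids[i], ids[j], .fmtNum(M[i, j]), sep = ","), con)
    }
  }
  invisible(file)
}

#' Read a relationship matrix written by [writeRelMatrix()]
#'
#' @param file path.
#' @return A [RelationshipMatrix-class] (dense storage).
#' @export
readRelMatrix <- function(file) {
  lines <- readLines(file)
  kind <- "A"
  if (startsWith(lines[1L], "#kind=")) {
    kind <- sub("^#kind=", "", lines[1L])
    lines <- lines[-1L]
  }
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (identical(header, c("id_i", "id_j", "value"))) {
    parts <- strsplit(lines[-1L], ",", fixed = TRUE)
    ii <- vapply(parts, `[`, character(1L), 1L)
    jj <- vapply(parts, `[`, character(1L), 2L)
    vv <- as.numeric(vapply(parts, `[`, character(1L), 3L))
    ids <- unique(ii)
    M <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    M[cbind(match(ii, ids), match(jj, ids))] <- vv
    M[cbind(match(jj, ids), match(ii, ids))] <- vv
  } else {
    ids <- header[-1L]
    parts <- strsplit(lines[-1L], ",", fixed = TRUE)
    M <- t(vapply(parts, function(p) as.numeric(p[-1L]),
                  numeric(length(ids))))
    dimnames(M) <- list(ids, ids)
    M <- (M + t(M)) / 2
  }
  relationshipMatrix(M, ids, kind)
}

#' Write / read a Gamma matrix as labelled dense CSV
#'
#' @param gamma a [GammaMatrix-class].
#' @param file path.
#' @return `file` (write) or a [GammaMatrix-class] (read).
#' @export
writeGammaMatrix <- function(gamma, file) {
  v <- gammaValues(gamma)
  labels <- gammaLabels(gamma)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(c("label", labels), collapse = ","), con)
  for (i in seq_along(labels))
    writeLines(paste(c(labels[i], .fmtNum(v[i, ])), collapse = ","), con)
  invisible(file)
}

#' @rdname writeGammaMatrix
#' @export
readGammaMatrix <- function(file) {
  lines <- readLines(file)
  labels <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]][-1L]
  parts <- strsplit(lines[-1L], ",", fixed = TRUE)
  v <- t(vapply(parts, function(p) as.numeric(p[-1L]),
                numeric(length(labels))))
  v <- (v + t(v)) / 2
  gammaMatrix(v, labels)
}

#' Write a phylogenetic tree in Newick format
#'
#' @param tree an `ape` phylo object (e.g. from [gammaTree()]).
#' @param file path.
#' @return `file`, invisibly.
#' @export
writeNewickTree <- function(tree, file) {
  ape::write.tree(tree, file = file)
  invisible(file)
}

#' Standardize phenotypes by trial
#'
#' Centers and scales `value` within each site to mean 0 and SD 1 (n-1
#' divisor). Sites with fewer than 2 records, or with zero variance, are
#' errors. The per-site means and SDs applied are attached as
#' `attr(, "parameters")`.
#'
#' @param phenotypes data frame `id`, `site`, `family`, `value`.
#' @return The standardized data frame.
#' @export
standardizeByTrial <- function(phenotypes) {
  .checkPhenotypes(phenotypes)
  out <- phenotypes
  params <- list()
  for (s in unique(out$site)) {
    idx <- which(out$site == s)
    if (length(idx) < 2L)
      stop("site '", s, "' has fewer than 2 records")
    mu <- mean(out$value[idx])
    sdv <- sd(out$value[idx])
    if (sdv == 0) stop("site '", s, "' has constant phenotype values")
    out$value[idx] <- (out$value[idx] - mu) / sdv
    params[[s]] <- c(mean = mu, sd = sdv)
  }
  attr(out, "parameters") <- do.call(rbind, params)
  out
}

#' Cross-reference ids across pipeline inputs
#'
#' Errors when phenotyped (or genotyped) ids are absent from the
#' pedigree, listing the first 10 offenders.
#'
#' @param phenotypes data frame with an `id` column, or `NULL`.
#' @param ped a [Pedigree-class].
#' @param geno optional [GenotypeMatrix-class].
#' @return `TRUE`, invisibly, when consistent.
#' @export
checkCrossReferences <- function(phenotypes, ped, geno = NULL) {
  if (!is.null(phenotypes)) {
    bad <- setdiff(unique(phenotypes$id), ped@id)
    if (length(bad))
      stop("phenotyped ids absent from pedigree: ",
           paste(utils::head(bad, 10L), collapse = ", "))
  }
  if (!is.null(geno)) {
    bad <- setdiff(genoIds(geno), ped@id)
    if (length(bad))
      stop("genotyped ids absent from pedigree: ",
           paste(utils::head(bad, 10L), collapse = ", "))
  }
  invisible(TRUE)
}
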