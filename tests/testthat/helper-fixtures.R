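# Fixtures are generated in code; nothing is read from disk.

trioPed <- function() {
  Pedigree(data.frame(id = c("A", "B", "C"),
                      sire = c(NA, NA, "A"),
                      dam = c(NA, NA, "B")))
}

# founders A,B; C = A x B; F = C x A (F inbred, F = 0.25)
inbredPed <- function() {
  Pedigree(data.frame(id = c("A", "B", "C", "F"),
                      sire = c(NA, NA, "A", "C"),
                      dam = c(NA, NA, "B", "A")))
}

# random overlapping-generation pedigree; founders carry group labels
# drawn from K groups when withGroups = TRUE
randomPedigreeDF <- function(n, nFounders = 20, withGroups = FALSE, K = 3) {
  id <- sprintf("I%04d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (nFounders + 1):n) {
    pool <- id[seq_len(i - 1)]
    pr <- sample(pool, 2)
    sire[i] <- pr[1]; dam[i] <- pr[2]
  }
  df <- data.frame(id = id, sire = sire, dam = dam,
                   stringsAsFactors = FALSE)
  if (withGroups) {
    g <- sprintf("g%d", sample(K, n, replace = TRUE))
    df$sire_group <- ifelse(is.na(df$sire), g, NA)
    g2 <- sprintf("g%d", sample(K, n, replace = TRUE))
    df$dam_group <- ifelse(is.na(df$dam), g2, NA)
  }
  df
}

randomGamma <- function(K, scale = 0.5) {
  L <- matrix(rnorm(K * K, 0, 0.3), K)
  G <- scale * diag(K) + 0.2 + tcrossprod(L) / K
  G <- (G + t(G)) / 2
  dimnames(G) <- list(sprintf("g%d", 1:K), sprintf("g%d", 1:K))
  gammaMatrix(G)
}

# small complete dataset for solver tests: pedigree, phenotypes,
# genotyped subset with relationship machinery
smallDataset <- function(seed = 101) {
  simPopulation("desk", seed = seed, K = 2, m = 120, nPerPop = 8,
                nGenerations = 2L, familiesPerGen = 8L,
                progenyPerFamily = 6L, nSites = 2L)
}

maxAbs <- function(x) max(abs(x))
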