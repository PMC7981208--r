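#' Per-population genetic diversity summaries
#'
#' For each population: sample size, observed heterozygosity H_O (fraction
#' of heterozygous non-missing calls, averaged over loci), unbiased expected
#' heterozygosity H_E (per locus \code{2n/(2n-1) * (1 - sum p^2)}, averaged
#' over loci), and allelic richness A_R rarefied to a common gene count by
#' the hypergeometric expectation of the number of alleles observed in a
#' subsample.
#'
#' @param gm a \code{\link{GenotypeMatrix-class}}.
#' @param rarefactionGenes gene count for rarefaction; defaults to the
#'   smallest per-population, per-locus number of non-missing gene copies.
#' @return data.frame with one row per population: \code{population},
#'   \code{n}, \code{Ho}, \code{He}, \code{Ar}.
#' @export
diversity <- function(gm, rarefactionGenes = NULL) {
  stopifnot(is(gm, "GenotypeMatrix"))
  cts <- .alleleCounts(gm)
  if (any(colSums(cts$tot) == 0))
    stop("a locus has no non-missing calls in any population")
  if (is.null(rarefactionGenes)) {
    pos <- cts$tot[cts$tot > 0]
    rarefactionGenes <- max(2L, min(pos))
  }
  g <- rarefactionGenes
  G <- genotypes(gm)
  out <- lapply(seq_along(cts$pops), function(k) {
    rows <- populations(gm) == cts$pops[k]
    sub <- G[rows, , drop = FALSE]
    nonmiss <- colSums(!is.na(sub))
    ok <- nonmiss > 0
    ho <- mean(colSums(sub == 1, na.rm = TRUE)[ok] / nonmiss[ok])
    nTot <- cts$tot[k, ]
    p <- ifelse(nTot > 0, cts$alt[k, ] / pmax(nTot, 1), NA)
    heL <- (nTot / pmax(nTot - 1, 1)) * (1 - (p^2 + (1 - p)^2))
    he <- mean(heL[ok & nTot > 1])
    # expected number of distinct alleles in a draw of g genes without
    # replacement (biallelic): 2 - P(all ref) - P(all alt)
    nAlt <- cts$alt[k, ]
    nRef <- nTot - nAlt
    arOk <- ok & nTot >= g
    pAllRef <- exp(lchoose(nRef[arOk], g) - lchoose(nTot[arOk], g))
    pAllAlt <- exp(lchoose(nAlt[arOk], g) - lchoose(nTot[arOk], g))
    ar <- mean(2 - pAllRef - pAllAlt)
    data.frame(population = cts$pops[k], n = sum(rows),
               Ho = ho, He = he, Ar = ar, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "rarefactionGenes") <- g
  res
}

# Weir-Cockerham (1984) variance components for one biallelic locus
# across r populations; n = individuals, p = alt frequency, h = observed
# heterozygote frequency, all per population
.wcComponents <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) /
       (4 * nbar))
  c <- hbar / 2
  c(a = a, b = b, c = c)
}

# multilocus WC theta for a two-population subset of a genotype matrix
.wcFst <- function(G, popIdx) {
  num <- 0; den <- 0
  for (l in seq_len(ncol(G))) {
    gl <- G[, l]
    n <- h <- p <- numeric(2)
    for (k in 1:2) {
      gk <- gl[popIdx == k]
      gk <- gk[!is.na(gk)]
      n[k] <- length(gk)
      if (n[k] == 0) break
      p[k] <- sum(gk) / (2 * n[k])
      h[k] <- mean(gk == 1)
    }
    if (any(n < 2)) next
    w <- .wcComponents(n, p, h)
    if (!all(is.finite(w))) next
    num <- num + w["a"]
    den <- den + sum(w)
  }
  if (den == 0) return(NA_real_)
  unname(num / den)
}

#' Pairwise Weir-Cockerham F_ST with permutation p-values
#'
#' Multilocus Weir-Cockerham (1984) estimator for every population pair,
#' with p-values from permuting individuals between the two populations
#' (add-one correction: \code{p = (1 + #(perm >= obs)) / (nPermutations +
#' 1)}). The reported estimate matrix clamps negative estimates at 0; the
#' permutation test uses the raw estimator.
#'
#' @param gm a \code{\link{GenotypeMatrix-class}} with >= 2 populations,
#'   each with >= 2 individuals.
#' @param nPermutations label permutations per pair (default 999, minimum
#'   99).
#' @param seed integer seed.
#' @return list with matrices \code{fst} (clamped estimates, lower
#'   triangle), \code{pValue} (upper triangle mirrored), and \code{raw}
#'   (unclamped estimates).
#' @export
pairwiseFst <- function(gm, nPermutations = 999, seed = 1L) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (nPermutations < 99) stop("use at least 99 permutations")
  pops <- levels(populations(gm))
  if (length(pops) < 2) stop("need at least 2 populations")
  sizes <- table(populations(gm))
  if (any(sizes < 2))
    stop("population(s) with < 2 individuals: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  set.seed(as.integer(seed))
  G <- genotypes(gm)
  est <- pmat <- matrix(NA_real_, length(pops), length(pops),
                        dimnames = list(pops, pops))
  for (i in seq_along(pops)[-1]) for (j in seq_len(i - 1)) {
    rows <- which(populations(gm) %in% pops[c(j, i)])
    sub <- G[rows, , drop = FALSE]
    popIdx <- ifelse(populations(gm)[rows] == pops[j], 1L, 2L)
    obs <- .wcFst(sub, popIdx)
    perm <- vapply(seq_len(nPermutations), function(q)
      .wcFst(sub, sample(popIdx)), numeric(1))
    est[i, j] <- obs
    pmat[i, j] <- pmat[j, i] <- (1 + sum(perm >= obs, na.rm = TRUE)) /
      (nPermutations + 1)
  }
  list(fst = pmax(est, 0), pValue = pmat, raw = est,
       nPermutations = nPermutations)
}
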