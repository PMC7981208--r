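#' Bayesian genotype probability under a reference sample
#'
#' Posterior-predictive probability of observing a diploid biallelic
#' genotype given the allele counts of a reference population sample, under
#' a Dirichlet prior with concentration 1/k per allele (k = 2 here, so 1/2),
#' the Rannala-Mountain convention: the two gene copies are drawn
#' sequentially from the Dirichlet-multinomial, heterozygotes carrying the
#' ordering factor 2. Returns log10 probabilities; alleles absent from the
#' reference keep positive probability through the prior mass.
#'
#' @param g genotype as the count of the alternate allele (0, 1 or 2),
#'   vectorized over loci; \code{NA} gives \code{NA}.
#' @param nAlt alternate-allele count in the reference sample.
#' @param nTot total allele count (2 x non-missing individuals).
#' @param tau prior concentration per allele (default 0.5).
#' @return log10 genotype probabilities, same length as \code{g}.
#' @examples
#' # reference sample (ref:1, alt:1); query homozygous reference
#' 10^genotypeLogLik(0L, nAlt = 1, nTot = 2)   # 0.3125
#' @export
genotypeLogLik <- function(g, nAlt, nTot, tau = 0.5) {
  if (any(nTot < 0, na.rm = TRUE)) stop("negative reference counts")
  nRef <- nTot - nAlt
  d1 <- nTot + 2 * tau
  d2 <- nTot + 1 + 2 * tau
  p0 <- (nRef + tau) * (nRef + 1 + tau) / (d1 * d2)
  p1 <- 2 * (nRef + tau) * (nAlt + tau) / (d1 * d2)
  p2 <- (nAlt + tau) * (nAlt + 1 + tau) / (d1 * d2)
  out <- rep(NA_real_, length(g))
  out[!is.na(g) & g == 0] <- log10(p0)[!is.na(g) & g == 0]
  out[!is.na(g) & g == 1] <- log10(p1)[!is.na(g) & g == 1]
  out[!is.na(g) & g == 2] <- log10(p2)[!is.na(g) & g == 2]
  out
}

# per-population alternate and total allele counts
.alleleCounts <- function(gm) {
  pops <- levels(populations(gm))
  G <- genotypes(gm)
  alt <- matrix(0, length(pops), ncol(G), dimnames = list(pops, NULL))
  tot <- alt
  for (k in seq_along(pops)) {
    rows <- populations(gm) == pops[k]
    alt[k, ] <- colSums(G[rows, , drop = FALSE], na.rm = TRUE)
    tot[k, ] <- 2 * colSums(!is.na(G[rows, , drop = FALSE]))
  }
  list(alt = alt, tot = tot, pops = pops)
}

# log10-likelihood of every individual in every reference population;
# the home population is computed leave-one-out (own alleles removed)
.assignmentLogLik <- function(gm, tau = 0.5) {
  cts <- .alleleCounts(gm)
  G <- genotypes(gm)
  n <- nrow(G)
  ll <- matrix(NA_real_, n, length(cts$pops),
               dimnames = list(NULL, cts$pops))
  for (k in seq_along(cts$pops)) {
    # plain likelihood via 3 indicator matrix products
    lp <- rbind(genotypeLogLik(rep(0L, ncol(G)), cts$alt[k, ], cts$tot[k, ],
                               tau),
                genotypeLogLik(rep(1L, ncol(G)), cts$alt[k, ], cts$tot[k, ],
                               tau),
                genotypeLogLik(rep(2L, ncol(G)), cts$alt[k, ], cts$tot[k, ],
                               tau))
    acc <- numeric(n)
    for (g in 0:2) {
      ind <- (!is.na(G)) & G == g
      acc <- acc + as.vector(ind %*% lp[g + 1L, ])
    }
    ll[, k] <- acc
  }
  # leave-one-out correction for each individual's own population
  pops <- cts$pops
  for (i in seq_len(n)) {
    k <- match(as.character(populations(gm)[i]), pops)
    gi <- G[i, ]
    obs <- !is.na(gi)
    if (sum(populations(gm) == pops[k]) < 1) next
    ll[i, k] <- sum(genotypeLogLik(gi[obs],
                                   cts$alt[k, obs] - gi[obs],
                                   cts$tot[k, obs] - 2, tau))
  }
  ll
}

#' Detect first-generation migrants by assignment likelihood
#'
#' For every individual, computes the log10-likelihood of its multilocus
#' genotype in every reference population (its own population leave-one-out)
#' and the statistic Lambda = log10(L_max) - log10(L_home), which is 0 iff
#' the home population is the maximum-likelihood origin. Significance is
#' calibrated by Monte-Carlo resampling: \code{nSim} individuals per
#' population are simulated by drawing alleles independently per locus from
#' the estimated population frequencies, and the p-value is the (add-one
#' corrected) fraction of simulated home-population individuals with Lambda
#' at least as large as observed. Individuals with p below \code{alpha} are
#' flagged as first-generation migrants and assigned to the population with
#' the highest likelihood.
#'
#' @param gm a \code{\link{GenotypeMatrix-class}} with >= 2 populations.
#' @param alpha type-I error threshold (default 0.01).
#' @param nSim simulated individuals per population (default 10000,
#'   minimum 100).
#' @param seed integer seed for the null simulation.
#' @param tau Dirichlet prior concentration per allele (default 0.5).
#' @return data.frame with one row per individual: \code{home},
#'   \code{bestPop}, \code{lambda}, \code{pValue}, \code{migrant}; the full
#'   log-likelihood matrix is attached as attribute \code{"logLik"}.
#' @export
detectMigrants <- function(gm, alpha = 0.01, nSim = 10000L, seed = 1L,
                           tau = 0.5) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (nlevels(populations(gm)) < 2) stop("need at least 2 populations")
  if (nSim < 100) stop("nSim must be at least 100")
  set.seed(as.integer(seed))
  ll <- .assignmentLogLik(gm, tau)
  pops <- colnames(ll)
  homeIdx <- match(as.character(populations(gm)), pops)
  llHome <- ll[cbind(seq_len(nrow(ll)), homeIdx)]
  llMax <- apply(ll, 1, max)
  lambda <- llMax - llHome
  bestPop <- pops[max.col(ll, ties.method = "first")]

  cts <- .alleleCounts(gm)
  G <- genotypes(gm)
  L <- ncol(G)
  pval <- rep(NA_real_, nrow(G))
  for (k in seq_along(pops)) {
    f <- ifelse(cts$tot[k, ] > 0, cts$alt[k, ] / pmax(cts$tot[k, ], 1), 0)
    # Exchangeable null: the observed statistic pairs an individual's
    # genotype with the leave-one-out counts of its home sample, so each
    # simulated individual gets both a genotype and an independent
    # pseudo-reference of the same leave-one-out size drawn from the
    # estimated frequencies. Evaluating simulated genotypes against the
    # fixed observed counts instead is badly anticonservative when the
    # locus count is large relative to the sample size.
    nRefGenes <- pmax(cts$tot[k, ] - 2L, 0L)
    Gsim <- matrix(rbinom(nSim * L, 2, rep(f, each = nSim)), nSim, L)
    refAlt <- matrix(rbinom(nSim * L, rep(nRefGenes, each = nSim),
                            rep(f, each = nSim)), nSim, L)
    refTot <- matrix(rep(nRefGenes, each = nSim), nSim, L)
    llHomeSim <- rowSums(matrix(genotypeLogLik(as.vector(Gsim),
                                               as.vector(refAlt),
                                               as.vector(refTot), tau),
                                nSim, L))
    llSim <- matrix(NA_real_, nSim, length(pops))
    llSim[, k] <- llHomeSim
    for (j in seq_along(pops)[-k]) {
      lp <- rbind(
        genotypeLogLik(rep(0L, L), cts$alt[j, ], cts$tot[j, ], tau),
        genotypeLogLik(rep(1L, L), cts$alt[j, ], cts$tot[j, ], tau),
        genotypeLogLik(rep(2L, L), cts$alt[j, ], cts$tot[j, ], tau))
      acc <- numeric(nSim)
      for (g in 0:2) acc <- acc + as.vector((Gsim == g) %*% lp[g + 1L, ])
      llSim[, j] <- acc
    }
    lamSim <- apply(llSim, 1, max) - llSim[, k]
    mine <- which(homeIdx == k)
    if (length(mine))
      pval[mine] <- (1 + vapply(lambda[mine],
                                function(x) sum(lamSim >= x),
                                numeric(1))) / (nSim + 1)
  }
  res <- data.frame(individual = seq_len(nrow(G)),
                    home = as.character(populations(gm)),
                    bestPop = bestPop, lambda = lambda, pValue = pval,
                    migrant = pval < alpha,
                    stringsAsFactors = FALSE)
  attr(res, "logLik") <- ll
  res
}

#' Random subset of loci
#'
#' Uniform sample of \code{k} loci without replacement, seeded.
#'
#' @param gm a \code{\link{GenotypeMatrix-class}}.
#' @param k number of loci to keep.
#' @param seed integer seed.
#' @return a \code{GenotypeMatrix} restricted to the sampled loci.
#' @export
subsetLoci <- function(gm, k, seed = 1L) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (k > ncol(genotypes(gm))) stop("k exceeds the number of loci")
  set.seed(as.integer(seed))
  keep <- sort(sample.int(ncol(genotypes(gm)), k))
  new("GenotypeMatrix", geno = genotypes(gm)[, keep, drop = FALSE],
      pop = populations(gm), loci = gm@loci[keep], truth = gm@truth)
}
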