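#' Specification of a synthetic structured-genotype dataset
#'
#' Populations drift apart from a common ancestral allele-frequency pool
#' under the Balding-Nichols model: at each locus the ancestral frequency p
#' is drawn from a (rescaled) Beta distribution and each population's
#' frequency from Beta(p (1-F)/F, (1-p)(1-F)/F), so the expected
#' differentiation equals the target F. Planted first-generation migrants
#' are drawn from their true source population's frequencies but labelled
#' with the sink population.
#'
#' @param sampleSizes named integer vector, individuals per population
#'   (names are the population labels).
#' @param nLoci number of biallelic loci.
#' @param fst target differentiation in [0, 1).
#' @param ancestralBeta length-2 shape parameters of the ancestral
#'   frequency Beta (default c(1, 1), i.e. uniform).
#' @param ancestralRange frequencies are rescaled into this interval to
#'   avoid near-monomorphic loci (default c(0.05, 0.95)).
#' @param migrants data.frame with columns \code{pop} (labelled sink),
#'   \code{index} (individual index within the sink sample) and
#'   \code{source} (true origin population).
#' @param missingRate per-call missing-data probability.
#' @param seed integer seed.
#' @return a validated spec (list of class \code{"genotypeSimSpec"}).
#' @export
genotypeSimSpec <- function(sampleSizes, nLoci, fst = 0.1,
                            ancestralBeta = c(1, 1),
                            ancestralRange = c(0.05, 0.95),
                            migrants = NULL, missingRate = 0,
                            seed = 1L) {
  stopifnot(all(sampleSizes >= 1), !is.null(names(sampleSizes)),
            fst >= 0, fst < 1, nLoci >= 1,
            missingRate >= 0, missingRate < 1)
  if (!is.null(migrants)) {
    stopifnot(all(c("pop", "index", "source") %in% names(migrants)),
              all(migrants$pop %in% names(sampleSizes)),
              all(migrants$source %in% names(sampleSizes)),
              all(migrants$index >= 1),
              all(migrants$index <= sampleSizes[migrants$pop]))
  }
  structure(list(sampleSizes = sampleSizes, nLoci = as.integer(nLoci),
                 fst = fst, ancestralBeta = ancestralBeta,
                 ancestralRange = ancestralRange, migrants = migrants,
                 missingRate = missingRate, seed = as.integer(seed)),
            class = "genotypeSimSpec")
}

#' Generate genotypes under the Balding-Nichols model
#'
#' @param spec a \code{\link{genotypeSimSpec}}.
#' @return a \code{\link{GenotypeMatrix-class}}; planted migrants are
#'   recorded in its \code{truth} slot.
#' @export
makeGenotypes <- function(spec) {
  stopifnot(inherits(spec, "genotypeSimSpec"))
  set.seed(spec$seed)
  pops <- names(spec$sampleSizes)
  L <- spec$nLoci
  pAnc <- spec$ancestralRange[1] + diff(spec$ancestralRange) *
    rbeta(L, spec$ancestralBeta[1], spec$ancestralBeta[2])
  freq <- matrix(NA_real_, length(pops), L, dimnames = list(pops, NULL))
  for (k in seq_along(pops)) {
    if (spec$fst == 0) {
      freq[k, ] <- pAnc
    } else {
      a <- pAnc * (1 - spec$fst) / spec$fst
      b <- (1 - pAnc) * (1 - spec$fst) / spec$fst
      freq[k, ] <- rbeta(L, a, b)
    }
  }
  n <- sum(spec$sampleSizes)
  geno <- matrix(NA_integer_, n, L)
  pop <- factor(rep(pops, spec$sampleSizes), levels = pops)
  for (k in seq_along(pops)) {
    rows <- which(pop == pops[k])
    geno[rows, ] <- matrix(rbinom(length(rows) * L, 2,
                                  rep(freq[k, ], each = length(rows))),
                           length(rows), L)
  }
  truth <- data.frame(individual = integer(), trueSource = character(),
                      stringsAsFactors = FALSE)
  if (!is.null(spec$migrants)) {
    offset <- c(0, cumsum(spec$sampleSizes))[seq_along(pops)]
    names(offset) <- pops
    for (r in seq_len(nrow(spec$migrants))) {
      i <- offset[spec$migrants$pop[r]] + spec$migrants$index[r]
      src <- spec$migrants$source[r]
      geno[i, ] <- rbinom(L, 2, freq[src, ])
      truth <- rbind(truth, data.frame(individual = as.integer(i),
                                       trueSource = src,
                                       stringsAsFactors = FALSE))
    }
  }
  if (spec$missingRate > 0) {
    drop <- matrix(runif(n * L) < spec$missingRate, n, L)
    # never blank out a whole locus
    keepOne <- sapply(seq_len(L), function(l) which(!drop[, l])[1])
    drop[cbind(pmax(keepOne, 1, na.rm = TRUE), seq_len(L))] <- FALSE
    geno[drop] <- NA_integer_
  }
  new("GenotypeMatrix", geno = geno, pop = pop,
      loci = sprintf("L%04d", seq_len(L)), truth = truth)
}
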