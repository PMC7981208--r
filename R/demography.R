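#' Expected folded joint SFS under a divergence scenario
#'
#' Monte-Carlo coalescent expectation: averages, over \code{nReps}
#' simulated genealogies, the branch time subtending each (i, j)
#' derived-allele configuration; under the infinite-sites assumption the
#' expected spectrum is proportional to these times. The result is folded
#' and normalized to sum to 1 over unmasked entries.
#'
#' @param scenario one of the six divergence scenarios.
#' @param params named parameter vector (see \code{\link{scenarioParams}}).
#' @param n1,n2 haploid sample sizes.
#' @param nReps number of genealogy replicates (default 3000).
#' @param seed optional integer seed (set for reproducible expectations;
#'   the fitter uses a fixed seed per fit so the likelihood surface is
#'   deterministic).
#' @return a \code{\link{FoldedJSFS-class}} of relative expected
#'   proportions; \code{meta$nReps} records the replicate count.
#' @export
expectedJSFS <- function(scenario, params, n1, n2, nReps = 3000,
                         seed = NULL) {
  ep <- .scenarioEpochs(scenario, params)
  if (!is.null(seed)) set.seed(as.integer(seed))
  u <- .coal_branch_lengths(as.integer(n1), as.integer(n2), ep, 1.0,
                            as.integer(nReps))
  fd <- foldJSFS(u)
  tot <- sum(fd$entries[!fd$mask])
  new("FoldedJSFS", entries = fd$entries / tot, mask = fd$mask,
      n1 = as.integer(n1), n2 = as.integer(n2),
      meta = list(scenario = scenario, params = params, nReps = nReps))
}

#' Composite Poisson log-likelihood of an observed spectrum
#'
#' Treats unmasked entries as independent Poisson counts with mean
#' \code{theta * expected}, the multiplicative scaling \code{theta} profiled
#' out analytically (\code{theta = sum(obs) / sum(expected)}). Zero expected
#' cells (Monte-Carlo sampling artifacts) are floored at
#' \code{1 / (10 * nReps * sites)} before taking logs.
#'
#' @param obs observed \code{\link{FoldedJSFS-class}} of site counts.
#' @param expected relative expectation from \code{\link{expectedJSFS}}.
#' @param floor optional explicit floor for zero expected cells.
#' @return list with \code{logL} and the profiled \code{theta}.
#' @export
compositeLogLik <- function(obs, expected, floor = NULL) {
  stopifnot(is(obs, "FoldedJSFS"), is(expected, "FoldedJSFS"))
  if (!identical(dim(obs@entries), dim(expected@entries)))
    stop("observed and expected spectra have different shapes")
  un <- !(obs@mask | expected@mask)
  if (!any(un)) stop("all cells are masked")
  x <- obs@entries[un]
  e <- expected@entries[un]
  if (is.null(floor)) {
    nReps <- if (!is.null(expected@meta$nReps)) expected@meta$nReps else 1e4
    floor <- 1 / (10 * nReps * max(sum(x), 1))
  }
  e[e <= 0] <- floor
  theta <- sum(x) / sum(e)
  lambda <- theta * e
  list(logL = sum(dpois(x, lambda, log = TRUE)), theta = theta)
}

# optimization bounds (natural scale) per parameter
.paramBounds <- function(names) {
  lo <- c(N1 = 0.05, N2 = 0.05, Ts = 0.01, Tam = 0.01, Tsc = 0.01,
          m12 = 1e-3, m21 = 1e-3, mA = 1e-3, mB = 1e-3, mC = 1e-3,
          mD = 1e-3)
  hi <- c(N1 = 10, N2 = 10, Ts = 10, Tam = 10, Tsc = 10,
          m12 = 40, m21 = 40, mA = 40, mB = 40, mC = 40, mD = 40)
  list(lo = lo[names], hi = hi[names])
}

#' Fit one divergence scenario to an observed folded joint SFS
#'
#' Multi-start bounded optimization of the composite Poisson likelihood,
#' staged by precision: replicate Nelder-Mead searches in log-parameter
#' space (out of bounds penalized) from perturbed starts, iterated
#' refinement of the top candidates on a lower-noise surface, and a final
#' polish plus likelihood evaluation at high replicate count. One fixed
#' seed per stage drives the Monte-Carlo expectation (common random
#' numbers), making every surface deterministic; the final-stage seed is
#' shared across scenarios so AICs are comparable.
#'
#' @param obs observed \code{\link{FoldedJSFS-class}}.
#' @param scenario scenario identifier.
#' @param nReplicates optimizer restarts (default 20).
#' @param seed integer seed (drives starts and the Monte-Carlo surface).
#' @param nReps genealogies per likelihood evaluation in the multi-start
#'   search stage (default 6000; the composite likelihood is noticeably
#'   biased and noisy below a few thousand genealogies).
#' @param maxit Nelder-Mead iteration cap per search replicate
#'   (default 400).
#' @param startValues optional named vector of start values; defaults to 1
#'   for sizes, 0.5 for times and 1 for migration rates. Each restart
#'   perturbs every coordinate by an independent factor in [1/4, 4]
#'   (log-uniform); the first restart uses the unperturbed values.
#' @param nRefine number of top search candidates to polish (default 3).
#' @param refineReps genealogies per evaluation in the refinement stage
#'   (default \code{3 * nReps}).
#' @param refineRounds successive Nelder-Mead rounds per candidate in the
#'   refinement stage; each round restarts the simplex at the previous
#'   endpoint, which re-expands it and escapes premature contraction
#'   (default 2).
#' @param refineMaxit iteration cap per refinement round (default 300).
#' @param finalReps genealogies per evaluation in the last polish round
#'   and for the reported likelihood (default \code{20 * nReps}), shared
#'   seed across scenarios so AICs are comparable.
#' @param polishMaxit iteration cap of the last Nelder-Mead polish, run on
#'   the \code{finalReps} surface from the winning candidate (default
#'   150).
#' @return a \code{\link{DivergenceFit-class}}.
#' @export
fitModel <- function(obs, scenario, nReplicates = 20, seed = 1L,
                     nReps = 6000, maxit = 400, startValues = NULL,
                     nRefine = 3, refineReps = 3 * nReps, refineRounds = 2,
                     refineMaxit = 300, finalReps = 20 * nReps,
                     polishMaxit = 150) {
  stopifnot(is(obs, "FoldedJSFS"), nReplicates >= 1)
  scenario <- match.arg(scenario, c("SI", "IM", "AM", "SC", "PAM", "PSC"))
  pn <- scenarioParams(scenario)
  b <- .paramBounds(pn)
  seed <- as.integer(seed)
  surfSeed <- seed %% 100000L + 7919L

  makeObjective <- function(reps) function(logPar) {
    par <- exp(logPar)
    names(par) <- pn
    pen <- sum(pmax(logPar - log(b$hi), 0)^2) +
      sum(pmax(log(b$lo) - logPar, 0)^2)
    par <- pmin(pmax(par, b$lo), b$hi)
    ex <- expectedJSFS(scenario, par, obs@n1, obs@n2, reps,
                       seed = surfSeed)
    -compositeLogLik(obs, ex)$logL + 1e4 * pen
  }
  objSearch <- makeObjective(nReps)

  if (is.null(startValues)) {
    startValues <- setNames(rep(1, length(pn)), pn)
    startValues[grep("^T", pn)] <- 0.5
  }
  set.seed(seed)
  starts <- matrix(rep(log(startValues[pn]), each = nReplicates),
                   nReplicates, length(pn))
  if (nReplicates > 1)
    starts[-1, ] <- starts[-1, , drop = FALSE] +
      matrix(runif((nReplicates - 1) * length(pn), -log(4), log(4)),
             nReplicates - 1, length(pn))

  reps <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    fit <- tryCatch(
      optim(starts[r, ], objSearch, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = 1e-7)),
      error = function(e) NULL)
    if (!is.null(fit))
      reps[[r]] <- data.frame(replicate = r, value = -fit$value,
                              convergence = fit$convergence,
                              t(setNames(exp(fit$par), pn)))
  }
  reps <- do.call(rbind, reps)
  if (is.null(reps)) stop("optimizer failed in all replicates")
  ord <- order(-reps$value)

  # polish the top candidates on a lower-noise surface, then pick the best
  # at a common high-precision evaluation
  objRefine <- makeObjective(refineReps)
  cand <- list()
  for (r in head(ord, max(1L, nRefine))) {
    lp <- log(pmin(pmax(unlist(reps[r, pn]), b$lo), b$hi))
    for (round in seq_len(refineRounds)) {
      ref <- tryCatch(
        optim(lp, objRefine, method = "Nelder-Mead",
              control = list(maxit = refineMaxit, reltol = 1e-8)),
        error = function(e) NULL)
      if (is.null(ref)) break
      lp <- ref$par
    }
    cand <- c(cand, list(pmin(pmax(exp(lp), b$lo), b$hi)))
  }
  finals <- vapply(cand, function(p) {
    names(p) <- pn
    ex <- expectedJSFS(scenario, p, obs@n1, obs@n2, finalReps,
                       seed = surfSeed + 1L)
    compositeLogLik(obs, ex)$logL
  }, numeric(1))
  par <- cand[[which.max(finals)]]
  names(par) <- pn

  # last polish on the same surface the reported likelihood uses
  if (polishMaxit > 0) {
    objFinal <- function(logPar) {
      par <- exp(logPar)
      names(par) <- pn
      pen <- sum(pmax(logPar - log(b$hi), 0)^2) +
        sum(pmax(log(b$lo) - logPar, 0)^2)
      par <- pmin(pmax(par, b$lo), b$hi)
      ex <- expectedJSFS(scenario, par, obs@n1, obs@n2, finalReps,
                         seed = surfSeed + 1L)
      -compositeLogLik(obs, ex)$logL + 1e4 * pen
    }
    pol <- tryCatch(
      optim(log(par), objFinal, method = "Nelder-Mead",
            control = list(maxit = polishMaxit, reltol = 1e-9)),
      error = function(e) NULL)
    if (!is.null(pol)) {
      par <- pmin(pmax(exp(pol$par), b$lo), b$hi)
      names(par) <- pn
    }
  }

  ex <- expectedJSFS(scenario, par, obs@n1, obs@n2, finalReps,
                     seed = surfSeed + 1L)
  cl <- compositeLogLik(obs, ex)
  K <- length(pn)
  new("DivergenceFit", scenario = scenario, params = par,
      logL = cl$logL, K = as.integer(K), aic = aic(cl$logL, K),
      theta = cl$theta, replicates = reps)
}

#' Fit and compare several divergence scenarios
#'
#' Fits each scenario with \code{\link{fitModel}} (same seed, so the
#' Monte-Carlo surfaces are comparable) and assembles the model-selection
#' table: K, logL, AIC, relative score and Akaike weight.
#'
#' @param obs observed \code{\link{FoldedJSFS-class}}.
#' @param scenarios character vector of scenarios to fit.
#' @param ... passed to \code{\link{fitModel}}.
#' @return list with \code{fits} (named list of \code{DivergenceFit}) and
#'   \code{table} (data.frame sorted by AIC).
#' @export
fitScenarios <- function(obs, scenarios = c("SI", "IM", "SC"), ...) {
  fits <- lapply(scenarios, function(s) fitModel(obs, s, ...))
  names(fits) <- scenarios
  aics <- vapply(fits, function(f) f@aic, numeric(1))
  tab <- data.frame(
    scenario = scenarios,
    K = vapply(fits, function(f) f@K, integer(1)),
    logL = vapply(fits, function(f) f@logL, numeric(1)),
    AIC = aics,
    score = if (length(aics) > 1 && diff(range(aics)) > 0)
      modelScores(aics) else rep(NA_real_, length(aics)),
    wAIC = akaikeWeights(aics),
    row.names = NULL)
  list(fits = fits, table = tab[order(tab$AIC), ])
}

#' Akaike information criterion
#'
#' @param logL maximized log-likelihood.
#' @param K number of free parameters (>= 1).
#' @return \code{2K - 2 logL}, vectorized.
#' @export
aic <- function(logL, K) {
  if (any(K < 1)) stop("K must be >= 1")
  2 * K - 2 * logL
}

#' Relative AIC scores across a model set
#'
#' \code{(Dmax - DAIC_i) / Dmax} with \code{DAIC_i = AIC_i - min(AIC)} and
#' \code{Dmax = max(AIC) - min(AIC)}: the best model scores 1, the worst 0.
#'
#' @param aics vector of AIC values (>= 2 models, not all equal).
#' @return scores in [0, 1].
#' @examples
#' modelScores(c(4448, 4780, 5796))   # best 1, worst 0
#' @export
modelScores <- function(aics) {
  if (length(aics) < 2) stop("need at least two models")
  dmax <- max(aics) - min(aics)
  if (dmax == 0) stop("all AICs equal; scores undefined")
  (dmax - (aics - min(aics))) / dmax
}

#' Akaike weights
#'
#' \code{w_i = exp(-DAIC_i / 2) / sum_j exp(-DAIC_j / 2)}, computed after
#' subtracting the minimum AIC for overflow safety.
#'
#' @param aics vector of AIC values.
#' @return weights summing to 1.
#' @examples
#' akaikeWeights(c(0, 2))   # ~0.73, ~0.27
#' @export
akaikeWeights <- function(aics) {
  d <- aics - min(aics)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Inputs for converting diffusion-scale estimates to biological units
#'
#' @param mu mutation rate per site per generation (default 2.3e-9).
#' @param x number of SNPs originally detected.
#' @param y number of RAD tags (each \code{tagLength} bp) in the initial
#'   data set.
#' @param z number of SNPs retained for the analysis.
#' @param generationTime generation time in years (default 10).
#' @param tagLength RAD tag length in bp (default 73).
#' @return list of class \code{"conversionInputs"}.
#' @export
conversionInputs <- function(mu = 2.3e-9, x, y, z, generationTime = 10,
                             tagLength = 73) {
  stopifnot(mu > 0, x > 0, y > 0, z > 0, generationTime > 0, tagLength > 0)
  structure(list(mu = mu, x = x, y = y, z = z,
                 generationTime = generationTime, tagLength = tagLength),
            class = "conversionInputs")
}

#' Convert a scenario fit to biological units
#'
#' The effective genome length is \code{L = z * y * tagLength / x}; the
#' ancestral effective size is \code{Nref = theta / (4 L mu)}; times (in
#' units of 2*Nref generations) convert to years by multiplying with
#' \code{2 * Nref * generationTime}; migration rates (in units of 2*Nref)
#' divide by \code{2 * Nref} to give the proportion of migrants per
#' generation.
#'
#' @param fit a \code{\link{DivergenceFit-class}}, or a list with elements
#'   \code{theta} and \code{params}.
#' @param inputs a \code{\link{conversionInputs}}.
#' @return list with \code{L}, \code{Nref}, \code{timesYears} (named, one
#'   per time parameter) and \code{migrantProportions} (named, one per
#'   migration parameter).
#' @export
convertUnits <- function(fit, inputs) {
  stopifnot(inherits(inputs, "conversionInputs"))
  theta <- if (is(fit, "DivergenceFit")) fit@theta else fit$theta
  params <- if (is(fit, "DivergenceFit")) fit@params else fit$params
  L <- inputs$z * inputs$y * inputs$tagLength / inputs$x
  if (L <= 0) stop("effective length must be positive")
  Nref <- theta / (4 * L * inputs$mu)
  tm <- params[grep("^T", names(params))]
  mg <- params[grep("^m", names(params))]
  list(L = L, Nref = Nref,
       timesYears = tm * 2 * Nref * inputs$generationTime,
       migrantProportions = mg / (2 * Nref))
}
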