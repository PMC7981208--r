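#' Divergence scenarios and their parameters
#'
#' Six two-population divergence histories, parameterized on the diffusion
#' scale (sizes N1, N2 relative to the ancestral reference size; times in
#' units of 2*Nref generations; migration rates in units of 2*Nref):
#' \describe{
#'   \item{SI}{strict isolation: split, no gene flow. Parameters N1, N2,
#'     Ts. K = 3.}
#'   \item{IM}{isolation-with-migration: continuous asymmetric gene flow
#'     (m12, m21) since the split. Parameters N1, N2, Ts, m12, m21. K = 5.}
#'   \item{AM}{ancient migration: gene flow for Tam right after the split,
#'     then isolation for Ts until the present. Parameters N1, N2, Ts, Tam,
#'     m12, m21. K = 6.}
#'   \item{SC}{secondary contact: isolation for Ts after the split, then
#'     gene flow for Tsc until the present. Parameters N1, N2, Ts, Tsc,
#'     m12, m21. K = 6.}
#'   \item{PAM}{two ancient-migration episodes (each Tam/2, sharing one
#'     m12/m21 pair), then isolation for Ts. Parameters as AM. K = 6.}
#'   \item{PSC}{two secondary-contact episodes after isolation Ts: first
#'     (mA, mB) then (mC, mD), each lasting Tsc/2. Parameters N1, N2, Ts,
#'     Tsc, mA, mB, mC, mD. K = 8.}
#' }
#' m12 is the rate at which population 1 receives genes from population 2
#' (backward in time, a lineage in 1 jumps to 2 at that rate).
#'
#' @param scenario one of \code{"SI"}, \code{"IM"}, \code{"AM"},
#'   \code{"SC"}, \code{"PAM"}, \code{"PSC"}.
#' @return character vector of parameter names for the scenario.
#' @export
scenarioParams <- function(scenario) {
  switch(match.arg(scenario, c("SI", "IM", "AM", "SC", "PAM", "PSC")),
    SI  = c("N1", "N2", "Ts"),
    IM  = c("N1", "N2", "Ts", "m12", "m21"),
    AM  = c("N1", "N2", "Ts", "Tam", "m12", "m21"),
    SC  = c("N1", "N2", "Ts", "Tsc", "m12", "m21"),
    PAM = c("N1", "N2", "Ts", "Tam", "m12", "m21"),
    PSC = c("N1", "N2", "Ts", "Tsc", "mA", "mB", "mC", "mD"))
}

# epoch table for the structured coalescent, rows from the present
# backwards: (t_end, N1, N2, m12, m21); the last t_end is the divergence
# time, older than which a single ancestral deme of size 1 (= Nref) remains
.scenarioEpochs <- function(scenario, par) {
  need <- scenarioParams(scenario)
  par <- unlist(par)
  if (!all(need %in% names(par)))
    stop(scenario, " needs parameters: ", paste(need, collapse = ", "))
  par <- par[need]
  if (any(par[c("N1", "N2")] <= 0)) stop("population sizes must be > 0")
  tm <- par[grep("^T", names(par))]
  if (any(tm < 0)) stop("times must be >= 0")
  mg <- par[grep("^m", names(par))]
  if (length(mg) && any(mg < 0)) stop("migration rates must be >= 0")
  e <- function(tEnd, m12, m21)
    c(tEnd, par[["N1"]], par[["N2"]], m12, m21)
  rows <- switch(scenario,
    SI  = list(e(par[["Ts"]], 0, 0)),
    IM  = list(e(par[["Ts"]], par[["m12"]], par[["m21"]])),
    AM  = list(e(par[["Ts"]], 0, 0),
               e(par[["Ts"]] + par[["Tam"]], par[["m12"]], par[["m21"]])),
    SC  = list(e(par[["Tsc"]], par[["m12"]], par[["m21"]]),
               e(par[["Tsc"]] + par[["Ts"]], 0, 0)),
    PAM = list(e(par[["Ts"]], 0, 0),
               e(par[["Ts"]] + par[["Tam"]] / 2, par[["m12"]],
                 par[["m21"]]),
               e(par[["Ts"]] + par[["Tam"]], par[["m12"]], par[["m21"]])),
    PSC = list(e(par[["Tsc"]] / 2, par[["mC"]], par[["mD"]]),
               e(par[["Tsc"]], par[["mA"]], par[["mB"]]),
               e(par[["Tsc"]] + par[["Ts"]], 0, 0)))
  m <- do.call(rbind, rows)
  colnames(m) <- c("tEnd", "N1", "N2", "m12", "m21")
  # drop zero-length epochs (e.g. Tsc = 0 collapses SC onto SI)
  keep <- c(m[1, "tEnd"] > 0, diff(m[, "tEnd"]) > 0)
  keep[length(keep)] <- TRUE
  m[keep, , drop = FALSE]
}

#' Fold an unfolded joint spectrum
#'
#' Pools each cell (i, j) with its mirror (n1-i, n2-j): the pooled mass is
#' kept in the member of the pair with the smaller total count (ties broken
#' toward the smaller first index), the mirror is masked, self-mirroring
#' cells are kept as they are, and the two monomorphic corners are masked.
#'
#' @param u unfolded (n1+1) x (n2+1) matrix indexed by derived-allele
#'   counts.
#' @return list with folded \code{entries} and logical \code{mask}.
#' @export
foldJSFS <- function(u) {
  n1 <- nrow(u) - 1L; n2 <- ncol(u) - 1L
  i <- row(u) - 1L; j <- col(u) - 1L
  mi <- n1 - i; mj <- n2 - j
  self <- i == mi & j == mj
  keep <- (i + j < mi + mj) | (i + j == mi + mj & i < mi)
  um <- matrix(u[cbind(as.vector(mi) + 1L, as.vector(mj) + 1L)],
               n1 + 1L, n2 + 1L)
  f <- matrix(0, n1 + 1L, n2 + 1L)
  f[self] <- u[self]
  f[keep] <- u[keep] + um[keep]
  mask <- !(keep | self)
  mask[1L, 1L] <- TRUE
  mask[n1 + 1L, n2 + 1L] <- TRUE
  f[mask] <- 0
  list(entries = f, mask = mask)
}

#' Specification of a synthetic joint-SFS dataset
#'
#' @param scenario one of the six divergence scenarios (see
#'   \code{\link{scenarioParams}}).
#' @param params named numeric vector of true scenario parameters.
#' @param n1,n2 haploid sample sizes of the two populations.
#' @param nLoci number of unlinked segregating loci (one SNP each).
#' @param seed integer seed.
#' @return a validated spec (list of class \code{"scenarioSimSpec"}).
#' @export
scenarioSimSpec <- function(scenario, params, n1, n2, nLoci, seed = 1L) {
  scenario <- match.arg(scenario, c("SI", "IM", "AM", "SC", "PAM", "PSC"))
  .scenarioEpochs(scenario, params) # validates
  stopifnot(n1 >= 2, n2 >= 2, nLoci >= 1)
  structure(list(scenario = scenario, params = params,
                 n1 = as.integer(n1), n2 = as.integer(n2),
                 nLoci = as.integer(nLoci), seed = as.integer(seed)),
            class = "scenarioSimSpec")
}

#' Simulate a folded joint SFS under a divergence scenario
#'
#' Neutral coalescent Monte Carlo with unlinked loci: each locus draws an
#' independent genealogy under the scenario's piecewise history and
#' contributes exactly one segregating site, placed on a branch with
#' probability proportional to its length. The folded spectrum's unmasked
#' entries therefore sum to \code{nLoci}; the monomorphic corners are
#' structurally empty and masked.
#'
#' @param spec a \code{\link{scenarioSimSpec}}.
#' @return a \code{\link{FoldedJSFS-class}} of site counts.
#' @export
simulateJSFS <- function(spec) {
  stopifnot(inherits(spec, "scenarioSimSpec"))
  ep <- .scenarioEpochs(spec$scenario, spec$params)
  set.seed(spec$seed)
  u <- .coal_sample_jsfs(spec$n1, spec$n2, ep, 1.0, spec$nLoci)
  fd <- foldJSFS(u)
  new("FoldedJSFS", entries = fd$entries, mask = fd$mask,
      n1 = spec$n1, n2 = spec$n2,
      meta = list(scenario = spec$scenario, params = spec$params,
                  seed = spec$seed))
}
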