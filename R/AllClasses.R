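#' Gridded ocean velocity field
#'
#' Time-stamped horizontal velocities on a regular lon/lat grid with a land
#' mask and bathymetry. Velocities are in m/s; bathymetry is positive depth
#' in metres; masked (land) cells carry zero velocity.
#'
#' @slot lon,lat strictly increasing node coordinates (degrees E / N).
#' @slot time strictly increasing time stamps (days). A single stamp denotes
#'   a steady field.
#' @slot u,v numeric arrays of dimension \code{c(nlon, nlat, ntime)} (m/s).
#' @slot mask logical \code{nlon x nlat} matrix, \code{TRUE} on land.
#' @slot bathy numeric \code{nlon x nlat} matrix of water depth (m).
#' @export
setClass("FlowField",
  representation(lon = "numeric", lat = "numeric", time = "numeric",
                 u = "array", v = "array", mask = "matrix",
                 bathy = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@lon) < 2 || length(object@lat) < 2)
      msg <- c(msg, "degenerate grid: need at least 2 nodes per axis")
    if (any(diff(object@lon) <= 0) || any(diff(object@lat) <= 0))
      msg <- c(msg, "lon/lat nodes must be strictly increasing")
    if (length(object@time) > 1 && any(diff(object@time) <= 0))
      msg <- c(msg, "time stamps must be strictly increasing")
    dims <- c(length(object@lon), length(object@lat), length(object@time))
    if (!identical(dim(object@u), dims) || !identical(dim(object@v), dims))
      msg <- c(msg, "u and v must have dim c(nlon, nlat, ntime)")
    if (!identical(dim(object@mask), dims[1:2]))
      msg <- c(msg, "mask must be nlon x nlat")
    if (all(object@mask))
      msg <- c(msg, "at least one ocean cell must remain unmasked")
    ocean <- !object@mask
    if (any(!is.finite(object@u[ocean])) || any(!is.finite(object@v[ocean])))
      msg <- c(msg, "u and v must be finite on ocean cells")
    if (any(abs(object@u[object@mask]) > 0) ||
        any(abs(object@v[object@mask]) > 0))
      msg <- c(msg, "masked cells must carry zero velocity")
    if (length(msg)) msg else TRUE
  })

#' Analytic flow for testing the Lagrangian stepper
#'
#' Wraps a function \code{f(lon, lat, time)} returning \code{list(u, v)} in
#' m/s so closed-form velocity fields can drive the particle model directly,
#' without grid-interpolation error.
#'
#' @slot fun the velocity function.
#' @export
setClass("FlowFunction", representation(fun = "function"))

#' Ensemble of Lagrangian particles
#'
#' One row per particle: source site, spawning year, release day (model
#' days), current position and depth, age (days), state (\code{"active"},
#' \code{"recruited"}, \code{"expired"}) and, when recruited, the zone and
#' day of recruitment. \code{stepLog} holds per-step conservation tallies
#' after a simulation; \code{visits} optionally holds a cells x particles
#' visited-cell indicator for pathway maps, with the grid stored in
#' \code{visitGrid}.
#'
#' @slot particles the per-particle data.frame.
#' @slot stepLog data.frame of per-step counts (released, active, recruited,
#'   expired).
#' @slot visits \code{NULL} or a logical matrix (ncell x nparticles).
#' @slot visitGrid list with \code{lon}, \code{lat} node vectors of the grid
#'   used for visit logging.
#' @export
setClass("ParticleEnsemble",
  representation(particles = "data.frame", stepLog = "data.frame",
                 visits = "ANY", visitGrid = "list"),
  prototype(stepLog = data.frame(), visits = NULL, visitGrid = list()),
  validity = function(object) {
    need <- c("id", "source", "year", "releaseDay", "lon", "lat", "depth",
              "age", "state", "recruitSite", "recruitDay")
    if (!all(need %in% names(object@particles)))
      return(paste("particles must have columns:",
                   paste(need, collapse = ", ")))
    st <- object@particles$state
    if (!all(st %in% c("active", "recruited", "expired")))
      return("state must be active/recruited/expired")
    TRUE
  })

#' Annual connectivity matrix
#'
#' Destination sites (rows) x source sites (columns); entries are the
#' percentage of particles released at the source during one spawning year
#' that recruited to the destination. A column for a site with zero releases
#' is \code{NA} (undefined), never silently zero.
#'
#' @slot year the spawning-year label.
#' @slot entries the percentage matrix.
#' @slot released named vector of particles released per source.
#' @export
setClass("ConnectivityMatrix",
  representation(year = "numeric", entries = "matrix",
                 released = "numeric"),
  validity = function(object) {
    e <- object@entries[!is.na(object@entries)]
    if (any(e < 0 | e > 100)) return("entries must lie in [0, 100]")
    cs <- colSums(object@entries)
    if (any(cs[!is.na(cs)] > 100 + 1e-9))
      return("column sums must not exceed 100")
    TRUE
  })

#' Multi-year connectivity summary
#'
#' Element-wise mean, standard deviation (population convention, divide by
#' the number of years) and count of years with nonzero connectivity.
#'
#' @slot mean,sd numeric matrices.
#' @slot nYears integer matrix of years with entry > 0.
#' @slot years the year labels summarized.
#' @export
setClass("ConnectivitySummary",
  representation(mean = "matrix", sd = "matrix", nYears = "matrix",
                 years = "numeric"))

#' Diploid SNP genotypes with population labels
#'
#' Biallelic genotypes stored as counts of the alternate allele (0, 1, 2;
#' \code{NA} for missing) in an individuals x loci integer matrix. The
#' \code{truth} slot records planted first-generation migrants when the
#' object came from the synthetic generator.
#'
#' @slot geno integer matrix, individuals x loci.
#' @slot pop factor of population labels, one per individual.
#' @slot loci character vector of locus identifiers.
#' @slot truth data.frame with columns \code{individual} (row index) and
#'   \code{trueSource} (population label); empty when not simulated.
#' @export
setClass("GenotypeMatrix",
  representation(geno = "matrix", pop = "factor", loci = "character",
                 truth = "data.frame"),
  prototype(truth = data.frame(individual = integer(),
                               trueSource = character())),
  validity = function(object) {
    if (nrow(object@geno) != length(object@pop))
      return("one population label per individual is required")
    if (ncol(object@geno) != length(object@loci))
      return("one identifier per locus is required")
    g <- object@geno[!is.na(object@geno)]
    if (length(g) && (any(g < 0) || any(g > 2)))
      return("genotypes must be 0, 1, 2 or NA")
    if (any(colSums(!is.na(object@geno)) < 1))
      return("every locus needs at least one non-missing call")
    TRUE
  })

#' Folded two-population joint site frequency spectrum
#'
#' \code{(n1+1) x (n2+1)} matrix indexed by minor-allele counts 0..n1 and
#' 0..n2 in the two populations (haploid sample sizes n1, n2). Masked
#' entries (the monomorphic corners and the redundant folded half) are
#' excluded from likelihoods. \code{meta} carries provenance such as the
#' number of coalescent replicates behind an expectation.
#'
#' @slot entries numeric matrix of site counts (data) or relative expected
#'   proportions (model expectation).
#' @slot mask logical matrix, \code{TRUE} for excluded cells.
#' @slot n1,n2 haploid sample sizes.
#' @slot meta list of provenance fields.
#' @export
setClass("FoldedJSFS",
  representation(entries = "matrix", mask = "matrix",
                 n1 = "integer", n2 = "integer", meta = "list"),
  prototype(meta = list()),
  validity = function(object) {
    if (!identical(dim(object@entries), c(object@n1 + 1L, object@n2 + 1L)))
      return("entries must be (n1+1) x (n2+1)")
    if (!identical(dim(object@mask), dim(object@entries)))
      return("mask must match entries")
    if (any(object@entries[!object@mask] < 0))
      return("entries must be nonnegative")
    TRUE
  })

#' Fit of one divergence scenario to an observed spectrum
#'
#' @slot scenario one of "SI", "IM", "AM", "SC", "PAM", "PSC".
#' @slot params named vector of best-fit parameters (diffusion scaling:
#'   sizes relative to the ancestral size, times in 2*Nref generations,
#'   migration in units of 2*Nref).
#' @slot logL composite Poisson log-likelihood at the best fit.
#' @slot K number of free parameters.
#' @slot aic Akaike information criterion, \code{2K - 2 logL}.
#' @slot theta optimal multiplicative scaling of the relative expectation.
#' @slot replicates data.frame logging every optimizer restart.
#' @export
setClass("DivergenceFit",
  representation(scenario = "character", params = "numeric",
                 logL = "numeric", K = "integer", aic = "numeric",
                 theta = "numeric", replicates = "data.frame"),
  validity = function(object) {
    if (abs(object@aic - (2 * object@K - 2 * object@logL)) > 1e-6)
      return("AIC must equal 2K - 2 logL")
    TRUE
  })

setMethod("show", "FlowField", function(object) {
  cat("FlowField:", length(object@lon), "x", length(object@lat), "nodes,",
      length(object@time), "time stamp(s)\n")
  cat("  lon:", min(object@lon), "to", max(object@lon),
      " lat:", min(object@lat), "to", max(object@lat), "\n")
  cat("  land cells:", sum(object@mask), "/", length(object@mask), "\n")
  sp <- sqrt(object@u[, , 1]^2 + object@v[, , 1]^2)[!object@mask]
  cat("  max speed (first stamp):", signif(max(sp), 3), "m/s\n")
})

setMethod("show", "ParticleEnsemble", function(object) {
  st <- table(factor(object@particles$state,
                     levels = c("active", "recruited", "expired")))
  cat("ParticleEnsemble:", nrow(object@particles), "particles (",
      paste(names(st), as.integer(st), collapse = ", "), ")\n")
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat("ConnectivityMatrix, year", object@year, "\n")
  print(round(object@entries, 2))
})

setMethod("show", "ConnectivitySummary", function(object) {
  cat("ConnectivitySummary over", length(object@years), "year(s)\n")
  cat("mean (%):\n"); print(round(object@mean, 2))
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@geno), "individuals x",
      ncol(object@geno), "loci;",
      nlevels(object@pop), "populations\n")
  print(table(object@pop))
})

setMethod("show", "FoldedJSFS", function(object) {
  cat("FoldedJSFS: haploid sample sizes", object@n1, "x", object@n2,
      "; unmasked entries sum to", signif(sum(object@entries[!object@mask]), 6),
      "\n")
})

setMethod("show", "DivergenceFit", function(object) {
  cat("DivergenceFit:", object@scenario, " K =", object@K,
      " logL =", round(object@logL, 2), " AIC =", round(object@aic, 2), "\n")
  print(signif(object@params, 4))
})

#' @describeIn FlowField-class number of grid nodes per axis.
#' @param x,object an object of the documented class.
#' @export
gridDims <- function(x) c(nlon = length(x@lon), nlat = length(x@lat),
                          ntime = length(x@time))

#' Per-particle table of a ParticleEnsemble
#' @param x a \code{ParticleEnsemble}.
#' @return the particles data.frame.
#' @export
particles <- function(x) x@particles

#' Connectivity entries accessor
#' @param x a \code{ConnectivityMatrix}.
#' @return the destination x source percentage matrix.
#' @export
connectivityEntries <- function(x) x@entries

#' Spectrum entries accessor
#' @param x a \code{FoldedJSFS}.
#' @return the entry matrix with masked cells set to \code{NA}.
#' @export
sfsEntries <- function(x) {
  e <- x@entries
  e[x@mask] <- NA
  e
}

#' Genotype accessor
#' @param x a \code{GenotypeMatrix}.
#' @return integer matrix of alternate-allele counts.
#' @export
genotypes <- function(x) x@geno

#' Population labels accessor
#' @param x a \code{GenotypeMatrix}.
#' @return factor of population labels.
#' @export
populations <- function(x) x@pop
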