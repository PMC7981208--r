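#' Annual connectivity matrix from particle fates
#'
#' Entry (i, j) is 100 times the number of particles released at source j in
#' the given spawning year that recruited to destination i, divided by the
#' number released at j that year. Sources with zero releases that year get
#' an \code{NA} column (undefined, not silently zero) with a warning.
#'
#' @param ensemble a simulated \code{\link{ParticleEnsemble-class}}.
#' @param sites character vector fixing the site order (rows and columns);
#'   defaults to the sorted union of sources and recruitment sites.
#' @param year the spawning year to tabulate (defaults to the only year
#'   present).
#' @return a \code{\link{ConnectivityMatrix-class}}.
#' @export
buildAnnualMatrix <- function(ensemble, sites = NULL, year = NULL) {
  p <- particles(ensemble)
  if (is.null(year)) {
    year <- unique(p$year)
    if (length(year) != 1)
      stop("multiple spawning years present; choose one")
  }
  p <- p[p$year == year, ]
  if (is.null(sites))
    sites <- sort(unique(c(p$source, p$recruitSite[!is.na(p$recruitSite)])))
  released <- vapply(sites, function(s) sum(p$source == s), numeric(1))
  m <- matrix(0, length(sites), length(sites),
              dimnames = list(destination = sites, source = sites))
  rec <- p[p$state == "recruited" & p$recruitSite %in% sites, ]
  if (nrow(rec)) {
    tab <- table(factor(rec$recruitSite, levels = sites),
                 factor(rec$source, levels = sites))
    m <- m + 100 * sweep(unclass(tab), 2, pmax(released, 1), "/")
  }
  if (any(released == 0)) {
    warning("no releases in year ", year, " for site(s): ",
            paste(sites[released == 0], collapse = ", "),
            "; column(s) undefined")
    m[, released == 0] <- NA_real_
  }
  new("ConnectivityMatrix", year = as.numeric(year), entries = m,
      released = released)
}

#' Summarize connectivity over years
#'
#' Element-wise mean, standard deviation over years (population convention,
#' dividing by the number of years) and the count of years with nonzero
#' connectivity.
#'
#' @param matrices list of \code{\link{ConnectivityMatrix-class}} objects
#'   with identical site sets.
#' @return a \code{\link{ConnectivitySummary-class}}.
#' @export
summarizeConnectivity <- function(matrices) {
  stopifnot(length(matrices) >= 1,
            all(vapply(matrices, is, logical(1), "ConnectivityMatrix")))
  dn <- dimnames(matrices[[1]]@entries)
  for (m in matrices)
    if (!identical(dimnames(m@entries), dn))
      stop("matrices have mismatched site sets")
  arr <- simplify2array(lapply(matrices, connectivityEntries))
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1)
  mu <- apply(arr, c(1, 2), mean)
  sdPop <- sqrt(apply(arr, c(1, 2), function(x) mean((x - mean(x))^2)))
  nz <- apply(arr, c(1, 2), function(x) sum(x > 0))
  dimnames(mu) <- dimnames(sdPop) <- dimnames(nz) <- dn
  new("ConnectivitySummary", mean = mu, sd = sdPop,
      nYears = nz, years = vapply(matrices, function(m) m@year, numeric(1)))
}

#' Display transform for connectivity percentages
#'
#' \code{log10(10 x + 1)}: maps 0 to 0, compresses percentages spanning
#' orders of magnitude into decades, and preserves ranking.
#'
#' @param x nonnegative percentages.
#' @return transformed values.
#' @examples
#' logTransform(c(0, 0.1, 9.9))   # 0, log10(2), 2
#' @export
logTransform <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("percentages must be nonnegative")
  log10(10 * x + 1)
}

#' Pathway density of successful source-to-target particles
#'
#' For each grid cell, the percentage of particles that were released at
#' \code{source}, recruited to \code{target}, and visited the cell at least
#' once (revisits count once). Requires a simulation run with
#' \code{recordVisits = TRUE}.
#'
#' @param ensemble a simulated \code{\link{ParticleEnsemble-class}} carrying
#'   a visit log.
#' @param source,target site identifiers.
#' @return a matrix (nlon x nlat, on the visit grid) of percentages, with
#'   attributes \code{lon}, \code{lat} and \code{nSuccessful}.
#' @export
pathwayDensity <- function(ensemble, source, target) {
  if (is.null(ensemble@visits))
    stop("ensemble carries no visit log; run with recordVisits = TRUE")
  p <- particles(ensemble)
  ok <- which(p$source == source & p$state == "recruited" &
                p$recruitSite == target)
  if (!length(ok))
    stop("no successful particles from '", source, "' to '", target, "'")
  dens <- 100 * rowMeans(ensemble@visits[, ok, drop = FALSE])
  m <- matrix(dens, length(ensemble@visitGrid$lon),
              length(ensemble@visitGrid$lat))
  structure(m, lon = ensemble@visitGrid$lon, lat = ensemble@visitGrid$lat,
            nSuccessful = length(ok))
}
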