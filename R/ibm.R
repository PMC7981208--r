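#' Release schedule for larval particles
#'
#' Releases are tied to grid cells: every ocean cell shallower than
#' \code{shallowDepth} and within \code{siteRadiusKm} of a site's coordinate
#' is eligible, and receives \code{particlesPerCellPerDay} particles on every
#' day of the spawning window in every spawning year. Initial depths are
#' uniform in \code{depthRange}.
#'
#' @param sites data.frame with columns \code{id}, \code{lon}, \code{lat}.
#' @param years integer vector of spawning years (labels; consecutive years
#'   are \code{yearLength} days apart on the model clock).
#' @param windowDays length-2 day-of-year window, default days 213-304
#'   (1 August - 31 October, 92 release days).
#' @param particlesPerCellPerDay released per eligible cell per day
#'   (default 100).
#' @param shallowDepth bathymetry criterion in metres (default 1000).
#' @param siteRadiusKm cell-to-site association radius (default 100).
#' @param depthRange initial depth range in metres (default 0-200).
#' @param yearLength days per model year (default 365).
#' @return a validated spec (list of class \code{"releaseSpec"}).
#' @export
releaseSpec <- function(sites, years = 1L, windowDays = c(213L, 304L),
                        particlesPerCellPerDay = 100L,
                        shallowDepth = 1000, siteRadiusKm = 100,
                        depthRange = c(0, 200), yearLength = 365) {
  stopifnot(all(c("id", "lon", "lat") %in% names(sites)),
            particlesPerCellPerDay >= 1,
            windowDays[2] >= windowDays[1],
            depthRange[1] >= 0, depthRange[2] > depthRange[1])
  structure(list(sites = sites, years = as.integer(years),
                 windowDays = as.integer(windowDays),
                 particlesPerCellPerDay = as.integer(particlesPerCellPerDay),
                 shallowDepth = shallowDepth, siteRadiusKm = siteRadiusKm,
                 depthRange = depthRange, yearLength = yearLength),
            class = "releaseSpec")
}

#' Pelagic larval duration window
#'
#' Competency opens at \code{minMonths} and the larva dies at
#' \code{maxMonths}; months are 30.44-day blocks (exact multiples are used,
#' no rounding), giving a calendar-free, reproducible age gate.
#'
#' @param minMonths minimum competency age (default 15).
#' @param maxMonths maximum planktonic duration (default 22).
#' @return list of class \code{"pldWindow"} with ages in days.
#' @export
pldWindow <- function(minMonths = 15, maxMonths = 22) {
  stopifnot(minMonths > 0, maxMonths > minMonths)
  structure(list(minMonths = minMonths, maxMonths = maxMonths,
                 minAgeDays = minMonths * 30.44,
                 maxAgeDays = maxMonths * 30.44),
            class = "pldWindow")
}

#' Random-walk diffusion parameters
#'
#' @param Kh horizontal diffusivity (m^2/s, default 100).
#' @param Kv vertical diffusivity (m^2/s, default 1e-4).
#' @param dtMinutes model time step (minutes, default 30).
#' @return list of class \code{"diffusionSpec"}.
#' @export
diffusionSpec <- function(Kh = 100, Kv = 1e-4, dtMinutes = 30) {
  stopifnot(Kh >= 0, Kv >= 0, dtMinutes > 0)
  structure(list(Kh = Kh, Kv = Kv, dtMinutes = dtMinutes),
            class = "diffusionSpec")
}

#' Recruitment zones around population sites
#'
#' @param sites data.frame with columns \code{id}, \code{lon}, \code{lat}
#'   and optionally \code{radiusKm} (default 100).
#' @return data.frame of class \code{"recruitmentZones"}.
#' @export
recruitmentZones <- function(sites, radiusKm = 100) {
  stopifnot(all(c("id", "lon", "lat") %in% names(sites)))
  if (is.null(sites$radiusKm)) sites$radiusKm <- radiusKm
  stopifnot(all(sites$radiusKm > 0))
  class(sites) <- c("recruitmentZones", "data.frame")
  sites
}

#' Schedule particle releases on a flow field
#'
#' @param field a \code{\link{FlowField-class}}.
#' @param spec a \code{\link{releaseSpec}}.
#' @param seed integer seed for the uniform initial depths.
#' @return an initial \code{\link{ParticleEnsemble-class}} (all active,
#'   age 0).
#' @export
scheduleReleases <- function(field, spec, seed = 1L) {
  stopifnot(is(field, "FlowField"), inherits(spec, "releaseSpec"))
  set.seed(as.integer(seed))
  grid <- expand.grid(lon = field@lon, lat = field@lat)
  ocean <- !as.vector(field@mask)
  shallow <- as.vector(field@bathy) < spec$shallowDepth

  rows <- vector("list", nrow(spec$sites))
  for (s in seq_len(nrow(spec$sites))) {
    site <- spec$sites[s, ]
    d <- distanceKm(grid$lon, grid$lat, site$lon, site$lat)
    elig <- which(ocean & shallow & d <= spec$siteRadiusKm)
    if (!length(elig))
      stop("site '", site$id, "' has no eligible release cell ",
           "(ocean, depth < ", spec$shallowDepth, " m, within ",
           spec$siteRadiusKm, " km)")
    days <- seq(spec$windowDays[1], spec$windowDays[2])
    per <- spec$particlesPerCellPerDay
    combos <- expand.grid(cell = elig, day = days, year = spec$years)
    n <- nrow(combos) * per
    idx <- rep(seq_len(nrow(combos)), each = per)
    rows[[s]] <- data.frame(
      source = as.character(site$id),
      year = combos$year[idx],
      releaseDay = (combos$year[idx] - min(spec$years)) * spec$yearLength +
        combos$day[idx],
      lon = grid$lon[combos$cell[idx]],
      lat = grid$lat[combos$cell[idx]],
      depth = runif(n, spec$depthRange[1], spec$depthRange[2]),
      stringsAsFactors = FALSE)
  }
  p <- do.call(rbind, rows)
  p <- data.frame(id = seq_len(nrow(p)), p,
                  age = 0, state = "active",
                  recruitSite = NA_character_, recruitDay = NA_real_,
                  stringsAsFactors = FALSE)
  new("ParticleEnsemble", particles = p)
}

#' One midpoint Runge-Kutta advection step
#'
#' Evaluates the velocity at the current position, takes a half step,
#' re-evaluates at the midpoint, and applies the full step. Metre
#' displacements convert to degrees at the particle's (respectively the
#' midpoint's) latitude. \code{NA} velocities (out-of-domain queries)
#' propagate to \code{NA} positions for the caller's boundary policy.
#'
#' @param flow a \code{FlowField} or \code{FlowFunction}.
#' @param lon,lat current positions (degrees), vectorized.
#' @param time current time (days).
#' @param dtSeconds step length in seconds.
#' @return list with \code{lon}, \code{lat} of the new positions.
#' @export
advectRK2 <- function(flow, lon, lat, time, dtSeconds) {
  v1 <- velocityAt(flow, lon, lat, time)
  lonH <- lon + 0.5 * dtSeconds * v1$u * .degLonPerMeter(lat)
  latH <- lat + 0.5 * dtSeconds * v1$v * .degLatPerMeter(lat)
  v2 <- velocityAt(flow, lonH, latH, time + 0.5 * dtSeconds / 86400)
  list(lon = lon + dtSeconds * v2$u * .degLonPerMeter(latH),
       lat = lat + dtSeconds * v2$v * .degLatPerMeter(latH))
}

#' One random-walk diffusion displacement
#'
#' Independent Gaussian displacements per axis with variance \code{2 K dt};
#' the vertical component is intended to be reflected into the confinement
#' layer by the caller (see \code{\link{reflectDepth}}).
#'
#' @param spec a \code{\link{diffusionSpec}}.
#' @param n number of particles.
#' @return list with \code{dx}, \code{dy} (m, horizontal) and \code{dz} (m,
#'   vertical, positive down).
#' @export
randomWalkStep <- function(spec, n) {
  dt <- spec$dtMinutes * 60
  sdh <- sqrt(2 * spec$Kh * dt)
  sdv <- sqrt(2 * spec$Kv * dt)
  list(dx = if (sdh > 0) rnorm(n, 0, sdh) else numeric(n),
       dy = if (sdh > 0) rnorm(n, 0, sdh) else numeric(n),
       dz = if (sdv > 0) rnorm(n, 0, sdv) else numeric(n))
}

#' Reflect depths into the confinement layer
#'
#' Folds arbitrary real depths into \code{[0, zmax]} by repeated reflection
#' at the surface and at the confinement depth.
#'
#' @param z depths (m), any real values.
#' @param zmax confinement depth (m, default 200).
#' @return depths in \code{[0, zmax]}.
#' @export
reflectDepth <- function(z, zmax = 200) {
  z <- abs(z) %% (2 * zmax)
  ifelse(z > zmax, 2 * zmax - z, z)
}

# precompute, per grid cell, the recruitment zone it belongs to
# (nearest site among those within radius; 0 = none)
.cellZones <- function(lonNodes, latNodes, zones) {
  grid <- expand.grid(lon = lonNodes, lat = latNodes)
  zone <- integer(nrow(grid))
  best <- rep(Inf, nrow(grid))
  for (s in seq_len(nrow(zones))) {
    d <- distanceKm(grid$lon, grid$lat, zones$lon[s], zones$lat[s])
    hit <- d <= zones$radiusKm[s] & d < best
    zone[hit] <- s
    best[hit] <- d[hit]
  }
  zone
}

#' Run the Lagrangian larval transport simulation
#'
#' Steps every released particle through advection (midpoint Runge-Kutta),
#' random-walk diffusion, the land/domain boundary policy and ageing, until
#' it recruits (inside a zone's grid cells at age >= the competency
#' minimum), expires (age > maximum duration) or the clock runs out.
#' Depths are confined to \code{[0, confinementDepth]} by reflection.
#'
#' Boundary policies when a step lands on land or leaves the domain:
#' \code{"slide"} retries the zonal and then the meridional component alone
#' (cancelling the blocked component), \code{"reflect"} bounces the
#' displacement back, \code{"halt"} leaves the particle in place for the
#' step.
#'
#' @param flow a \code{FlowField} or \code{FlowFunction}.
#' @param ensemble initial \code{\link{ParticleEnsemble-class}} from
#'   \code{\link{scheduleReleases}}.
#' @param zones \code{\link{recruitmentZones}}.
#' @param pld a \code{\link{pldWindow}}.
#' @param diffusion a \code{\link{diffusionSpec}}.
#' @param boundary one of \code{"slide"}, \code{"reflect"}, \code{"halt"}.
#' @param confinementDepth vertical confinement (m, default 200).
#' @param recordVisits log each particle's visited grid cells (needed for
#'   \code{\link{pathwayDensity}}); requires a \code{FlowField} grid or an
#'   explicit \code{visitGrid}.
#' @param visitGrid optional list with \code{lon}, \code{lat} node vectors
#'   for visit logging with an analytic flow.
#' @param seed integer seed for the diffusion random walk.
#' @return the final \code{ParticleEnsemble} with fates, a per-step
#'   conservation log, and (optionally) the visit matrix.
#' @export
runSimulation <- function(flow, ensemble, zones, pld = pldWindow(),
                          diffusion = diffusionSpec(),
                          boundary = c("slide", "reflect", "halt"),
                          confinementDepth = 200,
                          recordVisits = FALSE, visitGrid = NULL,
                          seed = 1L) {
  boundary <- match.arg(boundary)
  stopifnot(is(ensemble, "ParticleEnsemble"),
            inherits(zones, "recruitmentZones"),
            inherits(pld, "pldWindow"), inherits(diffusion, "diffusionSpec"))
  set.seed(as.integer(seed))
  p <- ensemble@particles
  n <- nrow(p)

  if (is.null(visitGrid)) {
    if (is(flow, "FlowField"))
      visitGrid <- list(lon = flow@lon, lat = flow@lat)
    else if (recordVisits)
      stop("recordVisits with an analytic flow needs an explicit visitGrid")
  }
  if (is(flow, "FlowField")) {
    tcov <- max(flow@time) - min(flow@time)
    span <- max(p$releaseDay) - min(p$releaseDay) + pld$maxAgeDays
    if (length(flow@time) > 1 && tcov < span)
      stop("flow field time coverage (", tcov, " d) shorter than release ",
           "span plus maximum planktonic duration (", round(span), " d)")
  }

  zcell <- integer(0); nxv <- 0L
  if (!is.null(visitGrid)) {
    zcell <- .cellZones(visitGrid$lon, visitGrid$lat, zones)
    nxv <- length(visitGrid$lon)
  } else {
    zcell <- NULL
  }
  visits <- NULL
  if (recordVisits)
    visits <- matrix(FALSE, length(visitGrid$lon) * length(visitGrid$lat), n)

  dtDays <- diffusion$dtMinutes / 1440
  dtSec <- diffusion$dtMinutes * 60
  t0 <- min(p$releaseDay)
  tEnd <- max(p$releaseDay) + pld$maxAgeDays
  nSteps <- ceiling((tEnd - t0) / dtDays)

  lon <- p$lon; lat <- p$lat; dep <- p$depth; age <- p$age
  state <- p$state
  recruitSite <- p$recruitSite; recruitDay <- p$recruitDay
  logRows <- vector("list", nSteps)

  cellOf <- function(qlon, qlat) {
    i <- .nearestIndex(qlon, visitGrid$lon)
    j <- .nearestIndex(qlat, visitGrid$lat)
    i + nxv * (j - 1L)
  }

  t <- t0
  for (step in seq_len(nSteps)) {
    act <- which(state == "active" & p$releaseDay <= t)
    if (length(act)) {
      adv <- advectRK2(flow, lon[act], lat[act], t, dtSec)
      rw <- randomWalkStep(diffusion, length(act))
      newLon <- adv$lon + rw$dx * .degLonPerMeter(lat[act])
      newLat <- adv$lat + rw$dy * .degLatPerMeter(lat[act])
      dep[act] <- reflectDepth(dep[act] + rw$dz, confinementDepth)

      bad <- isBlocked(flow, newLon, newLat)
      if (any(bad)) {
        b <- which(bad)
        if (boundary == "slide") {
          # zonal component alone, then meridional alone, else stay
          okLon <- !isBlocked(flow, newLon[b], lat[act][b])
          keepLon <- b[okLon]
          newLat[keepLon] <- lat[act][keepLon]
          rest <- b[!okLon]
          if (length(rest)) {
            okLat <- !isBlocked(flow, lon[act][rest], newLat[rest])
            keepLat <- rest[okLat]
            newLon[keepLat] <- lon[act][keepLat]
            stay <- rest[!okLat]
            newLon[stay] <- lon[act][stay]
            newLat[stay] <- lat[act][stay]
          }
        } else if (boundary == "reflect") {
          refLon <- 2 * lon[act][b] - newLon[b]
          refLat <- 2 * lat[act][b] - newLat[b]
          okRef <- !isBlocked(flow, refLon, refLat)
          keep <- b[okRef]
          newLon[keep] <- refLon[okRef]
          newLat[keep] <- refLat[okRef]
          stay <- b[!okRef]
          newLon[stay] <- lon[act][stay]
          newLat[stay] <- lat[act][stay]
        } else { # halt
          newLon[b] <- lon[act][b]
          newLat[b] <- lat[act][b]
        }
      }
      lon[act] <- newLon
      lat[act] <- newLat
      age[act] <- age[act] + dtDays

      if (!is.null(visitGrid)) {
        cells <- cellOf(lon[act], lat[act])
        if (recordVisits)
          visits[cbind(cells, act)] <- TRUE
      }
      comp <- which(age[act] >= pld$minAgeDays &
                      age[act] <= pld$maxAgeDays)
      if (length(comp)) {
        if (!is.null(visitGrid)) {
          z <- zcell[cells[comp]]
        } else {
          # analytic flow without a grid: point-in-circle membership
          sub <- act[comp]
          z <- integer(length(sub)); best <- rep(Inf, length(sub))
          for (s in seq_len(nrow(zones))) {
            d <- distanceKm(lon[sub], lat[sub], zones$lon[s], zones$lat[s])
            hit <- d <= zones$radiusKm[s] & d < best
            z[hit] <- s; best[hit] <- d[hit]
          }
        }
        hit <- z > 0L
        if (any(hit)) {
          who <- act[comp][hit]
          state[who] <- "recruited"
          recruitSite[who] <- as.character(zones$id[z[hit]])
          recruitDay[who] <- t + dtDays
        }
      }
      dead <- act[age[act] > pld$maxAgeDays & state[act] == "active"]
      state[dead] <- "expired"
    }
    t <- t + dtDays
    logRows[[step]] <- c(step = step, time = t,
                         released = sum(p$releaseDay <= t),
                         active = sum(state == "active" & p$releaseDay <= t),
                         recruited = sum(state == "recruited"),
                         expired = sum(state == "expired"))
  }

  p$lon <- lon; p$lat <- lat; p$depth <- dep; p$age <- age
  p$state <- state; p$recruitSite <- recruitSite; p$recruitDay <- recruitDay
  new("ParticleEnsemble", particles = p,
      stepLog = as.data.frame(do.call(rbind, logRows)),
      visits = visits,
      visitGrid = if (is.null(visitGrid)) list() else visitGrid)
}
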