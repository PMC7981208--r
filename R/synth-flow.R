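#' Specification of an idealized ocean flow field
#'
#' Describes an analytic velocity field built from up to three components:
#' a closed anticyclonic gyre derived from a sinusoidal basin-mode
#' streamfunction (so velocities have an exact analytic form and are
#' divergence-free in the local metric), a zonal jet with a Gaussian
#' meridional profile (the eastward frontal current), and an optional weak
#' westward leakage corridor. Islands impose shallow bathymetry (and
#' optionally a land cell) within a radius of their centre.
#'
#' @param lonRange,latRange numeric length-2 domain bounds (degrees).
#' @param spacing grid spacing in degrees (> 0).
#' @param timeDays time stamps in days; a single value gives a steady field.
#' @param gyre \code{NULL} or list with \code{lonRange}, \code{latRange}
#'   (the gyre basin), and \code{strength} (peak zonal speed, m/s).
#' @param jet \code{NULL} or list with \code{lat} (core latitude),
#'   \code{width} (Gaussian e-folding half-width, degrees > 0) and
#'   \code{speed} (core eastward speed, m/s).
#' @param leakage \code{NULL} or list like \code{jet}; its \code{speed} is
#'   applied westward.
#' @param islands list of lists with \code{id}, \code{lon}, \code{lat},
#'   \code{radiusKm} (shallow-bathymetry radius), optional \code{depth}
#'   (shallow depth, m; default 200) and \code{land} (mask the nearest grid
#'   cell as land; default \code{FALSE}).
#' @param deepDepth open-ocean bathymetry (m; default 4000).
#' @param seed integer seed (kept for interface symmetry; the field is
#'   deterministic).
#' @return a validated spec (list of class \code{"flowFieldSpec"}).
#' @export
flowFieldSpec <- function(lonRange, latRange, spacing = 1,
                          timeDays = 0,
                          gyre = NULL, jet = NULL, leakage = NULL,
                          islands = list(), deepDepth = 4000,
                          seed = 1L) {
  stopifnot(length(lonRange) == 2, length(latRange) == 2,
            lonRange[2] > lonRange[1], latRange[2] > latRange[1],
            spacing > 0, deepDepth > 0)
  if (!is.null(jet)) stopifnot(jet$width > 0, is.finite(jet$speed))
  if (!is.null(leakage)) stopifnot(leakage$width > 0,
                                   is.finite(leakage$speed))
  if (!is.null(gyre)) stopifnot(is.finite(gyre$strength))
  structure(list(lonRange = lonRange, latRange = latRange,
                 spacing = spacing, timeDays = timeDays, gyre = gyre,
                 jet = jet, leakage = leakage, islands = islands,
                 deepDepth = deepDepth, seed = as.integer(seed)),
            class = "flowFieldSpec")
}

# analytic gyre velocities at (lon, lat); basin-mode streamfunction
# psi = Psi0 sin(pi x~) sin(pi y~), u = -dpsi/dy, v = +dpsi/dx in a local
# equirectangular metric anchored at the basin centre latitude.
.gyreVelocity <- function(gyre, lon, lat) {
  lx <- diff(gyre$lonRange); ly <- diff(gyre$latRange)
  latC <- mean(gyre$latRange)
  lxM <- lx * M_PER_DEG * cos(latC * pi / 180)
  lyM <- ly * M_PER_DEG
  xt <- (lon - gyre$lonRange[1]) / lx
  yt <- (lat - gyre$latRange[1]) / ly
  inside <- xt >= 0 & xt <= 1 & yt >= 0 & yt <= 1
  # Psi0 < 0 gives counterclockwise (Southern-Hemisphere anticyclonic)
  # rotation; strength is the peak |u| on the basin midline
  psi0 <- -gyre$strength * lyM / pi
  u <- ifelse(inside, -psi0 * (pi / lyM) * sin(pi * xt) * cos(pi * yt), 0)
  v <- ifelse(inside,  psi0 * (pi / lxM) * cos(pi * xt) * sin(pi * yt), 0)
  list(u = u, v = v)
}

#' Analytic streamfunction of the gyre component (m^2/s)
#'
#' Exposed so tests can check the discrete velocities against
#' finite differences of the streamfunction.
#'
#' @param gyre the \code{gyre} component of a \code{\link{flowFieldSpec}}.
#' @param lon,lat coordinates (degrees), vectorized.
#' @return streamfunction values (0 outside the gyre basin).
#' @export
gyreStreamfunction <- function(gyre, lon, lat) {
  lx <- diff(gyre$lonRange); ly <- diff(gyre$latRange)
  lyM <- ly * M_PER_DEG
  xt <- (lon - gyre$lonRange[1]) / lx
  yt <- (lat - gyre$latRange[1]) / ly
  inside <- xt >= 0 & xt <= 1 & yt >= 0 & yt <= 1
  psi0 <- -gyre$strength * lyM / pi
  ifelse(inside, psi0 * sin(pi * xt) * sin(pi * yt), 0)
}

.componentVelocity <- function(spec, lon, lat) {
  u <- numeric(length(lon)); v <- numeric(length(lon))
  if (!is.null(spec$gyre)) {
    g <- .gyreVelocity(spec$gyre, lon, lat)
    u <- u + g$u; v <- v + g$v
  }
  if (!is.null(spec$jet))
    u <- u + spec$jet$speed * exp(-((lat - spec$jet$lat) / spec$jet$width)^2)
  if (!is.null(spec$leakage))
    u <- u - spec$leakage$speed *
      exp(-((lat - spec$leakage$lat) / spec$leakage$width)^2)
  list(u = u, v = v)
}

#' Build an idealized gridded velocity field
#'
#' Evaluates the analytic components of a \code{\link{flowFieldSpec}} on the
#' grid, applies island bathymetry and land masking, and returns a
#' \code{\link{FlowField-class}} object. Masked cells carry zero velocity.
#'
#' @param spec a \code{\link{flowFieldSpec}}.
#' @return a \code{FlowField}.
#' @examples
#' field <- makeFlowField(flowFieldSpec(c(0, 10), c(-42, -34),
#'   jet = list(lat = -38, width = 1.5, speed = 0.3)))
#' velocityAt(field, 5, -38, 0)$u   # 0.3 m/s at the jet core
#' @export
makeFlowField <- function(spec) {
  stopifnot(inherits(spec, "flowFieldSpec"))
  lon <- seq(spec$lonRange[1], spec$lonRange[2], by = spec$spacing)
  lat <- seq(spec$latRange[1], spec$latRange[2], by = spec$spacing)
  if (length(lon) <= 1 || length(lat) <= 1)
    stop("degenerate grid: <= 1 node on an axis")
  nt <- length(spec$timeDays)
  grid <- expand.grid(lon = lon, lat = lat)
  vel <- .componentVelocity(spec, grid$lon, grid$lat)
  u1 <- matrix(vel$u, length(lon), length(lat))
  v1 <- matrix(vel$v, length(lon), length(lat))

  bathy <- matrix(spec$deepDepth, length(lon), length(lat))
  mask <- matrix(FALSE, length(lon), length(lat))
  for (isl in spec$islands) {
    d <- matrix(distanceKm(grid$lon, grid$lat, isl$lon, isl$lat),
                length(lon), length(lat))
    shallow <- if (is.null(isl$depth)) 200 else isl$depth
    bathy[d <= isl$radiusKm] <- pmin(bathy[d <= isl$radiusKm], shallow)
    if (isTRUE(isl$land)) mask[which.min(d)] <- TRUE
  }
  u1[mask] <- 0; v1[mask] <- 0
  u <- array(rep(u1, nt), dim = c(length(lon), length(lat), nt))
  v <- array(rep(v1, nt), dim = c(length(lon), length(lat), nt))
  new("FlowField", lon = lon, lat = lat, time = as.numeric(spec$timeDays),
      u = u, v = v, mask = mask, bathy = bathy)
}
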