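#' Velocity at arbitrary points of a flow
#'
#' For a \code{\link{FlowField-class}}, bilinear interpolation in lon/lat and
#' linear interpolation in time between the bracketing stored means (times
#' outside the stored range clamp to the nearest stamp). For a
#' \code{\link{FlowFunction-class}}, the analytic function is evaluated
#' directly. Queries outside the spatial domain return \code{NA}, signalling
#' a boundary condition to the caller; land cells contribute zero velocity
#' to the interpolation stencil.
#'
#' @param flow a \code{FlowField} or \code{FlowFunction}.
#' @param lon,lat query coordinates (degrees), vectorized.
#' @param time query time (days), scalar or vector.
#' @return list with numeric vectors \code{u} and \code{v} (m/s).
#' @export
setGeneric("velocityAt", function(flow, lon, lat, time)
  standardGeneric("velocityAt"))

# bilinear spatial weights for one time slice
.interpSlice <- function(uM, vM, i, j, wx, wy) {
  nx <- nrow(uM)
  k00 <- i + nx * (j - 1)
  k10 <- k00 + 1
  k01 <- k00 + nx
  k11 <- k01 + 1
  w00 <- (1 - wx) * (1 - wy); w10 <- wx * (1 - wy)
  w01 <- (1 - wx) * wy;       w11 <- wx * wy
  list(u = uM[k00] * w00 + uM[k10] * w10 + uM[k01] * w01 + uM[k11] * w11,
       v = vM[k00] * w00 + vM[k10] * w10 + vM[k01] * w01 + vM[k11] * w11)
}

#' @rdname velocityAt
#' @export
setMethod("velocityAt", "FlowField", function(flow, lon, lat, time) {
  nx <- length(flow@lon); ny <- length(flow@lat); nt <- length(flow@time)
  out <- lon < flow@lon[1] | lon > flow@lon[nx] |
         lat < flow@lat[1] | lat > flow@lat[ny] | is.na(lon) | is.na(lat)
  i <- pmin(pmax(findInterval(lon, flow@lon), 1L), nx - 1L)
  j <- pmin(pmax(findInterval(lat, flow@lat), 1L), ny - 1L)
  wx <- (lon - flow@lon[i]) / (flow@lon[i + 1L] - flow@lon[i])
  wy <- (lat - flow@lat[j]) / (flow@lat[j + 1L] - flow@lat[j])
  wx[out] <- 0; wy[out] <- 0; i[out] <- 1L; j[out] <- 1L

  if (nt == 1L) {
    r <- .interpSlice(flow@u[, , 1L], flow@v[, , 1L], i, j, wx, wy)
  } else {
    tq <- if (length(time) == 1L) rep(time, length(lon)) else time
    tq <- pmin(pmax(tq, flow@time[1]), flow@time[nt])
    k <- pmin(pmax(findInterval(tq, flow@time), 1L), nt - 1L)
    wt <- (tq - flow@time[k]) / (flow@time[k + 1L] - flow@time[k])
    r <- list(u = numeric(length(lon)), v = numeric(length(lon)))
    for (kk in sort(unique(k))) {
      sel <- k == kk
      a <- .interpSlice(flow@u[, , kk], flow@v[, , kk],
                        i[sel], j[sel], wx[sel], wy[sel])
      b <- .interpSlice(flow@u[, , kk + 1L], flow@v[, , kk + 1L],
                        i[sel], j[sel], wx[sel], wy[sel])
      r$u[sel] <- (1 - wt[sel]) * a$u + wt[sel] * b$u
      r$v[sel] <- (1 - wt[sel]) * a$v + wt[sel] * b$v
    }
  }
  r$u[out] <- NA_real_; r$v[out] <- NA_real_
  r
})

#' @rdname velocityAt
#' @export
setMethod("velocityAt", "FlowFunction", function(flow, lon, lat, time) {
  flow@fun(lon, lat, time)
})

#' Is a point on land or outside the domain?
#'
#' A point is unavailable when it falls outside the grid bounds or inside a
#' masked (land) grid cell; cell membership is nearest-node. Analytic flows
#' have no land.
#'
#' @param flow a \code{FlowField} or \code{FlowFunction}.
#' @param lon,lat coordinates (degrees), vectorized.
#' @return logical vector.
#' @export
setGeneric("isBlocked", function(flow, lon, lat) standardGeneric("isBlocked"))

#' @rdname isBlocked
#' @export
setMethod("isBlocked", "FlowField", function(flow, lon, lat) {
  nx <- length(flow@lon); ny <- length(flow@lat)
  out <- lon < flow@lon[1] | lon > flow@lon[nx] |
         lat < flow@lat[1] | lat > flow@lat[ny] | is.na(lon) | is.na(lat)
  i <- .nearestIndex(lon, flow@lon)
  j <- .nearestIndex(lat, flow@lat)
  land <- flow@mask[cbind(i, j)]
  out | land
})

#' @rdname isBlocked
#' @export
setMethod("isBlocked", "FlowFunction", function(flow, lon, lat) {
  rep(FALSE, length(lon))
})

.nearestIndex <- function(x, nodes) {
  i <- findInterval(x, nodes, all.inside = TRUE)
  i + as.integer(x - nodes[i] > nodes[pmin(i + 1L, length(nodes))] - x)
}
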