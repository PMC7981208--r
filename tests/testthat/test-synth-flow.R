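test_that("all-zero component speeds give a zero field", {
  spec <- flowFieldSpec(c(0, 10), c(-45, -35), spacing = 1,
                        gyre = list(lonRange = c(0, 10),
                                    latRange = c(-45, -35), strength = 0),
                        jet = list(lat = -40, width = 2, speed = 0))
  f <- makeFlowField(spec)
  expect_true(all(f@u == 0))
  expect_true(all(f@v == 0))
})

test_that("jet speed equals the stated Gaussian profile", {
  spec <- flowFieldSpec(c(0, 10), c(-45, -35), spacing = 0.5,
                        jet = list(lat = -40, width = 2, speed = 0.3))
  f <- makeFlowField(spec)
  core <- which(f@lat == -40)
  expect_equal(f@u[3, core, 1], 0.3)
  off <- which(f@lat == -38)   # 2 degrees = one e-folding width
  expect_equal(f@u[3, off, 1], 0.3 * exp(-1))
  expect_true(all(f@v == 0))
})

test_that("gyre velocities match streamfunction derivatives and are
           divergence-free in the local metric", {
  g <- list(lonRange = c(0, 12), latRange = c(-44, -32), strength = 0.2)
  spec <- flowFieldSpec(c(0, 12), c(-44, -32), spacing = 0.5, gyre = g)
  f <- makeFlowField(spec)
  latC <- mean(g$latRange)
  mLon <- 111320 * cos(latC * pi / 180)
  mLat <- 111320
  # centred finite differences of the analytic streamfunction
  h <- 1e-4
  lon0 <- 5.5; lat0 <- -37.5   # grid nodes: no interpolation error
  dpsidy <- (gyreStreamfunction(g, lon0, lat0 + h) -
             gyreStreamfunction(g, lon0, lat0 - h)) / (2 * h * mLat)
  dpsidx <- (gyreStreamfunction(g, lon0 + h, lat0) -
             gyreStreamfunction(g, lon0 - h, lat0)) / (2 * h * mLon)
  vel <- velocityAt(f, lon0, lat0, 0)
  expect_equal(vel$u, -dpsidy, tolerance = 1e-3)
  expect_equal(vel$v,  dpsidx, tolerance = 1e-3)

  # discrete divergence over interior nodes, relative to the speed scale
  u <- f@u[, , 1]; v <- f@v[, , 1]
  nx <- length(f@lon); ny <- length(f@lat)
  dudx <- (u[3:nx, 2:(ny - 1)] - u[1:(nx - 2), 2:(ny - 1)]) /
    (2 * 0.5 * mLon)
  dvdy <- (v[2:(nx - 1), 3:ny] - v[2:(nx - 1), 1:(ny - 2)]) /
    (2 * 0.5 * mLat)
  lengthScale <- 6 * mLon
  expect_lt(max(abs(dudx + dvdy)) * lengthScale, 0.05 * 0.2)

  # closed circulation: the line integral around the gyre centre is nonzero
  th <- seq(0, 2 * pi, length.out = 200)[-1]
  cl <- 6 + 2.5 * cos(th); clat <- -38 + 2.5 * sin(th)
  vv <- velocityAt(f, cl, clat, 0)
  circ <- sum(-vv$u * sin(th) + vv$v * cos(th))
  expect_gt(abs(circ), 1)
})

test_that("islands set shallow bathymetry; land cells carry no velocity", {
  spec <- flowFieldSpec(c(0, 10), c(-45, -35), spacing = 1,
                        jet = list(lat = -40, width = 2, speed = 0.3),
                        islands = list(list(id = "I", lon = 5, lat = -40,
                                            radiusKm = 150, land = TRUE)))
  f <- makeFlowField(spec)
  expect_true(any(f@bathy < 1000))
  expect_true(all(f@bathy[!f@mask & f@bathy < 1000] == 200))
  expect_true(any(f@mask))
  expect_true(all(f@u[, , 1][f@mask] == 0))
  expect_true(all(diff(f@lon) > 0) && all(diff(f@lat) > 0))
})

test_that("degenerate grids are rejected", {
  expect_error(makeFlowField(flowFieldSpec(c(0, 0.5), c(-45, -35),
                                           spacing = 1)),
               "degenerate")
})
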