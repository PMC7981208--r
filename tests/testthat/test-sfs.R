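test_that("folding pools mirror cells, masks corners and preserves
           totals", {
  set.seed(1)
  u <- matrix(rpois(5 * 7, 20), 5, 7)   # n1 = 4, n2 = 6
  u[1, 1] <- 0; u[5, 7] <- 0            # monomorphic corners empty
  fd <- foldJSFS(u)
  expect_equal(sum(fd$entries[!fd$mask]), sum(u))
  expect_true(fd$mask[1, 1] && fd$mask[5, 7])
  # every unmasked off-centre cell holds its own plus its mirror's mass
  expect_equal(fd$entries[1, 2], u[1, 2] + u[5, 6])
  expect_equal(fd$entries[2, 1], u[2, 1] + u[4, 7])
  # a self-mirroring centre cell is kept as is
  expect_equal(fd$entries[3, 4], u[3, 4])
})

test_that("simulated spectra are seeded, counted and masked correctly", {
  spec <- scenarioSimSpec("IM", c(N1 = 1, N2 = 1, Ts = 1, m12 = 2,
                                  m21 = 2), 8, 8, nLoci = 500, seed = 10)
  s1 <- simulateJSFS(spec)
  s2 <- simulateJSFS(spec)
  expect_identical(s1@entries, s2@entries)   # bit-identical repeats
  expect_equal(sum(s1@entries[!s1@mask]), 500)
  expect_true(s1@mask[1, 1] && s1@mask[9, 9])
})

test_that("a symmetric IM history folds to a transposition-symmetric
           spectrum", {
  e <- expectedJSFS("IM", c(N1 = 1, N2 = 1, Ts = 1, m12 = 2, m21 = 2),
                    8, 8, nReps = 30000, seed = 2)
  full <- e@entries
  full[e@mask] <- 0
  # unfold the pooled mass back to a symmetric support for comparison
  asym <- sum(abs(full - t(full))) / sum(full)
  expect_lt(asym, 0.12)
})

test_that("vanishing divergence reduces to a panmictic 1/i spectrum", {
  ep <- seaconnect:::.scenarioEpochs("SI", c(N1 = 1, N2 = 1, Ts = 1e-9))
  set.seed(4)
  u <- seaconnect:::.coal_branch_lengths(6L, 6L, ep, 1, 30000)
  tot <- vapply(1:11, function(s) sum(u[outer(0:6, 0:6, "+") == s]),
                numeric(1))
  expect_equal(tot / tot[1], 1 / (1:11), tolerance = 0.06)
})

test_that("the simulated spectrum follows the expectation law (length-
           biased locus retention)", {
  p <- c(N1 = 1, N2 = 1, Ts = 0.5, m12 = 1, m21 = 0.25)
  s <- simulateJSFS(scenarioSimSpec("IM", p, 10, 10, nLoci = 20000,
                                    seed = 5))
  e <- expectedJSFS("IM", p, 10, 10, nReps = 150000, seed = 6)
  un <- !(s@mask | e@mask)
  obs <- s@entries[un]
  exp <- 20000 * e@entries[un]
  chi <- sum((obs - exp)^2 / exp)
  expect_gt(pchisq(chi, sum(un), lower.tail = FALSE), 0.001)
})

test_that("deep divergence concentrates mass toward fixed differences", {
  deep <- simulateJSFS(scenarioSimSpec("SI", c(N1 = 1, N2 = 1, Ts = 30),
                                       6, 6, nLoci = 2000, seed = 6))
  # folded fixed-difference corner: all minor alleles in one population
  corner <- deep@entries[1, 7] + deep@entries[7, 1]
  expect_gt(corner / 2000, 0.5)
  shallow <- simulateJSFS(scenarioSimSpec("SI",
                                          c(N1 = 1, N2 = 1, Ts = 0.05),
                                          6, 6, nLoci = 2000, seed = 6))
  cornerS <- shallow@entries[1, 7] + shallow@entries[7, 1]
  expect_lt(cornerS, corner / 5)
})

test_that("invalid scenario parameters are rejected", {
  expect_error(scenarioSimSpec("SC", c(N1 = 1, N2 = 1, Ts = 1), 8, 8, 10),
               "needs parameters")
  expect_error(scenarioSimSpec("IM", c(N1 = -1, N2 = 1, Ts = 1, m12 = 0,
                                       m21 = 0), 8, 8, 10), "sizes")
  expect_error(scenarioSimSpec("IM", c(N1 = 1, N2 = 1, Ts = -1, m12 = 0,
                                       m21 = 0), 8, 8, 10), "times")
})
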