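test_that("AIC, scores and weights follow their definitions", {
  expect_equal(aic(0, 1), 2)
  expect_equal(aic(-2216, 8), 4448)
  expect_equal(aic(-2387, 3), 4780)
  expect_equal(modelScores(c(10, 20, 30)), c(1, 0.5, 0))
  expect_error(modelScores(c(5, 5)), "equal")
  expect_error(modelScores(7), "two models")
  expect_equal(akaikeWeights(c(0, 0)), c(0.5, 0.5))
  w <- akaikeWeights(c(0, 2))
  expect_equal(w, c(exp(0), exp(-1)) / (exp(0) + exp(-1)),
               tolerance = 1e-12)
  # invariance to adding a constant; monotone decreasing in AIC
  a <- c(101, 130, 95, 120)
  expect_equal(modelScores(a), modelScores(a + 55))
  expect_equal(akaikeWeights(a), akaikeWeights(a + 55))
  expect_equal(sum(akaikeWeights(a)), 1)
  expect_equal(order(akaikeWeights(a)), order(-a))
  # huge spreads stay finite thanks to max-subtraction
  expect_equal(sum(akaikeWeights(c(4448, 9007))), 1)
})

test_that("composite Poisson likelihood matches hand arithmetic and
           profiles theta", {
  obs <- smallFoldedSFS(5, 2, 3, 10)
  ex <- smallFoldedSFS(0.2, 0.2, 0.2, 0.4)
  cl <- compositeLogLik(obs, ex)
  expect_equal(cl$theta, 20)
  lam <- 20 * c(0.2, 0.2, 0.2, 0.4)
  expect_equal(cl$logL, sum(dpois(c(5, 2, 3, 10), lam, log = TRUE)))
  # exactly proportional observation attains the saturated likelihood
  prop <- smallFoldedSFS(4, 4, 4, 8)
  clp <- compositeLogLik(prop, ex)
  expect_equal(clp$theta, 20)
  expect_equal(clp$logL, sum(dpois(c(4, 4, 4, 8), c(4, 4, 4, 8),
                                   log = TRUE)))
  # masking an empty cell leaves the likelihood unchanged
  obs2 <- obs; obs2@mask[1, 2] <- TRUE; obs2@entries[1, 2] <- 0
  ex2 <- ex; ex2@mask[1, 2] <- TRUE
  cl2 <- compositeLogLik(obs2, ex2)
  lam2 <- (15 / 0.8) * c(0.2, 0.2, 0.4)
  expect_equal(cl2$logL, sum(dpois(c(2, 3, 10), lam2, log = TRUE)))
})

test_that("secondary contact with a vanishing contact time collapses onto
           strict isolation", {
  si <- expectedJSFS("SI", c(N1 = 1, N2 = 1.5, Ts = 1), 8, 8,
                     nReps = 40000, seed = 3)
  sc <- expectedJSFS("SC", c(N1 = 1, N2 = 1.5, Ts = 1, Tsc = 0,
                             m12 = 5, m21 = 5), 8, 8,
                     nReps = 40000, seed = 3)
  un <- !si@mask
  expect_equal(sc@entries[un], si@entries[un], tolerance = 0.05)
})

test_that("a single-replicate fit equals one seeded run", {
  obs <- simulateJSFS(scenarioSimSpec("SI", c(N1 = 1, N2 = 1, Ts = 1),
                                      8, 8, nLoci = 800, seed = 12))
  f1 <- fitModel(obs, "SI", nReplicates = 1, seed = 9, nReps = 500,
                 maxit = 60, nRefine = 1, refineReps = 500,
                 refineRounds = 1, refineMaxit = 30, finalReps = 2000)
  f2 <- fitModel(obs, "SI", nReplicates = 1, seed = 9, nReps = 500,
                 maxit = 60, nRefine = 1, refineReps = 500,
                 refineRounds = 1, refineMaxit = 30, finalReps = 2000)
  expect_identical(f1@params, f2@params)
  expect_equal(f1@aic, 2 * f1@K - 2 * f1@logL)
  expect_equal(nrow(f1@replicates), 1)
})

test_that("scenario comparison assembles a coherent selection table", {
  obs <- simulateJSFS(scenarioSimSpec("SI", c(N1 = 1, N2 = 1, Ts = 2),
                                      8, 8, nLoci = 1000, seed = 30))
  cmp <- fitScenarios(obs, scenarios = c("SI", "IM"), nReplicates = 2,
                      seed = 31, nReps = 800, maxit = 120, nRefine = 1,
                      refineReps = 2400, refineRounds = 1,
                      refineMaxit = 80, finalReps = 16000,
                      polishMaxit = 0)
  tab <- cmp$table
  expect_setequal(tab$scenario, c("SI", "IM"))
  expect_equal(tab$AIC, 2 * tab$K - 2 * tab$logL)
  expect_equal(sum(tab$wAIC), 1)
  expect_equal(tab$score[order(tab$AIC)], c(1, 0))
  expect_true(all(diff(tab$AIC) >= 0))   # sorted by AIC
})

test_that("unit conversions satisfy their algebraic round trips", {
  # theta = 4 L mu exactly recovers Nref = 1
  inp <- conversionInputs(mu = 2.3e-9, x = 1000, y = 1, z = 1000)
  expect_equal(inp$z * inp$y * inp$tagLength / inp$x, 73)
  fit <- list(theta = 4 * 73 * 2.3e-9,
              params = c(Ts = 1, m12 = 2, m21 = 0.5))
  conv <- convertUnits(fit, inp)
  expect_equal(conv$L, 73)
  expect_equal(conv$Nref, 1)
  expect_equal(unname(conv$timesYears["Ts"]), 2 * 1 * 10)
  expect_equal(unname(conv$migrantProportions["m12"]), 1)
  # doubling generation time doubles all year-denominated outputs
  inp2 <- conversionInputs(mu = 2.3e-9, x = 1000, y = 1, z = 1000,
                           generationTime = 20)
  expect_equal(convertUnits(fit, inp2)$timesYears,
               2 * conv$timesYears)
  expect_error(conversionInputs(mu = 0, x = 1, y = 1, z = 1), "")
})
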