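mkEnsemble <- function(df) {
  base <- data.frame(id = seq_len(nrow(df)), year = 1, releaseDay = 213,
                     lon = 0, lat = 0, depth = 50, age = 500,
                     stringsAsFactors = FALSE)
  p <- cbind(base, df)
  p$recruitDay <- ifelse(p$state == "recruited", 700, NA_real_)
  new("ParticleEnsemble", particles = p)
}

test_that("annual matrix counts recruits over releases", {
  ens <- mkEnsemble(data.frame(
    source = rep("A", 10),
    state = c(rep("recruited", 3), rep("expired", 7)),
    recruitSite = c(rep("B", 3), rep(NA, 7)),
    stringsAsFactors = FALSE))
  expect_warning(m <- buildAnnualMatrix(ens, sites = c("A", "B")),
                 "undefined")   # B recruits arrivals but releases nothing
  expect_equal(connectivityEntries(m)["B", "A"], 30)
  expect_equal(connectivityEntries(m)["A", "A"], 0)
})

test_that("full retention gives a diagonal of 100", {
  ens <- mkEnsemble(data.frame(
    source = rep(c("A", "B"), each = 5),
    state = "recruited",
    recruitSite = rep(c("A", "B"), each = 5),
    stringsAsFactors = FALSE))
  m <- connectivityEntries(buildAnnualMatrix(ens, sites = c("A", "B")))
  expect_equal(diag(m), c(A = 100, B = 100))
  expect_equal(sum(m) - sum(diag(m)), 0)
})

test_that("no recruits gives an all-zero matrix; zero releases are
           flagged undefined", {
  ens <- mkEnsemble(data.frame(source = rep("A", 4), state = "expired",
                               recruitSite = NA_character_,
                               stringsAsFactors = FALSE))
  expect_warning(m <- buildAnnualMatrix(ens, sites = c("A", "B")),
                 "undefined")
  e <- connectivityEntries(m)
  expect_true(all(e[, "A"] == 0))
  expect_true(all(is.na(e[, "B"])))
})

test_that("summaries use mean, population SD and nonzero-year counts", {
  m1 <- new("ConnectivityMatrix", year = 1,
            entries = matrix(c(10, 0, 0, 0), 2, 2,
                             dimnames = list(c("A", "B"), c("A", "B"))),
            released = c(A = 10, B = 10))
  m2 <- new("ConnectivityMatrix", year = 2,
            entries = matrix(0, 2, 2,
                             dimnames = list(c("A", "B"), c("A", "B"))),
            released = c(A = 10, B = 10))
  s <- summarizeConnectivity(list(m1, m2))
  expect_equal(s@mean["A", "A"], 5)
  expect_equal(s@sd["A", "A"], 5)   # population convention
  expect_equal(s@nYears["A", "A"], 1)
  expect_true(all(s@nYears[s@mean == 0] == 0))
  one <- summarizeConnectivity(list(m1))
  expect_equal(one@mean, m1@entries)
  expect_true(all(one@sd == 0))
  expect_true(all(one@nYears %in% 0:1))
})

test_that("the display transform is log10(10x + 1)", {
  expect_equal(logTransform(0), 0)
  expect_equal(logTransform(9.9), 2)
  expect_equal(logTransform(0.1), log10(2))
  x <- c(0, 0.01, 0.5, 3, 47, 100)
  expect_true(all(diff(logTransform(x)) > 0))
  expect_error(logTransform(-1), "nonnegative")
})

test_that("pathway density counts particles once per visited cell", {
  p <- data.frame(id = 1:2, source = "A", year = 1, releaseDay = 213,
                  lon = 0, lat = 0, depth = 50, age = 500,
                  state = "recruited", recruitSite = "B", recruitDay = 700,
                  stringsAsFactors = FALSE)
  visits <- matrix(FALSE, 4, 2)
  visits[1:2, 1] <- TRUE           # cells 1,2 on trajectory 1
  visits[2:3, 2] <- TRUE           # cells 2,3 on trajectory 2
  ens <- new("ParticleEnsemble", particles = p, visits = visits,
             visitGrid = list(lon = c(0, 1), lat = c(0, 1)))
  d <- pathwayDensity(ens, "A", "B")
  expect_equal(as.vector(d), c(50, 100, 50, 0))
  expect_error(pathwayDensity(ens, "A", "C"), "no successful")
})
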