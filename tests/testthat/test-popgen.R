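test_that("heterozygosities match hand arithmetic on one locus", {
  # genotypes AA, AB, BB: Ho = 1/3; unbiased He = (6/5)(1 - 0.5) = 0.6
  gm <- new("GenotypeMatrix", geno = matrix(c(0L, 1L, 2L), 3, 1),
            pop = factor(rep("P", 3)), loci = "L1")
  d <- diversity(gm)
  expect_equal(d$Ho, 1 / 3)
  expect_equal(d$He, 0.6)
  expect_equal(d$n, 3)
})

test_that("monomorphic data give zero diversity and unit richness", {
  gm <- new("GenotypeMatrix", geno = matrix(0L, 4, 3),
            pop = factor(rep("P", 4)),
            loci = paste0("L", 1:3))
  d <- diversity(gm)
  expect_equal(d$Ho, 0)
  expect_equal(d$He, 0)
  expect_equal(d$Ar, 1)
})

test_that("rarefied richness interpolates between 1 and 2 and is bounded
           below by the single-gene draw", {
  gm <- new("GenotypeMatrix",
            geno = matrix(c(0L, 0L, 1L, 2L, 0L, 1L, 1L, 2L), 4, 2),
            pop = factor(rep("P", 4)), loci = c("L1", "L2"))
  d2 <- diversity(gm, rarefactionGenes = 2)
  d8 <- diversity(gm, rarefactionGenes = 8)
  expect_true(all(d2$Ar >= 1 & d2$Ar <= 2))
  expect_gt(d8$Ar, d2$Ar)          # richness grows with the draw
  expect_equal(d8$Ar, 2)           # full draw sees both alleles
})

test_that("Weir-Cockerham components match the hand-computed toy", {
  # pop1 {AA, AB}: p = 0.25, h = 0.5 ; pop2 {BB, BB}: p = 1, h = 0
  w <- seaconnect:::.wcComponents(n = c(2, 2), p = c(0.25, 1),
                                  h = c(0.5, 0))
  expect_equal(unname(w), c(0.25, 0, 0.125), tolerance = 1e-12)
  gm <- new("GenotypeMatrix", geno = matrix(c(0L, 1L, 2L, 2L), 4, 1),
            pop = factor(c("P1", "P1", "P2", "P2")), loci = "L1")
  r <- pairwiseFst(gm, nPermutations = 99, seed = 1)
  expect_equal(r$raw["P2", "P1"], 2 / 3, tolerance = 1e-12)
})

test_that("fixed alternate alleles give an estimate of 1 and panmixia
           stays near 0", {
  gm <- new("GenotypeMatrix",
            geno = rbind(matrix(0L, 6, 20), matrix(2L, 6, 20)),
            pop = factor(rep(c("P1", "P2"), each = 6)),
            loci = paste0("L", 1:20))
  r <- pairwiseFst(gm, nPermutations = 99, seed = 2)
  expect_equal(unname(r$fst["P2", "P1"]), 1)
  expect_lt(r$pValue["P2", "P1"], 0.05)

  null <- makeGenotypes(twoPopSpec(fst = 0, nLoci = 400, n = 30,
                                   seed = 21))
  rn <- pairwiseFst(null, nPermutations = 199, seed = 3)
  expect_lt(abs(rn$raw["P2", "P1"]), 0.01)   # within ~3 SE of 0
  expect_gt(rn$pValue["P2", "P1"], 0.05)
  expect_equal(unname(rn$fst["P2", "P1"]),
               max(0, unname(rn$raw["P2", "P1"])))
})

test_that("the Balding-Nichols generator hits its target
           differentiation", {
  gm <- makeGenotypes(twoPopSpec(fst = 0.2, nLoci = 1000, n = 30,
                                 seed = 31))
  r <- pairwiseFst(gm, nPermutations = 99, seed = 4)
  expect_gt(r$raw["P2", "P1"], 0.15)
  expect_lt(r$raw["P2", "P1"], 0.25)
  # estimator invariant to population order
  gm2 <- new("GenotypeMatrix", geno = genotypes(gm)[c(31:60, 1:30), ],
             pop = factor(rep(c("P2", "P1"), each = 30),
                          levels = c("P1", "P2")),
             loci = gm@loci)
  r2 <- pairwiseFst(gm2, nPermutations = 99, seed = 4)
  expect_equal(r2$raw["P2", "P1"], r$raw["P2", "P1"], tolerance = 1e-12)
})

test_that("the estimator is invariant to swapping allele labels", {
  gm <- makeGenotypes(twoPopSpec(fst = 0.1, nLoci = 200, n = 20,
                                 seed = 41))
  swapped <- new("GenotypeMatrix", geno = 2L - genotypes(gm),
                 pop = populations(gm), loci = gm@loci)
  r1 <- pairwiseFst(gm, nPermutations = 99, seed = 5)
  r2 <- pairwiseFst(swapped, nPermutations = 99, seed = 5)
  expect_equal(r1$raw, r2$raw, tolerance = 1e-12)
})

test_that("permutation p-values are uniform under the null", {
  ps <- vapply(1:20, function(r) {
    gm <- makeGenotypes(twoPopSpec(fst = 0, nLoci = 120, n = 15,
                                   seed = 700 + r))
    pairwiseFst(gm, nPermutations = 99, seed = r)$pValue["P2", "P1"]
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("undersized populations are rejected", {
  gm <- new("GenotypeMatrix", geno = matrix(c(0L, 1L, 2L), 3, 1),
            pop = factor(c("P1", "P1", "P2")), loci = "L1")
  expect_error(pairwiseFst(gm), "P2")
})
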