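# shared small fixtures, built in code

# spatially uniform steady flow field on a small grid
uniformField <- function(u = 0.1, v = 0, lonR = c(-2, 2), latR = c(-2, 2),
                         spacing = 0.5) {
  spec <- flowFieldSpec(lonR, latR, spacing = spacing)
  f <- makeFlowField(spec)
  f@u[] <- u
  f@v[] <- v
  f
}

# analytic solid-body rotation about (0, 0), angular rate omega (rad/s),
# in the local equirectangular metric used by the stepper
solidBodyFlow <- function(omega) {
  new("FlowFunction", fun = function(lon, lat, time) {
    list(u = -omega * lat * 111320, v = omega * lon * 111320)
  })
}

# two-population genotype spec used across assignment tests
twoPopSpec <- function(fst, nLoci = 300, n = 50, migrants = NULL,
                       seed = 1L) {
  genotypeSimSpec(sampleSizes = c(P1 = n, P2 = n), nLoci = nLoci,
                  fst = fst, migrants = migrants, seed = seed)
}

# hand-built folded 3x3 spectrum (n1 = n2 = 2) with the standard mask
smallFoldedSFS <- function(x01, x02, x10, x11) {
  e <- matrix(0, 3, 3)
  e[1, 2] <- x01; e[1, 3] <- x02; e[2, 1] <- x10; e[2, 2] <- x11
  mask <- matrix(TRUE, 3, 3)
  mask[1, 2] <- mask[1, 3] <- mask[2, 1] <- mask[2, 2] <- FALSE
  new("FoldedJSFS", entries = e, mask = mask, n1 = 2L, n2 = 2L)
}
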