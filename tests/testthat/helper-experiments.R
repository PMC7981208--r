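# Desk-scale experiments shared by the acceptance tests.

# Two-island gyre-plus-jet dispersal experiment: an anticyclonic gyre
# basin occupies the western corner, island A sits just east of it on the
# core of an eastward frontal jet (0.25 m/s), island B ~10,350 km
# downstream. At the jet-core speed the crossing takes ~479 days, inside
# the 15-22 month competency window, so transport is only realized in the
# jet direction (B's larvae are swept east out of the domain). One release
# cell per island, 100 particles/cell/day over a 5-day window: 1,000
# particles.
twoIslandRun <- function(seed = 1L) {
  sites <- data.frame(id = c("A", "B"), lon = c(0, 118), lat = c(-38, -38))
  spec <- flowFieldSpec(
    c(-21, 126), c(-45, -31), spacing = 1,
    gyre = list(lonRange = c(-20, -6), latRange = c(-44, -32),
                strength = 0.15),
    jet = list(lat = -38, width = 1.5, speed = 0.25),
    islands = list(list(id = "A", lon = 0, lat = -38, radiusKm = 60),
                   list(id = "B", lon = 118, lat = -38, radiusKm = 60)))
  field <- makeFlowField(spec)
  rel <- releaseSpec(sites, windowDays = c(213L, 217L))
  ens <- scheduleReleases(field, rel, seed = seed)
  runSimulation(field, ens, recruitmentZones(sites),
                pld = pldWindow(), diffusion = diffusionSpec(),
                seed = seed + 1L)
}

# Null calibration of the migrant detector: one panmictic pool of 100
# individuals split arbitrarily into two labelled halves.
nullCalibrationRun <- function(seed = 1L, nSim = 10000L) {
  gm <- makeGenotypes(genotypeSimSpec(c(P1 = 50, P2 = 50), nLoci = 300,
                                      fst = 0, seed = seed))
  detectMigrants(gm, alpha = 0.01, nSim = nSim, seed = seed + 1L)
}

# the frozen IM truth of the demographic recovery experiment (chosen by an
# identifiability analysis of the expected-data likelihood; see the
# methods vignette)
imTruth <- c(N1 = 1, N2 = 1, Ts = 0.5, m12 = 1, m21 = 0.25)
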