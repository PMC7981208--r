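# seaconnect

Multidisciplinary connectivity analysis for marine populations with
long-lived planktonic larvae — for population geneticists and larval
ecologists who need to combine physical transport modelling with genetic
estimates of gene flow in one reproducible pipeline.

Rock lobsters and similar taxa drift for over a year as plankton, so
populations thousands of kilometres apart can exchange recruits along
ocean currents. `seaconnect` implements the three quantitative layers such
a study needs, plus seeded generators for every input:

- **Lagrangian larval transport (IBM).** Particles are advected on gridded
  velocity fields with midpoint second-order Runge–Kutta steps and
  random-walk diffusion (per-axis variance 2KΔt), confined to the upper
  200 m, released at 100 particles per shallow grid cell per day through
  an August–October spawning window, and recruited into 100-km zones when
  their age lies in the competency window (15–22 months). Results
  aggregate into annual connectivity matrices *M\_t* (destination ×
  source percentages), multi-year mean/SD/nonzero-year summaries, the
  log10(10x+1) display transform, and pathway-density maps (percentage of
  successful particles crossing each cell).
- **Migrant detection and source–sink arithmetic.** Rannala–Mountain
  Bayesian genotype assignment (Dirichlet prior 1/k, leave-one-out home
  likelihood), the first-generation migrant statistic
  Λ = log10 L\_max − log10 L\_home with Monte-Carlo calibration
  (Paetkau-style resampling, default 10,000 simulated individuals,
  α = 0.01), and directional aggregation of sink × source migrant tables
  into "X% of migrants move from basin A to basin B" summaries; Θ × M
  converts mutation-scaled coalescent estimates to migrants per
  generation.
- **Divergence-model selection on the folded joint SFS.** Six
  two-population histories (strict isolation SI; isolation-with-migration
  IM; ancient migration AM; secondary contact SC; and the two-event
  variants PAM, PSC) fitted to a folded joint site frequency spectrum by
  Monte-Carlo coalescent expectation and Poisson composite likelihood
  (scale θ profiled analytically), compared with AIC, the relative score
  (Δmax − ΔAIC)/Δmax and Akaike weights, and converted to biological
  units via L = z·y·73/x, N\_ref = θ/(4Lμ), a 10-year generation time and
  per-generation migrant proportions.
- **Population-genetic summaries.** H\_O, unbiased H\_E, rarefied allelic
  richness, and pairwise Weir–Cockerham F\_ST with permutation p-values.
- **Synthetic data.** Analytic gyre/jet/leakage flow fields (streamfunction
  gyre with an exact divergence-free oracle), Balding–Nichols structured
  genotypes with planted migrants at a target F\_ST, and coalescent JSFS
  realizations under all six scenarios — everything seeded and
  bit-reproducible.

## Worked example

Score a published-style model-comparison table (K and the maximized
log-likelihood per scenario) and aggregate replicate migrant tables into
directional totals:

```r
library(seaconnect)

tab <- read.csv(system.file("extdata", "divergence_model_fits.csv",
                            package = "seaconnect"))
tab$score <- round(modelScores(tab$AIC), 2)
tab$wAIC  <- round(akaikeWeights(tab$AIC), 2)
tab
#>   scenario K  logL  AIC score wAIC
#> 1      PSC 8 -2216 4448  1.00    1
#> 2       SI 3 -2387 4780  0.93    0
#> 3       SC 6 -2892 5796  0.70    0
#> 4       IM 5 -3039 6089  0.64    0
#> 5      PAM 6 -4497 9007  0.00    0
#> 6       AM 6 -4266 8544  0.10    0

grp <- c(JPA_Am = "Indian", JPA_SP = "Indian",
         JTR_Go = "Atlantic", JTR_NI = "Atlantic", JTR_Tr = "Atlantic")
tabs <- lapply(1:3, function(s) readMigrantTable(
  system.file("extdata", paste0("contemporary_migrants_s", s, ".csv"),
              package = "seaconnect")))
aggregateDirectionalSet(tabs, grp)$range
#>       from       to minTotal maxTotal minPercent maxPercent
#> 1   Indian Atlantic        2        7   14.28571   29.16667
#> 2 Atlantic   Indian       12       17   70.83333   85.71429
```

The scoring table says the two-event secondary-contact history (PSC) is
the best-supported divergence mode (score 1.00, Akaike weight 1) and
ranks the others; the aggregation says 71–86% of detected
first-generation migrants moved from the Atlantic group to the Indian
group across the three replicate SNP subsets — the west-to-east
contemporary asymmetry.

A transport run takes a flow field (synthetic or NetCDF), a release
schedule and recruitment zones:

```r
field <- makeFlowField(flowFieldSpec(
  c(-21, 126), c(-45, -31), spacing = 1,
  gyre = list(lonRange = c(-20, -6), latRange = c(-44, -32),
              strength = 0.15),
  jet = list(lat = -38, width = 1.5, speed = 0.25),
  islands = list(list(id = "A", lon = 0,   lat = -38, radiusKm = 60),
                 list(id = "B", lon = 118, lat = -38, radiusKm = 60))))
sites <- data.frame(id = c("A", "B"), lon = c(0, 118), lat = c(-38, -38))
ens <- scheduleReleases(field, releaseSpec(sites, windowDays = c(213, 217)),
                        seed = 1)
out <- runSimulation(field, ens, recruitmentZones(sites), seed = 2)
connectivityEntries(buildAnnualMatrix(out, sites = c("A", "B")))
#>            source
#> destination    A B
#>           A  0.0 0
#>           B 53.8 0
```

Here 53.8% of island A's larvae rode the frontal jet ~10,000 km and
recruited at island B between 16 and 22 months of age; nothing travels
the other way — a one-way source–sink link.

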