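# Shared simulation helpers for the test suite. Everything is generated in
# code at test time; seeds are fixed per test for reproducibility.

quietly <- function(expr) suppressMessages(expr)

# a straight fibre localization table with known ground truth
straightFibreTable <- function(length = 5000, density = 0.2, sigmaLoc = 20,
                               muLoc = 3, background = 0, seed = 1,
                               start = c(500, 500), heading = 0) {
  bb <- sampleBackbone(FibreSpec(length, 1e9, startPoint = start,
    initialHeading = heading), seed = seed)
  s <- placeLabels(bb, LabelField(density), seed = seed + 1)
  tab <- simulateLocalizations(s, ImagingModel(sigmaLoc = sigmaLoc,
    muLoc = muLoc, backgroundDensity = background,
    fieldOfView = c(0, length + 1000, 0, length + 1000)),
    bb, channel = "cy3", seed = seed + 2)
  list(table = tab, backbone = bb, s = s)
}

# profiles of the foreign (initially population-B) channel on the fibres of
# population A, projected onto the true (resampled) backbones
foreignProfiles <- function(popA, imaging, foreign = "cy5", binWidth = 25,
                            seed = 1) {
  set.seed(seed)
  lapply(popA, function(f) {
    tab <- imageFibre(f, imaging)
    bb <- resampleBackbone(f$backbone, 25)
    proj <- quietly(projectToBackbone(tab, bb))
    densityProfile(proj, binWidth = binWidth, channel = foreign,
      fibreId = f$fibreId)
  })
}

# per-fibre foreign-channel linear densities for population A
foreignDensities <- function(popA, imaging, foreign = "cy5", seed = 1) {
  set.seed(seed)
  vapply(popA, function(f) {
    tab <- imageFibre(f, imaging)
    bb <- resampleBackbone(f$backbone, 25)
    proj <- quietly(projectToBackbone(tab, bb))
    linearDensity(proj, bb, channel = foreign)
  }, numeric(1))
}

# one mechanism-discrimination replicate: two 10-fibre populations, exchange
# under the given mechanism, then classify from the foreign-channel profiles
mechanismReplicate <- function(mechanism, seed, nFibres = 15) {
  xm <- switch(mechanism,
    random_insertion = ExchangeModel("random_insertion", k = 0.15),
    end_exchange = ExchangeModel("end_exchange", k = 1.5, endWindow = 500),
    fragmentation_recombination =
      ExchangeModel("fragmentation_recombination", k = 0.7))
  exp <- simulateExchangeExperiment(nFibres, times = 6,
    fieldA = LabelField(0.15), fieldB = LabelField(0.15), xm = xm,
    seed = seed)
  popA <- exp$snapshots[[1]]$populationA
  profiles <- foreignProfiles(popA,
    ImagingModel(sigmaLoc = 20, muLoc = 3, backgroundDensity = 0),
    seed = seed + 1000)
  classifyMechanism(profiles)
}

# analyzed Cy3-like microdomain ensemble: the standard study conditions
# (5-um fibres, m = 0.8, r0 = 300 nm, alpha = 500 nm, sigma_loc = 20 nm,
# mean 3 localizations per label); clustering radius 500 nm (> the largest
# unlabelled stretch) and a >= 4-um well-reconstructed-fibre filter
cy3Ensemble <- function(nFibres = 30, seed = 1, r0 = 300, alpha = 500) {
  sim <- simulateFibreField(nFibres,
    list(cy3 = LabelField(0.15, m = 0.8, r0 = r0, alpha = alpha)),
    ImagingModel(sigmaLoc = 20, muLoc = 3, backgroundDensity = 0.5),
    contourLength = 5000, persistenceLength = 10000, seed = seed)
  res <- quietly(analyzeFibreTable(sim$table, eps = 500))
  keep <- Filter(function(f) backboneLength(f$backbone) >= 4000, res$fibres)
  list(sim = sim, fibres = keep,
    curve = ensembleCorrelation(keep, "cy3"))
}
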