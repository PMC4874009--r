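test_that("exchange-state classification follows the threshold rules", {
  cls <- classifyExchangeState(c(a = 50, b = 0, c = 25), equilibriumRef = 50)
  expect_identical(as.character(cls$class),
    c("fully_mixed", "unexchanged", "partial"))
  expect_identical(cls$fibreId, c("a", "b", "c"))
  expect_error(classifyExchangeState(10, equilibriumRef = 0),
    "equilibriumRef")
})

test_that("density time courses summarize per-fibre foreign densities", {
  imaging <- ImagingModel(sigmaLoc = 20, muLoc = 3, backgroundDensity = 0)
  xm <- ExchangeModel("random_insertion", k = 0.3, inertFraction = 0.3,
    inertSegmentLength = 800)
  exp <- simulateExchangeExperiment(12, times = c(0, 24), fieldA =
    LabelField(0.15), fieldB = LabelField(0.15), xm = xm, seed = 90)

  densT0 <- foreignDensities(exp$snapshots[[1]]$populationA, imaging,
    seed = 91)
  densT1 <- foreignDensities(exp$snapshots[[2]]$populationA, imaging,
    seed = 92)
  # reference: original single-colour red fibres (population B at t = 0)
  refDens <- foreignDensities(exp$snapshots[[1]]$populationB, imaging,
    seed = 93)
  tc <- densityTimecourse(list(list(time = 0, densities = densT0),
                               list(time = 24, densities = densT1)),
    referenceDensities = refDens)
  ref <- attr(tc, "equilibriumRef")
  expect_equal(ref, 0.5 * mean(refDens), tolerance = 1e-12)

  # before exchange the foreign channel is essentially empty
  expect_lt(tc$mean[1], 0.05 * ref)
  # heterogeneous exchange widens the distribution markedly
  expect_gt(tc$sd[2], 3 * max(tc$sd[1], 1e-9))

  hist2 <- attr(tc, "histograms")[[2]]
  expect_identical(sum(hist2$count), tc$n[2])
  expect_identical(hist2$binStart[2] - hist2$binStart[1], 5)

  single <- densityTimecourse(list(list(time = 1, densities = 31)))
  expect_identical(single$mean, 31)
  expect_true(is.na(single$sd))
  expect_error(densityTimecourse(list(list(time = 0,
    densities = numeric(0)))), "empty time point")
})

test_that("late-time classification with inert segments yields all three classes", {
  imaging <- ImagingModel(sigmaLoc = 20, muLoc = 3, backgroundDensity = 0)
  xm <- ExchangeModel("random_insertion", k = 0.4, inertFraction = 0.45,
    inertSegmentLength = 2500)
  exp <- simulateExchangeExperiment(30, times = 48,
    fieldA = LabelField(0.15), fieldB = LabelField(0.15), xm = xm, seed = 94)
  dens <- foreignDensities(exp$snapshots[[1]]$populationA, imaging,
    seed = 95)
  ref <- 0.5 * mean(foreignDensities(exp$snapshots[[1]]$populationB,
    imaging, seed = 96))
  cls <- classifyExchangeState(dens, ref)
  expect_gte(nlevels(droplevels(cls$class)), 2)
  expect_true("partial" %in% cls$class || "unexchanged" %in% cls$class)
  expect_true("fully_mixed" %in% cls$class)
})

test_that("mean foreign density is non-decreasing in time under exchange", {
  imaging <- ImagingModel(sigmaLoc = 20, muLoc = 3, backgroundDensity = 0)
  xm <- ExchangeModel("random_insertion", k = 0.08)
  exp <- simulateExchangeExperiment(12, times = c(0, 2, 6, 16, 48),
    fieldA = LabelField(0.15), fieldB = LabelField(0.15), xm = xm, seed = 97)
  means <- vapply(seq_along(exp$times), function(i)
    mean(foreignDensities(exp$snapshots[[i]]$populationA, imaging,
      seed = 98 + i)), numeric(1))
  expect_lte(sum(diff(means) < 0), 1)   # at most one Monte-Carlo inversion
  expect_gt(means[5], means[1])
})

test_that("positional insertion profiles separate uniform from end-localized exchange", {
  imaging <- ImagingModel(sigmaLoc = 20, muLoc = 3, backgroundDensity = 0)

  expR <- simulateExchangeExperiment(40, times = 6,
    fieldA = LabelField(0.15), fieldB = LabelField(0.15),
    xm = ExchangeModel("random_insertion", k = 0.15), seed = 100)
  profR <- foreignProfiles(expR$snapshots[[1]]$populationA, imaging,
    seed = 101)
  posR <- positionalInsertionProfile(profR)
  expect_equal(endCentreRatio(posR), 1, tolerance = 0.15)

  expE <- simulateExchangeExperiment(15, times = 6,
    fieldA = LabelField(0.15), fieldB = LabelField(0.15),
    xm = ExchangeModel("end_exchange", k = 1.5, endWindow = 500),
    seed = 102)
  profE <- foreignProfiles(expE$snapshots[[1]]$populationA, imaging,
    seed = 103)
  expect_gt(endCentreRatio(positionalInsertionProfile(profE)), 2)

  emptyProf <- new("DensityProfile", fibreId = "e", channel = "cy5",
    binWidth = 25, binStarts = (0:99) * 25, counts = rep(0, 100))
  expect_error(positionalInsertionProfile(c(profR[1:9],
    list(emptyProf))), "no foreign localizations")
  expect_error(positionalInsertionProfile(profR[1:5]), ">= 10 fibres")
})

test_that("bundling is detected as simultaneous two-channel occupancy", {
  bb <- sampleBackbone(FibreSpec(4000, 1e9, startPoint = c(500, 500)),
    seed = 104)
  imaging <- ImagingModel(sigmaLoc = 20, muLoc = 3, backgroundDensity = 0)
  mk <- function(channel, seed) {
    s <- placeLabels(bb, LabelField(0.15), seed = seed)
    tab <- simulateLocalizations(s, imaging, bb, channel = channel,
      channels = c("cy3", "cy5"), seed = seed + 1)
    proj <- quietly(projectToBackbone(tab, bb))
    densityProfile(proj, channel = channel, fibreId = "b")
  }
  pG <- mk("cy3", 105)
  pR <- mk("cy5", 107)
  # a two-colour bundle: both channels occupy the same backbone
  expect_gt(bundleOverlap(pG, pR), 0.8)

  # a single-colour fibre shows no overlap
  pEmpty <- new("DensityProfile", fibreId = "b", channel = "cy5",
    binWidth = 25, binStarts = binStarts(pG), counts = 0 * profileCounts(pG))
  expect_identical(bundleOverlap(pG, pEmpty), 0)
  expect_error(bundleOverlap(pEmpty, pEmpty), "all-empty")

  # an unmixed two-population sample at t ~ 0: no fibre flagged as bundle
  exp0 <- simulateExchangeExperiment(10, times = 0,
    fieldA = LabelField(0.15), fieldB = LabelField(0.15),
    xm = ExchangeModel("random_insertion", k = 0.3), seed = 108)
  overlaps <- vapply(exp0$snapshots[[1]]$populationA, function(f) {
    tab <- imageFibre(f, imaging)
    bbr <- resampleBackbone(f$backbone, 25)
    proj <- quietly(projectToBackbone(tab, bbr))
    gg <- densityProfile(proj, channel = "cy3", fibreId = f$fibreId)
    rr <- densityProfile(proj, channel = "cy5", fibreId = f$fibreId)
    bundleOverlap(gg, rr)
  }, numeric(1))
  expect_gte(mean(overlaps <= 0.5), 0.95)
})

test_that("mechanism signatures classify single replicates correctly", {
  expect_identical(
    mechanismReplicate("random_insertion", seed = 110)$mechanism,
    "random_insertion")
  expect_identical(
    mechanismReplicate("end_exchange", seed = 111)$mechanism,
    "end_exchange")
  expect_identical(
    mechanismReplicate("fragmentation_recombination", seed = 112)$mechanism,
    "fragmentation_recombination")
})
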