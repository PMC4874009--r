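test_that("worm-like-chain backbones honour the rigid-rod limit and the arc-length contract", {
  bb <- sampleBackbone(FibreSpec(5000, persistenceLength = 1e9), seed = 1)
  v <- vertices(bb)
  ee <- sqrt(sum((v[nrow(v), ] - v[1, ])^2))
  expect_equal(ee, 5000, tolerance = 1 / 5000)
  expect_lt(abs(backboneLength(bb) - 5000) / 5000, 0.005)
  expect_lte(max(diff(arcLengths(bb))), 10)

  expect_error(sampleBackbone(FibreSpec(0)), "contourLength")
  expect_error(FibreSpec(5000, persistenceLength = -1), "persistenceLength")
  expect_error(sampleBackbone(FibreSpec(5000), step = 50), "step")
})

test_that("mean squared end-to-end distance matches the closed-form WLC oracle", {
  set.seed(42)
  R2 <- replicate(600, {
    b <- sampleBackbone(FibreSpec(4000, persistenceLength = 4000))
    v <- vertices(b)
    sum((v[nrow(v), ] - v[1, ])^2)
  })
  expect_equal(mean(R2), wlcMeanSquaredR(4000, 4000), tolerance = 0.05)
})

test_that("homogeneous labelling is a Poisson process with the stated intensity", {
  bb <- sampleBackbone(FibreSpec(10000, 1e9), seed = 2)
  set.seed(3)
  n <- replicate(200, length(placeLabels(bb, LabelField(0.02))))
  expect_gte(mean(n), 185)
  expect_lte(mean(n), 215)

  expect_identical(placeLabels(bb, LabelField(0)), numeric(0))
  expect_error(LabelField(0.02, m = 0.5), "r0 and alpha")
  expect_error(LabelField(-1), "meanLinearDensity")
})

test_that("the microdomain field has the damped-oscillation autocorrelation with a negative lobe", {
  F <- domainField(300, 500, seed = 4)
  s <- seq(0, 1e6, by = 5)
  f <- F(s)
  expect_lt(abs(mean(f)), 0.05)
  expect_equal(stats::var(f), 1, tolerance = 0.15)
  # direct pair-product autocorrelation of the intensity over a 1-mm fibre
  emp <- vapply(c(150, 450, 600, 750, 1050), function(lagnm) {
    k <- lagnm / 5
    mean(f[1:(length(f) - k)] * f[(1 + k):length(f)])
  }, numeric(1))
  # positive inside the domain, negative lobe between r0 and 3 r0
  expect_gt(emp[1], 0.2)
  expect_lt(emp[2], -0.05)
  expect_lt(emp[3], -0.05)
  expect_lt(emp[4], -0.02)
  expect_gt(emp[5], -0.05)    # recovered towards zero past 3 r0
})

test_that("overcounting and localization noise follow the imaging model", {
  bb <- sampleBackbone(FibreSpec(5000, 1e9), seed = 5)
  labels <- seq(50, 4950, length.out = 100)
  model <- ImagingModel(sigmaLoc = 20, muLoc = 3, backgroundDensity = 0)
  set.seed(6)
  tot <- replicate(100, nLocalizations(
    simulateLocalizations(labels, model, bb, channel = "cy3")))
  expect_gte(mean(tot), 285)
  expect_lte(mean(tot), 315)

  # single label at the origin: isotropic Gaussian of the stated width
  one <- Backbone(rbind(c(-1, 0), c(1, 0)))
  m1 <- ImagingModel(sigmaLoc = 20, muLoc = 10000,
    countDistribution = "deterministic", backgroundDensity = 0)
  tab <- simulateLocalizations(1, m1, one, seed = 7)
  d <- locData(tab)
  expect_equal(stats::sd(d$x), 20, tolerance = 0.5 / 20)
  expect_equal(stats::sd(d$y), 20, tolerance = 0.5 / 20)

  # no blinking: exactly one localization per label
  m2 <- ImagingModel(sigmaLoc = 20, muLoc = 1,
    countDistribution = "deterministic", backgroundDensity = 0)
  tab2 <- simulateLocalizations(labels, m2, bb, seed = 8)
  expect_identical(as.integer(table(locData(tab2)$labelId)), rep(1L, 100))
  expect_error(ImagingModel(sigmaLoc = 0), "sigmaLoc")
})

test_that("exchange kinetics follow the stated per-label law and conserve labels", {
  mkpop <- function(ch, seed) {
    set.seed(seed)
    lapply(1:10, function(i) list(fibreId = paste0(ch, i), backbone = NULL,
      length = 5000, s = sort(runif(200, 0, 5000)),
      channel = rep(ch, 200), inert = rep(FALSE, 200)))
  }
  popA <- mkpop("cy3", 10); popB <- mkpop("cy5", 11)

  # k = 0: identities unchanged for any t
  out0 <- applyExchange(popA, popB, ExchangeModel("random_insertion", k = 0),
    t = 100, seed = 12)
  expect_identical(lapply(out0$populationA, `[[`, "channel"),
    lapply(popA, `[[`, "channel"))

  # k t >> 1: foreign fraction -> 0.5 (binomial limit of the kinetics)
  out <- applyExchange(popA, popB, ExchangeModel("random_insertion", k = 5),
    t = 10, seed = 13)
  frac <- mean(unlist(lapply(out$populationA, `[[`, "channel")) == "cy5")
  expect_equal(frac, 0.5, tolerance = 0.02 / 0.5)
  # positions and counts invariant
  expect_identical(lapply(out$populationA, `[[`, "s"),
    lapply(popA, `[[`, "s"))

  # end exchange: swapped labels lie within the end window by construction
  oute <- applyExchange(popA, popB,
    ExchangeModel("end_exchange", k = 5, endWindow = 500), t = 10, seed = 14)
  for (i in seq_along(popA)) {
    swapped <- oute$populationA[[i]]$channel != popA[[i]]$channel
    ssw <- popA[[i]]$s[swapped]
    expect_true(all(ssw <= 500 | ssw >= 4500))
  }

  # inert labels never change identity
  popI <- lapply(popA, function(f) { f$inert[1:100] <- TRUE; f })
  outi <- applyExchange(popI, popB, ExchangeModel("random_insertion", k = 5),
    t = 10, seed = 15)
  for (i in seq_along(popI))
    expect_identical(outi$populationA[[i]]$channel[1:100],
      popI[[i]]$channel[1:100])

  # fragmentation-recombination conserves the total label count
  outf <- applyExchange(popA, popB,
    ExchangeModel("fragmentation_recombination", k = 0.5), t = 8, seed = 16)
  nIn <- sum(lengths(lapply(c(popA, popB), `[[`, "s")))
  nOut <- sum(lengths(lapply(c(outf$populationA, outf$populationB), `[[`, "s")))
  expect_identical(nIn, nOut)

  expect_error(ExchangeModel("osmosis"), "unknown mechanism")
  expect_error(applyExchange(popA, popA,
    ExchangeModel("random_insertion"), t = 1), "disjoint")
})

test_that("seeded simulations are bit-reproducible", {
  fields <- list(cy3 = LabelField(0.1, m = 0.8, r0 = 300, alpha = 500),
                 cy5 = LabelField(0.05))
  a <- simulateFibreField(3, fields, ImagingModel(), contourLength = 3000,
    seed = 99)
  b <- simulateFibreField(3, fields, ImagingModel(), contourLength = 3000,
    seed = 99)
  expect_identical(locData(a$table), locData(b$table))
})

test_that("inert segments are contiguous blocks covering the requested fraction", {
  set.seed(20)
  s <- runif(5000, 0, 1e5)
  inert <- assignInertSegments(s, 1e5, 0.3, segmentLength = 500, seed = 21)
  expect_equal(mean(inert), 0.3, tolerance = 0.25)
  expect_identical(assignInertSegments(s, 1e5, 0), rep(FALSE, 5000))
  expect_identical(assignInertSegments(s, 1e5, 1), rep(TRUE, 5000))
  expect_error(assignInertSegments(s, 1e5, 1.2), "inertFraction")
})
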