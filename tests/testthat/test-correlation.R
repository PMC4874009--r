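mkProfile <- function(counts, binWidth = 25, channel = "cy3", id = "f") {
  new("DensityProfile", fibreId = id, channel = channel,
    binWidth = binWidth, binStarts = (seq_along(counts) - 1) * binWidth,
    counts = as.numeric(counts))
}

test_that("unbiased autocovariance normalized by the squared mean", {
  g <- autocorrelate(mkProfile(c(1, 2, 3)))
  expect_identical(lags(g), c(0, 25, 50))
  expect_equal(values(g), c(1 / 6, 0, -0.25))

  gconst <- autocorrelate(mkProfile(rep(5, 40)))
  expect_true(all(values(gconst) == 0))

  expect_error(autocorrelate(mkProfile(rep(0, 40))), "empty channel")
})

test_that("homogeneous Poisson profiles autocorrelate to zero beyond lag 0", {
  set.seed(72)
  curves <- lapply(1:50, function(i)
    autocorrelate(mkProfile(rpois(200, 4))))
  ens <- ensembleAverage(curves)
  pos <- lags(ens) >= 25 & lags(ens) <= 2000
  expect_lt(abs(mean(values(ens)[pos])), 0.005)
  # the 95% CI covers zero at >= 90% of positive lags
  expect_gte(mean(abs(values(ens)[pos]) <= ci95(ens)[pos]), 0.9)
})

test_that("cross-correlation is zero against a constant, equals autocorrelation for identical channels, and is symmetric", {
  set.seed(72)
  a <- mkProfile(rpois(100, 5))
  b <- mkProfile(rep(3, 100), channel = "cy5")
  expect_true(all(values(crosscorrelate(a, b)) == 0))

  expect_equal(values(crosscorrelate(a, a)), values(autocorrelate(a)))

  c2 <- mkProfile(rpois(100, 5), channel = "cy5")
  expect_equal(values(crosscorrelate(a, c2)), values(crosscorrelate(c2, a)))

  expect_error(crosscorrelate(a, mkProfile(rpois(60, 5))), "binning mismatch")
})

test_that("independent channels cross-correlate to zero across the lag range", {
  set.seed(73)
  curves <- lapply(1:40, function(i)
    crosscorrelate(mkProfile(rpois(160, 4)),
                   mkProfile(rpois(160, 4), channel = "cy5")))
  ens <- ensembleAverage(curves)
  covered <- abs(values(ens)) <= ci95(ens)
  expect_gte(mean(covered), 0.9)
  expect_lt(abs(mean(values(ens))), 0.01)
})

test_that("ensemble averages carry per-lag n and t-based confidence intervals", {
  cur <- fibrestorm:::CorrelationCurve(c(0, 25), c(0.5, -0.2))
  same <- ensembleAverage(list(cur, cur, cur))
  expect_equal(values(same), values(cur))
  expect_equal(ci95(same), c(0, 0))
  expect_identical(nFibres(same), c(3L, 3L))

  two <- ensembleAverage(list(
    fibrestorm:::CorrelationCurve(0, 1),
    fibrestorm:::CorrelationCurve(0, -1)))
  expect_identical(values(two), 0)
  # SE across fibres is 1, so the CI half-width is t_{0.975,1}
  expect_equal(ci95(two), stats::qt(0.975, 1))

  single <- ensembleAverage(list(cur))
  expect_true(all(is.na(ci95(single))))

  # fibres of different lengths: n(r) is non-increasing in r
  set.seed(74)
  mixed <- ensembleAverage(lapply(c(60, 100, 160), function(n)
    autocorrelate(mkProfile(rpois(n, 4)))))
  expect_true(all(diff(nFibres(mixed)) <= 0))
})

test_that("the pair-distance oracle sees isolated separations and the Poisson null", {
  g <- pairDistanceOracle(c(0, 100), D = 25, L = 1000)
  nz <- which(values(g) > -1 + 1e-9)
  expect_identical(lags(g)[values(g) == max(values(g))], 100)
  expect_true(all(values(g)[lags(g) != 100] <= 0))

  set.seed(75)
  s <- runif(1e4, 0, 1e4)
  go <- pairDistanceOracle(s, D = 25, L = 1e4)
  pos <- lags(go) > 0 & lags(go) <= 2000
  npairs <- length(s) * (length(s) - 1) / 2
  expected <- npairs * 2 * 25 / 1e4 * (1 - lags(go)[pos] / 1e4)
  se <- sqrt(expected) / expected
  expect_true(all(abs(values(go)[pos]) < 3 * se))
})

test_that("autocorrelate and the pair-distance oracle agree on the same fibres", {
  set.seed(76)
  ga.l <- list(); go.l <- list()
  for (i in 1:20) {
    bb <- sampleBackbone(FibreSpec(5000, 1e9))
    s <- placeLabels(bb, LabelField(0.1, m = 0.8, r0 = 300, alpha = 500))
    mu <- 1 + rgeom(length(s), 1 / 3)
    sl <- rep(s, mu) + rnorm(sum(mu), 0, 20)
    sl <- sl[sl >= 0 & sl <= 5000]
    ga.l[[i]] <- autocorrelate(densityProfile(data.frame(s = sl), L = 5000),
      kMax = 1000)
    go.l[[i]] <- pairDistanceOracle(sl, D = 25, L = 5000, kMax = 1000)
  }
  # per-fibre mean absolute difference over lags 50-1000 nm
  perFibre <- vapply(1:20, function(i) {
    sel <- lags(ga.l[[i]]) >= 50 & lags(ga.l[[i]]) <= 1000
    mean(abs(values(ga.l[[i]])[sel] -
      values(go.l[[i]])[lags(go.l[[i]]) %in% lags(ga.l[[i]])[sel]]))
  }, numeric(1))
  expect_lt(stats::median(perFibre), 0.05)
  # ensemble level: the two estimators agree within Monte-Carlo error
  ea <- ensembleAverage(ga.l); eo <- ensembleAverage(go.l)
  sel <- lags(ea) >= 50 & lags(ea) <= 1000
  dd <- values(ea)[sel] - values(eo)[lags(eo) %in% lags(ea)[sel]]
  se <- ci95(ea)[sel] / stats::qt(0.975, nFibres(ea)[sel] - 1)
  expect_gte(mean(abs(dd) <= pmax(0.05, 2 * se)), 0.95)
})
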