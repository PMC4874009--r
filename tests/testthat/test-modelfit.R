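# ensemble-style curve with constant weights built from exact model values
exactCurve <- function(values, lag = seq(25, 2000, by = 25), se = 0.01,
                       n = 10L) {
  fibrestorm:::CorrelationCurve(lag = lag, value = values, nFibres = n,
    ci95 = se * stats::qt(0.975, n - 1))
}

test_that("noise-free generative curves are recovered exactly", {
  r <- seq(25, 2000, by = 25)
  c1 <- exactCurve(overcountingModel(r, 0.5, 40))
  f1 <- fitOvercounting(c1)
  expect_equal(f1@amplitude, 0.5, tolerance = 1e-6)
  expect_equal(f1@sigma, 40, tolerance = 1e-6)
  expect_lt(f1@chisq, 1e-8)

  c2 <- exactCurve(microemulsionModel(r, 0.3, 20, 0.2, 300, 500))
  f2 <- fitMicroemulsion(c2)
  expect_equal(f2@amplitude, 0.3, tolerance = 1e-4)
  expect_equal(f2@sigma, 20, tolerance = 1e-4)
  expect_equal(f2@domainAmplitude, 0.2, tolerance = 1e-4)
  expect_equal(f2@r0, 300, tolerance = 1e-4)
  expect_equal(f2@alpha, 500, tolerance = 1e-4)
})

test_that("a zero curve fits with vanishing amplitude and chi-squared", {
  cz <- exactCurve(rep(0, 80))
  fz <- fitOvercounting(cz)
  expect_lt(abs(fz@amplitude), 1e-6)
  expect_lt(fz@chisq, 1e-8)
})

test_that("fixing B to zero reduces the micro-emulsion fit to the overcounting fit", {
  set.seed(81)
  r <- seq(25, 2000, by = 25)
  cur <- exactCurve(overcountingModel(r, 0.4, 30) + rnorm(length(r), 0, 0.01))
  oc <- fitOvercounting(cur)
  me <- fitMicroemulsion(cur, fixB = 0)
  expect_identical(me@domainAmplitude, 0)
  expect_identical(me@sigma, oc@sigma)
  expect_identical(me@amplitude, oc@amplitude)
  expect_identical(me@chisq, oc@chisq)
})

test_that("the micro-emulsion fit never exceeds the overcounting chi-squared (nesting)", {
  set.seed(82)
  r <- seq(25, 2000, by = 25)
  for (i in 1:5) {
    cur <- exactCurve(overcountingModel(r, runif(1, 0.1, 1),
      runif(1, 15, 60)) + rnorm(length(r), 0, 0.02), se = 0.02)
    f1 <- fitOvercounting(cur)
    f2 <- fitMicroemulsion(cur)
    expect_lte(f2@chisq, f1@chisq * (1 + 1e-8))
  }
})

test_that("model comparison follows the parsimony rule", {
  r <- seq(25, 2000, by = 25)
  cur <- exactCurve(overcountingModel(r, 0.5, 30))
  f1 <- fitOvercounting(cur)
  f2 <- fitMicroemulsion(cur)
  cmp <- compareFits(f1, f2)
  # both chi-squared vanish on the shared generative curve: ratio ~ 1 and
  # the simpler model is adopted
  expect_identical(cmp@selected, "overcounting")

  cur2 <- exactCurve(microemulsionModel(r, 0.3, 20, 0.3, 300, 500),
    se = 0.005)
  cmp2 <- compareFits(fitOvercounting(cur2), fitMicroemulsion(cur2))
  expect_gte(cmp2@ratio, 3.5)
  expect_identical(cmp2@selected, "microemulsion")

  bad <- new("OvercountingFit", amplitude = 1, sigma = 10,
    se = c(A = NA_real_, sigma = NA_real_), chisq = 1, df = 10L,
    converged = FALSE)
  expect_error(compareFits(bad, fitMicroemulsion(cur2)), "converged")
})

test_that("fitted parameters recover generative truth at the profile level", {
  # 10 independent label-position ensembles per condition; median relative
  # errors of (sigma, r0, alpha) stay within 20%
  set.seed(83)
  errs <- replicate(10, {
    curves <- lapply(1:15, function(i) {
      bb <- sampleBackbone(FibreSpec(5000, 1e9))
      s <- placeLabels(bb, LabelField(0.15, m = 0.8, r0 = 300, alpha = 500))
      mu <- 1 + rgeom(length(s), 1 / 3)
      sl <- rep(s, mu) + rnorm(sum(mu), 0, 20)
      autocorrelate(densityProfile(data.frame(s = sl[sl >= 0 & sl <= 5000]),
        L = 5000))
    })
    f <- fitMicroemulsion(ensembleAverage(curves), fitRange = c(50, 1500))
    c(abs(f@r0 - 300) / 300, abs(f@alpha - 500) / 500)
  })
  expect_lte(stats::median(errs[1, ]), 0.2)
  expect_lte(stats::median(errs[2, ]), 0.2)

  # homogeneous condition: sigma of the overcounting model estimates the
  # localization precision
  sig <- replicate(10, {
    curves <- lapply(1:15, function(i) {
      bb <- sampleBackbone(FibreSpec(5000, 1e9))
      s <- placeLabels(bb, LabelField(0.15))
      mu <- 1 + rgeom(length(s), 1 / 3)
      sl <- rep(s, mu) + rnorm(sum(mu), 0, 20)
      autocorrelate(densityProfile(data.frame(s = sl[sl >= 0 & sl <= 5000]),
        L = 5000))
    })
    fitOvercounting(ensembleAverage(curves), fitRange = c(25, 1500))@sigma
  })
  expect_lte(stats::median(abs(sig - 20) / 20), 0.2)
})

test_that("the fitted microdomain model is anti-correlated at intermediate distances", {
  r <- seq(25, 2000, by = 25)
  f <- fitMicroemulsion(exactCurve(
    microemulsionModel(r, 0.3, 20, 0.25, 300, 500)))
  rr <- seq(300, 900, by = 10)
  pred <- microemulsionModel(rr, f@amplitude, f@sigma, f@domainAmplitude,
    f@r0, f@alpha)
  expect_lt(min(pred), 0)
  # the lobe sits around ~500 nm for 300-nm domains
  expect_lt(pred[rr == 500], 0)
})
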