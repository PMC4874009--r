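## Spatial auto- and cross-correlation of density profiles with unbiased
## normalization, ensemble averaging, and a brute-force pair-distance
## estimator used as an independent cross-check.

.autocov <- function(x, kmax) {
  N <- length(x)
  mu <- mean(x)
  dev <- x - mu
  vapply(0:kmax, function(k)
    sum(dev[1:(N - k)] * dev[(1 + k):N]) / (N - k), numeric(1))
}

#' Spatial autocorrelation of a density profile
#'
#' Unbiased autocovariance of the binned counts `x_1..x_N` with mean `mu`,
#' `C(k D) = (1/(N-k)) * sum_i (x_i - mu) (x_{i+k} - mu)`, normalized by the
#' squared mean: `g(k D) = C(k D) / mu^2`, so a homogeneous random profile
#' gives g = 0 at all positive lags. Computed for
#' `k = 0 .. min(N - 1, kMax / D)`.
#'
#' @param profile A [DensityProfile-class] with at least 8 bins.
#' @param kMax Largest lag in nm.
#' @return A [CorrelationCurve-class] (single fibre, CI undefined).
#' @examples
#' p <- new("DensityProfile", fibreId = "f", channel = "cy3", binWidth = 25,
#'   binStarts = c(0, 25, 50), counts = c(1, 2, 3))
#' values(autocorrelate(p))  # 0.1667, 0, -0.25
#' @export
autocorrelate <- function(profile, kMax = 2000) {
  stopifnot(is(profile, "DensityProfile"))
  x <- profileCounts(profile)
  N <- length(x)
  if (N < 3) stop("profile too short to correlate")
  mu <- mean(x)
  if (mu == 0) stop("empty channel: profile mean is zero")
  D <- binWidth(profile)
  kmax <- min(N - 1L, floor(kMax / D))
  C <- .autocov(x, kmax)
  CorrelationCurve(lag = (0:kmax) * D, value = C / mu^2)
}

#' Spatial cross-correlation of two channels on one fibre
#'
#' `C_AB(k D) = (1/(N-k)) * sum_i (a_i - mu_A) (b_{i+k} - mu_B)`, averaged
#' over lags `+k` and `-k` (i.e. symmetrized with `C_BA`), normalized by
#' `mu_A * mu_B`. Independent channel distributions give g_AB = 0 at all
#' lags.
#'
#' @param profileA,profileB [DensityProfile-class] objects for the same
#'   fibre on the same binning.
#' @param kMax Largest lag in nm.
#' @return A [CorrelationCurve-class].
#' @export
crosscorrelate <- function(profileA, profileB, kMax = 2000) {
  stopifnot(is(profileA, "DensityProfile"), is(profileB, "DensityProfile"))
  a <- profileCounts(profileA); b <- profileCounts(profileB)
  if (length(a) != length(b) || binWidth(profileA) != binWidth(profileB))
    stop("binning mismatch between channels")
  N <- length(a)
  if (N < 3) stop("profiles too short to correlate")
  muA <- mean(a); muB <- mean(b)
  if (muA <= 0 || muB <= 0) stop("empty channel: profile mean is zero")
  D <- binWidth(profileA)
  kmax <- min(N - 1L, floor(kMax / D))
  da <- a - muA; db <- b - muB
  cab <- vapply(0:kmax, function(k)
    sum(da[1:(N - k)] * db[(1 + k):N]) / (N - k), numeric(1))
  cba <- vapply(0:kmax, function(k)
    sum(db[1:(N - k)] * da[(1 + k):N]) / (N - k), numeric(1))
  CorrelationCurve(lag = (0:kmax) * D, value = (cab + cba) / 2 / (muA * muB))
}

#' Ensemble average of per-fibre correlation curves
#'
#' Per-lag unweighted mean over all fibres long enough to contribute that
#' lag; the 95% confidence half-width is `t_{0.975, n-1} * SE` across
#' fibres, and the per-lag fibre count `n(r)` is recorded. Fibres are
#' weighted equally regardless of length or localization count.
#'
#' @param curves List of [CorrelationCurve-class] objects on the same lag
#'   grid convention (multiples of one bin width).
#' @return A [CorrelationCurve-class]; a single input curve is returned
#'   as-is with its CI marked undefined.
#' @export
ensembleAverage <- function(curves) {
  stopifnot(length(curves) >= 1)
  if (length(curves) == 1L) {
    cur <- curves[[1]]
    return(CorrelationCurve(lags(cur), values(cur), nFibres = 1L,
      ci95 = NA_real_))
  }
  D <- unique(vapply(curves, function(cu) {
    l <- lags(cu); if (length(l) > 1) l[2] - l[1] else NA_real_
  }, numeric(1)))
  D <- D[is.finite(D)]
  if (length(unique(D)) > 1) stop("curves are on different lag grids")
  allLags <- sort(unique(unlist(lapply(curves, lags))))
  vals <- vapply(allLags, function(l) {
    v <- unlist(lapply(curves, function(cu) values(cu)[lags(cu) == l]))
    n <- length(v)
    ci <- if (n >= 2)
      stats::qt(0.975, n - 1) * stats::sd(v) / sqrt(n) else NA_real_
    c(mean(v), n, ci)
  }, numeric(3))
  CorrelationCurve(lag = allLags, value = vals[1, ],
    nFibres = as.integer(vals[2, ]), ci95 = vals[3, ])
}

#' Brute-force pair-distance correlation estimator
#'
#' Independent cross-check for [autocorrelate()]: the histogram of all
#' pairwise arc separations `|s_i - s_j|` in bins of width `D` centred on
#' the lags `k D`, divided by the expected pair count of a homogeneous
#' process of equal mean density on `[0, L]`, minus 1.
#'
#' @param s Arc positions (nm) of the localizations on one fibre.
#' @param D Bin width (nm).
#' @param L Fibre length (nm).
#' @param kMax Largest lag in nm.
#' @return A [CorrelationCurve-class].
#' @export
pairDistanceOracle <- function(s, D = 25, L = max(s), kMax = 2000) {
  n <- length(s)
  if (n < 2) stop("need >= 2 positions")
  pd <- abs(as.vector(stats::dist(s)))
  kmax <- min(floor((L - D / 2) / D), floor(kMax / D))
  lag <- (0:kmax) * D
  lo <- pmax(lag - D / 2, 0)
  hi <- pmin(lag + D / 2, L)
  obs <- vapply(seq_along(lag), function(i)
    sum(pd >= lo[i] & pd < hi[i]), numeric(1))
  npairs <- n * (n - 1) / 2
  expct <- npairs * ((L - lo)^2 - (L - hi)^2) / L^2
  CorrelationCurve(lag = lag, value = obs / expct - 1)
}
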