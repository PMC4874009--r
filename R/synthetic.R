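## Forward simulator: worm-like-chain fibres, microdomain-modulated labelling,
## STORM imaging artefacts (overcounting, localization noise, background) and
## molecular exchange between two fibre populations.

#' Sample a worm-like-chain fibre backbone
#'
#' Discretized 2-D worm-like chain: the backbone is a polyline of equal
#' segments whose heading increments are independent Gaussians with variance
#' `step / persistenceLength` (2-D convention, so the tangent--tangent
#' correlation decays as `exp(-arc / (2 * persistenceLength))`).
#'
#' @param spec A [FibreSpec-class].
#' @param step Target segment length in nm (<= 10); the actual step divides
#'   the contour length exactly.
#' @param seed Optional integer seed.
#' @return A [Backbone-class] whose total arc length equals the contour
#'   length.
#' @examples
#' bb <- sampleBackbone(FibreSpec(5000, persistenceLength = 1e9), seed = 1)
#' backboneLength(bb)
#' @export
sampleBackbone <- function(spec, step = 5, seed = NULL) {
  stopifnot(is(spec, "FibreSpec"))
  validObject(spec)
  if (step <= 0 || step > 10) stop("step must be in (0, 10] nm")
  if (!is.null(seed)) set.seed(seed)
  L <- spec@contourLength
  n <- max(2L, as.integer(ceiling(L / step)))
  h <- L / n
  dtheta <- stats::rnorm(n - 1L, 0, sqrt(h / spec@persistenceLength))
  theta <- spec@initialHeading + c(0, cumsum(dtheta))
  x <- spec@startPoint[1] + c(0, cumsum(h * cos(theta)))
  y <- spec@startPoint[2] + c(0, cumsum(h * sin(theta)))
  Backbone(cbind(x, y))
}

#' Closed-form worm-like-chain mean squared end-to-end distance
#'
#' With the 2-D convention used by [sampleBackbone()] the tangent correlation
#' decay length is `lambda = 2 * P`, and direct integration of
#' `<t(s) . t(s')> = exp(-|s - s'| / lambda)` gives
#' `<R^2> = 2 * lambda * L * (1 - (lambda / L) * (1 - exp(-L / lambda)))`.
#'
#' @param L Contour length (nm).
#' @param P Persistence length (nm), 2-D convention.
#' @return Expected squared end-to-end distance (nm^2).
#' @export
wlcMeanSquaredR <- function(L, P) {
  lam <- 2 * P
  2 * lam * L * (1 - (lam / L) * (1 - exp(-L / lam)))
}

#' Stationary microdomain modulation field
#'
#' Spectral synthesis of a zero-mean, unit-variance stationary random field
#' `F(s)` whose autocorrelation is the damped oscillation
#' `exp(-d / alpha) * cos(pi * d / (2 * r0))`: a superposition of `K` cosines
#' with uniform random phases and angular frequencies drawn from the matching
#' Lorentzian-pair spectral density (Cauchy offsets of scale `1/alpha` around
#' `+/- pi/(2*r0)`). Generator and fitter thus share one functional family.
#'
#' @param r0 Mean microdomain size (nm).
#' @param alpha Coherence length (nm).
#' @param K Number of spectral components.
#' @param seed Optional integer seed.
#' @return A function `F(s)` mapping arc positions (nm) to field values.
#' @examples
#' F <- domainField(300, 500, seed = 1)
#' var(F(seq(0, 1e5, by = 5)))  # ~ 1
#' @export
domainField <- function(r0, alpha, K = 256L, seed = NULL) {
  if (!is.finite(r0) || r0 <= 0 || !is.finite(alpha) || alpha <= 0)
    stop("r0 and alpha must be positive")
  if (!is.null(seed)) set.seed(seed)
  omega0 <- pi / (2 * r0)
  omega <- sample(c(-1, 1), K, replace = TRUE) * omega0 +
    stats::rcauchy(K, location = 0, scale = 1 / alpha)
  phase <- stats::runif(K, 0, 2 * pi)
  amp <- sqrt(2 / K)
  function(s) {
    out <- numeric(length(s))
    # chunked so very long fibres do not allocate a huge outer product
    chunk <- 20000L
    for (i0 in seq(1L, length(s), by = chunk)) {
      idx <- i0:min(i0 + chunk - 1L, length(s))
      out[idx] <- amp * as.vector(cos(outer(s[idx], omega) +
        rep(phase, each = length(idx))) %*% rep(1, K))
    }
    out
  }
}

#' Place fluorescent labels along a backbone
#'
#' Labels are drawn from an inhomogeneous Poisson process with intensity
#' `lambda(s) = lambda0 * (1 + m * F(s))`, clipped at zero, where `F` is the
#' [domainField()] modulation. `m = 0` gives homogeneous Poisson labelling
#' (the Cy5-like case); `m > 0` produces microdomains richer in the labelled
#' monomer (the Cy3-like case).
#'
#' @param backbone A [Backbone-class].
#' @param field A [LabelField-class].
#' @param seed Optional integer seed.
#' @param ds Arc discretization (nm) used to sample the inhomogeneous
#'   process when `m > 0`.
#' @return Sorted numeric vector of label arc positions (nm).
#' @export
placeLabels <- function(backbone, field, seed = NULL, ds = 5) {
  stopifnot(is(backbone, "Backbone"), is(field, "LabelField"))
  validObject(field)
  if (!is.null(seed)) set.seed(seed)
  L <- backboneLength(backbone)
  lam0 <- field@meanLinearDensity
  if (lam0 == 0) return(numeric(0))
  if (field@m == 0) {
    n <- stats::rpois(1, lam0 * L)
    return(sort(stats::runif(n, 0, L)))
  }
  F <- domainField(field@r0, field@alpha)
  grid <- seq(0, L - ds, by = ds)
  lam <- pmax(0, lam0 * (1 + field@m * F(grid + ds / 2)))
  counts <- stats::rpois(length(grid), lam * ds)
  s <- rep(grid, counts) + stats::runif(sum(counts), 0, ds)
  sort(s)
}

## interpolate points at arc positions s along a backbone polyline
.pointOnBackbone <- function(bb, s) {
  arc <- bb@arc
  v <- bb@vertices
  seg <- findInterval(s, arc, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), nrow(v) - 1L)
  frac <- (s - arc[seg]) / (arc[seg + 1L] - arc[seg])
  v[seg, , drop = FALSE] +
    (v[seg + 1L, , drop = FALSE] - v[seg, , drop = FALSE]) * frac
}

#' Resample a backbone at a coarser regular arc step
#'
#' @param bb A [Backbone-class].
#' @param step New vertex spacing (nm).
#' @return A [Backbone-class] with vertices at multiples of `step` (the
#'   original endpoints are kept).
#' @export
resampleBackbone <- function(bb, step = 25) {
  stopifnot(is(bb, "Backbone"), step > 0)
  L <- backboneLength(bb)
  s <- unique(c(seq(0, L, by = step), L))
  Backbone(.pointOnBackbone(bb, s))
}

.localizationCounts <- function(nLabels, model) {
  switch(model@countDistribution,
    geometric = 1L + stats::rgeom(nLabels, prob = 1 / model@muLoc),
    poisson = stats::rpois(nLabels, model@muLoc),
    deterministic = rep(as.integer(round(model@muLoc)), nLabels))
}

#' Simulate STORM localizations for labels on a fibre
#'
#' Each label emits `N` localizations (`N` geometric, Poisson or
#' deterministic with mean `muLoc` — the overcounting of a blinking
#' fluorophore), each displaced from the label's 2-D position by isotropic
#' Gaussian noise of standard deviation `sigmaLoc`. Background localizations
#' are uniform over the field of view; frames are assigned uniformly at
#' random and carry no kinetic meaning.
#'
#' @param labels Numeric vector of label arc positions on `backbone` (nm).
#' @param model An [ImagingModel-class].
#' @param backbone The [Backbone-class] carrying the labels.
#' @param channel Channel identity per label (scalar or vector).
#' @param fibreId Fibre identifier recorded in the ground-truth columns.
#' @param background If `TRUE`, add uniform background localizations over the
#'   model's field of view (background rows have `labelId = NA`).
#' @param channels Declared channel set of the output table.
#' @param seed Optional integer seed.
#' @return A [LocalizationTable-class] with ground-truth columns `fibreId`
#'   and `labelId`.
#' @export
simulateLocalizations <- function(labels, model, backbone,
                                  channel = "cy3", fibreId = "f1",
                                  background = TRUE,
                                  channels = sort(unique(channel)),
                                  seed = NULL) {
  stopifnot(is(model, "ImagingModel"), is(backbone, "Backbone"))
  validObject(model)
  if (!is.null(seed)) set.seed(seed)
  if (length(labels) && (any(labels < 0) ||
      any(labels > backboneLength(backbone) + 1e-6)))
    stop("labels must lie on the backbone")
  channel <- rep_len(as.character(channel), length(labels))
  nl <- length(labels)
  counts <- if (nl) .localizationCounts(nl, model) else integer(0)
  total <- sum(counts)
  if (total) {
    xy <- .pointOnBackbone(backbone, rep(labels, counts))
    x <- xy[, 1] + stats::rnorm(total, 0, model@sigmaLoc)
    y <- xy[, 2] + stats::rnorm(total, 0, model@sigmaLoc)
    d <- data.frame(x = x, y = y,
      frame = sample.int(model@nFrames, total, replace = TRUE) - 1L,
      channel = rep(channel, counts),
      precision = model@sigmaLoc,
      fibreId = fibreId,
      labelId = rep(seq_len(nl), counts))
  } else {
    d <- data.frame(x = numeric(0), y = numeric(0), frame = integer(0),
      channel = character(0), precision = numeric(0),
      fibreId = character(0), labelId = integer(0))
  }
  if (background && model@backgroundDensity > 0) {
    d <- rbind(d, .backgroundTable(model, channels))
  }
  LocalizationTable(d, channels = channels)
}

## uniform background localizations over the field of view
.backgroundTable <- function(model, channels) {
  fov <- model@fieldOfView
  areaUm2 <- (fov[2] - fov[1]) * (fov[4] - fov[3]) / 1e6
  nb <- stats::rpois(1, model@backgroundDensity * areaUm2)
  data.frame(x = stats::runif(nb, fov[1], fov[2]),
    y = stats::runif(nb, fov[3], fov[4]),
    frame = sample.int(model@nFrames, nb, replace = TRUE) - 1L,
    channel = sample(channels, nb, replace = TRUE),
    precision = rep(model@sigmaLoc, nb),
    fibreId = rep(NA_character_, nb), labelId = rep(NA_integer_, nb))
}

#' Assign contiguous inert segments along a fibre
#'
#' Inert (non-exchanging) segments are placed as contiguous arc-length blocks
#' of the stated length until the requested fraction of the contour is
#' covered; labels inside any block never change identity under exchange.
#'
#' @param labelS Label arc positions (nm).
#' @param L Fibre contour length (nm).
#' @param inertFraction Target covered fraction of arc length, in `[0, 1]`.
#' @param segmentLength Block length (nm).
#' @param seed Optional integer seed.
#' @return Logical vector flagging labels inside inert blocks.
#' @export
assignInertSegments <- function(labelS, L, inertFraction,
                                segmentLength = 500, seed = NULL) {
  if (inertFraction < 0 || inertFraction > 1)
    stop("inertFraction must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (inertFraction == 0 || !length(labelS))
    return(rep(FALSE, length(labelS)))
  if (inertFraction >= 1) return(rep(TRUE, length(labelS)))
  seg <- min(segmentLength, L)
  nBlocks <- max(1L, round(inertFraction * L / seg))
  starts <- stats::runif(nBlocks, 0, L - seg)
  inert <- rep(FALSE, length(labelS))
  for (a in starts) inert <- inert | (labelS >= a & labelS < a + seg)
  inert
}

## a labelled-fibre population is a list of fibres:
##   list(fibreId, backbone (or NULL after recombination), length,
##        s, channel, inert)
.asPopulation <- function(x) {
  lapply(seq_along(x), function(i) {
    f <- x[[i]]
    if (is.null(f$length))
      f$length <- backboneLength(f$backbone)
    if (is.null(f$inert)) f$inert <- rep(FALSE, length(f$s))
    if (is.null(f$fibreId)) f$fibreId <- paste0("f", i)
    f
  })
}

#' Apply a molecular-exchange mechanism to two fibre populations
#'
#' Evolves per-label channel identities of two initially single-colour fibre
#' populations mixed 1:1 for `t` hours.
#'
#' * `random_insertion`: every non-inert label independently exchanges with
#'   probability `1 - exp(-k t)` against the common monomer pool (50/50 after
#'   mixing) — expulsion and reinclusion anywhere along the fibre.
#' * `end_exchange`: identical kinetics, but only labels within `endWindow`
#'   of either fibre end are exchangeable.
#' * `fragmentation_recombination`: scission events at rate `k` per fibre per
#'   hour at uniform arc positions; all fragments from both populations are
#'   re-joined by uniform random pairing into fibres of the original lengths,
#'   leaving a block-like label pattern.
#'
#' Label positions and per-fibre counts are invariant under the first two
#' mechanisms; fragmentation permutes whole blocks of labels.
#'
#' @param populationA,populationB Lists of fibres, each
#'   `list(fibreId, backbone, s, channel, inert)` (as produced by
#'   [simulateExchangeExperiment()] internals or built by hand); the two
#'   populations must start with disjoint channel sets.
#' @param xm An [ExchangeModel-class].
#' @param t Elapsed time in hours (>= 0).
#' @param seed Optional integer seed.
#' @return `list(populationA, populationB)` with updated channel identities
#'   (and, for fragmentation, recombined label blocks; recombined fibres have
#'   `backbone = NULL`).
#' @export
applyExchange <- function(populationA, populationB, xm, t, seed = NULL) {
  stopifnot(is(xm, "ExchangeModel"))
  validObject(xm)
  if (t < 0) stop("t must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  popA <- .asPopulation(populationA)
  popB <- .asPopulation(populationB)
  chA <- unique(unlist(lapply(popA, `[[`, "channel")))
  chB <- unique(unlist(lapply(popB, `[[`, "channel")))
  if (length(intersect(chA, chB)))
    stop("populations must have disjoint initial channels")
  pool <- c(chA, chB)
  if (xm@k == 0 || t == 0) return(list(populationA = popA, populationB = popB))

  if (xm@mechanism == "fragmentation_recombination")
    return(.fragmentRecombine(popA, popB, xm, t))

  p <- 1 - exp(-xm@k * t)
  swapFibre <- function(f) {
    n <- length(f$s)
    if (!n) return(f)
    eligible <- !f$inert
    if (xm@mechanism == "end_exchange") {
      if (xm@endWindow > f$length / 2)
        stop("endWindow must be <= half the contour length")
      eligible <- eligible &
        (f$s <= xm@endWindow | f$s >= f$length - xm@endWindow)
    }
    swap <- eligible & stats::runif(n) < p
    if (any(swap))
      f$channel[swap] <- sample(pool, sum(swap), replace = TRUE)
    f
  }
  list(populationA = lapply(popA, swapFibre),
       populationB = lapply(popB, swapFibre))
}

## fragmentation-recombination: cut every fibre at Pois(k t) uniform points,
## pool the fragments of both populations, and rebuild fibres of the original
## lengths from a random permutation of the fragment pool
.fragmentRecombine <- function(popA, popB, xm, t) {
  all <- c(popA, popB)
  frags <- list()
  for (f in all) {
    ncuts <- stats::rpois(1, xm@k * t)
    cuts <- sort(stats::runif(ncuts, 0, f$length))
    bounds <- c(0, cuts, f$length)
    for (j in seq_len(length(bounds) - 1L)) {
      keep <- f$s >= bounds[j] & f$s < bounds[j + 1L]
      frags[[length(frags) + 1L]] <- list(
        len = bounds[j + 1L] - bounds[j],
        s = f$s[keep] - bounds[j],
        channel = f$channel[keep],
        inert = f$inert[keep])
    }
  }
  frags <- frags[sample.int(length(frags))]
  targets <- vapply(all, `[[`, numeric(1), "length")
  rebuilt <- vector("list", length(all))
  fi <- 1L
  for (i in seq_along(targets)) {
    len <- 0; s <- numeric(0); channel <- character(0); inert <- logical(0)
    while (fi <= length(frags) &&
           (len < targets[i] || i == length(targets))) {
      fr <- frags[[fi]]; fi <- fi + 1L
      s <- c(s, fr$s + len); channel <- c(channel, fr$channel)
      inert <- c(inert, fr$inert); len <- len + fr$len
    }
    rebuilt[[i]] <- list(fibreId = all[[i]]$fibreId, backbone = NULL,
      length = len, s = s, channel = channel, inert = inert)
  }
  nA <- length(popA)
  list(populationA = rebuilt[seq_len(nA)],
       populationB = rebuilt[nA + seq_len(length(all) - nA)])
}

## ---------------------------------------------------------------------------
## Field- and experiment-level convenience generators
## ---------------------------------------------------------------------------

#' Simulate a two-colour field of labelled fibres
#'
#' Generates `nFibres` worm-like-chain fibres on a staggered grid (default
#' pitch keeps neighbouring fibres well separated), labels every fibre in
#' each declared channel with its [LabelField-class], images all labels with
#' one [ImagingModel-class] (field of view grown to cover the layout) and
#' adds uniform background.
#'
#' @param nFibres Number of fibres.
#' @param fields Named list of [LabelField-class] objects, one per channel
#'   (names are the channel tokens, e.g. `list(cy3 = ..., cy5 = ...)`).
#' @param imaging An [ImagingModel-class]; its field of view is replaced by
#'   the grid layout extent.
#' @param contourLength,persistenceLength Fibre geometry (nm).
#' @param spacing Grid pitch between fibre start points (nm); the default
#'   (2.2x the contour length) guarantees distinct fibres can never touch.
#' @param startPoints Optional n x 2 matrix of start points overriding the
#'   grid layout.
#' @param headings Optional numeric vector of initial headings (radians).
#' @param seed Optional integer seed.
#' @return `list(table, truth)`: the observable [LocalizationTable-class]
#'   (all fibres + background) and the [GroundTruth-class].
#' @export
simulateFibreField <- function(nFibres, fields, imaging = ImagingModel(),
                               contourLength = 5000,
                               persistenceLength = 10000,
                               spacing = 2.2 * contourLength,
                               startPoints = NULL, headings = NULL,
                               seed = NULL) {
  stopifnot(nFibres >= 1, length(fields) >= 1, !is.null(names(fields)))
  if (!is.null(seed)) set.seed(seed)
  channels <- names(fields)
  ncols <- ceiling(sqrt(nFibres))
  nrows <- ceiling(nFibres / ncols)
  if (is.null(startPoints)) {
    ij <- expand.grid(col = seq_len(ncols), row = seq_len(nrows))[seq_len(nFibres), ]
    startPoints <- cbind((ij$col - 0.5) * spacing, (ij$row - 0.5) * spacing)
    fov <- c(0, ncols * spacing, 0, nrows * spacing)
  } else {
    startPoints <- as.matrix(startPoints)
    pad <- contourLength
    fov <- c(min(startPoints[, 1]) - pad, max(startPoints[, 1]) + pad,
             min(startPoints[, 2]) - pad, max(startPoints[, 2]) + pad)
  }
  if (is.null(headings)) headings <- stats::runif(nFibres, 0, 2 * pi)
  imaging@fieldOfView <- fov

  fibres <- vector("list", nFibres)
  parts <- vector("list", 0L)
  for (i in seq_len(nFibres)) {
    fid <- sprintf("f%02d", i)
    bb <- sampleBackbone(FibreSpec(contourLength, persistenceLength,
      startPoint = startPoints[i, ], initialHeading = headings[i]))
    s <- numeric(0); channel <- character(0)
    for (ch in channels) {
      sc <- placeLabels(bb, fields[[ch]])
      s <- c(s, sc); channel <- c(channel, rep(ch, length(sc)))
    }
    tab <- simulateLocalizations(s, imaging, bb, channel = channel,
      fibreId = fid, background = FALSE, channels = channels)
    parts[[length(parts) + 1L]] <- locData(tab)
    fibres[[i]] <- list(fibreId = fid, backbone = bb, s = s,
      channel = channel, inert = rep(FALSE, length(s)))
  }
  parts[[length(parts) + 1L]] <- .backgroundTable(imaging, channels)
  d <- do.call(rbind, parts)
  list(table = LocalizationTable(d, channels = channels),
       truth = new("GroundTruth", fibres = fibres,
         params = list(fields = fields, imaging = imaging,
           contourLength = contourLength,
           persistenceLength = persistenceLength)))
}

#' Simulate a molecular-exchange time series
#'
#' For each requested time point an independent pair of single-colour fibre
#' populations is generated (mirroring aliquots withdrawn from a mixed
#' solution: different fibres are imaged at each time), inert segments are
#' assigned, the exchange mechanism is applied for the elapsed time, and the
#' evolved label populations are returned. Fragmentation--recombination
#' resamples backbones for the recombined fibres, whose original geometry is
#' no longer meaningful.
#'
#' @param nFibres Fibres per population per time point.
#' @param times Numeric vector of time points (hours).
#' @param fieldA,fieldB [LabelField-class] of the two populations (channels
#'   `channelA`/`channelB`).
#' @param xm An [ExchangeModel-class].
#' @param channelA,channelB Channel tokens of the two populations.
#' @param contourLength,persistenceLength Fibre geometry (nm).
#' @param seed Optional integer seed.
#' @return `list(times, snapshots)`; `snapshots[[i]]` holds `populationA`
#'   and `populationB` label populations at `times[i]` (every fibre carries a
#'   backbone).
#' @export
simulateExchangeExperiment <- function(nFibres, times, fieldA, fieldB, xm,
                                       channelA = "cy3", channelB = "cy5",
                                       contourLength = 5000,
                                       persistenceLength = 10000,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  makePop <- function(n, field, ch) {
    lapply(seq_len(n), function(i) {
      bb <- sampleBackbone(FibreSpec(contourLength, persistenceLength))
      s <- placeLabels(bb, field)
      list(fibreId = sprintf("%s_%02d", ch, i), backbone = bb,
        length = backboneLength(bb), s = s,
        channel = rep(ch, length(s)),
        inert = assignInertSegments(s, backboneLength(bb),
          xm@inertFraction, xm@inertSegmentLength))
    })
  }
  snapshots <- lapply(times, function(t) {
    popA <- makePop(nFibres, fieldA, channelA)
    popB <- makePop(nFibres, fieldB, channelB)
    out <- applyExchange(popA, popB, xm, t)
    # recombined fibres need fresh geometry for imaging
    out$populationA <- lapply(out$populationA, function(f) {
      if (is.null(f$backbone)) {
        f$backbone <- sampleBackbone(FibreSpec(max(f$length, 20),
          persistenceLength))
        f$length <- backboneLength(f$backbone)
      }
      f
    })
    out$populationB <- lapply(out$populationB, function(f) {
      if (is.null(f$backbone)) {
        f$backbone <- sampleBackbone(FibreSpec(max(f$length, 20),
          persistenceLength))
        f$length <- backboneLength(f$backbone)
      }
      f
    })
    out
  })
  list(times = times, snapshots = snapshots)
}

#' Image one labelled fibre from an exchange population
#'
#' Convenience wrapper: simulates localizations for all labels of a single
#' population fibre (both channels) on its backbone, without background.
#'
#' @param fibre One fibre entry of an exchange population.
#' @param imaging An [ImagingModel-class].
#' @param channels Declared channel set of the output table.
#' @param seed Optional integer seed.
#' @return A [LocalizationTable-class].
#' @export
imageFibre <- function(fibre, imaging, channels = c("cy3", "cy5"),
                       seed = NULL) {
  simulateLocalizations(fibre$s, imaging, fibre$backbone,
    channel = fibre$channel, fibreId = fibre$fibreId,
    background = FALSE, channels = channels, seed = seed)
}
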