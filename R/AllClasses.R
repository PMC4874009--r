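#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core data containers
## ---------------------------------------------------------------------------

#' LocalizationTable: single-molecule localization data
#'
#' The universal exchange format between pipeline stages: one row per
#' localization with planar coordinates in nanometres, the acquisition frame,
#' and the colour channel. Optional columns carry the localization precision
#' (`precision`, nm), the fibre cluster assignment filled in by
#' [clusterAndFilter()] (`clusterId`, `-1` = background) and, for simulated
#' data, the ground-truth parent ids (`fibreId`, `labelId`, `NA` = background).
#'
#' @slot data A `data.frame` with at least columns `x`, `y` (nm, finite),
#'   `frame` (integer, >= 0) and `channel`.
#' @slot channels Character vector, the declared channel set (e.g.
#'   `c("cy3", "cy5")`).
#'
#' @seealso [readLocalizations()], [simulateFibreField()]
#' @export
setClass("LocalizationTable",
  representation(data = "data.frame", channels = "character"))

setValidity("LocalizationTable", function(object) {
  d <- object@data
  msg <- character()
  need <- c("x", "y", "frame", "channel")
  miss <- setdiff(need, names(d))
  if (length(miss))
    return(sprintf("missing column: %s", paste(miss, collapse = ", ")))
  if (nrow(d)) {
    if (!all(is.finite(d$x)) || !all(is.finite(d$y)))
      msg <- c(msg, "coordinates must be finite")
    if (any(d$frame < 0, na.rm = TRUE))
      msg <- c(msg, "frame indices must be >= 0")
    if (!all(d$channel %in% object@channels))
      msg <- c(msg, sprintf("unknown channel token: %s",
        paste(setdiff(unique(d$channel), object@channels), collapse = ", ")))
    if ("precision" %in% names(d) &&
        any(!is.na(d$precision) & d$precision <= 0))
      msg <- c(msg, "precision must be > 0 where present")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a LocalizationTable
#'
#' @param data A `data.frame` with columns `x`, `y`, `frame`, `channel` and
#'   optionally `precision`, `clusterId`, `fibreId`, `labelId`.
#' @param channels Declared channel set; defaults to the channels present.
#' @return A [LocalizationTable-class] object.
#' @examples
#' tab <- LocalizationTable(data.frame(
#'   x = c(0, 50), y = c(0, 10), frame = 0:1, channel = "cy3"))
#' nLocalizations(tab)
#' @export
LocalizationTable <- function(data,
                              channels = sort(unique(as.character(data$channel)))) {
  data <- as.data.frame(data)
  if (nrow(data)) data$channel <- as.character(data$channel)
  new("LocalizationTable", data = data, channels = as.character(channels))
}

#' Backbone: ordered fibre centre line
#'
#' An ordered planar polyline with the cumulative arc length at every vertex;
#' the geometric reference frame for all one-dimensional statistics along a
#' fibre.
#'
#' @slot vertices Numeric matrix with columns `x`, `y` (nm).
#' @slot arc Numeric vector, cumulative arc length (nm) per vertex, starting
#'   at 0 and strictly increasing.
#' @seealso [traceBackbone()], [sampleBackbone()], [projectToBackbone()]
#' @export
setClass("Backbone", representation(vertices = "matrix", arc = "numeric"))

setValidity("Backbone", function(object) {
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2L) return("vertices must be an n x 2 matrix")
  if (nrow(v) < 2L) return("a backbone needs at least 2 vertices")
  if (length(object@arc) != nrow(v)) return("arc length per vertex required")
  if (any(diff(object@arc) <= 0)) return("arc length must be strictly increasing")
  if (object@arc[1] != 0) return("arc length must start at 0")
  TRUE
})

#' Construct a Backbone from an ordered vertex list
#'
#' Consecutive duplicate vertices are dropped; the cumulative arc length is
#' computed from the segment chord lengths.
#'
#' @param vertices Numeric matrix (or 2-column data.frame) of ordered vertex
#'   coordinates in nm.
#' @return A [Backbone-class] object.
#' @export
Backbone <- function(vertices) {
  v <- as.matrix(vertices)[, 1:2, drop = FALSE]
  storage.mode(v) <- "double"
  dimnames(v) <- list(NULL, c("x", "y"))
  seg <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
  keep <- c(TRUE, seg > 0)
  v <- v[keep, , drop = FALSE]
  seg <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
  new("Backbone", vertices = v, arc = c(0, cumsum(seg)))
}

#' DensityProfile: binned localization counts along a backbone
#'
#' Histogram of projected arc-length coordinates in half-open bins
#' `[k*binWidth, (k+1)*binWidth)` covering the whole backbone, per fibre and
#' per channel. The default bin width is 25 nm.
#'
#' @slot fibreId Identifier of the source fibre.
#' @slot channel Channel the profile was computed for.
#' @slot binWidth Bin width in nm.
#' @slot binStarts Left edges of the bins (nm).
#' @slot counts Localization counts per bin.
#' @seealso [densityProfile()], [autocorrelate()]
#' @export
setClass("DensityProfile",
  representation(fibreId = "character", channel = "character",
    binWidth = "numeric", binStarts = "numeric", counts = "numeric"))

setValidity("DensityProfile", function(object) {
  if (object@binWidth <= 0) return("bin width must be > 0")
  if (length(object@binStarts) != length(object@counts))
    return("binStarts and counts must have equal length")
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})

#' CorrelationCurve: spatial correlation versus lag
#'
#' A lag grid (multiples of the profile bin width) with dimensionless
#' correlation values g(r), the number of fibres contributing at each lag, and
#' 95% confidence half-widths (NA when undefined, e.g. for a single fibre).
#'
#' @slot lag Lags r in nm, non-negative, strictly increasing.
#' @slot value g(r) values; 0 for a homogeneous random profile at r > 0.
#' @slot nFibres Number of fibres contributing per lag.
#' @slot ci95 95% confidence-interval half-width per lag (NA if undefined).
#' @seealso [autocorrelate()], [crosscorrelate()], [ensembleAverage()]
#' @export
setClass("CorrelationCurve",
  representation(lag = "numeric", value = "numeric",
    nFibres = "integer", ci95 = "numeric"))

setValidity("CorrelationCurve", function(object) {
  n <- length(object@lag)
  if (length(object@value) != n || length(object@nFibres) != n ||
      length(object@ci95) != n)
    return("lag, value, nFibres and ci95 must have equal length")
  if (n && (any(object@lag < 0) || any(diff(object@lag) <= 0)))
    return("lags must be non-negative and strictly increasing")
  TRUE
})

CorrelationCurve <- function(lag, value, nFibres = 1L, ci95 = NA_real_) {
  n <- length(lag)
  new("CorrelationCurve", lag = as.numeric(lag), value = as.numeric(value),
    nFibres = rep_len(as.integer(nFibres), n),
    ci95 = rep_len(as.numeric(ci95), n))
}

#' FibreCandidate: one fibre cluster from segmentation
#'
#' @slot clusterId Integer cluster label (>= 1).
#' @slot members Integer indices of member rows in the source table.
#' @slot bbox Bounding box `c(xmin, xmax, ymin, ymax)` in nm.
#' @slot count Number of member localizations.
#' @slot elongation Principal-axis elongation ratio (sqrt of the eigenvalue
#'   ratio of the coordinate covariance), >= 1.
#' @seealso [clusterAndFilter()]
#' @export
setClass("FibreCandidate",
  representation(clusterId = "integer", members = "integer",
    bbox = "numeric", count = "integer", elongation = "numeric"))

setValidity("FibreCandidate", function(object) {
  if (anyDuplicated(object@members)) return("members must be unique")
  if (object@count != length(object@members)) return("count mismatch")
  if (length(object@bbox) != 4L) return("bbox must be c(xmin,xmax,ymin,ymax)")
  if (is.finite(object@elongation) && object@elongation < 1)
    return("elongation ratio must be >= 1")
  TRUE
})

#' GroundTruth: the simulator's generative record
#'
#' For each simulated fibre: the true backbone, the label arc positions, the
#' per-label channel identity and inert flag. Localization-level parentage
#' lives in the simulated table's `fibreId`/`labelId` columns. Used as the
#' recovery oracle in tests; never consumed by the analysis stages.
#'
#' @slot fibres List, one element per fibre:
#'   `list(fibreId, backbone, s, channel, inert)`.
#' @slot params List of the generative parameter objects.
#' @export
setClass("GroundTruth", representation(fibres = "list", params = "list"))

setValidity("GroundTruth", function(object) {
  for (f in object@fibres) {
    if (!all(c("fibreId", "backbone", "s", "channel") %in% names(f)))
      return("each fibre needs fibreId, backbone, s, channel")
    if (length(f$s) != length(f$channel))
      return("each label needs exactly one channel identity")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Generative parameter objects
## ---------------------------------------------------------------------------

#' FibreSpec: geometry of a simulated fibre
#'
#' @slot contourLength Contour length in nm (> 0); real PA fibres are
#'   micrometres long.
#' @slot persistenceLength Persistence length P in nm (> 0), 2-D convention:
#'   heading variance grows as arc/P, so the tangent correlation decays as
#'   exp(-arc/(2P)).
#' @slot startPoint Numeric length-2, start coordinates (nm).
#' @slot initialHeading Initial heading in radians.
#' @export
setClass("FibreSpec",
  representation(contourLength = "numeric", persistenceLength = "numeric",
    startPoint = "numeric", initialHeading = "numeric"))

setValidity("FibreSpec", function(object) {
  if (length(object@contourLength) != 1 || !is.finite(object@contourLength) ||
      object@contourLength <= 0)
    return("contourLength must be a single positive number")
  if (length(object@persistenceLength) != 1 || object@persistenceLength <= 0)
    return("persistenceLength must be > 0")
  if (length(object@startPoint) != 2) return("startPoint must be length 2")
  TRUE
})

#' @rdname FibreSpec-class
#' @param contourLength,persistenceLength,startPoint,initialHeading See slots.
#' @return A `FibreSpec` object.
#' @export
FibreSpec <- function(contourLength, persistenceLength = 10000,
                      startPoint = c(0, 0), initialHeading = 0) {
  new("FibreSpec", contourLength = contourLength,
    persistenceLength = persistenceLength,
    startPoint = as.numeric(startPoint),
    initialHeading = as.numeric(initialHeading))
}

#' LabelField: labelling intensity along a fibre
#'
#' Labels are placed by an inhomogeneous Poisson process with intensity
#' `lambda(s) = meanLinearDensity * (1 + m * F(s))` clipped at zero, where
#' `F` is a zero-mean unit-variance stationary random field whose
#' autocorrelation is the damped oscillation
#' `exp(-d/alpha) * cos(pi*d/(2*r0))` — the generative counterpart of the
#' micro-emulsion model fitted by [fitMicroemulsion()]. `m = 0` gives
#' homogeneous Poisson labelling (no microdomains).
#'
#' @slot meanLinearDensity Mean label density lambda0 in labels per nm (> 0,
#'   or 0 for an unlabelled channel).
#' @slot m Modulation depth in `[0, 1]`.
#' @slot r0 Mean microdomain size in nm (> 0 when `m > 0`).
#' @slot alpha Domain coherence length in nm (> 0 when `m > 0`).
#' @export
setClass("LabelField",
  representation(meanLinearDensity = "numeric", m = "numeric",
    r0 = "numeric", alpha = "numeric"))

setValidity("LabelField", function(object) {
  if (object@meanLinearDensity < 0) return("meanLinearDensity must be >= 0")
  if (object@m < 0 || object@m > 1) return("modulation depth m must be in [0, 1]")
  if (object@m > 0 && (!is.finite(object@r0) || object@r0 <= 0 ||
      !is.finite(object@alpha) || object@alpha <= 0))
    return("r0 and alpha must be positive when m > 0")
  TRUE
})

#' @rdname LabelField-class
#' @param meanLinearDensity,m,r0,alpha See slots.
#' @return A `LabelField` object.
#' @export
LabelField <- function(meanLinearDensity, m = 0, r0 = NA_real_,
                       alpha = NA_real_) {
  new("LabelField", meanLinearDensity = meanLinearDensity, m = m,
    r0 = as.numeric(r0), alpha = as.numeric(alpha))
}

#' ImagingModel: STORM acquisition artefacts
#'
#' Each label emits a random number of localizations (overcounting from
#' fluorophore blinking), displaced from the true label position by isotropic
#' Gaussian localization noise; background localizations are uniform over the
#' field of view.
#'
#' @slot sigmaLoc Localization precision in nm (> 0).
#' @slot muLoc Mean localizations per label (>= 1).
#' @slot countDistribution `"geometric"` (default; heavier tail, matches
#'   blinking), `"poisson"`, or `"deterministic"`.
#' @slot backgroundDensity Background localizations per square micrometre.
#' @slot fieldOfView Numeric length-4 `c(xmin, xmax, ymin, ymax)` in nm.
#' @slot nFrames Number of acquisition frames (frames carry no kinetic
#'   meaning in the simulator).
#' @export
setClass("ImagingModel",
  representation(sigmaLoc = "numeric", muLoc = "numeric",
    countDistribution = "character", backgroundDensity = "numeric",
    fieldOfView = "numeric", nFrames = "integer"))

setValidity("ImagingModel", function(object) {
  if (object@sigmaLoc <= 0) return("sigmaLoc must be > 0")
  if (object@muLoc < 1) return("muLoc must be >= 1")
  if (!object@countDistribution %in% c("geometric", "poisson", "deterministic"))
    return("countDistribution must be geometric, poisson or deterministic")
  if (object@backgroundDensity < 0) return("backgroundDensity must be >= 0")
  if (length(object@fieldOfView) != 4L) return("fieldOfView must be length 4")
  if (object@nFrames < 1L) return("nFrames must be >= 1")
  TRUE
})

#' @rdname ImagingModel-class
#' @param sigmaLoc,muLoc,countDistribution,backgroundDensity,fieldOfView,nFrames
#'   See slots.
#' @return An `ImagingModel` object.
#' @export
ImagingModel <- function(sigmaLoc = 20, muLoc = 3,
                         countDistribution = c("geometric", "poisson",
                                               "deterministic"),
                         backgroundDensity = 0.5,
                         fieldOfView = c(0, 10000, 0, 10000),
                         nFrames = 20000L) {
  new("ImagingModel", sigmaLoc = sigmaLoc, muLoc = muLoc,
    countDistribution = match.arg(countDistribution),
    backgroundDensity = backgroundDensity,
    fieldOfView = as.numeric(fieldOfView), nFrames = as.integer(nFrames))
}

#' ExchangeModel: monomer exchange mechanism and kinetics
#'
#' Candidate mechanisms for molecular exchange between fibres:
#' `random_insertion` (expulsion and reinclusion of monomers anywhere along
#' the fibre), `end_exchange` (polymerization--depolymerization confined to
#' within `endWindow` of the fibre ends) and `fragmentation_recombination`
#' (fibre scission and random re-joining of fragments, leaving a block-like
#' label pattern). Per-label kinetics are memoryless with a single rate `k`:
#' a label has exchanged by time t with probability `1 - exp(-k*t)`.
#' Contiguous inert segments (non-exchanging arc-length blocks) model locally
#' cohesive regions that resist exchange.
#'
#' @slot mechanism One of `"random_insertion"`, `"end_exchange"`,
#'   `"fragmentation_recombination"`.
#' @slot k Exchange rate per label per hour (scission events per fibre per
#'   hour for fragmentation), >= 0.
#' @slot endWindow Arc-length window from either fibre end within which
#'   labels are exchangeable (`end_exchange` only), nm.
#' @slot inertFraction Fraction of arc length assigned to inert contiguous
#'   segments, in `[0, 1]`.
#' @slot inertSegmentLength Mean inert segment length in nm.
#' @export
setClass("ExchangeModel",
  representation(mechanism = "character", k = "numeric",
    endWindow = "numeric", inertFraction = "numeric",
    inertSegmentLength = "numeric"))

setValidity("ExchangeModel", function(object) {
  mech <- c("random_insertion", "end_exchange", "fragmentation_recombination")
  if (!object@mechanism %in% mech)
    return(sprintf("unknown mechanism '%s'", object@mechanism))
  if (object@k < 0) return("rate k must be >= 0")
  if (object@inertFraction < 0 || object@inertFraction > 1)
    return("inertFraction must be in [0, 1]")
  if (object@mechanism == "end_exchange" &&
      (!is.finite(object@endWindow) || object@endWindow <= 0))
    return("endWindow must be > 0 for end_exchange")
  TRUE
})

#' @rdname ExchangeModel-class
#' @param mechanism,k,endWindow,inertFraction,inertSegmentLength See slots.
#' @return An `ExchangeModel` object.
#' @export
ExchangeModel <- function(mechanism = c("random_insertion", "end_exchange",
                                        "fragmentation_recombination"),
                          k = 0.1, endWindow = NA_real_, inertFraction = 0,
                          inertSegmentLength = 500) {
  mechanism <- if (is.character(mechanism) && length(mechanism) == 1 &&
                   !mechanism %in% eval(formals(ExchangeModel)$mechanism))
    mechanism else match.arg(mechanism)
  new("ExchangeModel", mechanism = mechanism, k = k,
    endWindow = as.numeric(endWindow), inertFraction = inertFraction,
    inertSegmentLength = inertSegmentLength)
}

## ---------------------------------------------------------------------------
## Model-fit result objects
## ---------------------------------------------------------------------------

#' OvercountingFit: overcounting-only model fit
#'
#' Weighted least-squares fit of `g(r) = A * exp(-r^2 / (4 sigma^2))` to an
#' ensemble correlation curve. The short-range Gaussian decay is the
#' signature of multiple localizations of the same dye; its standard
#' deviation `sigma` estimates the experimental resolution.
#'
#' @slot amplitude Fitted amplitude A.
#' @slot sigma Fitted sigma (nm).
#' @slot se Named numeric, 1-standard-error estimates of the parameters.
#' @slot chisq Weighted chi-squared of the fit.
#' @slot df Degrees of freedom (lags used minus parameters).
#' @slot converged Logical convergence flag.
#' @seealso [fitOvercounting()]
#' @export
setClass("OvercountingFit",
  representation(amplitude = "numeric", sigma = "numeric", se = "numeric",
    chisq = "numeric", df = "integer", converged = "logical"))

#' MicroemulsionFit: overcounting + microdomain model fit
#'
#' Weighted least-squares fit of
#' `g(r) = A*exp(-r^2/(4 sigma^2)) + B*exp(-r/alpha)*cos(pi*r/(2*r0))`,
#' where the first term is the overcounting contribution and the damped
#' oscillation describes microdomains of mean size `r0` with coherence
#' length `alpha`.
#'
#' @slot amplitude Fitted overcounting amplitude A.
#' @slot sigma Fitted sigma (nm).
#' @slot domainAmplitude Fitted domain amplitude B.
#' @slot r0 Fitted mean microdomain size (nm).
#' @slot alpha Fitted coherence length (nm).
#' @slot se Named numeric, 1-standard-error estimates.
#' @slot chisq Weighted chi-squared of the fit.
#' @slot df Degrees of freedom.
#' @slot converged Logical convergence flag.
#' @seealso [fitMicroemulsion()]
#' @export
setClass("MicroemulsionFit",
  representation(amplitude = "numeric", sigma = "numeric",
    domainAmplitude = "numeric", r0 = "numeric", alpha = "numeric",
    se = "numeric", chisq = "numeric", df = "integer", converged = "logical"))

#' ModelComparison: chi-squared comparison of the two correlation models
#'
#' @slot ratio chi-squared(overcounting) / chi-squared(micro-emulsion).
#' @slot selected `"microemulsion"` if the ratio reaches `threshold`, else
#'   `"overcounting"` (parsimony: adopt the simpler model unless the
#'   microdomain term improves the fit enough).
#' @slot threshold Selection threshold on the ratio.
#' @seealso [compareFits()]
#' @export
setClass("ModelComparison",
  representation(ratio = "numeric", selected = "character",
    threshold = "numeric"))
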