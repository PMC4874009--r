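## Accessor generics and show methods.

#' @name accessors
#' @title Accessors for fibrestorm data objects
#' @description Small accessor functions used instead of direct slot access.
#' @param object,x A fibrestorm S4 object.
#' @param ... Further arguments (unused).
#' @return The accessed component.
NULL

#' @rdname accessors
#' @export
setGeneric("nLocalizations", function(object) standardGeneric("nLocalizations"))

#' @rdname accessors
#' @export
setMethod("nLocalizations", "LocalizationTable",
  function(object) nrow(object@data))

#' @rdname accessors
#' @export
setGeneric("locData", function(object) standardGeneric("locData"))

#' @rdname accessors
#' @export
setMethod("locData", "LocalizationTable", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("locChannels", function(object) standardGeneric("locChannels"))

#' @rdname accessors
#' @export
setMethod("locChannels", "LocalizationTable", function(object) object@channels)

#' @export
#' @rdname accessors
setMethod("as.data.frame", "LocalizationTable",
  function(x, ...) x@data)

#' Subset a LocalizationTable by row
#' @param x A [LocalizationTable-class].
#' @param i Row index.
#' @param j,...,drop Ignored.
#' @return A [LocalizationTable-class] with the selected rows.
#' @export
setMethod("[", "LocalizationTable", function(x, i, j, ..., drop = FALSE) {
  initialize(x, data = x@data[i, , drop = FALSE], channels = x@channels)
})

#' @rdname accessors
#' @export
setGeneric("vertices", function(object) standardGeneric("vertices"))

#' @rdname accessors
#' @export
setMethod("vertices", "Backbone", function(object) object@vertices)

#' @rdname accessors
#' @export
setGeneric("arcLengths", function(object) standardGeneric("arcLengths"))

#' @rdname accessors
#' @export
setMethod("arcLengths", "Backbone", function(object) object@arc)

#' @rdname accessors
#' @export
setGeneric("backboneLength", function(object) standardGeneric("backboneLength"))

#' @rdname accessors
#' @export
setMethod("backboneLength", "Backbone",
  function(object) object@arc[length(object@arc)])

#' @rdname accessors
#' @export
setGeneric("profileCounts", function(object) standardGeneric("profileCounts"))

#' @rdname accessors
#' @export
setMethod("profileCounts", "DensityProfile", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("binWidth", function(object) standardGeneric("binWidth"))

#' @rdname accessors
#' @export
setMethod("binWidth", "DensityProfile", function(object) object@binWidth)

#' @rdname accessors
#' @export
setGeneric("binStarts", function(object) standardGeneric("binStarts"))

#' @rdname accessors
#' @export
setMethod("binStarts", "DensityProfile", function(object) object@binStarts)

#' @rdname accessors
#' @export
setGeneric("lags", function(object) standardGeneric("lags"))

#' @rdname accessors
#' @export
setMethod("lags", "CorrelationCurve", function(object) object@lag)

#' @rdname accessors
#' @export
setGeneric("values", function(object) standardGeneric("values"))

#' @rdname accessors
#' @export
setMethod("values", "CorrelationCurve", function(object) object@value)

#' @rdname accessors
#' @export
setGeneric("nFibres", function(object) standardGeneric("nFibres"))

#' @rdname accessors
#' @export
setMethod("nFibres", "CorrelationCurve", function(object) object@nFibres)

#' @rdname accessors
#' @export
setGeneric("ci95", function(object) standardGeneric("ci95"))

#' @rdname accessors
#' @export
setMethod("ci95", "CorrelationCurve", function(object) object@ci95)

#' @export
#' @rdname accessors
setMethod("as.data.frame", "CorrelationCurve", function(x, ...) {
  data.frame(lag_nm = x@lag, value = x@value, n_fibres = x@nFibres,
    ci95_halfwidth = x@ci95)
})

#' @export
#' @rdname accessors
setMethod("as.data.frame", "DensityProfile", function(x, ...) {
  data.frame(bin_start_nm = x@binStarts, value = x@counts,
    n_fibres = 1L, ci95_halfwidth = NA_real_)
})

#' @rdname accessors
#' @export
setGeneric("members", function(object) standardGeneric("members"))

#' @rdname accessors
#' @export
setMethod("members", "FibreCandidate", function(object) object@members)

#' @rdname accessors
#' @export
setGeneric("elongation", function(object) standardGeneric("elongation"))

#' @rdname accessors
#' @export
setMethod("elongation", "FibreCandidate", function(object) object@elongation)

#' @rdname accessors
#' @export
setGeneric("truthFibres", function(object) standardGeneric("truthFibres"))

#' @rdname accessors
#' @export
setMethod("truthFibres", "GroundTruth", function(object) object@fibres)

#' @rdname accessors
#' @export
setGeneric("chisq", function(object) standardGeneric("chisq"))

#' @rdname accessors
#' @export
setMethod("chisq", "OvercountingFit", function(object) object@chisq)

#' @rdname accessors
#' @export
setMethod("chisq", "MicroemulsionFit", function(object) object@chisq)

#' Fitted parameters of a correlation-model fit
#' @param object An [OvercountingFit-class] or [MicroemulsionFit-class].
#' @return Named numeric vector of fitted parameters.
#' @export
setMethod("coef", "OvercountingFit", function(object)
  c(A = object@amplitude, sigma = object@sigma))

#' @rdname coef-OvercountingFit-method
#' @export
setMethod("coef", "MicroemulsionFit", function(object)
  c(A = object@amplitude, sigma = object@sigma, B = object@domainAmplitude,
    r0 = object@r0, alpha = object@alpha))

## show methods -------------------------------------------------------------

setMethod("show", "LocalizationTable", function(object) {
  d <- object@data
  cat(sprintf("LocalizationTable with %d localizations, channels: %s\n",
    nrow(d), paste(object@channels, collapse = ", ")))
  if (nrow(d)) {
    tab <- table(d$channel)
    cat("  per channel:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
    if ("clusterId" %in% names(d))
      cat(sprintf("  clustered: %d fibres, %d background\n",
        length(setdiff(unique(d$clusterId), -1L)), sum(d$clusterId == -1L)))
  }
})

setMethod("show", "Backbone", function(object) {
  cat(sprintf("Backbone: %d vertices, arc length %.1f nm\n",
    nrow(object@vertices), backboneLength(object)))
})

setMethod("show", "DensityProfile", function(object) {
  cat(sprintf(
    "DensityProfile [fibre %s, channel %s]: %d bins of %.0f nm, %d counts\n",
    object@fibreId, object@channel, length(object@counts), object@binWidth,
    as.integer(sum(object@counts))))
})

setMethod("show", "CorrelationCurve", function(object) {
  cat(sprintf("CorrelationCurve: %d lags (%.0f..%.0f nm), max n = %d fibres\n",
    length(object@lag), min(object@lag), max(object@lag),
    if (length(object@nFibres)) max(object@nFibres) else 0L))
})

setMethod("show", "FibreCandidate", function(object) {
  cat(sprintf(
    "FibreCandidate %d: %d localizations, elongation %.1f, bbox [%.0f..%.0f] x [%.0f..%.0f] nm\n",
    object@clusterId, object@count, object@elongation,
    object@bbox[1], object@bbox[2], object@bbox[3], object@bbox[4]))
})

setMethod("show", "GroundTruth", function(object) {
  nl <- vapply(object@fibres, function(f) length(f$s), numeric(1))
  cat(sprintf("GroundTruth: %d fibres, %d labels total\n",
    length(object@fibres), as.integer(sum(nl))))
})

setMethod("show", "OvercountingFit", function(object) {
  cat(sprintf(
    "Overcounting model fit: A = %.4g, sigma = %.4g nm (chi2 = %.4g, df = %d, %s)\n",
    object@amplitude, object@sigma, object@chisq, object@df,
    if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "MicroemulsionFit", function(object) {
  cat(sprintf(
    "Micro-emulsion model fit: A = %.4g, sigma = %.4g nm, B = %.4g, r0 = %.4g nm, alpha = %.4g nm\n  (chi2 = %.4g, df = %d, %s)\n",
    object@amplitude, object@sigma, object@domainAmplitude, object@r0,
    object@alpha, object@chisq, object@df,
    if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "ModelComparison", function(object) {
  cat(sprintf(
    "Model comparison: chi2 ratio = %.3g (threshold %.2g) -> %s model\n",
    object@ratio, object@threshold, object@selected))
})
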