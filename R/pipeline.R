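## End-to-end convenience wrappers: localization table -> fibres ->
## profiles -> ensemble correlation curves.

#' Run segmentation, backbone tracing and profiling on a localization table
#'
#' Clusters the table, traces a backbone for every accepted candidate with
#' at least `minTraceLocs` localizations (the well-reconstructed-fibre
#' criterion), projects the member localizations and computes one density
#' profile per declared channel.
#'
#' @param table A [LocalizationTable-class].
#' @param eps,minPts,minSize,minElongation Segmentation parameters, see
#'   [clusterAndFilter()].
#' @param minTraceLocs Minimum localizations for backbone tracing.
#' @param grid Raster cell size for tracing (nm).
#' @param cutoff Projection cutoff (nm).
#' @param binWidth Profile bin width (nm).
#' @return `list(segmentation, fibres)`; each element of `fibres` is
#'   `list(fibreId, candidate, backbone, projected, profiles)` with
#'   `profiles` a named list (one [DensityProfile-class] per channel).
#' @examples
#' sim <- simulateFibreField(2, list(cy3 = LabelField(0.05)),
#'   ImagingModel(backgroundDensity = 0.2), contourLength = 3000, seed = 1)
#' res <- analyzeFibreTable(sim$table)
#' length(res$fibres)
#' @export
analyzeFibreTable <- function(table, eps = 100, minPts = 5, minSize = 100,
                              minElongation = 3, minTraceLocs = 300,
                              grid = 25, cutoff = 100, binWidth = 25) {
  seg <- clusterAndFilter(table, eps = eps, minPts = minPts,
    minSize = minSize, minElongation = minElongation)
  channels <- locChannels(table)
  fibres <- list()
  for (cand in seg$candidates) {
    if (cand@count < minTraceLocs) next
    bb <- tryCatch(traceBackbone(seg$table, cand, grid = grid,
      cutoff = cutoff), error = function(e) NULL)
    if (is.null(bb)) next
    proj <- projectToBackbone(seg$table, bb, candidate = cand,
      cutoff = cutoff)
    fid <- sprintf("fibre%02d", cand@clusterId)
    profiles <- lapply(channels, function(ch)
      densityProfile(proj, binWidth = binWidth, channel = ch,
        fibreId = fid))
    names(profiles) <- channels
    fibres[[length(fibres) + 1L]] <- list(fibreId = fid, candidate = cand,
      backbone = bb, projected = proj, profiles = profiles)
  }
  list(segmentation = seg, fibres = fibres)
}

#' Ensemble correlation curve over analyzed fibres
#'
#' Computes per-fibre spatial autocorrelation (one channel) or two-channel
#' cross-correlation (two channels) of the density profiles and averages
#' them with [ensembleAverage()]. Fibres whose relevant profile is empty
#' are skipped.
#'
#' @param fibres The `fibres` element of an [analyzeFibreTable()] result
#'   (or any list of entries with a `profiles` list).
#' @param channels One channel name for autocorrelation, two for
#'   cross-correlation.
#' @param kMax Largest lag (nm).
#' @return An ensemble [CorrelationCurve-class].
#' @export
ensembleCorrelation <- function(fibres, channels, kMax = 2000) {
  curves <- list()
  for (f in fibres) {
    cu <- tryCatch({
      if (length(channels) == 1L)
        autocorrelate(f$profiles[[channels]], kMax = kMax)
      else
        crosscorrelate(f$profiles[[channels[1]]], f$profiles[[channels[2]]],
          kMax = kMax)
    }, error = function(e) NULL)
    if (!is.null(cu)) curves[[length(curves) + 1L]] <- cu
  }
  if (!length(curves)) stop("no usable fibres for the requested channels")
  ensembleAverage(curves)
}

#' Per-fibre foreign-channel linear densities from analyzed fibres
#'
#' @param fibres The `fibres` element of an [analyzeFibreTable()] result.
#' @param channel Channel to measure.
#' @return Named numeric vector of linear densities (um^-1).
#' @export
fibreDensities <- function(fibres, channel) {
  out <- vapply(fibres, function(f)
    linearDensity(f$projected, f$backbone, channel = channel), numeric(1))
  names(out) <- vapply(fibres, `[[`, character(1), "fibreId")
  out
}
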