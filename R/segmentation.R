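## Fibre identification: density-based clustering of localizations with
## background removal and shape filtering.

## all point pairs within eps, found via an eps-sized grid (each point only
## needs to be compared with points in its own and the 8 neighbouring cells)
.epsPairs <- function(x, y, eps) {
  n <- length(x)
  ix <- floor(x / eps); iy <- floor(y / eps)
  key <- paste(ix, iy, sep = ",")
  cells <- split(seq_len(n), key)
  cellIdx <- unique(data.frame(ix = ix, iy = iy, key = key,
    stringsAsFactors = FALSE))
  out <- vector("list", 0L)
  e2 <- eps^2
  for (r in seq_len(nrow(cellIdx))) {
    a <- cells[[cellIdx$key[r]]]
    for (dx in -1:1) for (dy in 0:1) {
      # visit each unordered cell pair once
      if (dy == 0 && dx < 0) next
      nb <- paste(cellIdx$ix[r] + dx, cellIdx$iy[r] + dy, sep = ",")
      b <- cells[[nb]]
      if (is.null(b)) next
      if (dx == 0 && dy == 0) {
        if (length(a) < 2L) next
        cmb <- utils::combn(a, 2L)
        i <- cmb[1L, ]; j <- cmb[2L, ]
      } else {
        i <- rep(a, times = length(b)); j <- rep(b, each = length(a))
      }
      keep <- (x[i] - x[j])^2 + (y[i] - y[j])^2 <= e2
      if (any(keep))
        out[[length(out) + 1L]] <- cbind(i[keep], j[keep])
    }
  }
  if (length(out)) do.call(rbind, out) else matrix(integer(0), ncol = 2)
}

## DBSCAN semantics: core points have >= minPts neighbours within eps
## (neighbourhood includes the point itself); clusters are connected
## components of core points; border points join a neighbouring core's
## cluster; everything else is noise (0)
.dbscan <- function(x, y, eps, minPts) {
  n <- length(x)
  pairs <- .epsPairs(x, y, eps)
  deg <- tabulate(c(pairs[, 1], pairs[, 2]), nbins = n)
  core <- (deg + 1L) >= minPts
  labels <- integer(n)
  if (!any(core)) return(labels)
  cc <- pairs[core[pairs[, 1]] & core[pairs[, 2]], , drop = FALSE]
  coreIds <- which(core)
  g <- igraph::graph_from_edgelist(
    matrix(match(as.vector(cc), coreIds), ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(coreIds) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  labels[coreIds] <- comp
  # border points: non-core with a core neighbour (ties: first core seen)
  bc <- pairs[xor(core[pairs[, 1]], core[pairs[, 2]]), , drop = FALSE]
  if (nrow(bc)) {
    borderPt <- ifelse(core[bc[, 1]], bc[, 2], bc[, 1])
    corePt <- ifelse(core[bc[, 1]], bc[, 1], bc[, 2])
    first <- !duplicated(borderPt)
    labels[borderPt[first]] <- labels[corePt[first]]
  }
  labels
}

#' Identify fibres by density-based clustering and remove background
#'
#' Density-based clustering (DBSCAN semantics: core points have at least
#' `minPts` neighbours within `eps`, counting themselves) of the pooled
#' two-channel localization table, followed by size and shape filters:
#' clusters with fewer than `minSize` localizations or a principal-axis
#' elongation ratio below `minElongation` are discarded as non-fibre
#' aggregates. All non-member localizations are flagged background
#' (`clusterId = -1`). Channels are pooled for clustering so a mixed or
#' bundled fibre is a single object; per-channel identity is retained for
#' downstream analysis.
#'
#' @param table A [LocalizationTable-class].
#' @param eps Neighbourhood radius in nm (about twice the imaging
#'   resolution).
#' @param minPts Minimum neighbourhood size for a core point.
#' @param minSize Minimum cluster size in localizations.
#' @param minElongation Minimum principal-axis elongation ratio (sqrt of the
#'   coordinate-covariance eigenvalue ratio).
#' @return `list(table, candidates)`: the input table with `clusterId`
#'   filled (accepted fibres numbered from 1 by decreasing size) and a list
#'   of [FibreCandidate-class] objects.
#' @examples
#' sim <- simulateFibreField(2, list(cy3 = LabelField(0.05)),
#'   ImagingModel(backgroundDensity = 0.2), contourLength = 3000, seed = 1)
#' seg <- clusterAndFilter(sim$table)
#' length(seg$candidates)
#' @export
clusterAndFilter <- function(table, eps = 100, minPts = 5, minSize = 100,
                             minElongation = 3) {
  stopifnot(is(table, "LocalizationTable"))
  if (eps <= 0) stop("eps must be > 0")
  d <- locData(table)
  if (!nrow(d)) {
    d$clusterId <- integer(0)
    return(list(table = LocalizationTable(d, locChannels(table)),
      candidates = list()))
  }
  raw <- .dbscan(d$x, d$y, eps, minPts)
  candidates <- list()
  clusterId <- rep(-1L, nrow(d))
  keptSizes <- integer(0)
  kept <- list()
  for (cl in setdiff(unique(raw), 0L)) {
    idx <- which(raw == cl)
    if (length(idx) < minSize) next
    cov <- stats::cov(cbind(d$x[idx], d$y[idx]))
    ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
    elong <- if (ev[2] <= .Machine$double.eps * ev[1]) Inf
             else sqrt(ev[1] / ev[2])
    if (elong < minElongation) next
    kept[[length(kept) + 1L]] <- list(idx = idx, elong = elong)
    keptSizes <- c(keptSizes, length(idx))
  }
  ord <- order(keptSizes, decreasing = TRUE)
  for (k in seq_along(ord)) {
    kk <- kept[[ord[k]]]
    clusterId[kk$idx] <- k
    candidates[[k]] <- new("FibreCandidate", clusterId = as.integer(k),
      members = as.integer(kk$idx),
      bbox = c(range(d$x[kk$idx]), range(d$y[kk$idx])),
      count = length(kk$idx), elongation = kk$elong)
  }
  d$clusterId <- clusterId
  list(table = LocalizationTable(d, locChannels(table)),
       candidates = candidates)
}

#' Per-cluster summary of a segmented table
#'
#' @param seg Result of [clusterAndFilter()].
#' @return A `data.frame` with one row per accepted fibre: cluster id,
#'   localization counts per channel, bounding box and elongation.
#' @export
segmentationSummary <- function(seg) {
  d <- locData(seg$table)
  rows <- lapply(seg$candidates, function(cand) {
    idx <- members(cand)
    counts <- table(factor(d$channel[idx], levels = locChannels(seg$table)))
    cbind(data.frame(clusterId = cand@clusterId, n = cand@count,
      elongation = cand@elongation,
      xmin = cand@bbox[1], xmax = cand@bbox[2],
      ymin = cand@bbox[3], ymax = cand@bbox[4]),
      as.data.frame.matrix(t(as.matrix(counts))))
  })
  do.call(rbind, rows)
}
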