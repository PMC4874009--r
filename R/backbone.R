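## Backbone tracing and arc-length statistics: raster -> thinning -> longest
## geodesic -> smoothing, then projection, 25-nm density profiles, apparent
## width (resolution estimate), linear density and persistence length.

.shiftMat <- function(M, di, dj) {
  n <- nrow(M); m <- ncol(M)
  out <- matrix(FALSE, n, m)
  si <- max(1, 1 + di):min(n, n + di)
  sj <- max(1, 1 + dj):min(m, m + dj)
  out[si - di, sj - dj] <- M[si, sj]
  out
}

.dilate <- function(M) {
  out <- M
  for (di in -1:1) for (dj in -1:1)
    if (di || dj) out <- out | .shiftMat(M, di, dj)
  out
}

.erode <- function(M) {
  out <- M
  for (di in -1:1) for (dj in -1:1)
    if (di || dj) out <- out & .shiftMat(M, di, dj)
  out
}

## Zhang-Suen morphological thinning of a logical matrix
.thin <- function(M) {
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      P2 <- .shiftMat(M, -1, 0); P3 <- .shiftMat(M, -1, 1)
      P4 <- .shiftMat(M, 0, 1);  P5 <- .shiftMat(M, 1, 1)
      P6 <- .shiftMat(M, 1, 0);  P7 <- .shiftMat(M, 1, -1)
      P8 <- .shiftMat(M, 0, -1); P9 <- .shiftMat(M, -1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
           (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      del <- M & B >= 2 & B <= 6 & A == 1
      del <- if (pass == 1)
        del & !(P2 & P4 & P6) & !(P4 & P6 & P8)
      else
        del & !(P2 & P4 & P8) & !(P2 & P6 & P8)
      if (any(del)) { M[del] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  M
}

## centred moving average that shrinks its window at the ends
.movavg <- function(v, w = 5) {
  n <- length(v)
  half <- w %/% 2
  vapply(seq_len(n), function(i)
    mean(v[max(1, i - half):min(n, i + half)]), numeric(1))
}

#' Trace the backbone of a fibre candidate
#'
#' Reconstructs the fibre centre line from its member localizations:
#' (i) rasterize onto a square grid (default 25 nm), threshold occupancy and
#' dilate once to close single-cell sampling gaps, (ii) morphological
#' (Zhang--Suen) skeletonization of the mask, (iii) extract the longest
#' geodesic path through the 8-connected skeleton graph (fragments closer
#' than `gapBridge` are first bridged with chord edges; weighted double
#' sweep), (iv) smooth the vertex chain with a centred moving average
#' (window 5 vertices), extend the endpoints to the extremal projected
#' localizations and recentre each vertex on the locally averaged
#' transverse offset of the data.
#'
#' @param table A [LocalizationTable-class] (typically the output of
#'   [clusterAndFilter()]).
#' @param candidate A [FibreCandidate-class]; if `NULL` all rows of `table`
#'   are used.
#' @param grid Raster cell size in nm.
#' @param minOccupancy Minimum localizations per cell for occupancy.
#' @param smoothWindow Moving-average window (vertices).
#' @param cutoff Perpendicular cutoff (nm) used for the endpoint extension.
#' @param gapBridge Maximum unlabelled gap (nm) bridged by a straight chord
#'   when the skeleton falls into fragments: a fibre is continuous even
#'   where no label happens to sit (e.g. between labelling microdomains).
#' @return A [Backbone-class].
#' @export
traceBackbone <- function(table, candidate = NULL, grid = 25,
                          minOccupancy = 1, smoothWindow = 5,
                          cutoff = 100, gapBridge = 600) {
  coords <- if (is(table, "LocalizationTable")) {
    d <- locData(table)
    idx <- if (is.null(candidate)) seq_len(nrow(d)) else members(candidate)
    cbind(d$x[idx], d$y[idx])
  } else as.matrix(table)[, 1:2, drop = FALSE]
  if (nrow(coords) < 3) stop("tracing error: fewer than 3 localizations")

  x0 <- min(coords[, 1]) - grid; y0 <- min(coords[, 2]) - grid
  ix <- floor((coords[, 1] - x0) / grid) + 1L
  iy <- floor((coords[, 2] - y0) / grid) + 1L
  nx <- max(ix) + 1L; ny <- max(iy) + 1L
  occ <- matrix(0L, ny, nx)
  for (k in seq_along(ix)) occ[iy[k], ix[k]] <- occ[iy[k], ix[k]] + 1L
  M <- occ >= minOccupancy
  if (sum(M) < 3) stop("tracing error: fewer than 3 occupied grid cells")

  # dilation bridges single-cell sampling gaps in the sparse occupancy mask
  sk <- .thin(.dilate(M))
  pix <- which(sk, arr.ind = TRUE)      # rows: (row = iy, col = ix)
  if (nrow(pix) < 2) stop("tracing error: degenerate skeleton")

  # 8-connected skeleton graph, Euclidean edge weights (cell units)
  id <- matrix(0L, nrow(sk), ncol(sk))
  id[pix] <- seq_len(nrow(pix))
  edges <- list(); wts <- list()
  offs <- rbind(c(0, 1), c(1, 0), c(1, 1), c(-1, 1))
  for (k in seq_len(nrow(offs))) {
    r2 <- pix[, 1] + offs[k, 1]; c2 <- pix[, 2] + offs[k, 2]
    ok <- r2 >= 1 & r2 <= nrow(sk) & c2 >= 1 & c2 <= ncol(sk)
    ok[ok] <- sk[cbind(r2[ok], c2[ok])]
    if (!any(ok)) next
    edges[[length(edges) + 1L]] <-
      cbind(id[pix[ok, , drop = FALSE]], id[cbind(r2[ok], c2[ok])])
    wts[[length(wts) + 1L]] <-
      rep(sqrt(sum(offs[k, ]^2)), sum(ok))
  }
  if (!length(edges)) stop("tracing error: disconnected skeleton")
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  igraph::E(g)$weight <- unlist(wts)
  g <- igraph::add_vertices(g, max(0L, nrow(pix) - igraph::vcount(g)))
  # a fibre is continuous even where labelling is locally absent: bridge
  # skeleton fragments separated by less than gapBridge with chord edges
  comp <- igraph::components(g)
  while (comp$no > 1L) {
    bestPair <- NULL; bestDist <- gapBridge / grid
    for (ca in seq_len(comp$no - 1L)) for (cb in (ca + 1L):comp$no) {
      ia <- which(comp$membership == ca); ib <- which(comp$membership == cb)
      dd <- outer(pix[ia, 1], pix[ib, 1], "-")^2 +
            outer(pix[ia, 2], pix[ib, 2], "-")^2
      mi <- which.min(dd)
      if (sqrt(dd[mi]) < bestDist) {
        bestDist <- sqrt(dd[mi])
        bestPair <- c(ia[(mi - 1) %% length(ia) + 1],
                      ib[(mi - 1) %/% length(ia) + 1])
      }
    }
    if (is.null(bestPair)) break
    g <- igraph::add_edges(g, bestPair, weight = bestDist)
    comp <- igraph::components(g)
  }
  main <- which(comp$membership == which.max(comp$csize))
  # weighted double sweep for the longest geodesic
  d1 <- igraph::distances(g, v = main[1], to = main)[1, ]
  u <- main[which.max(d1)]
  d2 <- igraph::distances(g, v = u, to = main)[1, ]
  w <- main[which.max(d2)]
  path <- igraph::shortest_paths(g, from = u, to = w)$vpath[[1]]
  chain <- pix[as.integer(path), , drop = FALSE]
  if (nrow(chain) < 2) stop("tracing error: degenerate skeleton path")

  px <- x0 + (chain[, 2] - 0.5) * grid
  py <- y0 + (chain[, 1] - 0.5) * grid
  px <- .movavg(px, smoothWindow)
  py <- .movavg(py, smoothWindow)
  bb <- Backbone(cbind(px, py))

  # extend each endpoint along its end tangent to the farthest localization
  # projecting onto the outward ray within the perpendicular cutoff
  v <- vertices(bb)
  extend <- function(tip, inner, pts) {
    u <- tip - inner; u <- u / sqrt(sum(u^2))
    rel <- sweep(pts, 2, tip)
    t <- rel %*% u
    perp <- abs(rel[, 1] * u[2] - rel[, 2] * u[1])
    t <- t[perp <= cutoff & t > 0]
    if (length(t)) tip + max(t) * u else tip
  }
  v1 <- extend(v[1, ], v[2, ], coords)
  v2 <- extend(v[nrow(v), ], v[nrow(v) - 1, ], coords)
  bb <- Backbone(rbind(v1, v[2:(nrow(v) - 1), , drop = FALSE], v2))
  # recentre on the data: the raster skeleton wobbles by a fraction of the
  # cell size, which would inflate the apparent width
  .recentreBackbone(bb, coords, cutoff = cutoff)
}

## offset each vertex along its normal by the locally averaged transverse
## residual of the member localizations (averaged over `window` vertices so
## the backbone does not absorb the localization noise itself)
.recentreBackbone <- function(bb, coords, cutoff = 100, window = 7) {
  proj <- suppressMessages(projectToBackbone(coords, bb, cutoff = cutoff))
  v <- vertices(bb); arc <- arcLengths(bb)
  n <- nrow(v)
  # mean signed offset of the localizations nearest each vertex
  nearest <- findInterval(proj$s, c(-Inf, (arc[-n] + arc[-1]) / 2, Inf))
  dsum <- dnum <- numeric(n)
  for (i in seq_along(nearest)) {
    k <- nearest[i]
    dsum[k] <- dsum[k] + proj$d[i]
    dnum[k] <- dnum[k] + 1
  }
  dbar <- ifelse(dnum > 0, dsum / pmax(dnum, 1), NA_real_)
  ok <- is.finite(dbar)
  if (!any(ok)) return(bb)
  dbar[!ok] <- stats::approx(arc[ok], dbar[ok], xout = arc[!ok],
    rule = 2)$y
  dbar <- .movavg(dbar, window)
  # left normals (consistent with the sign convention of d)
  seg <- diff(v)
  seglen <- sqrt(rowSums(seg^2))
  nx <- -seg[, 2] / seglen; ny <- seg[, 1] / seglen
  vx <- c(nx[1], (nx[-1] + nx[-length(nx)]) / 2, nx[length(nx)])
  vy <- c(ny[1], (ny[-1] + ny[-length(ny)]) / 2, ny[length(ny)])
  nrm <- sqrt(vx^2 + vy^2)
  Backbone(cbind(v[, 1] + dbar * vx / nrm, v[, 2] + dbar * vy / nrm))
}

#' Project localizations onto a backbone
#'
#' Each localization is mapped to its nearest point on the backbone
#' polyline: `s` is the arc-length coordinate of the foot point and `d` the
#' signed transverse offset (positive to the left of the direction of
#' increasing `s`). Ties between equidistant segments are broken toward
#' smaller `s`. Localizations farther than `cutoff` from the backbone are
#' dropped and their count reported via the `"dropped"` attribute.
#'
#' @param table A [LocalizationTable-class], data.frame with `x`/`y`, or a
#'   2-column coordinate matrix.
#' @param bb A [Backbone-class].
#' @param candidate Optional [FibreCandidate-class] restricting the rows of
#'   `table`.
#' @param cutoff Transverse cutoff in nm.
#' @return A `data.frame` with columns `s`, `d`, `index` (row in the input),
#'   `channel` (if available); attributes `backboneLength` and `dropped`.
#' @export
projectToBackbone <- function(table, bb, candidate = NULL, cutoff = 100) {
  stopifnot(is(bb, "Backbone"))
  validObject(bb)
  if (is(table, "LocalizationTable")) {
    d <- locData(table)
    idx <- if (is.null(candidate)) seq_len(nrow(d)) else members(candidate)
    pts <- cbind(d$x[idx], d$y[idx])
    channel <- d$channel[idx]
  } else {
    pts <- as.matrix(as.data.frame(table))[, 1:2, drop = FALSE]
    idx <- seq_len(nrow(pts))
    channel <- rep(NA_character_, nrow(pts))
  }
  n <- nrow(pts)
  v <- vertices(bb); arc <- arcLengths(bb)
  best <- rep(Inf, n); bestS <- numeric(n); bestD <- numeric(n)
  for (j in seq_len(nrow(v) - 1L)) {
    a <- v[j, ]; b <- v[j + 1L, ]
    len <- arc[j + 1L] - arc[j]
    ux <- (b[1] - a[1]) / len; uy <- (b[2] - a[2]) / len
    rx <- pts[, 1] - a[1]; ry <- pts[, 2] - a[2]
    t <- pmin(pmax(rx * ux + ry * uy, 0), len)
    dx <- rx - t * ux; dy <- ry - t * uy
    dist2 <- dx * dx + dy * dy
    cross <- ux * ry - uy * rx
    upd <- dist2 < best   # strict: ties stay with the smaller-s segment
    if (any(upd)) {
      best[upd] <- dist2[upd]
      bestS[upd] <- arc[j] + t[upd]
      bestD[upd] <- sign(cross[upd]) * sqrt(dist2[upd])
    }
  }
  keep <- abs(bestD) <= cutoff
  dropped <- sum(!keep)
  if (dropped) message(dropped, " localization(s) beyond the ", cutoff,
    " nm projection cutoff dropped")
  out <- data.frame(s = bestS[keep], d = bestD[keep],
    index = idx[keep], channel = channel[keep])
  attr(out, "backboneLength") <- backboneLength(bb)
  attr(out, "dropped") <- dropped
  out
}

#' Arc-length density profile of projected localizations
#'
#' Counts projected `s` coordinates in half-open bins
#' `[k * binWidth, (k+1) * binWidth)` covering the full backbone; the last
#' partial bin is kept. The default 25-nm bin is the standard profile
#' resolution for these fibres.
#'
#' @param projected Output of [projectToBackbone()] (or any data.frame with
#'   an `s` column).
#' @param binWidth Bin width in nm.
#' @param L Backbone length (nm); defaults to the `backboneLength`
#'   attribute of `projected`.
#' @param channel Optional channel filter. A channel with no localizations
#'   yields an all-zero profile (the channel may simply be absent from this
#'   fibre); an empty *input* is a contract error.
#' @param fibreId Identifier stored in the profile.
#' @return A [DensityProfile-class].
#' @export
densityProfile <- function(projected, binWidth = 25, L = NULL,
                           channel = NULL, fibreId = "fibre") {
  if (binWidth <= 0) stop("binWidth must be > 0")
  if (is.null(L)) L <- attr(projected, "backboneLength")
  if (is.null(L)) stop("backbone length unknown; pass L")
  if (!nrow(as.data.frame(projected)))
    stop("no projected localizations")
  s <- projected$s
  if (!is.null(channel) && "channel" %in% names(projected))
    s <- s[projected$channel == channel]
  nbins <- max(1L, as.integer(ceiling(L / binWidth - 1e-9)))
  bin <- pmin(floor(s / binWidth) + 1L, nbins)
  counts <- tabulate(bin, nbins = nbins)
  new("DensityProfile", fibreId = as.character(fibreId),
    channel = if (is.null(channel)) "all" else channel,
    binWidth = binWidth, binStarts = (seq_len(nbins) - 1) * binWidth,
    counts = as.numeric(counts))
}

#' Apparent fibre width (experimental resolution estimate)
#'
#' Full width at half maximum of a Gaussian fitted to the transverse-offset
#' distribution: `2 * sqrt(2 * log(2)) * sigma_hat`, with `sigma_hat` the
#' maximum-likelihood Gaussian width of the signed offsets `d`. Since the
#' physical fibre (~7 nm) is far below the imaging resolution, this width
#' estimates the resolution itself.
#'
#' @param projected Output of [projectToBackbone()], or a numeric vector of
#'   signed offsets.
#' @return Apparent width (FWHM) in nm.
#' @export
apparentWidth <- function(projected) {
  d <- if (is.numeric(projected)) projected else projected$d
  if (length(d) < 50) stop("need >= 50 projected localizations")
  sigma <- stats::sd(d)
  if (!is.finite(sigma)) stop("estimation error: width fit failed")
  2 * sqrt(2 * log(2)) * sigma
}

#' Linear density of localizations along a fibre
#'
#' Number of projected localizations of a channel per unit arc length,
#' reported per micrometre — the proxy for the local concentration of the
#' labelled species.
#'
#' @param projected Output of [projectToBackbone()].
#' @param bb The [Backbone-class] (for its total length), or a number (nm).
#' @param channel Optional channel filter.
#' @return Linear density in localizations per micrometre.
#' @export
linearDensity <- function(projected, bb, channel = NULL) {
  L <- if (is(bb, "Backbone")) backboneLength(bb) else as.numeric(bb)
  if (L <= 0) stop("backbone length must be > 0")
  s <- projected$s
  if (!is.null(channel) && "channel" %in% names(projected))
    s <- s[projected$channel == channel]
  length(s) / (L / 1000)
}

#' Persistence length from backbone tangent correlations
#'
#' Exponential fit to the tangent--tangent correlation
#' `<cos theta(ds)> = exp(-ds / (2P))` (2-D convention) over separations up
#' to half the contour length. A list of backbones is pooled before fitting
#' (ensemble estimate).
#'
#' @param bb A [Backbone-class] or a list of them.
#' @param maxFrac Largest separation used, as a fraction of the contour.
#' @return Persistence length P in nm; `Inf` with attribute `rigid = TRUE`
#'   for a straight backbone.
#' @export
persistenceLength <- function(bb, maxFrac = 0.5) {
  bbs <- if (is(bb, "Backbone")) list(bb) else bb
  corSum <- NULL; corN <- NULL; h <- NULL
  for (b in bbs) {
    v <- vertices(b)
    if (nrow(v) < 11) stop("need a backbone with >= 10 segments")
    seg <- diff(v)
    theta <- atan2(seg[, 2], seg[, 1])
    ns <- length(theta)
    hh <- backboneLength(b) / ns
    if (is.null(h)) h <- hh
    kmax <- max(1L, floor(ns * maxFrac))
    if (is.null(corSum)) { corSum <- numeric(kmax); corN <- numeric(kmax) }
    kmax <- min(kmax, length(corSum))
    for (k in seq_len(kmax)) {
      cc <- cos(theta[(1 + k):ns] - theta[1:(ns - k)])
      corSum[k] <- corSum[k] + sum(cc)
      corN[k] <- corN[k] + length(cc)
    }
  }
  ck <- corSum / pmax(corN, 1)
  ds <- h * seq_along(ck)
  use <- corN > 0 & ck > 0.1
  if (all(ck[corN > 0] > 0.99)) {
    out <- Inf
    attr(out, "rigid") <- TRUE
    return(out)
  }
  if (sum(use) < 2) stop("estimation error: correlation does not decay usably")
  slope <- sum(ds[use] * log(ck[use])) / sum(ds[use]^2)
  if (slope >= 0) stop("estimation error: non-decaying tangent correlation")
  -1 / (2 * slope)
}
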