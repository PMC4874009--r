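## Reading/writing localization tables, profiles and correlation curves.
## The canonical internal unit is nm; tables are planar (TIRF geometry).

#' Describe the on-disk dialect of a localization table
#'
#' Vendor exports differ in column names, units and delimiters; a dialect
#' maps them onto the canonical columns. With `units = "pixels"` coordinates
#' are converted by exact multiplication with `pixelSize` (e.g. a 0.17 um
#' camera pixel is `pixelSize = 170`).
#'
#' @param columns Named character vector mapping canonical names (`x`, `y`,
#'   `frame`, `channel`, optionally `precision`) to file column names.
#' @param units `"nm"` or `"pixels"`.
#' @param pixelSize nm per pixel; required when `units = "pixels"`.
#' @param delimiter Field delimiter.
#' @return A list of class `locDialect`.
#' @examples
#' dia <- localizationDialect(units = "pixels", pixelSize = 170)
#' @export
localizationDialect <- function(columns = c(x = "x", y = "y",
                                            frame = "frame",
                                            channel = "channel"),
                                units = c("nm", "pixels"),
                                pixelSize = NA_real_,
                                delimiter = ",") {
  units <- match.arg(units)
  if (units == "pixels" && (!is.finite(pixelSize) || pixelSize <= 0))
    stop("pixelSize must be > 0 when units are pixels")
  structure(list(columns = columns, units = units, pixelSize = pixelSize,
    delimiter = delimiter), class = "locDialect")
}

#' Read a localization table
#'
#' Reads a delimited localization list (one row per localization), renames
#' columns according to the dialect, converts coordinates to nm, drops rows
#' with non-finite coordinates (logging the count) and validates channel
#' tokens against the declared set.
#'
#' @param path File path.
#' @param dialect A [localizationDialect()].
#' @param channels Declared channel set; defaults to the channels present.
#' @return A [LocalizationTable-class].
#' @export
readLocalizations <- function(path, dialect = localizationDialect(),
                              channels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- as.data.frame(data.table::fread(path, sep = dialect$delimiter,
    header = TRUE, showProgress = FALSE))
  cols <- dialect$columns
  need <- c("x", "y", "frame", "channel")
  for (nm in need) {
    src <- if (nm %in% names(cols)) cols[[nm]] else nm
    if (!src %in% names(d)) stop("missing column: ", nm)
    names(d)[names(d) == src] <- nm
  }
  if ("precision" %in% names(cols) && cols[["precision"]] %in% names(d))
    names(d)[names(d) == cols[["precision"]]] <- "precision"
  if (dialect$units == "pixels") {
    d$x <- d$x * dialect$pixelSize
    d$y <- d$y * dialect$pixelSize
    if ("precision" %in% names(d)) d$precision <- d$precision * dialect$pixelSize
  }
  bad <- !is.finite(d$x) | !is.finite(d$y)
  if (any(bad)) {
    message(sum(bad), " localization(s) with non-finite coordinates dropped")
    d <- d[!bad, , drop = FALSE]
  }
  d$channel <- as.character(d$channel)
  if (is.null(channels)) channels <- sort(unique(d$channel))
  unknown <- setdiff(unique(d$channel), channels)
  if (length(unknown))
    stop("unknown channel token: ", paste(unknown, collapse = ", "))
  LocalizationTable(d, channels = channels)
}

#' Write a localization table
#'
#' @param table A [LocalizationTable-class].
#' @param path Output file path.
#' @param delimiter Field delimiter.
#' @return `path`, invisibly.
#' @export
writeLocalizations <- function(table, path, delimiter = ",") {
  stopifnot(is(table, "LocalizationTable"))
  data.table::fwrite(locData(table), path, sep = delimiter)
  invisible(path)
}

#' Write a correlation curve or density profile
#'
#' Delimited text with header `lag_nm` (curves) or `bin_start_nm`
#' (profiles), `value`, `n_fibres`, `ci95_halfwidth`; values are written at
#' full precision (round-trips are lossless to 1e-9 relative).
#'
#' @param curve A [CorrelationCurve-class] or [DensityProfile-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeCurve <- function(curve, path) {
  d <- as.data.frame(curve)
  if (!nrow(d)) stop("refusing to write an empty curve")
  dt <- data.table::as.data.table(lapply(d, function(col)
    if (is.double(col)) format(col, digits = 17, trim = TRUE) else col))
  data.table::fwrite(dt, path, sep = ",", quote = FALSE)
  invisible(path)
}

#' Read a correlation curve written by [writeCurve()]
#'
#' @param path File path.
#' @return A [CorrelationCurve-class] (for `lag_nm` files) or a
#'   [DensityProfile-class] (for `bin_start_nm` files).
#' @export
readCurve <- function(path) {
  d <- as.data.frame(data.table::fread(path, showProgress = FALSE))
  if ("lag_nm" %in% names(d)) {
    new("CorrelationCurve", lag = as.numeric(d$lag_nm),
      value = as.numeric(d$value), nFibres = as.integer(d$n_fibres),
      ci95 = as.numeric(d$ci95_halfwidth))
  } else if ("bin_start_nm" %in% names(d)) {
    bs <- as.numeric(d$bin_start_nm)
    new("DensityProfile", fibreId = "file", channel = "unknown",
      binWidth = if (length(bs) > 1) bs[2] - bs[1] else 25,
      binStarts = bs, counts = as.numeric(d$value))
  } else stop("unrecognized curve file: ", path)
}

#' Write a ground-truth sidecar
#'
#' Structured JSON keyed by fibre id: backbone vertices, label arc positions,
#' channel identities and inert flags, plus the generative parameters.
#'
#' @param truth A [GroundTruth-class].
#' @param path Output file path (JSON).
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  stopifnot(is(truth, "GroundTruth"))
  fib <- lapply(truthFibres(truth), function(f) {
    list(fibreId = f$fibreId,
      backbone = if (!is.null(f$backbone)) unname(vertices(f$backbone)),
      s = f$s, channel = f$channel, inert = f$inert)
  })
  names(fib) <- vapply(fib, `[[`, character(1), "fibreId")
  jsonlite::write_json(list(fibres = fib), path, auto_unbox = TRUE,
    digits = NA, null = "null")
  invisible(path)
}

#' Load a run configuration
#'
#' One structured YAML (or JSON) file with sections mirroring the pipeline
#' stages: `fibres`, `labelFields`, `imaging`, `exchange`, `segmentation`,
#' `backbone`, `correlation`, `modelfit`, `kinetics`, `times`, `seed`.
#' Missing sections fall back to package defaults; the returned list always
#' carries every section.
#'
#' @param path Path to a YAML/JSON configuration file.
#' @return Nested named list of configuration values.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    fibres = list(count = 20, contourLength = 5000,
      persistenceLength = 10000),
    labelFields = list(
      cy3 = list(meanLinearDensity = 0.05, m = 0.8, r0 = 300, alpha = 500),
      cy5 = list(meanLinearDensity = 0.05, m = 0)),
    imaging = list(sigmaLoc = 20, muLoc = 3, countDistribution = "geometric",
      backgroundDensity = 0.5, nFrames = 20000),
    exchange = list(mechanism = "random_insertion", k = 0.1,
      endWindow = 500, inertFraction = 0, inertSegmentLength = 500),
    segmentation = list(eps = 100, minPts = 5, minSize = 100,
      minElongation = 3),
    backbone = list(binWidth = 25, cutoff = 100, minTraceLocs = 300),
    correlation = list(kMax = 2000, excludeBelow = 25),
    modelfit = list(threshold = 2, minFibresPerLag = 5),
    kinetics = list(lo = 0.2, hi = 0.7, mixingFraction = 0.5,
      occupancyThreshold = 1),
    times = c(0, 1, 3, 6, 24, 48),
    seed = 1)
  merged <- utils::modifyList(defaults, cfg)
  merged
}
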