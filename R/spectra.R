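## 1D spectra: referencing to an internal standard and equidistant bucketing.

#' SpectrumSet: a set of 1D spectra on a common chemical-shift grid
#'
#' @slot ppm strictly monotone numeric grid of chemical shifts (ppm).
#' @slot intensities numeric matrix, one row per sample, one column per grid
#'   point; finite throughout.
#' @slot referenceTargetPpm chemical shift the reference signal is aligned
#'   to; default 8.463 ppm (formic acid).
#' @slot flags logical vector marking samples whose referencing failed (flat
#'   search window) and were left unshifted.
#' @export
setClass("SpectrumSet",
  representation(ppm = "numeric", intensities = "matrix",
                 referenceTargetPpm = "numeric", flags = "logical")
)

setValidity("SpectrumSet", function(object) {
  d <- diff(object@ppm)
  msgs <- character()
  if (length(object@ppm) < 2 || !(all(d > 0) || all(d < 0)))
    msgs <- c(msgs, "ppm axis must be strictly monotone")
  if (ncol(object@intensities) != length(object@ppm))
    msgs <- c(msgs, "intensity columns must match ppm grid")
  if (any(!is.finite(object@intensities)))
    msgs <- c(msgs, "intensities must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SpectrumSet
#'
#' @param ppm chemical-shift grid (strictly monotone).
#' @param intensities matrix of intensities, samples in rows.
#' @param referenceTargetPpm target shift of the internal reference signal.
#' @return a \code{\linkS4class{SpectrumSet}}.
#' @export
spectrumSet <- function(ppm, intensities, referenceTargetPpm = 8.463) {
  if (is.null(dim(intensities))) intensities <- matrix(intensities, nrow = 1)
  new("SpectrumSet", ppm = as.numeric(ppm), intensities = intensities,
      referenceTargetPpm = referenceTargetPpm,
      flags = logical(nrow(intensities)))
}

#' Read spectra from a wide CSV (first row the ppm grid)
#'
#' @param path CSV with the ppm grid as the first row and one sample per
#'   subsequent row (first column a sample id).
#' @param referenceTargetPpm see \code{\link{spectrumSet}}.
#' @return a \code{\linkS4class{SpectrumSet}}.
#' @export
readSpectra <- function(path, referenceTargetPpm = 8.463) {
  raw <- as.matrix(read.csv(path, header = FALSE, row.names = 1))
  spectrumSet(as.numeric(raw[1, ]), raw[-1, , drop = FALSE],
              referenceTargetPpm)
}

#' Reference spectra to an internal-standard signal
#'
#' Each spectrum is shifted along the chemical-shift axis so that the maximum
#' intensity inside the search window lies at the reference target (default
#' 8.463 ppm, formic acid). The shift is a pure axis translation applied by
#' linear re-interpolation onto the common grid; intensities are otherwise
#' unchanged. A spectrum whose window carries no peak above baseline (window
#' maximum not exceeding the window median by \code{minProminence} times the
#' window's median absolute deviation) is left unshifted, flagged, and
#' reported with a warning.
#'
#' @param s a \code{\linkS4class{SpectrumSet}}.
#' @param searchWindowPpm numeric length-2 window (lo, hi) containing the
#'   reference peak.
#' @param minProminence baseline heuristic multiplier (default 5).
#' @return the referenced \code{SpectrumSet}; slot \code{flags} marks
#'   unshifted spectra.
#' @export
referenceSpectra <- function(s, searchWindowPpm = c(8.35, 8.55),
                             minProminence = 5) {
  lo <- min(searchWindowPpm); hi <- max(searchWindowPpm)
  win <- which(s@ppm >= lo & s@ppm <= hi)
  if (!length(win)) stop("search window contains no grid points")
  out <- s@intensities
  flags <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    w <- s@intensities[i, win]
    madw <- stats::mad(w)
    if (max(w) - stats::median(w) <= minProminence * max(madw, 1e-12)) {
      warning(sprintf("spectrum %d: no clear reference peak in window; left unshifted", i))
      flags[i] <- TRUE
      next
    }
    peak <- s@ppm[win[which.max(w)]]
    delta <- s@referenceTargetPpm - peak   # translate axis by delta
    if (delta != 0)
      out[i, ] <- stats::approx(s@ppm + delta, s@intensities[i, ],
                                xout = s@ppm, rule = 2)$y
  }
  s@intensities <- out
  s@flags <- flags
  s
}

#' BucketTable: equidistantly bucketed spectra
#'
#' @slot bucketCenters ppm centers, equally spaced by \code{width}.
#' @slot values numeric matrix, samples x buckets; each value is the sum of
#'   grid intensities in the half-open interval [c - w/2, c + w/2).
#' @slot width bucket width in ppm.
#' @export
setClass("BucketTable",
  representation(bucketCenters = "numeric", values = "matrix",
                 width = "numeric")
)

#' Equidistant binning of spectra
#'
#' Buckets are half-open ppm intervals \code{[c - w/2, c + w/2)} with centers
#' at \code{lo + w/2 + k w}; with the default width 0.01 ppm and an integer
#' range this places centers at odd multiples of 0.005 ppm (e.g. 3.275,
#' 3.045). The bucket value is the sum of the intensities of all grid points
#' falling in the interval. Buckets overlapping any exclusion region (default:
#' the water band, 4.40-5.00 ppm) are dropped.
#'
#' @param s a \code{\linkS4class{SpectrumSet}}.
#' @param widthPpm bucket width in ppm (> 0), default 0.01.
#' @param rangePpm numeric (lo, hi) range to bucket; default the axis span.
#' @param exclusions list of (lo, hi) ppm intervals to exclude; default
#'   \code{list(c(4.40, 5.00))}.
#' @return a \code{\linkS4class{BucketTable}}; errors if no bucket survives.
#' @export
bucketSpectra <- function(s, widthPpm = 0.01, rangePpm = NULL,
                          exclusions = list(c(4.40, 5.00))) {
  if (widthPpm <= 0) stop("widthPpm must be > 0")
  if (is.null(rangePpm)) rangePpm <- range(s@ppm)
  lo <- min(rangePpm); hi <- max(rangePpm)
  nb <- floor((hi - lo) / widthPpm + 1e-9)
  if (nb < 1) stop("range narrower than one bucket")
  centers <- lo + widthPpm / 2 + widthPpm * (0:(nb - 1))
  keep <- vapply(centers, function(cc) {
    bl <- cc - widthPpm / 2; bh <- cc + widthPpm / 2
    !any(vapply(exclusions,
                function(ex) bl < max(ex) && bh > min(ex), logical(1)))
  }, logical(1))
  centers <- centers[keep]
  if (!length(centers)) stop("no buckets remain after exclusions")
  # half-open membership [c - w/2, c + w/2)
  vals <- matrix(0, nrow(s@intensities), length(centers))
  for (b in seq_along(centers)) {
    inb <- s@ppm >= centers[b] - widthPpm / 2 & s@ppm < centers[b] + widthPpm / 2
    vals[, b] <- rowSums(s@intensities[, inb, drop = FALSE])
  }
  colnames(vals) <- formatC(centers, format = "fg")
  new("BucketTable", bucketCenters = centers, values = vals, width = widthPpm)
}

#' Convert a BucketTable to the continuous block of a MixedDataset
#'
#' @param b a \code{\linkS4class{BucketTable}}.
#' @param sampleIds optional sample identifiers.
#' @param prefix column-name prefix for bucket variables (default "nmr_").
#' @return a \code{\linkS4class{MixedDataset}} with layer "nmr".
#' @export
bucketsToDataset <- function(b, sampleIds = NULL, prefix = "nmr_") {
  X <- b@values
  colnames(X) <- paste0(prefix, colnames(X))
  mixedDataset(continuous = X, layer = "nmr", sampleIds = sampleIds)
}
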