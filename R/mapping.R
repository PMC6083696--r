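#' Band-sum intensity map
#'
#' For every pixel, the raw sum of intensities at grid points inside the
#' closed window `center +/- halfwidth` — the "sum filter" used to image
#' pigment distribution at ~1140 and ~1540 cm^-1. No baseline or
#' emission correction is applied.
#'
#' @param map a [RamanHyperMap-class].
#' @param center window center in cm^-1.
#' @param halfwidth window half-width in cm^-1 (default 50).
#' @return numeric matrix of dimension `dim(map)`.
#' @export
bandIntensityMap <- function(map, center, halfwidth = 50) {
  stopifnot(is(map, "RamanHyperMap"))
  sel <- map@wavenumber >= center - halfwidth &
         map@wavenumber <= center + halfwidth
  if (!any(sel))
    stop(sprintf("window %g +/- %g cm-1 lies outside the axis (%g-%g)",
                 center, halfwidth, min(map@wavenumber), max(map@wavenumber)))
  v <- rowSums(map@intensities[, sel, drop = FALSE])
  matrix(v, nrow = map@nRow, ncol = map@nCol, byrow = TRUE)
}

#' Emission index map
#'
#' A per-pixel scalar background level: the median intensity over
#' peak-free reference windows (default 900-980 and 1700-1800 cm^-1).
#' Broad fluorescence emission raises the whole spectrum, so emissive
#' pixels score high while pigment or keratin bands (which sit outside
#' the reference windows) do not contribute. This operationalizes the
#' visual emission assessment of bright-field imaging; it is additive in
#' any constant offset.
#'
#' @param map a [RamanHyperMap-class] whose axis spans at least
#'   400 cm^-1.
#' @param refWindows list of `c(lo, hi)` peak-free windows.
#' @return numeric matrix of dimension `dim(map)`.
#' @export
emissionIndexMap <- function(map,
                             refWindows = list(c(900, 980),
                                               c(1700, 1800))) {
  stopifnot(is(map, "RamanHyperMap"))
  if (diff(range(map@wavenumber)) < 400)
    stop("axis must span at least 400 cm-1 for a background estimate")
  sel <- Reduce(`|`, lapply(refWindows, function(w)
    map@wavenumber >= w[1] & map@wavenumber <= w[2]))
  if (!any(sel))
    stop("reference windows lie outside the wavenumber axis")
  v <- apply(map@intensities[, sel, drop = FALSE], 1L, stats::median)
  matrix(v, nrow = map@nRow, ncol = map@nCol, byrow = TRUE)
}
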