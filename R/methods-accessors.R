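#' @describeIn RamanSpectrum-class wavenumber axis (cm^-1)
#' @export
setMethod("wavenumbers", "RamanSpectrum", function(object) object@wavenumber)

#' @describeIn RamanSpectrum-class intensity vector (a.u.)
#' @export
setMethod("intensities", "RamanSpectrum", function(object) object@intensity)

#' @describeIn RamanSpectrum-class excitation wavelength (nm)
#' @export
setMethod("excitationNm", "RamanSpectrum", function(object) object@excitation)

#' @describeIn RamanSpectrum-class region/colour label
#' @export
setMethod("regionLabel", "RamanSpectrum", function(object) object@region)

#' @describeIn RamanSpectrum-class replicate identifier
#' @export
setMethod("replicateId", "RamanSpectrum", function(object) object@replicate)

#' @describeIn RamanSpectrum-class number of spectral points
#' @export
setMethod("length", "RamanSpectrum", function(x) length(x@wavenumber))

setMethod("show", "RamanSpectrum", function(object) {
  cat(sprintf("RamanSpectrum: %d points, %.1f-%.1f cm-1\n",
              length(object@wavenumber),
              min(object@wavenumber), max(object@wavenumber)))
  if (!is.na(object@excitation))
    cat(sprintf("  excitation: %g nm\n", object@excitation))
  if (!is.na(object@region))
    cat(sprintf("  region: %s\n", object@region))
  if (!is.na(object@replicate))
    cat(sprintf("  replicate: %s\n", object@replicate))
  cat(sprintf("  source: %s\n", object@source))
})

#' @describeIn ExcitationSeries-class excitation wavelengths (nm), ascending
#' @export
setMethod("excitationNm", "ExcitationSeries", function(object)
  unname(vapply(object@spectra, function(s) s@excitation, numeric(1))))

#' @describeIn ExcitationSeries-class region label
#' @export
setMethod("regionLabel", "ExcitationSeries", function(object) object@region)

#' @describeIn ExcitationSeries-class number of excitations
#' @export
setMethod("length", "ExcitationSeries", function(x) length(x@spectra))

#' @describeIn ExcitationSeries-class extract one member spectrum by index
#'   or by excitation wavelength given as character (e.g. `series[["648"]]`)
#' @param i index or excitation wavelength (as character)
#' @param j,... unused
#' @export
setMethod("[[", "ExcitationSeries", function(x, i, j, ...) {
  if (is.character(i)) {
    exc <- excitationNm(x)
    k <- which(abs(exc - as.numeric(i)) < 1e-9)
    if (!length(k)) stop("no spectrum at excitation ", i, " nm")
    return(x@spectra[[k]])
  }
  x@spectra[[i]]
})

setMethod("show", "ExcitationSeries", function(object) {
  exc <- excitationNm(object)
  cat(sprintf("ExcitationSeries: %d excitations (%s nm)\n", length(exc),
              paste(format(exc, trim = TRUE), collapse = ", ")))
  if (!is.na(object@region)) cat(sprintf("  region: %s\n", object@region))
  g <- object@spectra[[1L]]@wavenumber
  cat(sprintf("  grid: %d points, %.1f-%.1f cm-1\n",
              length(g), min(g), max(g)))
})

#' @describeIn RamanHyperMap-class grid dimensions c(nRow, nCol)
#' @export
setMethod("dim", "RamanHyperMap", function(x) c(x@nRow, x@nCol))

#' @describeIn RamanHyperMap-class shared wavenumber axis
#' @export
setMethod("wavenumbers", "RamanHyperMap", function(object) object@wavenumber)

setMethod("show", "RamanHyperMap", function(object) {
  cat(sprintf("RamanHyperMap: %d x %d pixels, %d spectral points\n",
              object@nRow, object@nCol, length(object@wavenumber)))
  if (!is.na(object@pixelSize))
    cat(sprintf("  pixel size: %g um\n", object@pixelSize))
  if (!is.na(object@excitation))
    cat(sprintf("  excitation: %g nm\n", object@excitation))
})

#' Extract the spectrum of one pixel
#'
#' @param map a [RamanHyperMap-class].
#' @param row,col pixel coordinates (1-based).
#' @return A [RamanSpectrum-class].
#' @export
pixelSpectrum <- function(map, row, col) {
  stopifnot(is(map, "RamanHyperMap"),
            row >= 1, row <= map@nRow, col >= 1, col <= map@nCol)
  idx <- (row - 1L) * map@nCol + col
  RamanSpectrum(map@wavenumber, map@intensities[idx, ],
                excitation = map@excitation,
                source = sprintf("pixel(%d,%d)", row, col))
}

setMethod("show", "Peak", function(object) {
  cat(sprintf("Peak [%s]: center %.2f cm-1, height %.4g, fwhm %s, snr %.3g (%s)%s\n",
              object@band, object@center, object@height,
              if (is.na(object@fwhm)) "NA" else sprintf("%.2f", object@fwhm),
              object@snr, object@method,
              if (length(object@flags))
                paste0(" [", paste(object@flags, collapse = ","), "]")
              else ""))
})

#' @describeIn Peak-class fitted band center, cm^-1
#' @param object a Peak
#' @export
peakCenter <- function(object) object@center

#' @describeIn Peak-class peak height above local background, a.u.
#' @export
peakHeight <- function(object) object@height

#' @describeIn Peak-class signal-to-noise ratio
#' @export
peakSnr <- function(object) object@snr

#' @describeIn Peak-class quality flags ("edge", "fallback_argmax", ...)
#' @export
peakFlags <- function(object) object@flags

#' @describeIn BandTrack-class per-excitation peak table of a track
#' @export
setMethod("peakTable", "BandTrack", function(object) {
  cbind(band = object@band, object@points, stringsAsFactors = FALSE)
})

#' @describeIn BandTrack-class one-row-per-peak table from a list of Peaks
#' @export
setMethod("peakTable", "list", function(object) {
  stopifnot(all(vapply(object, is, logical(1), "Peak")))
  do.call(rbind, lapply(object, function(p) {
    data.frame(band = p@band, center = p@center, height = p@height,
               fwhm = p@fwhm, snr = p@snr, method = p@method,
               flags = paste(p@flags, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
})

setMethod("show", "BandTrack", function(object) {
  cat(sprintf("BandTrack [%s]: %d included excitations\n",
              object@band, nrow(object@points)))
  cat(sprintf("  reference: %.2f cm-1 at %g nm\n",
              object@reference$center, object@reference$excitation_nm))
  if (nrow(object@excluded))
    cat(sprintf("  excluded: %s\n",
                paste(sprintf("%g nm (%s)", object@excluded$excitation_nm,
                              object@excluded$reason), collapse = ", ")))
  cat(sprintf("  center range: %.2f cm-1\n",
              diff(range(object@points$center))))
})

#' @describeIn DispersionFit-class dispersion rate D in cm (per cm^-1 of
#'   excitation energy) or 1/eV
#' @export
setMethod("dispersionRate", "DispersionFit", function(object,
                                                      units = c("cm", "eV")) {
  units <- match.arg(units)
  if (units == "cm") object@D_cm else object@D_eV
})

#' @describeIn DispersionFit-class per-excitation product-rule values
#'   (2*lambda-bar)
#' @export
ammProducts <- function(object) {
  stopifnot(is(object, "DispersionFit"))
  object@products
}

#' @describeIn DispersionFit-class per-band regression table
#' @export
perBandFits <- function(object) {
  stopifnot(is(object, "DispersionFit"))
  object@perBand
}

setMethod("show", "DispersionFit", function(object) {
  cat("Amplitude-mode-model dispersion fit\n")
  cat(sprintf("  n = %d excitations; bands: %s\n", object@nPoints,
              paste(object@perBand$band, collapse = ", ")))
  cat(sprintf("  D = %.3e cm  (%.3e eV^-1)\n", object@D_cm, object@D_eV))
  cat(sprintf("  product regression: R2 = %.3f, p = %.3g\n",
              object@R2, object@p))
  cat(sprintf("  fit error: %s\n",
              if (is.na(object@fitErrorPct)) "n/a (D ~ 0)"
              else sprintf("%.1f%%", object@fitErrorPct)))
  cat(sprintf("  max band shift: %s cm-1; sample-related (> %g cm-1): %s\n",
              paste(sprintf("%s %.2f", object@perBand$band,
                            object@perBand$maxShift), collapse = ", "),
              object@shiftThreshold,
              if (object@significant) "yes" else "no"))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig [%s]: grid %g-%g cm-1 step %g\n", object@label,
              object@gridLo, object@gridHi, object@gridStep))
  cat(sprintf("  dispersion model: %s; overtones: %s; emission amp: %g; noise sd: %g\n",
              object@dispersionModel, object@overtones,
              object@emissionAmp, object@noiseSd))
  on <- object@bands$height > 0
  cat(sprintf("  bands: %s\n",
              paste(sprintf("%s@%g", object@bands$band[on],
                            object@bands$center[on]), collapse = ", ")))
})
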