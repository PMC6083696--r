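#' @import methods
NULL

#' RamanSpectrum: a single Raman trace
#'
#' Container for one Raman spectrum: an ascending wavenumber axis (cm^-1),
#' the matching intensities (arbitrary units) and acquisition metadata.
#'
#' @slot wavenumber numeric, strictly increasing wavenumber axis in cm^-1.
#' @slot intensity numeric, intensities in arbitrary units, same length.
#' @slot excitation numeric(1), laser excitation wavelength in nm (NA if
#'   unknown).
#' @slot region character(1), free-text region/colour label (e.g. "red",
#'   "yellow", "white").
#' @slot replicate character(1), replicate identifier.
#' @slot source character(1), file path of origin or "synthetic"/"memory".
#'
#' @seealso [RamanSpectrum()] for the user constructor,
#'   [readSpectrum()]/[writeSpectrum()] for file I/O.
#' @exportClass RamanSpectrum
setClass("RamanSpectrum",
  representation(
    wavenumber = "numeric",
    intensity  = "numeric",
    excitation = "numeric",
    region     = "character",
    replicate  = "character",
    source     = "character"
  ),
  prototype(
    excitation = NA_real_,
    region     = NA_character_,
    replicate  = NA_character_,
    source     = "memory"
  )
)

setValidity("RamanSpectrum", function(object) {
  wn <- object@wavenumber
  y  <- object@intensity
  msg <- character(0)
  if (length(wn) != length(y))
    msg <- c(msg, "wavenumber and intensity must have equal length")
  if (length(wn) < 2L)
    msg <- c(msg, "a spectrum needs at least 2 points")
  if (anyNA(wn) || any(!is.finite(wn)))
    msg <- c(msg, "wavenumbers must be finite")
  if (length(wn) >= 2L && any(diff(wn) <= 0))
    msg <- c(msg, "wavenumber axis must be strictly increasing")
  if (any(!is.finite(y)))
    msg <- c(msg, "intensities must be finite")
  if (length(object@excitation) != 1L)
    msg <- c(msg, "excitation must be a single value (possibly NA)")
  if (!is.na(object@excitation) && object@excitation <= 0)
    msg <- c(msg, "excitation wavelength must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a RamanSpectrum
#'
#' A descending wavenumber axis is accepted and silently normalized to
#' ascending (intensities co-reversed); duplicate wavenumbers are rejected
#' as ambiguous.
#'
#' @param wavenumber numeric axis in cm^-1, strictly monotone.
#' @param intensity numeric intensities, same length.
#' @param excitation excitation wavelength in nm, or NA.
#' @param region region/colour label.
#' @param replicate replicate identifier.
#' @param source provenance string.
#' @return A [RamanSpectrum-class] object.
#' @examples
#' s <- RamanSpectrum(1000:1010, rnorm(11), excitation = 532)
#' wavenumbers(s)
#' @export
RamanSpectrum <- function(wavenumber, intensity, excitation = NA_real_,
                          region = NA_character_, replicate = NA_character_,
                          source = "memory") {
  wavenumber <- as.numeric(wavenumber)
  intensity  <- as.numeric(intensity)
  if (anyDuplicated(wavenumber))
    stop("duplicate wavenumbers in spectrum (ambiguous input)")
  if (length(wavenumber) >= 2L && all(diff(wavenumber) < 0)) {
    wavenumber <- rev(wavenumber)
    intensity  <- rev(intensity)
  }
  new("RamanSpectrum",
      wavenumber = wavenumber, intensity = intensity,
      excitation = as.numeric(excitation)[1L],
      region = as.character(region)[1L],
      replicate = as.character(replicate)[1L],
      source = as.character(source)[1L])
}

#' ExcitationSeries: spectra of one region keyed by excitation wavelength
#'
#' Holds the replicate-averaged spectra of a single feather region, one per
#' excitation wavelength, ordered by ascending wavelength and sharing a
#' common wavenumber grid.
#'
#' @slot region character(1), region label.
#' @slot spectra list of [RamanSpectrum-class], ordered by excitation.
#' @slot notes character(1), free text.
#' @exportClass ExcitationSeries
setClass("ExcitationSeries",
  representation(region = "character", spectra = "list", notes = "character"),
  prototype(region = NA_character_, notes = "")
)

setValidity("ExcitationSeries", function(object) {
  sp <- object@spectra
  msg <- character(0)
  if (!length(sp))
    msg <- c(msg, "series contains no spectra")
  if (!all(vapply(sp, is, logical(1), "RamanSpectrum")))
    msg <- c(msg, "all entries must be RamanSpectrum objects")
  else {
    exc <- vapply(sp, function(s) s@excitation, numeric(1))
    if (anyNA(exc))
      msg <- c(msg, "every member spectrum needs an excitation wavelength")
    else {
      if (anyDuplicated(exc))
        msg <- c(msg, "excitation wavelengths must be unique")
      if (is.unsorted(exc, strictly = TRUE))
        msg <- c(msg, "spectra must be ordered by ascending excitation")
    }
    if (length(sp) > 1L) {
      g <- sp[[1L]]@wavenumber
      same <- vapply(sp[-1L], function(s)
        length(s@wavenumber) == length(g) &&
          isTRUE(all.equal(s@wavenumber, g, tolerance = 1e-9)),
        logical(1))
      if (!all(same))
        msg <- c(msg, "member spectra must share a common wavenumber grid (resampleSpectrum first)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExcitationSeries
#'
#' @param spectra list of [RamanSpectrum-class] objects, each carrying an
#'   excitation wavelength; they are reordered by ascending wavelength.
#' @param region region label; defaults to the common label of the members.
#' @param notes free text.
#' @return An [ExcitationSeries-class] object.
#' @export
ExcitationSeries <- function(spectra, region = NULL, notes = "") {
  exc <- vapply(spectra, function(s) s@excitation, numeric(1))
  spectra <- spectra[order(exc)]
  if (is.null(region)) {
    labs <- unique(stats::na.omit(vapply(spectra, function(s) s@region,
                                         character(1))))
    region <- if (length(labs) == 1L) labs else NA_character_
  }
  new("ExcitationSeries", region = region, spectra = spectra, notes = notes)
}

#' RamanHyperMap: a pixel grid of spectra sharing one wavenumber axis
#'
#' @slot nRow,nCol integer grid dimensions.
#' @slot pixelSize numeric, spatial step in micrometres.
#' @slot wavenumber shared wavenumber axis (cm^-1).
#' @slot intensities numeric matrix, one row per pixel in row-major order
#'   (pixel (r, c) is row `(r-1)*nCol + c`), one column per wavenumber.
#' @slot excitation excitation wavelength in nm.
#' @exportClass RamanHyperMap
setClass("RamanHyperMap",
  representation(
    nRow = "integer", nCol = "integer", pixelSize = "numeric",
    wavenumber = "numeric", intensities = "matrix", excitation = "numeric"
  ),
  prototype(pixelSize = NA_real_, excitation = NA_real_)
)

setValidity("RamanHyperMap", function(object) {
  msg <- character(0)
  if (object@nRow < 1L || object@nCol < 1L)
    msg <- c(msg, "grid dimensions must be positive")
  if (nrow(object@intensities) != object@nRow * object@nCol)
    msg <- c(msg, "number of pixel spectra must equal nRow * nCol")
  if (ncol(object@intensities) != length(object@wavenumber))
    msg <- c(msg, "intensity columns must match the wavenumber axis")
  if (length(object@wavenumber) >= 2L && any(diff(object@wavenumber) <= 0))
    msg <- c(msg, "wavenumber axis must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Construct a RamanHyperMap
#'
#' @param intensities pixel-by-wavenumber intensity matrix (row-major pixel
#'   order).
#' @param wavenumber shared wavenumber axis.
#' @param nRow,nCol grid dimensions.
#' @param pixelSize pixel pitch in micrometres.
#' @param excitation excitation wavelength in nm.
#' @return A [RamanHyperMap-class] object.
#' @export
RamanHyperMap <- function(intensities, wavenumber, nRow, nCol,
                          pixelSize = NA_real_, excitation = NA_real_) {
  new("RamanHyperMap",
      nRow = as.integer(nRow), nCol = as.integer(nCol),
      pixelSize = as.numeric(pixelSize),
      wavenumber = as.numeric(wavenumber),
      intensities = as.matrix(intensities),
      excitation = as.numeric(excitation)[1L])
}

#' Peak: one fitted Raman band
#'
#' @slot band band identifier ("CC", "CC2", "keratin_1006", ...).
#' @slot center fitted band center in cm^-1.
#' @slot height peak height above the local linear background, a.u.
#' @slot fwhm full width at half maximum in cm^-1 (NA when not estimable).
#' @slot window search window (lo, hi) in cm^-1.
#' @slot snr height over the robust noise level of the detrended window.
#' @slot method "argmax_parabolic" or "lorentzian_ls".
#' @slot flags zero or more of "edge", "fallback_argmax", "fwhm_edge".
#' @exportClass Peak
setClass("Peak",
  representation(
    band = "character", center = "numeric", height = "numeric",
    fwhm = "numeric", window = "numeric", snr = "numeric",
    method = "character", flags = "character"
  )
)

setValidity("Peak", function(object) {
  msg <- character(0)
  if (length(object@window) != 2L || object@window[1] >= object@window[2])
    msg <- c(msg, "window must be (lo, hi) with lo < hi")
  if (object@center < object@window[1] || object@center > object@window[2])
    msg <- c(msg, "center must lie inside the search window")
  clean <- !length(object@flags)
  if (clean && !(is.finite(object@height) && object@height > 0))
    msg <- c(msg, "height must be positive for an unflagged peak")
  if (clean && !is.na(object@fwhm) && object@fwhm <= 0)
    msg <- c(msg, "fwhm must be positive")
  if (!is.na(object@snr) && object@snr < 0)
    msg <- c(msg, "snr must be non-negative")
  if (length(msg)) msg else TRUE
})

#' BandTrack: one band followed across an excitation series
#'
#' Records the fitted band center at every included excitation wavelength,
#' the reference value (the center measured at the lowest excitation
#' energy, i.e. longest wavelength) and any excluded wavelengths with the
#' reason for exclusion.
#'
#' @slot band band identifier.
#' @slot window search window (lo, hi) in cm^-1.
#' @slot points data.frame with columns excitation_nm, E_invcm, E_eV,
#'   center, height, fwhm, snr, flags; one row per included excitation.
#' @slot reference list(center, excitation_nm, E_invcm) for the reference
#'   excitation.
#' @slot excluded data.frame with columns excitation_nm, reason.
#' @exportClass BandTrack
setClass("BandTrack",
  representation(
    band = "character", window = "numeric", points = "data.frame",
    reference = "list", excluded = "data.frame"
  )
)

setValidity("BandTrack", function(object) {
  p <- object@points
  msg <- character(0)
  need <- c("excitation_nm", "E_invcm", "E_eV", "center")
  if (!all(need %in% names(p)))
    msg <- c(msg, paste("points needs columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(p) < 1L)
      msg <- c(msg, "track has no included points")
    else {
      if (abs(object@reference$E_invcm - min(p$E_invcm)) > 1e-9)
        msg <- c(msg, "reference must be the included point with lowest excitation energy")
      w <- object@window
      if (any(p$center < w[1] | p$center > w[2]))
        msg <- c(msg, "all tracked centers must lie inside the band window")
    }
    if (nrow(object@excluded) &&
        length(intersect(object@excluded$excitation_nm, p$excitation_nm)))
      msg <- c(msg, "excluded and included excitations must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' DispersionFit: amplitude-mode-model dispersion analysis result
#'
#' Output of [fitDispersion()]: the per-excitation product-rule values
#' (the effective electron-phonon coupling 2*lambda-bar), the dispersion
#' rate D obtained as the regression slope of that product on excitation
#' energy, per-band regressions, and diagnostics.
#'
#' @slot products data.frame: excitation_nm, E_invcm, E_eV, product.
#' @slot perBand data.frame: band, slope_cm, intercept, R2, p, maxShift.
#' @slot D_cm dispersion rate, slope vs energy in cm^-1 (units cm).
#' @slot D_eV dispersion rate, slope vs energy in eV (units 1/eV);
#'   always D_cm * 8065.544.
#' @slot se_cm standard error of D_cm.
#' @slot R2,p coefficient of determination and two-sided slope p-value of
#'   the product regression (energy-axis invariant).
#' @slot fitErrorPct relative precision of D, 100 * SE / |D| (NA when D is
#'   numerically zero).
#' @slot nPoints number of included excitations.
#' @slot significant TRUE when any band shifts by more than the
#'   sample-related threshold (3 cm^-1) across the series.
#' @slot shiftThreshold the threshold used for `significant`, cm^-1.
#' @slot energyAxis axis the regression was computed on ("invcm" or "eV").
#' @slot tracks the list of [BandTrack-class] objects used.
#' @exportClass DispersionFit
setClass("DispersionFit",
  representation(
    products = "data.frame", perBand = "data.frame",
    D_cm = "numeric", D_eV = "numeric", se_cm = "numeric",
    R2 = "numeric", p = "numeric", fitErrorPct = "numeric",
    nPoints = "integer", significant = "logical",
    shiftThreshold = "numeric", energyAxis = "character",
    tracks = "list"
  )
)

setValidity("DispersionFit", function(object) {
  msg <- character(0)
  if (object@nPoints < 3L)
    msg <- c(msg, "a dispersion fit needs at least 3 excitations")
  if (any(object@products$product <= 0))
    msg <- c(msg, "product-rule values must be positive")
  if (is.finite(object@D_cm) &&
      abs(object@D_eV - object@D_cm * 8065.544) >
        1e-9 * max(1, abs(object@D_eV)))
    msg <- c(msg, "D_eV must equal D_cm * 8065.544")
  if (length(msg)) msg else TRUE
})

#' SimConfig: ground truth for the synthetic spectrum generator
#'
#' Describes the simulated sample: pigment and keratin band parameters,
#' the frequency-dispersion mechanism (none / linear in excitation energy /
#' a resonance-weighted chromophore ensemble), overtones, emission
#' background, polynomial baseline and noise.
#'
#' @slot label free-text label ("red-like", "yellow-like", ...).
#' @slot gridLo,gridHi,gridStep wavenumber grid in cm^-1.
#' @slot bands data.frame: band, center, height, fwhm. Bands "CC" and
#'   "CC2" are the pigment doublet; "keratin_*" are matrix bands.
#' @slot dispersionModel "none", "linear" or "ensemble".
#' @slot linearSlopes named numeric (CC, CC2): band-center shift in cm^-1
#'   per cm^-1 of excitation energy.
#' @slot linearRefEnergy excitation energy (cm^-1) at which linear-model
#'   centers equal their configured values.
#' @slot ensemble data.frame: weight, CC, CC2, eAbs, gamma. Each row is a
#'   chromophore sub-population with its band centers, absorption maximum
#'   (cm^-1) and resonance half-width Gamma (cm^-1).
#' @slot overtones logical; emit first overtones at twice the pigment
#'   band centers.
#' @slot overtoneRelHeight overtone height relative to the fundamental.
#' @slot emissionAmp,emissionCenter,emissionWidth broad Gaussian emission
#'   background (a.u., cm^-1, cm^-1).
#' @slot baseline polynomial baseline coefficients on the unit-scaled
#'   axis u = (wavenumber - gridLo) / (gridHi - gridLo).
#' @slot noiseSd standard deviation of additive Gaussian noise, a.u.
#' @slot seed base random seed.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    label = "character",
    gridLo = "numeric", gridHi = "numeric", gridStep = "numeric",
    bands = "data.frame",
    dispersionModel = "character",
    linearSlopes = "numeric", linearRefEnergy = "numeric",
    ensemble = "data.frame",
    overtones = "logical", overtoneRelHeight = "numeric",
    emissionAmp = "numeric", emissionCenter = "numeric",
    emissionWidth = "numeric",
    baseline = "numeric", noiseSd = "numeric", seed = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@gridStep <= 0) msg <- c(msg, "gridStep must be positive")
  if (object@gridLo >= object@gridHi) msg <- c(msg, "gridLo must be < gridHi")
  if (any(object@bands$height < 0)) msg <- c(msg, "band heights must be >= 0")
  if (any(object@bands$fwhm <= 0)) msg <- c(msg, "band fwhm must be positive")
  if (!object@dispersionModel %in% c("none", "linear", "ensemble"))
    msg <- c(msg, "dispersionModel must be none, linear or ensemble")
  if (object@dispersionModel == "ensemble") {
    e <- object@ensemble
    if (!nrow(e)) msg <- c(msg, "ensemble model needs at least one member")
    else {
      if (any(e$weight < 0) || sum(e$weight) == 0)
        msg <- c(msg, "ensemble weights must be >= 0 and not all zero")
      if (any(e$gamma <= 0))
        msg <- c(msg, "ensemble resonance widths must be positive")
    }
  }
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})
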