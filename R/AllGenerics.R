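#' @rdname RamanSpectrum-class
#' @param object,x a RamanAMM object
#' @export
setGeneric("wavenumbers", function(object) standardGeneric("wavenumbers"))

#' @rdname RamanSpectrum-class
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname RamanSpectrum-class
#' @export
setGeneric("excitationNm", function(object) standardGeneric("excitationNm"))

#' @rdname RamanSpectrum-class
#' @export
setGeneric("regionLabel", function(object) standardGeneric("regionLabel"))

#' @rdname RamanSpectrum-class
#' @export
setGeneric("replicateId", function(object) standardGeneric("replicateId"))

#' @rdname DispersionFit-class
#' @export
setGeneric("dispersionRate",
           function(object, units = c("cm", "eV")) standardGeneric("dispersionRate"))

#' @rdname BandTrack-class
#' @export
setGeneric("peakTable", function(object) standardGeneric("peakTable"))
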