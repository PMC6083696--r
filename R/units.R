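# 1 eV = 8065.544 cm^-1 (CODATA, truncated to the precision customary in
# vibrational spectroscopy)
EV_PER_INVCM <- 8065.544

#' Unit bridges between wavelength, wavenumber and electronvolt
#'
#' Excitation energies are used on two axes: absolute wavenumber
#' (cm^-1 = 1e7 / wavelength-in-nm) and electronvolt
#' (eV = cm^-1 / 8065.544).
#'
#' @param nm wavelength in nanometres (> 0).
#' @param invcm energy in cm^-1.
#' @param eV energy in electronvolt.
#' @return numeric vector in the target unit.
#' @examples
#' nmToInvcm(500)          # 20000
#' invcmToEv(8065.544)     # 1
#' @export
nmToInvcm <- function(nm) {
  if (any(!is.finite(nm)) || any(nm <= 0))
    stop("wavelength must be positive and finite")
  1e7 / nm
}

#' @rdname nmToInvcm
#' @export
invcmToNm <- function(invcm) {
  if (any(!is.finite(invcm)) || any(invcm <= 0))
    stop("wavenumber must be positive and finite")
  1e7 / invcm
}

#' @rdname nmToInvcm
#' @export
invcmToEv <- function(invcm) {
  if (any(!is.finite(invcm))) stop("input must be finite")
  invcm / EV_PER_INVCM
}

#' @rdname nmToInvcm
#' @export
evToInvcm <- function(eV) {
  if (any(!is.finite(eV))) stop("input must be finite")
  eV * EV_PER_INVCM
}

# run expr with a fixed RNG state, restoring the caller's stream
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  eval.parent(substitute(expr))
}
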