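#' Squared frequency ratios of a band track
#'
#' For each included excitation, `(nu_nR / nu_0R)^2`: the band wavenumber
#' at that excitation over the reference wavenumber (lowest excitation
#' energy), squared. The value at the reference excitation is exactly 1.
#'
#' @param track a [BandTrack-class].
#' @return data.frame: excitation_nm, E_invcm, E_eV, ratio2.
#' @export
ratioSquared <- function(track) {
  stopifnot(is(track, "BandTrack"))
  ref <- track@reference$center
  if (!is.finite(ref) || ref <= 0)
    stop("reference wavenumber must be positive")
  p <- track@points
  data.frame(excitation_nm = p$excitation_nm,
             E_invcm = p$E_invcm, E_eV = p$E_eV,
             ratio2 = (p$center / ref)^2)
}

#' Product-rule effective electron-phonon coupling (2 lambda-bar)
#'
#' The amplitude-mode-model product rule: at each excitation energy the
#' product over all dispersing modes of `(nu_nR / nu_0R)^2` equals twice
#' the effective electron-phonon coupling constant. With a single track
#' the product reduces to that track's squared ratio.
#'
#' @param tracks list of [BandTrack-class] sharing the same included
#'   excitations and reference excitation.
#' @return data.frame: excitation_nm, E_invcm, E_eV, product.
#' @export
ammProduct <- function(tracks) {
  if (is(tracks, "BandTrack")) tracks <- list(tracks)
  stopifnot(length(tracks) >= 1L,
            all(vapply(tracks, is, logical(1), "BandTrack")))
  ratios <- lapply(tracks, ratioSquared)
  ref <- ratios[[1L]][, c("excitation_nm", "E_invcm", "E_eV")]
  for (k in seq_along(ratios)[-1L]) {
    a <- ratios[[1L]]$excitation_nm
    b <- ratios[[k]]$excitation_nm
    if (length(a) != length(b) || any(sort(a) != sort(b))) {
      diff1 <- setdiff(a, b)
      diff2 <- setdiff(b, a)
      stop("tracks cover different excitation sets; only in first: {",
           paste(diff1, collapse = ", "), "}, only in track ", k, ": {",
           paste(diff2, collapse = ", "), "}")
    }
    if (abs(tracks[[k]]@reference$excitation_nm -
            tracks[[1L]]@reference$excitation_nm) > 1e-9)
      stop("tracks use different reference excitations")
  }
  prod <- Reduce(`*`, lapply(ratios, function(r)
    r$ratio2[order(r$excitation_nm)]))
  ord <- order(ref$excitation_nm)
  out <- ref[ord, , drop = FALSE]
  out$product <- prod
  out <- out[order(out$E_invcm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the amplitude-mode-model dispersion rate
#'
#' Ordinary least squares of the product-rule values (2 lambda-bar) on
#' excitation energy. The slope is the dispersion rate D; it is reported
#' on both energy axes (D_cm against energy in cm^-1, with units cm, and
#' D_eV = D_cm * 8065.544 against energy in eV, units 1/eV). R-squared
#' and the two-sided slope t-test p-value (n - 2 degrees of freedom) are
#' energy-axis invariant. The model fit error is the relative precision
#' of the slope, 100 * SE(D) / |D|. Per-band regressions of the squared
#' ratios on energy are reported alongside, together with each band's
#' center range (max shift); the fit is flagged sample-related
#' (`significant`) when any band shifts by more than `shiftThreshold`
#' (default 3 cm^-1, the combined spectral/calibration resolution bound).
#'
#' @param tracks list of [BandTrack-class] (or a single track) sharing
#'   included excitations; typically the C-C and C=C pigment bands.
#' @param energyAxis axis on which the regression is computed, "invcm"
#'   (default) or "eV"; results are reported in both unit systems either
#'   way.
#' @param shiftThreshold sample-related shift threshold in cm^-1.
#' @return A [DispersionFit-class].
#' @export
fitDispersion <- function(tracks, energyAxis = c("invcm", "eV"),
                          shiftThreshold = 3) {
  energyAxis <- match.arg(energyAxis)
  if (is(tracks, "BandTrack")) tracks <- list(tracks)
  products <- ammProduct(tracks)
  n <- nrow(products)
  if (n < 3L) stop("need at least 3 included excitations")
  E <- if (energyAxis == "invcm") products$E_invcm else products$E_eV
  if (stats::var(E) == 0) stop("zero variance in excitation energy (singular design)")

  regress <- function(yv, Ev) {
    fit <- stats::lm(yv ~ Ev)
    sm <- suppressWarnings(summary(fit))   # flat responses are handled below
    slope <- unname(stats::coef(fit)[2L])
    se <- sm$coefficients[2L, 2L]
    r2 <- sm$r.squared
    pval <- sm$coefficients[2L, 4L]
    if (all(abs(yv - mean(yv)) < 1e-14)) {   # exactly flat response
      slope <- 0
      r2 <- NA_real_
      pval <- NA_real_
      se <- NA_real_
    }
    list(slope = slope, intercept = unname(stats::coef(fit)[1L]),
         se = se, R2 = r2, p = pval)
  }

  prodFit <- regress(products$product, E)
  toCm <- if (energyAxis == "invcm") 1 else 1 / EV_PER_INVCM
  D_cm <- prodFit$slope * toCm
  se_cm <- prodFit$se * toCm
  D_eV <- D_cm * EV_PER_INVCM
  fitErr <- if (is.na(prodFit$se) || abs(D_cm) < 1e-15) NA_real_
            else 100 * se_cm / abs(D_cm)

  perBand <- do.call(rbind, lapply(tracks, function(tr) {
    r <- ratioSquared(tr)
    Eb <- if (energyAxis == "invcm") r$E_invcm else r$E_eV
    bf <- regress(r$ratio2, Eb)
    data.frame(band = tr@band,
               slope_cm = bf$slope * toCm,
               intercept = bf$intercept,
               R2 = bf$R2, p = bf$p,
               maxShift = diff(range(tr@points$center)),
               stringsAsFactors = FALSE)
  }))
  rownames(perBand) <- NULL

  new("DispersionFit",
      products = products, perBand = perBand,
      D_cm = D_cm, D_eV = D_eV, se_cm = se_cm,
      R2 = prodFit$R2, p = prodFit$p, fitErrorPct = fitErr,
      nPoints = as.integer(n),
      significant = any(perBand$maxShift > shiftThreshold),
      shiftThreshold = shiftThreshold,
      energyAxis = energyAxis, tracks = tracks)
}

#' Hue ordering of psittacofulvin-pigmented feathers
#'
#' The ordered hue scale magenta < red < orange < yellow (increasingly
#' "blue-shifted" absorption).
#'
#' @return character vector of hue levels in order.
#' @export
hueLevels <- function() c("magenta", "red", "orange", "yellow")

#' Hue trend of pigment band positions
#'
#' Summarizes, across a panel of feathers, how the C-C and C=C band
#' positions move along the hue scale (magenta = 1 ... yellow = 4):
#' per-hue median/min/max and the Spearman rank correlation between hue
#' order and band position (average ranks for ties; a constant band
#' position is reported as rho = 0).
#'
#' @param records data.frame with columns `specimen_id`, `hue` (values
#'   from [hueLevels()]), `nu_cc` and `nu_cc2` (band centers in cm^-1).
#' @return list with elements `summary` (per hue x band) and `spearman`
#'   (band, rho, p, n).
#' @export
hueTrend <- function(records) {
  need <- c("hue", "nu_cc", "nu_cc2")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  hue <- factor(records$hue, levels = hueLevels(), ordered = TRUE)
  if (anyNA(hue))
    stop("unknown hue value(s): ",
         paste(unique(records$hue[is.na(hue)]), collapse = ", "))
  if (length(unique(hue)) < 2L)
    stop("need at least 2 hue categories for a trend (degenerate input)")
  rank <- as.integer(hue)

  bands <- c(nu_cc = "nu_cc", nu_cc2 = "nu_cc2")
  summary <- do.call(rbind, lapply(names(bands), function(b) {
    v <- records[[b]]
    agg <- vapply(levels(hue)[levels(hue) %in% hue], function(h) {
      vi <- v[hue == h]
      c(median = stats::median(vi), min = min(vi), max = max(vi),
        n = length(vi))
    }, numeric(4))
    data.frame(band = b, hue = colnames(agg),
               median = agg["median", ], min = agg["min", ],
               max = agg["max", ], n = agg["n", ],
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  spearman <- do.call(rbind, lapply(names(bands), function(b) {
    v <- records[[b]]
    if (stats::sd(v) == 0) {
      rho <- 0; pval <- 1
    } else {
      ct <- suppressWarnings(
        stats::cor.test(rank, v, method = "spearman", exact = FALSE))
      rho <- unname(ct$estimate); pval <- ct$p.value
    }
    data.frame(band = b, rho = rho, p = pval, n = length(v),
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, spearman = spearman)
}
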