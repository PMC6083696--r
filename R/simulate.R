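lorentzianShape <- function(x, center, height, fwhm) {
  hw2 <- (fwhm / 2)^2
  height * hw2 / ((x - center)^2 + hw2)
}

#' The standard excitation wavelength list
#'
#' The 13 laser lines of the reference resonance experiment: krypton-ion
#' 351/407/413/568/648 nm, solid-state 375/448/532/594 nm and
#' 458/491/515 nm, plus the 785 nm mapping line.
#'
#' @return numeric vector of wavelengths in nm, ascending.
#' @export
defaultExcitations <- function() {
  sort(c(351, 407, 413, 568, 648, 375, 448, 532, 594, 458, 491, 515, 785))
}

#' Default band table of the synthetic sample
#'
#' Pigment doublet (CC 1137, CC2 1531 cm^-1) plus the four beta-keratin
#' matrix bands; heights are relative a.u., widths FWHM in cm^-1.
#'
#' @return data.frame with columns band, center, height, fwhm.
#' @export
defaultBands <- function() {
  data.frame(
    band   = c("CC", "CC2", "keratin_1006", "keratin_1240",
               "keratin_1450", "keratin_1670"),
    center = c(1137, 1531, 1006, 1240, 1450, 1670),
    height = c(1.00, 1.20, 0.20, 0.15, 0.15, 0.20),
    fwhm   = c(12, 14, 8, 18, 16, 20),
    stringsAsFactors = FALSE)
}

#' Build a synthetic-sample configuration
#'
#' The generator emulates feather Raman spectra: a psittacofulvin
#' doublet near 1137 / 1531 cm^-1, four beta-keratin matrix bands,
#' optional first overtones at twice the pigment centers, a broad
#' Gaussian emission background, a polynomial baseline and additive
#' Gaussian noise. Frequency dispersion of the pigment doublet follows
#' one of three mechanisms: `"none"` (single chromophore, yellow-like),
#' `"linear"` (centers move linearly with excitation energy) or
#' `"ensemble"` (a resonance-weighted mixture of chromophore
#' sub-populations, red-like).
#'
#' @param label free-text label.
#' @param gridLo,gridHi,gridStep wavenumber grid (cm^-1); default
#'   900-1800 at 1 cm^-1.
#' @param bands band table (band, center, height, fwhm).
#' @param dispersionModel "none", "linear" or "ensemble".
#' @param linearSlopes named c(CC=, CC2=) shift in cm^-1 per cm^-1 of
#'   excitation energy (linear model).
#' @param linearRefEnergy energy (cm^-1) where linear-model centers equal
#'   the configured ones; default the 648 nm line.
#' @param ensemble ensemble member table (weight, CC, CC2, eAbs, gamma).
#' @param overtones emit first overtones at 2x the pigment centers.
#' @param overtoneRelHeight overtone height relative to the fundamental.
#' @param emissionAmp,emissionCenter,emissionWidth broad Gaussian
#'   emission background.
#' @param baseline polynomial coefficients on the unit-scaled axis.
#' @param noiseSd additive Gaussian noise s.d. (0.02 gives SNR ~ 50 for
#'   a unit-height band).
#' @param seed base random seed.
#' @return A [SimConfig-class].
#' @export
simConfig <- function(label = "custom",
                      gridLo = 900, gridHi = 1800, gridStep = 1,
                      bands = defaultBands(),
                      dispersionModel = "none",
                      linearSlopes = c(CC = 0, CC2 = 0),
                      linearRefEnergy = nmToInvcm(648),
                      ensemble = data.frame(),
                      overtones = FALSE, overtoneRelHeight = 0.15,
                      emissionAmp = 0, emissionCenter = 1300,
                      emissionWidth = 900,
                      baseline = 0, noiseSd = 0.02, seed = 1) {
  new("SimConfig", label = label,
      gridLo = gridLo, gridHi = gridHi, gridStep = gridStep,
      bands = bands, dispersionModel = dispersionModel,
      linearSlopes = linearSlopes, linearRefEnergy = linearRefEnergy,
      ensemble = ensemble,
      overtones = overtones, overtoneRelHeight = overtoneRelHeight,
      emissionAmp = emissionAmp, emissionCenter = emissionCenter,
      emissionWidth = emissionWidth,
      baseline = as.numeric(baseline), noiseSd = noiseSd, seed = seed)
}

#' Preset configurations
#'
#' `redLikeConfig()`: a three-member chromophore ensemble whose band
#' centers spread over ~1131-1143 (C-C) and ~1524-1544 cm^-1 (C=C) with
#' absorption maxima from ~380 to ~680 nm; resonance selection then
#' shifts the apparent centers with excitation energy, giving a fitted
#' dispersion rate of order 1e-6 cm. `yellowLikeConfig()`: a single
#' chromophore (no dispersion) over a strong broad emission background
#' and noisier acquisition. `keratinConfig()`: unpigmented (white)
#' feather, matrix bands only. `pigmentOnlyConfig()`: doublet without
#' matrix bands. `linearConfig(D_true)`: linear dispersion calibrated so
#' the small-shift closed form 2 * sum(s_b / nu0_b) equals `D_true`,
#' split equally between the two bands.
#'
#' @param noiseSd,seed see [simConfig()].
#' @return A [SimConfig-class].
#' @rdname presets
#' @export
redLikeConfig <- function(noiseSd = 0.02, seed = 1) {
  simConfig(label = "red-like",
            dispersionModel = "ensemble",
            ensemble = data.frame(
              weight = c(1, 1, 1) / 3,
              CC   = c(1131, 1137, 1143),
              CC2  = c(1524, 1534, 1544),
              eAbs = 1e7 / c(680, 500, 380),
              gamma = c(2200, 2200, 2200)),
            noiseSd = noiseSd, seed = seed)
}

#' @rdname presets
#' @export
yellowLikeConfig <- function(noiseSd = 0.04, seed = 1) {
  b <- defaultBands()
  b$center[b$band == "CC"] <- 1140
  b$center[b$band == "CC2"] <- 1538
  simConfig(label = "yellow-like", bands = b, dispersionModel = "none",
            emissionAmp = 0.5, noiseSd = noiseSd, seed = seed)
}

#' @rdname presets
#' @export
keratinConfig <- function(noiseSd = 0.02, seed = 1) {
  b <- defaultBands()
  b$height[b$band %in% c("CC", "CC2")] <- 0
  simConfig(label = "white", bands = b, noiseSd = noiseSd, seed = seed)
}

#' @rdname presets
#' @export
pigmentOnlyConfig <- function(noiseSd = 0.02, seed = 1) {
  b <- defaultBands()
  b$height[grepl("^keratin", b$band)] <- 0
  simConfig(label = "pigment-only", bands = b, noiseSd = noiseSd,
            seed = seed)
}

#' @rdname presets
#' @param D_true target small-shift dispersion rate in cm.
#' @export
linearConfig <- function(D_true = 3.5e-6, noiseSd = 0.02, seed = 1) {
  b <- defaultBands()
  refs <- c(CC = b$center[b$band == "CC"], CC2 = b$center[b$band == "CC2"])
  simConfig(label = "linear", dispersionModel = "linear",
            linearSlopes = refs * D_true / 4,
            noiseSd = noiseSd, seed = seed)
}

#' Resonance-weighted apparent band center of a chromophore ensemble
#'
#' Each ensemble member is weighted by its population weight times a
#' Lorentzian resonance factor `gamma^2 / ((E_L - E_abs)^2 + gamma^2)`;
#' the apparent center is the weighted mean of the member centers. When
#' every resonance factor underflows numerically the population weights
#' are used unchanged and a `fallback` attribute is set.
#'
#' @param ensemble ensemble member table (weight, CC, CC2, eAbs, gamma).
#' @param band "CC" or "CC2".
#' @param E_L excitation energy in cm^-1.
#' @return apparent center in cm^-1 (with attribute `fallback` = TRUE
#'   when resonance weighting degenerated).
#' @export
ensembleBandCenter <- function(ensemble, band = c("CC", "CC2"), E_L) {
  band <- match.arg(band)
  if (!nrow(ensemble)) stop("empty ensemble")
  res <- ensemble$gamma^2 / ((E_L - ensemble$eAbs)^2 + ensemble$gamma^2)
  w <- ensemble$weight * res
  if (sum(w) < .Machine$double.xmin * nrow(ensemble)) {
    out <- sum(ensemble$weight * ensemble[[band]]) / sum(ensemble$weight)
    attr(out, "fallback") <- TRUE
    return(out)
  }
  sum(w * ensemble[[band]]) / sum(w)
}

# ground-truth pigment band centers for one excitation
pigmentCenters <- function(config, excitation_nm) {
  b <- config@bands
  base <- c(CC = b$center[b$band == "CC"],
            CC2 = b$center[b$band == "CC2"])
  switch(config@dispersionModel,
    none = base,
    linear = {
      dE <- nmToInvcm(excitation_nm) - config@linearRefEnergy
      base + config@linearSlopes[c("CC", "CC2")] * dE
    },
    ensemble = {
      E <- nmToInvcm(excitation_nm)
      c(CC = as.numeric(ensembleBandCenter(config@ensemble, "CC", E)),
        CC2 = as.numeric(ensembleBandCenter(config@ensemble, "CC2", E)))
    })
}

#' Simulate one Raman spectrum
#'
#' Sums Lorentzian bands at the (possibly excitation-shifted) pigment
#' centers and the fixed keratin centers, adds optional overtones at
#' twice the pigment centers, the polynomial baseline, the Gaussian
#' emission background and i.i.d. Gaussian noise. The ground-truth band
#' centers are attached as attribute `"truth"`.
#'
#' @param config a [SimConfig-class].
#' @param excitation_nm excitation wavelength in nm.
#' @param seed random seed (default `config@seed`); the caller's RNG
#'   stream is left untouched.
#' @return A [RamanSpectrum-class] with a `truth` attribute.
#' @export
simulateSpectrum <- function(config, excitation_nm = 532,
                             seed = config@seed) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  x <- seq(config@gridLo, config@gridHi, by = config@gridStep)
  b <- config@bands
  active <- b$height > 0
  if (any(active & (b$center < config@gridLo | b$center > config@gridHi)))
    stop("configured band center(s) outside the wavenumber grid")

  pc <- pigmentCenters(config, excitation_nm)
  y <- numeric(length(x))
  truthCenters <- c()
  for (i in which(active)) {
    ctr <- if (b$band[i] %in% c("CC", "CC2")) pc[[b$band[i]]]
           else b$center[i]
    y <- y + lorentzianShape(x, ctr, b$height[i], b$fwhm[i])
    truthCenters[b$band[i]] <- ctr
    if (config@overtones && b$band[i] %in% c("CC", "CC2") &&
        2 * ctr <= config@gridHi)
      y <- y + lorentzianShape(x, 2 * ctr,
                               config@overtoneRelHeight * b$height[i],
                               1.5 * b$fwhm[i])
  }
  if (any(config@baseline != 0)) {
    u <- (x - config@gridLo) / (config@gridHi - config@gridLo)
    y <- y + drop(outer(u, seq_along(config@baseline) - 1, `^`) %*%
                    config@baseline)
  }
  if (config@emissionAmp > 0)
    y <- y + config@emissionAmp *
      exp(-0.5 * ((x - config@emissionCenter) / config@emissionWidth)^2)
  if (config@noiseSd > 0)
    y <- y + withSeed(seed, stats::rnorm(length(x), sd = config@noiseSd))

  out <- RamanSpectrum(x, y, excitation = excitation_nm,
                       region = config@label, replicate = "sim",
                       source = "synthetic")
  attr(out, "truth") <- list(excitation_nm = excitation_nm,
                             centers = truthCenters,
                             emissionAmp = config@emissionAmp,
                             noiseSd = config@noiseSd)
  out
}

#' Simulate an excitation series with known dispersion
#'
#' Generates `replicates` noisy spectra per excitation wavelength,
#' averages the raw replicates (the excitation-series workflow) and
#' returns the resulting [ExcitationSeries-class] together with the
#' generator's ground truth from [trueDispersion()].
#'
#' @param config a [SimConfig-class].
#' @param excitations excitation wavelengths in nm (>= 3, unique).
#' @param replicates replicate spectra per excitation (default 3).
#' @param seed base random seed.
#' @return list(series, replicates, truth); `replicates` is a list (one
#'   entry per excitation) of the individual noisy spectra.
#' @export
simulateSeries <- function(config, excitations = defaultExcitations(),
                           replicates = 3, seed = config@seed) {
  stopifnot(is(config, "SimConfig"))
  if (length(excitations) < 3L) stop("need at least 3 excitations")
  if (anyDuplicated(excitations)) stop("duplicate excitation wavelengths")
  excitations <- sort(excitations)
  reps <- list()
  averaged <- list()
  for (i in seq_along(excitations)) {
    w <- excitations[i]
    ri <- lapply(seq_len(replicates), function(r) {
      s <- simulateSpectrum(config, w, seed = seed + 1009L * i + r)
      s@replicate <- paste0("r", r)
      s
    })
    reps[[as.character(w)]] <- ri
    averaged[[i]] <- averageReplicates(ri)
  }
  list(series = ExcitationSeries(averaged, region = config@label),
       replicates = reps,
       truth = trueDispersion(config, excitations))
}

#' Ground-truth dispersion of a configuration
#'
#' From the noiseless band centers implied by the configuration at the
#' given excitations: per-band center tables and linear slopes, the
#' exact product-rule values (reference = lowest excitation energy), the
#' dispersion rate `D_cm` as the exact least-squares slope of those
#' products on energy in cm^-1, and the small-shift closed form
#' `2 * sum(s_b / nu0_b)` (linear model only).
#'
#' @param config a [SimConfig-class].
#' @param excitations excitation wavelengths in nm.
#' @return list(centers, slopes, D_cm, D_eV, D_closed, refExcitation).
#' @export
trueDispersion <- function(config, excitations) {
  excitations <- sort(excitations)
  E <- nmToInvcm(excitations)
  cc <- vapply(excitations, function(w)
    pigmentCenters(config, w)[["CC"]], numeric(1))
  cc2 <- vapply(excitations, function(w)
    pigmentCenters(config, w)[["CC2"]], numeric(1))
  centers <- data.frame(excitation_nm = excitations, E_invcm = E,
                        CC = cc, CC2 = cc2)
  refIdx <- which.min(E)
  prod <- (cc / cc[refIdx])^2 * (cc2 / cc2[refIdx])^2
  D_cm <- if (max(abs(prod - mean(prod))) < 1e-14) 0
          else unname(stats::coef(stats::lm(prod ~ E))[2L])
  slopes <- c(
    CC = if (max(abs(cc - mean(cc))) < 1e-12) 0
         else unname(stats::coef(stats::lm(cc ~ E))[2L]),
    CC2 = if (max(abs(cc2 - mean(cc2))) < 1e-12) 0
          else unname(stats::coef(stats::lm(cc2 ~ E))[2L]))
  D_closed <- if (config@dispersionModel == "linear")
    2 * sum(config@linearSlopes[c("CC", "CC2")] /
              c(cc[refIdx], cc2[refIdx]))
  else 2 * sum(slopes / c(cc[refIdx], cc2[refIdx]))
  list(centers = centers, slopes = slopes,
       D_cm = D_cm, D_eV = D_cm * EV_PER_INVCM,
       D_closed = D_closed,
       refExcitation = excitations[refIdx])
}

#' Simulate band tracks directly (no spectra)
#'
#' A lightweight linear generator for calibration studies of the
#' dispersion fit alone: band centers move linearly with excitation
#' energy from their reference values and are jittered with Gaussian
#' center noise. Slopes are calibrated so the small-shift closed form
#' equals `D_true`, split equally between the two bands.
#'
#' @param nExc number of excitation energies.
#' @param eRange range of excitation energies in cm^-1.
#' @param D_true target dispersion rate in cm.
#' @param refs named reference centers c(CC=, CC2=) in cm^-1.
#' @param jitterSd center noise s.d. in cm^-1.
#' @param seed random seed.
#' @return list(tracks, D_true_exact, D_closed, slopes).
#' @export
simulateLinearTracks <- function(nExc = 10, eRange = c(15400, 26700),
                                 D_true = 3.5e-6,
                                 refs = c(CC = 1137, CC2 = 1531),
                                 jitterSd = 0.5, seed = 1) {
  E <- seq(eRange[1], eRange[2], length.out = nExc)
  E0 <- min(E)
  slopes <- refs * D_true / 4
  wl <- invcmToNm(E)
  noiselessCC <- refs[["CC"]] + slopes[["CC"]] * (E - E0)
  noiselessCC2 <- refs[["CC2"]] + slopes[["CC2"]] * (E - E0)
  jit <- withSeed(seed, matrix(stats::rnorm(2 * nExc, sd = jitterSd),
                               ncol = 2))
  mkTrack <- function(band, centers) {
    w <- range(centers) + c(-60, 60)
    pts <- data.frame(excitation_nm = wl, E_invcm = E,
                      E_eV = invcmToEv(E), center = centers,
                      height = 1, fwhm = 12, snr = Inf, flags = "",
                      stringsAsFactors = FALSE)
    pts <- pts[order(pts$E_invcm), , drop = FALSE]
    rownames(pts) <- NULL
    refIdx <- which.min(pts$E_invcm)
    new("BandTrack", band = band, window = w, points = pts,
        reference = list(center = pts$center[refIdx],
                         excitation_nm = pts$excitation_nm[refIdx],
                         E_invcm = pts$E_invcm[refIdx]),
        excluded = data.frame(excitation_nm = numeric(0),
                              reason = character(0)))
  }
  ccJ <- noiselessCC + if (jitterSd > 0) jit[, 1] else 0
  cc2J <- noiselessCC2 + if (jitterSd > 0) jit[, 2] else 0
  prod0 <- (noiselessCC / noiselessCC[1])^2 *
           (noiselessCC2 / noiselessCC2[1])^2
  list(tracks = list(CC = mkTrack("CC", ccJ),
                     CC2 = mkTrack("CC2", cc2J)),
       D_true_exact = unname(stats::coef(stats::lm(prod0 ~ E))[2L]),
       D_closed = 2 * sum(slopes / refs),
       slopes = slopes)
}

#' Simulate a multi-feather hue panel
#'
#' Band positions are drawn around hue-ordered means: the C-C and C=C
#' centers rise by `trend` cm^-1 per hue step from magenta to yellow,
#' emulating the blue-shift of shorter effective conjugation lengths.
#'
#' @param nPerHue records per hue; a single number or a named vector
#'   over [hueLevels()] (default c(6, 7, 7, 6), a 26-feather panel).
#' @param trend cm^-1 per hue step.
#' @param noiseSd s.d. of the per-feather scatter in cm^-1.
#' @param seed random seed.
#' @param base named c(nu_cc=, nu_cc2=) magenta-mean centers.
#' @return data.frame of hue records (specimen_id, hue, nu_cc, nu_cc2).
#' @export
simulateHuePanel <- function(nPerHue = c(6, 7, 7, 6), trend = 4,
                             noiseSd = 2, seed = 1,
                             base = c(nu_cc = 1130, nu_cc2 = 1524)) {
  lv <- hueLevels()
  if (length(nPerHue) == 1L) nPerHue <- rep(nPerHue, 4L)
  stopifnot(length(nPerHue) == 4L, all(nPerHue >= 1L))
  wins <- bandWindows()
  meansCC <- base[["nu_cc"]] + (seq_along(lv) - 1) * trend
  meansCC2 <- base[["nu_cc2"]] + (seq_along(lv) - 1) * trend
  if (any(meansCC < wins$CC[1] | meansCC > wins$CC[2]) ||
      any(meansCC2 < wins$CC2[1] | meansCC2 > wins$CC2[2]))
    stop("trend drives hue means outside the band windows")
  withSeed(seed, {
    rows <- list()
    for (h in seq_along(lv)) {
      n <- nPerHue[h]
      cc <- meansCC[h] + stats::rnorm(n, sd = noiseSd)
      cc2 <- meansCC2[h] + stats::rnorm(n, sd = noiseSd)
      rows[[h]] <- data.frame(
        specimen_id = sprintf("%s_%02d", substr(lv[h], 1, 3), seq_len(n)),
        hue = lv[h],
        nu_cc = pmin(pmax(cc, wins$CC[1]), wins$CC[2]),
        nu_cc2 = pmin(pmax(cc2, wins$CC2[1]), wins$CC2[2]),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Simulate a hyperspectral pixel grid
#'
#' Pixels inside the mask are drawn from `pigmentConfig`, the rest from
#' `backgroundConfig`. The ground-truth mask is attached as attribute
#' `"mask"`.
#'
#' @param nRows,nCols grid dimensions (>= 2 each).
#' @param mask `"disc"` (centred disc, radius ~ 1/3 of the short side),
#'   `"stripe"` (middle third of the columns), `"uniform"` (no pigment),
#'   or a logical nRows x nCols matrix.
#' @param pigmentConfig,backgroundConfig [SimConfig-class] objects for
#'   masked / unmasked pixels.
#' @param excitation_nm excitation wavelength of the scan.
#' @param pixelSize pixel pitch in micrometres.
#' @param seed base random seed.
#' @return A [RamanHyperMap-class] with a `mask` attribute.
#' @export
simulateHypermap <- function(nRows = 12, nCols = 12, mask = "disc",
                             pigmentConfig = redLikeConfig(),
                             backgroundConfig = keratinConfig(),
                             excitation_nm = 532, pixelSize = 30,
                             seed = 1) {
  stopifnot(nRows >= 2L, nCols >= 2L)
  if (is.character(mask)) {
    mk <- matrix(FALSE, nRows, nCols)
    if (mask == "disc") {
      r0 <- (nRows + 1) / 2; c0 <- (nCols + 1) / 2
      rad <- min(nRows, nCols) / 3
      for (r in seq_len(nRows)) for (cl in seq_len(nCols))
        if ((r - r0)^2 + (cl - c0)^2 <= rad^2) mk[r, cl] <- TRUE
    } else if (mask == "stripe") {
      lo <- floor(nCols / 3) + 1L; hi <- ceiling(2 * nCols / 3)
      mk[, lo:hi] <- TRUE
    } else if (mask != "uniform") stop("unknown mask keyword: ", mask)
    mask <- mk
  }
  if (!is.matrix(mask) || !all(dim(mask) == c(nRows, nCols)))
    stop("mask shape mismatch: need a ", nRows, " x ", nCols, " matrix")

  x <- seq(pigmentConfig@gridLo, pigmentConfig@gridHi,
           by = pigmentConfig@gridStep)
  xb <- seq(backgroundConfig@gridLo, backgroundConfig@gridHi,
            by = backgroundConfig@gridStep)
  if (!isTRUE(all.equal(x, xb)))
    stop("pigment and background configs must share one grid")

  inten <- matrix(0, nRows * nCols, length(x))
  for (r in seq_len(nRows)) for (cl in seq_len(nCols)) {
    idx <- (r - 1L) * nCols + cl
    cfg <- if (mask[r, cl]) pigmentConfig else backgroundConfig
    s <- simulateSpectrum(cfg, excitation_nm, seed = seed + idx)
    inten[idx, ] <- s@intensity
  }
  out <- RamanHyperMap(inten, x, nRow = nRows, nCol = nCols,
                       pixelSize = pixelSize, excitation = excitation_nm)
  attr(out, "mask") <- mask
  out
}

#' Write a simulated series as a file fixture
#'
#' Emits one delimited spectrum file per replicate, a manifest table and
#' (optionally) the ground truth as JSON — the on-disk layout consumed
#' by [readSeries()].
#'
#' @param sim output of [simulateSeries()].
#' @param dir output directory (created if needed).
#' @return path of the manifest file, invisibly.
#' @export
writeSeriesFixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (w in names(sim$replicates)) {
    for (s in sim$replicates[[w]]) {
      fn <- sprintf("spec_%snm_%s.csv", w, s@replicate)
      writeSpectrum(s, file.path(dir, fn))
      rows[[length(rows) + 1L]] <-
        data.frame(path = fn, excitation_nm = as.numeric(w),
                   region_label = s@region, replicate_id = s@replicate,
                   stringsAsFactors = FALSE)
    }
  }
  man <- do.call(rbind, rows)
  manPath <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manPath, row.names = FALSE, quote = FALSE)
  if (!is.null(sim$truth))
    jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(manPath)
}
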