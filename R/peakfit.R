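#' Default band search windows
#'
#' The pigment doublet windows are centred on ~1140 and ~1540 cm^-1 with
#' a +/- 50 cm^-1 half-width (the same windows used by the band-sum
#' mapping); the beta-keratin windows are +/- 20 cm^-1 around the four
#' matrix bands (phenylalanine 1006, 1240, CH2 1450, 1670 cm^-1).
#'
#' @return Named list of `c(lo, hi)` windows in cm^-1.
#' @export
bandWindows <- function() {
  list(CC  = c(1090, 1190),
       CC2 = c(1490, 1590),
       keratin_1006 = c(986, 1026),
       keratin_1240 = c(1220, 1260),
       keratin_1450 = c(1430, 1470),
       keratin_1670 = c(1650, 1690))
}

# robust noise level of a window: 1.4826 * MAD of detrended residuals.
# Detrending uses a short running median so that a smooth band profile
# (even one occupying most of the window) does not inflate the estimate.
windowNoise <- function(res) {
  n <- length(res)
  k <- min(7L, if (n %% 2L) n else n - 1L)
  if (k >= 3L) res <- res - stats::runmed(res, k, endrule = "median")
  stats::mad(res, constant = 1.4826)
}

# apex of the parabola through three (x, y) points; falls back to the
# middle point when the curvature is not concave
parabolicApex <- function(x3, y3) {
  d21 <- (y3[2] - y3[1]) / (x3[2] - x3[1])
  d32 <- (y3[3] - y3[2]) / (x3[3] - x3[2])
  a <- (d32 - d21) / (x3[3] - x3[1])
  if (!is.finite(a) || a >= 0)
    return(list(x = x3[2], y = y3[2]))
  b <- d21 - a * (x3[1] + x3[2])
  xa <- -b / (2 * a)
  c0 <- y3[1] - a * x3[1]^2 - b * x3[1]
  list(x = xa, y = a * xa^2 + b * xa + c0)
}

# FWHM from half-maximum crossings of the detrended profile
fwhmFromProfile <- function(x, yDet, iMax, height) {
  half <- height / 2
  left <- NA_real_
  right <- NA_real_
  if (iMax > 1L) {
    for (i in seq(iMax - 1L, 1L)) {
      if (yDet[i] <= half) {
        left <- x[i] + (x[i + 1L] - x[i]) *
          (half - yDet[i]) / (yDet[i + 1L] - yDet[i])
        break
      }
    }
  }
  n <- length(x)
  if (iMax < n) {
    for (i in seq(iMax + 1L, n)) {
      if (yDet[i] <= half) {
        right <- x[i - 1L] + (x[i] - x[i - 1L]) *
          (half - yDet[i - 1L]) / (yDet[i] - yDet[i - 1L])
        break
      }
    }
  }
  if (is.na(left) || is.na(right)) NA_real_ else right - left
}

#' Locate a band in a window
#'
#' Finds the strongest peak inside a wavenumber window. Two estimators:
#' \describe{
#'   \item{argmax_parabolic}{grid maximum refined by the parabola through
#'     the maximum and its two neighbours. Intensity-scale invariant and
#'     shift-equivariant; ties go to the lower wavenumber.}
#'   \item{lorentzian_ls}{least-squares Lorentzian plus linear offset,
#'     initialized at the grid maximum ([minpack.lm::nlsLM]); on
#'     non-convergence it falls back to argmax_parabolic and flags the
#'     peak `"fallback_argmax"`.}
#' }
#' Height is measured above the local linear trend of the window; the
#' signal-to-noise ratio divides it by 1.4826 x MAD of the detrended
#' window residuals. A maximum on the window edge is flagged `"edge"`.
#'
#' @param spec a [RamanSpectrum-class].
#' @param window `c(lo, hi)` in cm^-1, or NULL to use the default window
#'   of `band`.
#' @param band band identifier; see [bandWindows()] for the defaults.
#' @param method "argmax_parabolic" or "lorentzian_ls".
#' @return A [Peak-class].
#' @export
findBand <- function(spec, window = NULL, band = "CC",
                     method = c("argmax_parabolic", "lorentzian_ls")) {
  stopifnot(is(spec, "RamanSpectrum"))
  method <- match.arg(method)
  if (is.null(window)) {
    window <- bandWindows()[[band]]
    if (is.null(window)) stop("no default window for band '", band, "'")
  }
  sel <- spec@wavenumber >= window[1] & spec@wavenumber <= window[2]
  if (sum(sel) < 5L)
    stop(sprintf("window [%g, %g] contains fewer than 5 points",
                 window[1], window[2]))
  x <- spec@wavenumber[sel]
  y <- spec@intensity[sel]
  n <- length(x)

  # local linear trend for height-above-background and the noise level
  trend <- stats::lm.fit(cbind(1, x), y)
  yDet <- y - drop(trend$fitted.values)
  noise <- windowNoise(yDet)

  yMax <- max(y)
  iMax <- min(which(y == yMax))          # ties: lower wavenumber wins
  flags <- character(0)
  if (iMax == 1L || iMax == n) flags <- c(flags, "edge")

  trendAt <- function(x0) trend$coefficients[1] + trend$coefficients[2] * x0

  makeArgmax <- function() {
    if (length(flags) && "edge" %in% flags) {
      center <- x[iMax]
      height <- yDet[iMax]
      fwhm <- NA_real_
    } else {
      apex <- parabolicApex(x[(iMax - 1L):(iMax + 1L)],
                            y[(iMax - 1L):(iMax + 1L)])
      center <- apex$x
      height <- apex$y - trendAt(apex$x)
      fwhm <- fwhmFromProfile(x, yDet, iMax, yDet[iMax])
      if (is.na(fwhm)) flags <<- union(flags, "fwhm_edge")
    }
    snr <- if (noise > 0) max(0, height) / noise
           else if (height > 0) Inf else 0
    new("Peak", band = band, center = min(max(center, window[1]), window[2]),
        height = height, fwhm = fwhm, window = as.numeric(window),
        snr = snr, method = "argmax_parabolic", flags = flags)
  }

  if (method == "argmax_parabolic") return(makeArgmax())

  # lorentzian_ls
  fit <- tryCatch({
    df <- data.frame(x = x, y = y)
    start <- list(h = max(yDet[iMax], 1e-6 * max(abs(y), 1)),
                  ctr = x[iMax],
                  g = max(diff(range(x)) / 20, 2 * stats::median(diff(x))),
                  a = trend$coefficients[1], b = trend$coefficients[2])
    m <- minpack.lm::nlsLM(
      y ~ h * g^2 / ((x - ctr)^2 + g^2) + a + b * x,
      data = df, start = start,
      lower = c(h = 0, ctr = window[1], g = 1e-3, a = -Inf, b = -Inf),
      upper = c(h = Inf, ctr = window[2], g = diff(range(x)), a = Inf, b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(m)
    resid <- stats::resid(m)
    nz <- windowNoise(resid)
    snr <- if (nz > 0) cf[["h"]] / nz else if (cf[["h"]] > 0) Inf else 0
    new("Peak", band = band, center = cf[["ctr"]], height = cf[["h"]],
        fwhm = 2 * cf[["g"]], window = as.numeric(window), snr = snr,
        method = "lorentzian_ls", flags = flags)
  }, error = function(e) NULL)
  if (is.null(fit)) {
    flags <- union(flags, "fallback_argmax")
    return(makeArgmax())
  }
  fit
}

crediblePeak <- function(p, min_snr, min_fwhm) {
  !("edge" %in% p@flags) && is.finite(p@height) && p@height > 0 &&
    p@snr >= min_snr && !is.na(p@fwhm) && p@fwhm >= min_fwhm
}

#' Test a spectrum for the psittacofulvin doublet
#'
#' A spectrum is called pigmented when both the C-C (1090-1190 cm^-1)
#' and C=C (1490-1590 cm^-1) stretching bands are found with interior
#' maxima, signal-to-noise at or above `min_snr` and a width of at least
#' `min_fwhm` (polyene stretching bands are >~ 10 cm^-1 wide; narrower
#' maxima are smoothing-scale noise features). A white (keratin-only)
#' feather fails this test. Detected keratin bands are returned
#' alongside.
#'
#' @param spec a preprocessed [RamanSpectrum-class] covering both
#'   windows.
#' @param min_snr minimum signal-to-noise ratio for a band to count.
#' @param min_fwhm minimum credible band width in cm^-1.
#' @param method peak estimator, see [findBand()].
#' @return `list(present = logical, pigment = list of Peak,
#'   keratin = list of Peak)`.
#' @export
detectPsittacofulvin <- function(spec, min_snr = 5, min_fwhm = 6,
                                 method = "argmax_parabolic") {
  pig <- list()
  ok <- logical(0)
  for (b in c("CC", "CC2")) {
    p <- tryCatch(findBand(spec, band = b, method = method),
                  error = function(e) NULL)
    if (!is.null(p)) {
      pig[[b]] <- p
      ok <- c(ok, crediblePeak(p, min_snr, min_fwhm))
    } else ok <- c(ok, FALSE)
  }
  list(present = length(ok) == 2L && all(ok),
       pigment = pig,
       keratin = keratinBands(spec, min_snr = min_snr,
                              min_fwhm = min_fwhm, method = method))
}

#' Locate the beta-keratin matrix bands
#'
#' Applies [findBand()] in +/- 20 cm^-1 windows around 1006, 1240, 1450
#' and 1670 cm^-1 and keeps only interior peaks at or above the
#' signal-to-noise threshold.
#'
#' @inheritParams detectPsittacofulvin
#' @return Named list of [Peak-class] (possibly empty).
#' @export
keratinBands <- function(spec, min_snr = 5, min_fwhm = 6,
                         method = "argmax_parabolic") {
  out <- list()
  for (b in c("keratin_1006", "keratin_1240", "keratin_1450",
              "keratin_1670")) {
    p <- tryCatch(findBand(spec, band = b, method = method),
                  error = function(e) NULL)
    if (!is.null(p) && crediblePeak(p, min_snr, min_fwhm))
      out[[b]] <- p
  }
  out
}

#' The exclusion set used for feather dispersion runs
#'
#' 351 and 785 nm sit pre-resonant for the red psittacofulvins and 448 nm
#' produced spurious fits in the reference measurements; these are
#' configuration defaults for replication runs, not hard rules.
#'
#' @return Named character vector: names are wavelengths (nm), values the
#'   exclusion reason.
#' @export
defaultExclusions <- function() {
  c("351" = "pre-resonant", "448" = "spurious", "785" = "pre-resonant")
}

#' Track one band across an excitation series
#'
#' Fits the band at every included excitation and records the trajectory
#' of its center together with excitation energy on both the cm^-1 and
#' eV axes. The reference value (nu0R) is the center fitted at the
#' included excitation with the lowest energy (longest wavelength).
#'
#' @param series an [ExcitationSeries-class].
#' @param band band identifier ("CC" or "CC2" for the pigment doublet).
#' @param window optional `c(lo, hi)` override.
#' @param exclude excitation wavelengths (nm) to leave out.
#' @param reasons optional named character vector mapping excluded
#'   wavelengths to reasons (default reason "user"); see
#'   [defaultExclusions()].
#' @param method peak estimator, see [findBand()].
#' @return A [BandTrack-class].
#' @export
trackBand <- function(series, band = "CC", window = NULL,
                      exclude = numeric(0), reasons = NULL,
                      method = c("argmax_parabolic", "lorentzian_ls")) {
  stopifnot(is(series, "ExcitationSeries"))
  method <- match.arg(method)
  if (is.null(window)) window <- bandWindows()[[band]]
  exc <- excitationNm(series)
  excluded <- exc[exc %in% exclude]
  included <- setdiff(exc, exclude)
  if (length(included) < 3L)
    stop(sprintf("only %d excitation(s) left after exclusion; need >= 3",
                 length(included)))
  rows <- lapply(included, function(w) {
    p <- findBand(series[[as.character(w)]], window = window, band = band,
                  method = method)
    data.frame(excitation_nm = w,
               E_invcm = nmToInvcm(w),
               E_eV = invcmToEv(nmToInvcm(w)),
               center = p@center, height = p@height, fwhm = p@fwhm,
               snr = p@snr, flags = paste(p@flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  pts <- do.call(rbind, rows)
  pts <- pts[order(pts$E_invcm), , drop = FALSE]
  rownames(pts) <- NULL
  refIdx <- which.min(pts$E_invcm)
  reasonOf <- function(w) {
    if (!is.null(reasons) && as.character(w) %in% names(reasons))
      reasons[[as.character(w)]] else "user"
  }
  excl <- if (length(excluded))
    data.frame(excitation_nm = excluded,
               reason = vapply(excluded, reasonOf, character(1)),
               stringsAsFactors = FALSE)
  else data.frame(excitation_nm = numeric(0), reason = character(0))
  new("BandTrack", band = band, window = as.numeric(window), points = pts,
      reference = list(center = pts$center[refIdx],
                       excitation_nm = pts$excitation_nm[refIdx],
                       E_invcm = pts$E_invcm[refIdx]),
      excluded = excl)
}

#' Build band tracks from a measured peak table
#'
#' For data where band centers were measured elsewhere (e.g. an
#' instrument vendor's fit) the dispersion analysis can start from a
#' plain table with columns `band`, `excitation_nm` and `center`
#' (cm^-1).
#'
#' @param peaks data.frame or path to a delimited file with those
#'   columns.
#' @param bands which bands to extract (default: all present).
#' @param exclude excitation wavelengths (nm) to drop.
#' @param reasons named reasons for exclusions, as in [trackBand()].
#' @param windows named list of band windows; defaults widen
#'   [bandWindows()] when a center falls outside.
#' @return Named list of [BandTrack-class].
#' @export
tracksFromTable <- function(peaks, bands = NULL, exclude = numeric(0),
                            reasons = NULL, windows = bandWindows()) {
  if (is.character(peaks)) peaks <- readPeakTable(peaks)
  need <- c("band", "excitation_nm", "center")
  if (!all(need %in% names(peaks)))
    stop("peak table needs columns: ", paste(need, collapse = ", "))
  if (is.null(bands)) bands <- unique(peaks$band)
  out <- list()
  for (b in bands) {
    tb <- peaks[peaks$band == b, , drop = FALSE]
    excluded <- tb$excitation_nm[tb$excitation_nm %in% exclude]
    tb <- tb[!tb$excitation_nm %in% exclude, , drop = FALSE]
    if (nrow(tb) < 3L)
      stop(sprintf("band %s: only %d excitation(s) after exclusion; need >= 3",
                   b, nrow(tb)))
    w <- windows[[b]]
    if (is.null(w) || any(tb$center < w[1] | tb$center > w[2]))
      w <- range(tb$center) + c(-10, 10)
    pts <- data.frame(excitation_nm = tb$excitation_nm,
                      E_invcm = nmToInvcm(tb$excitation_nm),
                      E_eV = invcmToEv(nmToInvcm(tb$excitation_nm)),
                      center = tb$center,
                      height = if ("height" %in% names(tb)) tb$height
                               else NA_real_,
                      fwhm = if ("fwhm" %in% names(tb)) tb$fwhm
                             else NA_real_,
                      snr = if ("snr" %in% names(tb)) tb$snr else NA_real_,
                      flags = "", stringsAsFactors = FALSE)
    pts <- pts[order(pts$E_invcm), , drop = FALSE]
    rownames(pts) <- NULL
    refIdx <- which.min(pts$E_invcm)
    reasonOf <- function(wl) {
      if (!is.null(reasons) && as.character(wl) %in% names(reasons))
        reasons[[as.character(wl)]] else "user"
    }
    excl <- if (length(excluded))
      data.frame(excitation_nm = excluded,
                 reason = vapply(excluded, reasonOf, character(1)),
                 stringsAsFactors = FALSE)
    else data.frame(excitation_nm = numeric(0), reason = character(0))
    out[[b]] <- new("BandTrack", band = b, window = as.numeric(w),
                    points = pts,
                    reference = list(center = pts$center[refIdx],
                                     excitation_nm = pts$excitation_nm[refIdx],
                                     E_invcm = pts$E_invcm[refIdx]),
                    excluded = excl)
  }
  out
}

#' @rdname tracksFromTable
#' @param path delimited file (comma or tab, header) with columns
#'   `band`, `excitation_nm`, `center`.
#' @export
readPeakTable <- function(path) {
  if (!file.exists(path)) stop("peak table not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, comment.char = "#",
                    strip.white = TRUE)
}
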