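#' Crop a spectrum to a wavenumber range
#'
#' The analysis window for feather spectra is 900-1800 cm^-1, which
#' contains the pigment doublet and the beta-keratin matrix bands.
#'
#' @param spec a [RamanSpectrum-class].
#' @param lo,hi closed crop bounds in cm^-1.
#' @return The cropped [RamanSpectrum-class] (metadata preserved).
#' @export
cropSpectrum <- function(spec, lo = 900, hi = 1800) {
  stopifnot(is(spec, "RamanSpectrum"), lo < hi)
  keep <- spec@wavenumber >= lo & spec@wavenumber <= hi
  if (sum(keep) < 2L)
    stop(sprintf("crop [%g, %g] leaves fewer than 2 points", lo, hi))
  new("RamanSpectrum", wavenumber = spec@wavenumber[keep],
      intensity = spec@intensity[keep],
      excitation = spec@excitation, region = spec@region,
      replicate = spec@replicate, source = spec@source)
}

#' Savitzky-Golay smoothing
#'
#' Standard Savitzky-Golay convolution via [signal::sgolayfilt()]; the
#' filter reproduces polynomials up to `polyorder` exactly, and the
#' endpoints are handled by the truncated-window polynomial fit built
#' into the projection matrix.
#'
#' @param spec a [RamanSpectrum-class] on a uniform grid (use
#'   [resampleSpectrum()] first otherwise).
#' @param window_pts odd window length in points (> polyorder).
#' @param polyorder polynomial order.
#' @return Smoothed [RamanSpectrum-class], same length.
#' @export
smoothSavgol <- function(spec, window_pts = 11L, polyorder = 3L) {
  stopifnot(is(spec, "RamanSpectrum"))
  if (window_pts %% 2L != 1L || window_pts <= polyorder)
    stop("window_pts must be odd and greater than polyorder")
  d <- diff(spec@wavenumber)
  if (max(d) - min(d) > 1e-6 * stats::median(d))
    stop("spectrum is not on a uniform grid; resampleSpectrum() first")
  if (length(spec@intensity) < window_pts)
    stop("spectrum shorter than the smoothing window")
  y <- signal::sgolayfilt(spec@intensity, p = polyorder, n = window_pts)
  new("RamanSpectrum", wavenumber = spec@wavenumber, intensity = y,
      excitation = spec@excitation, region = spec@region,
      replicate = spec@replicate, source = spec@source)
}

# asymmetric least squares baseline (Eilers-style): minimise
# sum w_i (y_i - z_i)^2 + lambda * sum (d2 z)^2 with asymmetric weights
aslsBaseline <- function(y, lambda = 1e5, p = 0.01, maxIter = 50L,
                         tol = 1e-8) {
  m <- length(y)
  D <- Matrix::bandSparse(m - 2L, m, k = 0:2,
                          diagonals = list(rep(1, m - 2L),
                                           rep(-2, m - 2L),
                                           rep(1, m - 2L)))
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    z <- as.numeric(Matrix::solve(Matrix::Diagonal(x = w) + P, w * y))
    wNew <- ifelse(y > z, p, 1 - p)
    if (max(abs(wNew - w)) < tol) {
      converged <- TRUE
      w <- wNew
      break
    }
    w <- wNew
  }
  list(baseline = z, converged = converged)
}

# iterative polynomial baseline: refit after clipping the signal to the
# current fit so peaks do not pull the polynomial up
polyBaseline <- function(x, y, order = 3L, maxIter = 50L, tol = 1e-10) {
  u <- (x - mean(x)) / (diff(range(x)) / 2)
  X <- cbind(1, stats::poly(u, degree = order, raw = TRUE, simple = TRUE))
  yWork <- y
  z <- y
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    fit <- stats::lm.fit(X, yWork)
    zNew <- drop(fit$fitted.values)
    if (max(abs(zNew - z)) < tol * max(1, max(abs(y)))) {
      z <- zNew
      converged <- TRUE
      break
    }
    z <- zNew
    yWork <- pmin(yWork, z)
  }
  list(baseline = z, converged = converged)
}

#' Baseline correction
#'
#' Estimates a slowly varying background under the spectrum and subtracts
#' it. Two estimators are provided: asymmetric least squares (default;
#' a Whittaker smoother with asymmetric weights so the fit hugs the
#' valleys below peaks) and an iteratively clipped polynomial.
#'
#' If the iterative fit hits its iteration cap without meeting the
#' tolerance, a `convergence_warning` attribute is attached to the
#' returned spectrum rather than failing.
#'
#' @param spec a [RamanSpectrum-class].
#' @param method "asls" or "polynomial".
#' @param lambda smoothness penalty for asls.
#' @param p asymmetry parameter for asls (weight of points above the
#'   baseline).
#' @param order polynomial order for the polynomial method.
#' @param maxIter iteration cap.
#' @param returnBaseline if TRUE, return
#'   `list(corrected = , baseline = )` instead of just the corrected
#'   spectrum.
#' @return Corrected [RamanSpectrum-class], or a list when
#'   `returnBaseline = TRUE`.
#' @export
baselineCorrect <- function(spec, method = c("asls", "polynomial"),
                            lambda = 1e5, p = 0.01, order = 3L,
                            maxIter = 50L, returnBaseline = FALSE) {
  stopifnot(is(spec, "RamanSpectrum"))
  method <- match.arg(method)
  res <- if (method == "asls")
    aslsBaseline(spec@intensity, lambda = lambda, p = p, maxIter = maxIter)
  else
    polyBaseline(spec@wavenumber, spec@intensity, order = order,
                 maxIter = maxIter)
  out <- new("RamanSpectrum", wavenumber = spec@wavenumber,
             intensity = spec@intensity - res$baseline,
             excitation = spec@excitation, region = spec@region,
             replicate = spec@replicate, source = spec@source)
  if (!res$converged)
    attr(out, "convergence_warning") <-
      sprintf("baseline (%s) hit the %d-iteration cap", method, maxIter)
  if (returnBaseline)
    list(corrected = out,
         baseline = new("RamanSpectrum", wavenumber = spec@wavenumber,
                        intensity = res$baseline,
                        excitation = spec@excitation, region = spec@region,
                        replicate = spec@replicate, source = spec@source))
  else out
}

#' Scale intensities to the unit interval
#'
#' `(I - min) / (max - min)`: after normalization the minimum is exactly
#' 0 and the maximum exactly 1. Idempotent. Constant spectra are refused
#' as degenerate.
#'
#' @param spec a [RamanSpectrum-class].
#' @return Normalized [RamanSpectrum-class].
#' @export
normalize01 <- function(spec) {
  stopifnot(is(spec, "RamanSpectrum"))
  r <- range(spec@intensity)
  if (r[1] == r[2])
    stop("constant spectrum cannot be 0-1 normalized (degenerate input)")
  new("RamanSpectrum", wavenumber = spec@wavenumber,
      intensity = (spec@intensity - r[1]) / (r[2] - r[1]),
      excitation = spec@excitation, region = spec@region,
      replicate = spec@replicate, source = spec@source)
}

#' Average replicate spectra
#'
#' Pointwise arithmetic mean of replicates sharing one excitation
#' wavelength, region label and wavenumber grid.
#'
#' @param specs list of [RamanSpectrum-class] objects (length >= 1).
#' @return The mean [RamanSpectrum-class]; its replicate id is
#'   `"mean(n=k)"`.
#' @export
averageReplicates <- function(specs) {
  if (is(specs, "RamanSpectrum")) specs <- list(specs)
  stopifnot(length(specs) >= 1L,
            all(vapply(specs, is, logical(1), "RamanSpectrum")))
  exc <- vapply(specs, function(s) s@excitation, numeric(1))
  if (length(unique(exc[!is.na(exc)])) > 1L)
    stop("replicates mix excitation wavelengths: ",
         paste(unique(exc), collapse = ", "))
  reg <- vapply(specs, function(s) s@region, character(1))
  if (length(unique(reg[!is.na(reg)])) > 1L)
    stop("replicates mix region labels")
  g <- specs[[1L]]@wavenumber
  same <- vapply(specs, function(s)
    length(s@wavenumber) == length(g) &&
      isTRUE(all.equal(s@wavenumber, g, tolerance = 1e-9)), logical(1))
  if (!all(same))
    stop("replicates are not on a common grid; resampleSpectrum() first")
  ymat <- vapply(specs, function(s) s@intensity, numeric(length(g)))
  ymat <- matrix(ymat, nrow = length(g))
  new("RamanSpectrum", wavenumber = g, intensity = rowMeans(ymat),
      excitation = exc[1L],
      region = if (any(!is.na(reg))) reg[!is.na(reg)][1L] else NA_character_,
      replicate = sprintf("mean(n=%d)", length(specs)),
      source = specs[[1L]]@source)
}

#' The standard preprocessing chain
#'
#' Default order: crop (900-1800 cm^-1), Savitzky-Golay smoothing,
#' baseline correction, 0-1 normalization. Each stage can be switched
#' off or reparameterized; replicate averaging is a separate step
#' ([averageReplicates()]) because the two workflows interleave it
#' differently (the multi-feather survey normalizes replicates before
#' averaging; the excitation series averages raw replicates first and
#' normalizes the mean).
#'
#' @param spec a [RamanSpectrum-class].
#' @param crop `c(lo, hi)` in cm^-1, or NULL to skip.
#' @param savgol `c(window, order)` in points, or NULL to skip.
#' @param baselineMethod "asls", "polynomial" or NULL to skip.
#' @param normalize logical.
#' @param ... further arguments passed to [baselineCorrect()].
#' @return Preprocessed [RamanSpectrum-class].
#' @export
preprocessSpectrum <- function(spec, crop = c(900, 1800),
                               savgol = c(11L, 3L),
                               baselineMethod = "asls",
                               normalize = TRUE, ...) {
  if (!is.null(crop)) spec <- cropSpectrum(spec, crop[1], crop[2])
  if (!is.null(savgol)) spec <- smoothSavgol(spec, savgol[1], savgol[2])
  if (!is.null(baselineMethod))
    spec <- baselineCorrect(spec, method = baselineMethod, ...)
  if (normalize) spec <- normalize01(spec)
  spec
}
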