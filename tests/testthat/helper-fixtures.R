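# shared fixtures and independent oracles, built in code at test time

analyticLorentzian <- function(x, center, height = 1, fwhm = 16) {
  hw2 <- (fwhm / 2)^2
  height * hw2 / ((x - center)^2 + hw2)
}

# independent Savitzky-Golay convolution: least-squares polynomial
# projection row built from the pseudo-inverse of the local Vandermonde
# matrix, applied to interior points only
sgConvolveOracle <- function(y, window, order) {
  half <- (window - 1) %/% 2
  z <- seq(-half, half)
  A <- outer(z, 0:order, `^`)
  w <- solve(t(A) %*% A, t(A))[1, ]   # row evaluating the fit at z = 0
  n <- length(y)
  out <- rep(NA_real_, n)
  for (i in seq(half + 1, n - half))
    out[i] <- sum(w * y[(i - half):(i + half)])
  out
}

# brute-force product rule: explicit double loop over bands and
# excitations, no shared code with ammProduct()
bruteForceProducts <- function(tracks) {
  # ascending excitation energy = descending wavelength
  exc <- sort(tracks[[1]]@points$excitation_nm, decreasing = TRUE)
  vapply(exc, function(w) {
    p <- 1
    for (tr in tracks) {
      pts <- tr@points
      nuN <- pts$center[pts$excitation_nm == w]
      nu0 <- tr@reference$center
      p <- p * (nuN / nu0)^2
    }
    p
  }, numeric(1))
}

# a small on-disk toy spectrum
writeToyFile <- function(path, lines) {
  writeLines(lines, path)
  path
}
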