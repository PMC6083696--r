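test_that("cropping keeps the closed interval and composes by intersection", {
  s <- RamanSpectrum(800:1900, rnorm(1101))
  c1 <- cropSpectrum(s, 900, 1800)
  expect_length(c1, 901L)
  expect_equal(range(wavenumbers(c1)), c(900, 1800))

  # crop to the full existing range is the identity
  cFull <- cropSpectrum(s, 800, 1900)
  expect_equal(intensities(cFull), intensities(s))

  # crop of crop equals crop with intersected bounds
  a <- cropSpectrum(cropSpectrum(s, 900, 1800), 1000, 1700)
  b <- cropSpectrum(s, 1000, 1700)
  expect_equal(wavenumbers(a), wavenumbers(b))
  expect_equal(intensities(a), intensities(b))

  expect_error(cropSpectrum(s, 2000, 2100), "fewer than 2")

  # cropping a doublet to the C=C window leaves one pigment band
  d <- simulateSpectrum(pigmentOnlyConfig(noiseSd = 0), 648)
  cc2only <- cropSpectrum(d, 1490, 1590)
  pk <- findBand(cc2only, window = c(1490, 1590), band = "CC2")
  expect_false("edge" %in% peakFlags(pk))
  expect_equal(peakCenter(pk),
               attr(d, "truth")$centers[["CC2"]], tolerance = 1e-3)
})

test_that("Savitzky-Golay smoothing preserves polynomials and matches a direct convolution", {
  x <- seq(900, 1800, 1)
  ycub <- 2 + 0.01 * x - 3e-6 * x^2 + 1e-9 * x^3
  s <- RamanSpectrum(x, ycub)
  expect_equal(intensities(smoothSavgol(s, 11, 3)), ycub, tolerance = 1e-9)

  const <- RamanSpectrum(x, rep(4, length(x)))
  expect_equal(intensities(smoothSavgol(const)), rep(4, length(x)))

  # independent convolution oracle on noisy data (interior points)
  set.seed(42)
  noisy <- analyticLorentzian(x, 1137) + rnorm(length(x), sd = 0.05)
  sm <- intensities(smoothSavgol(RamanSpectrum(x, noisy), 11, 3))
  oracle <- sgConvolveOracle(noisy, 11, 3)
  keep <- !is.na(oracle)
  expect_equal(sm[keep], oracle[keep], tolerance = 1e-10)

  # and it actually reduces the noise
  resid_in <- noisy - analyticLorentzian(x, 1137)
  resid_out <- sm - analyticLorentzian(x, 1137)
  expect_lt(sd(resid_out), 0.75 * sd(resid_in))

  expect_error(smoothSavgol(RamanSpectrum(c(1, 2, 4, 8, 16, 32, 64, 70,
                                            80, 90, 100, 110),
                                          rnorm(12))),
               "uniform")
  expect_error(smoothSavgol(s, 10, 3), "odd")
})

test_that("baseline correction removes known backgrounds", {
  x <- seq(900, 1800, 1)

  # a spectrum that IS a line vanishes under the polynomial method
  line <- RamanSpectrum(x, 0.2 + 1e-3 * x)
  corr <- baselineCorrect(line, method = "polynomial", order = 1)
  expect_lt(max(abs(intensities(corr))), 1e-8 * max(abs(intensities(line))))

  # all-zero spectrum stays zero (asls)
  z <- RamanSpectrum(x, rep(0, length(x)))
  expect_equal(max(abs(intensities(baselineCorrect(z)))), 0)

  # Lorentzian + known linear ramp: corrected spectrum approaches the
  # pure Lorentzian; the oracle is direct subtraction of the ramp
  ramp <- 0.3 + 5e-4 * (x - 900)
  pure <- analyticLorentzian(x, 1137, fwhm = 12)
  s <- RamanSpectrum(x, pure + ramp)
  got <- intensities(baselineCorrect(s, method = "asls", lambda = 1e6))
  expect_lt(stats::median(abs(got - pure)), 0.02)
  expect_lt(max(abs(got - pure)), 0.10)

  # returnBaseline exposes the estimate itself
  bb <- baselineCorrect(s, returnBaseline = TRUE)
  expect_named(bb, c("corrected", "baseline"))
  expect_equal(intensities(bb$corrected) + intensities(bb$baseline),
               intensities(s))
})

test_that("0-1 normalization has exact bounds and is idempotent", {
  s <- RamanSpectrum(c(1000, 1100, 1200), c(2, 4, 6))
  n1 <- normalize01(s)
  expect_equal(intensities(n1), c(0, 0.5, 1))
  expect_equal(intensities(normalize01(n1)), intensities(n1))
  expect_error(normalize01(RamanSpectrum(1:8, rep(1, 8))), "constant")

  # property over random fixtures
  for (seed in 1:25) {
    sp <- simulateSpectrum(redLikeConfig(noiseSd = 0.05, seed = seed), 532)
    ns <- normalize01(sp)
    expect_identical(min(intensities(ns)), 0)
    expect_identical(max(intensities(ns)), 1)
  }
})

test_that("replicate averaging is an elementwise mean and order-invariant", {
  cfg <- simConfig(noiseSd = 0.05)
  reps <- lapply(1:3, function(r) simulateSpectrum(cfg, 532, seed = r))
  m <- averageReplicates(reps)
  oracle <- (intensities(reps[[1]]) + intensities(reps[[2]]) +
               intensities(reps[[3]])) / 3
  expect_equal(intensities(m), oracle)
  expect_equal(replicateId(m), "mean(n=3)")
  expect_equal(intensities(averageReplicates(rev(reps))), intensities(m))

  # identical replicates average to themselves
  same <- averageReplicates(list(reps[[1]], reps[[1]], reps[[1]]))
  expect_equal(intensities(same), intensities(reps[[1]]))

  # constant 0 and constant 1 average to 0.5
  s0 <- RamanSpectrum(1:10, rep(0, 10), excitation = 532)
  s1 <- RamanSpectrum(1:10, rep(1, 10), excitation = 532)
  expect_equal(intensities(averageReplicates(list(s0, s1))), rep(0.5, 10))

  # mixed excitations are a validation error
  sx <- RamanSpectrum(1:10, rnorm(10), excitation = 648)
  expect_error(averageReplicates(list(s0, sx)), "excitation")
})

test_that("the full preprocessing chain barely moves noiseless peak centers", {
  cfg <- redLikeConfig(noiseSd = 0)
  for (w in c(458, 532, 648)) {
    raw <- simulateSpectrum(cfg, w)
    truth <- attr(raw, "truth")$centers
    pp <- preprocessSpectrum(raw)
    for (b in c("CC", "CC2")) {
      pk <- findBand(pp, band = b)
      expect_lt(abs(peakCenter(pk) - truth[[b]]), 0.5)
    }
  }
})
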