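test_that("the generator is seed-deterministic and degenerates cleanly", {
  cfg <- redLikeConfig(noiseSd = 0.03, seed = 7)
  s1 <- simulateSpectrum(cfg, 532)
  s2 <- simulateSpectrum(cfg, 532)
  expect_identical(intensities(s1), intensities(s2))
  s3 <- simulateSpectrum(cfg, 532, seed = 8)
  expect_false(identical(intensities(s1), intensities(s3)))

  # the generator does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(simulateSpectrum(cfg, 532)); after <- rnorm(3)
  expect_identical(before, after)

  # all heights 0, no noise/baseline -> zero spectrum
  b <- defaultBands(); b$height <- 0
  z <- simulateSpectrum(simConfig(bands = b, noiseSd = 0), 532)
  expect_true(all(intensities(z) == 0))

  # bands outside the grid are a configuration error
  bad <- defaultBands(); bad$center[1] <- 500
  expect_error(simulateSpectrum(simConfig(bands = bad, noiseSd = 0), 532),
               "outside")

  # truth sidecar matches the placed Lorentzian
  s <- simulateSpectrum(redLikeConfig(noiseSd = 0), 648)
  tc <- attr(s, "truth")$centers
  expect_lt(abs(peakCenter(findBand(s, band = "CC")) - tc[["CC"]]), 0.05)
})

test_that("ensemble resonance weighting shifts apparent centers as designed", {
  ens <- redLikeConfig()@ensemble

  # single member: center independent of excitation energy
  one <- ens[2, ]
  expect_equal(ensembleBandCenter(one, "CC2", 15000),
               ensembleBandCenter(one, "CC2", 27000))
  expect_equal(ensembleBandCenter(one, "CC2", 20000), one$CC2)

  # narrow-resonance limit: excitation at a member's absorption maximum
  # selects that member
  ensN <- ens
  ensN$gamma <- 1e-6
  expect_equal(ensembleBandCenter(ensN, "CC2", ens$eAbs[1]), ens$CC2[1],
               tolerance = 1e-6)

  # when every resonance factor underflows, the population weights are
  # used as a fallback
  ensN$gamma <- 1e-150
  far <- ensembleBandCenter(ensN, "CC", 1e7)
  expect_equal(as.numeric(far), sum(ens$weight * ens$CC) / sum(ens$weight),
               tolerance = 1e-9)

  # red-like ensemble: apparent centers increase with excitation energy
  # over the solid-state + krypton lines, and the fitted D is positive
  wl <- setdiff(defaultExcitations(), c(351, 448, 785))
  ctrs <- vapply(sort(nmToInvcm(wl)), function(E)
    ensembleBandCenter(ens, "CC2", E), numeric(1))
  expect_true(all(diff(ctrs) > 0))
  sim <- simulateSeries(redLikeConfig(noiseSd = 0), excitations = wl,
                        replicates = 1)
  trks <- lapply(c("CC", "CC2"), function(b) trackBand(sim$series, b))
  expect_gt(fitDispersion(trks)@D_cm, 0)
})

test_that("series simulation carries exact closed-loop truth", {
  cfg <- linearConfig(D_true = 3.5e-6, noiseSd = 0)
  wl <- invcmToNm(seq(15400, 26700, length.out = 10))
  sim <- simulateSeries(cfg, excitations = wl, replicates = 1)
  expect_length(sim$series, 10L)

  # fitted D on noiseless spectra matches the generator truth closely
  trks <- lapply(c("CC", "CC2"), function(b) trackBand(sim$series, b))
  f <- fitDispersion(trks)
  expect_lt(abs(f@D_cm / sim$truth$D_cm - 1), 0.005)
  expect_equal(sim$truth$D_closed, 3.5e-6, tolerance = 1e-3)

  # dispersion_model none: spectra identical up to noise; |D| below
  # the sample-related significance level
  simN <- simulateSeries(simConfig(noiseSd = 0.02, seed = 4),
                         excitations = c(407, 458, 515, 568, 648),
                         replicates = 3)
  trksN <- lapply(c("CC", "CC2"), function(b) trackBand(simN$series, b))
  fN <- fitDispersion(trksN)
  expect_false(fN@significant)
  expect_equal(simN$truth$D_cm, 0)

  # 13-wavelength list minus the replication exclusions: 10 points
  sim13 <- simulateSeries(simConfig(noiseSd = 0.01, seed = 6),
                          replicates = 1)
  tr <- trackBand(sim13$series, "CC", exclude = c(351, 448, 785))
  expect_equal(nrow(tr@points), 10L)

  expect_error(simulateSeries(cfg, excitations = c(532, 532, 648)),
               "duplicate")
})

test_that("hue panels follow the configured trend and stay inside windows", {
  # trend 0, noise 0: all records identical within a hue and across hues
  flat <- simulateHuePanel(trend = 0, noiseSd = 0, seed = 1)
  expect_equal(length(unique(flat$nu_cc)), 1L)
  expect_equal(length(unique(flat$nu_cc2)), 1L)

  # trend without noise ranks perfectly
  ramp <- simulateHuePanel(trend = 4, noiseSd = 0, seed = 1)
  expect_equal(hueTrend(ramp)$spearman$rho, c(1, 1))
  expect_equal(nrow(ramp), 26L)

  # windows are honoured
  noisy <- simulateHuePanel(trend = 4, noiseSd = 6, seed = 2)
  expect_true(all(noisy$nu_cc >= 1090 & noisy$nu_cc <= 1190))
  expect_true(all(noisy$nu_cc2 >= 1490 & noisy$nu_cc2 <= 1590))

  # a trend that walks the means out of the window is refused
  expect_error(simulateHuePanel(trend = 25), "outside")
})

test_that("hypermap simulation attaches a faithful ground-truth mask", {
  hm <- simulateHypermap(7, 9, "stripe", seed = 10)
  msk <- attr(hm, "mask")
  expect_equal(dim(msk), c(7L, 9L))
  expect_equal(dim(hm), c(7L, 9L))
  # a masked pixel carries the doublet, an unmasked one does not
  rc <- which(msk, arr.ind = TRUE)[1, ]
  expect_true(detectPsittacofulvin(pixelSpectrum(hm, rc[1], rc[2]))$present)
  rc0 <- which(!msk, arr.ind = TRUE)[1, ]
  expect_false(detectPsittacofulvin(pixelSpectrum(hm, rc0[1], rc0[2]))$present)

  expect_error(simulateHypermap(4, 4, matrix(TRUE, 3, 3)), "mask shape")
})
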