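test_that("noiseless symmetric peaks are located to sub-grid accuracy", {
  x <- seq(1000, 1300, 1)
  s <- RamanSpectrum(x, analyticLorentzian(x, 1137.0, fwhm = 12))
  p1 <- findBand(s, window = c(1090, 1190))
  expect_lt(abs(peakCenter(p1) - 1137.0), 0.05)
  p2 <- findBand(s, window = c(1090, 1190), method = "lorentzian_ls")
  expect_lt(abs(peakCenter(p2) - 1137.0), 0.01)
  expect_equal(p2@fwhm, 12, tolerance = 0.01)

  # an off-grid center is refined below half the grid spacing
  s2 <- RamanSpectrum(x, analyticLorentzian(x, 1137.37, fwhm = 12))
  expect_lt(abs(peakCenter(findBand(s2, window = c(1090, 1190))) - 1137.37),
            0.5)
})

test_that("find_band is shift-equivariant and scale-invariant", {
  x <- seq(1000, 1300, 1)
  y <- analyticLorentzian(x, 1141.3, fwhm = 14)
  base <- peakCenter(findBand(RamanSpectrum(x, y), window = c(1090, 1190)))
  for (delta in c(-20.5, 13.25)) {
    sh <- peakCenter(findBand(RamanSpectrum(x + delta, y),
                              window = c(1090, 1190) + delta))
    expect_equal(sh, base + delta, tolerance = 1e-9)
  }
  sc <- peakCenter(findBand(RamanSpectrum(x, 37.5 * y),
                            window = c(1090, 1190)))
  expect_equal(sc, base, tolerance = 1e-12)
})

test_that("degenerate windows are flagged instead of inventing peaks", {
  flat <- RamanSpectrum(900:1800, rep(1, 901))
  pf <- findBand(flat, window = c(1090, 1190))
  expect_true("edge" %in% peakFlags(pf))

  # tie-break: two equal grid maxima -> lower wavenumber wins
  x <- seq_len(11) + 1000
  y <- c(0, 1, 2, 3, 4, 5, 5, 4, 3, 2, 1)
  pt <- findBand(RamanSpectrum(x, y), window = c(1001, 1011))
  expect_lte(peakCenter(pt), x[6] + 0.5)

  expect_error(findBand(flat, window = c(1090, 1093)), "fewer than 5")
})

test_that("doublet detection separates pigmented from keratin-only spectra", {
  white <- simulateSpectrum(keratinConfig(noiseSd = 0.02, seed = 11), 1064)
  dw <- detectPsittacofulvin(white)
  expect_false(dw$present)

  red <- simulateSpectrum(redLikeConfig(noiseSd = 0.02, seed = 12), 532)
  dr <- detectPsittacofulvin(smoothSavgol(red))
  expect_true(dr$present)
  expect_length(dr$pigment, 2L)
  truth <- attr(red, "truth")$centers
  expect_lt(abs(peakCenter(dr$pigment$CC) - truth[["CC"]]), 0.3)
  expect_lt(abs(peakCenter(dr$pigment$CC2) - truth[["CC2"]]), 0.3)

  # a doublet drowned in noise fails the SNR gate
  faint <- simulateSpectrum(redLikeConfig(noiseSd = 0.6, seed = 4), 532)
  expect_false(detectPsittacofulvin(faint, min_snr = 5)$present)
})

test_that("keratin band search returns exactly the matrix bands present", {
  white <- simulateSpectrum(keratinConfig(noiseSd = 0), 1064)
  kb <- keratinBands(white)
  expect_length(kb, 4L)
  truth <- c(keratin_1006 = 1006, keratin_1240 = 1240,
             keratin_1450 = 1450, keratin_1670 = 1670)
  for (b in names(truth))
    expect_lt(abs(peakCenter(kb[[b]]) - truth[[b]]), 2)

  pig <- simulateSpectrum(pigmentOnlyConfig(noiseSd = 0), 648)
  expect_length(keratinBands(pig), 0L)

  both <- simulateSpectrum(redLikeConfig(noiseSd = 0.01, seed = 3), 532)
  kb2 <- keratinBands(both)
  expect_true(all(grepl("^keratin", names(kb2))))
  expect_gte(length(kb2), 3L)
})

test_that("band tracking records trajectories, references and exclusions", {
  # identical spectra at 5 excitations: zero shift
  s0 <- simulateSpectrum(simConfig(noiseSd = 0), 532)
  specs <- lapply(c(407, 458, 515, 568, 648), function(w) {
    s <- s0; s@excitation <- w; s
  })
  ser <- ExcitationSeries(specs)
  tr <- trackBand(ser, "CC")
  expect_equal(diff(range(tr@points$center)), 0)
  expect_equal(tr@reference$excitation_nm, 648)

  # linear dispersion: centers follow nu0 + s * (E - E0)
  cfg <- linearConfig(D_true = 3.5e-6, noiseSd = 0)
  siml <- simulateSeries(cfg, excitations = c(407, 458, 515, 568, 648),
                         replicates = 1)
  trl <- trackBand(siml$series, "CC2")
  E <- trl@points$E_invcm
  E0 <- min(E)
  s_b <- cfg@linearSlopes[["CC2"]]
  nu0 <- trl@reference$center
  expect_lt(max(abs(trl@points$center - (nu0 + s_b * (E - E0)))), 0.3)

  # the 13-wavelength list with the replication exclusions: 10 points,
  # reference at 648 nm
  sim13 <- simulateSeries(redLikeConfig(noiseSd = 0.01, seed = 5),
                          replicates = 1)
  tr13 <- trackBand(sim13$series, "CC", exclude = c(351, 448, 785),
                    reasons = defaultExclusions())
  expect_equal(nrow(tr13@points), 10L)
  expect_equal(tr13@reference$excitation_nm, 648)
  expect_setequal(tr13@excluded$excitation_nm, c(351, 448, 785))
  expect_setequal(tr13@excluded$reason, c("pre-resonant", "spurious"))

  # too few points after exclusion is an error
  expect_error(trackBand(ser, "CC", exclude = c(458, 515, 568)),
               "need >= 3")
})

test_that("peak tables round trip through tracksFromTable", {
  sim <- simulateSeries(redLikeConfig(noiseSd = 0, seed = 8),
                        replicates = 1)
  tr <- trackBand(sim$series, "CC2", exclude = c(351, 448, 785))
  tab <- peakTable(tr)
  tab$band <- "CC2"
  tr2 <- tracksFromTable(tab[, c("band", "excitation_nm", "center")])
  expect_equal(tr2$CC2@points$center, tr@points$center)
  expect_equal(tr2$CC2@reference$center, tr@reference$center)
})
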