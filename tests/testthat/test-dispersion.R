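test_that("unit bridges are exact and invertible", {
  expect_equal(nmToInvcm(500), 20000)
  expect_equal(nmToInvcm(1000), 10000)
  expect_equal(nmToInvcm(648), 15432.1, tolerance = 0.1 / 15432)
  expect_equal(invcmToEv(8065.544), 1)
  expect_equal(invcmToEv(0), 0)
  x <- c(0.1, 1, 15432.0988, 27000)
  expect_equal(evToInvcm(invcmToEv(x)), x, tolerance = 1e-12)
  expect_equal(invcmToNm(nmToInvcm(c(351, 785))), c(351, 785))
  expect_error(nmToInvcm(-5))
  expect_error(nmToInvcm(0))
})

makeConstantTracks <- function(centers = c(CC = 1137, CC2 = 1531),
                               wl = c(407, 458, 515, 568, 648)) {
  lapply(names(centers), function(b) {
    E <- sort(nmToInvcm(wl))
    pts <- data.frame(excitation_nm = sort(wl, decreasing = TRUE),
                      E_invcm = E, E_eV = invcmToEv(E),
                      center = centers[[b]], height = 1, fwhm = 12,
                      snr = Inf, flags = "")
    new("BandTrack", band = b, window = centers[[b]] + c(-60, 60),
        points = pts,
        reference = list(center = centers[[b]],
                         excitation_nm = max(wl),
                         E_invcm = min(E)),
        excluded = data.frame(excitation_nm = numeric(0),
                              reason = character(0)))
  })
}

test_that("squared ratios equal 1 at the reference and match arithmetic", {
  tr <- makeConstantTracks()[[1]]
  r <- ratioSquared(tr)
  expect_true(all(r$ratio2 == 1))

  # direct arithmetic: nu0 = 1525, nuN = 1542
  tr@points$center <- c(1525, 1530, 1533, 1538, 1542)
  tr@reference$center <- 1525
  r2 <- ratioSquared(tr)
  expect_equal(r2$ratio2[1], 1)
  expect_equal(r2$ratio2[5], (1542 / 1525)^2)
  expect_equal(r2$ratio2[5], 1.02241935, tolerance = 1e-7)

  # closed form for a linear track: (1 + s*dE/nu0)^2
  lt <- simulateLinearTracks(jitterSd = 0)
  rl <- ratioSquared(lt$tracks$CC)
  dE <- rl$E_invcm - min(rl$E_invcm)
  nu0 <- lt$tracks$CC@reference$center
  expect_equal(rl$ratio2, (1 + lt$slopes[["CC"]] * dE / nu0)^2,
               tolerance = 1e-12)
})

test_that("the product rule multiplies bands and matches brute force", {
  cts <- makeConstantTracks()
  pr <- ammProduct(cts)
  expect_true(all(pr$product == 1))

  # one track degenerates to its own squared ratio
  one <- ammProduct(cts[1])
  expect_equal(one$product, ratioSquared(cts[[1]])$ratio2)

  # direct arithmetic at one excitation: 1.010 * 1.020 = 1.0302
  expect_equal(1.010 * 1.020, 1.0302)

  # order invariance and brute-force oracle on random jittered tracks
  for (seed in 1:10) {
    lt <- simulateLinearTracks(jitterSd = 1.5, seed = seed)
    p1 <- ammProduct(lt$tracks)
    p2 <- ammProduct(rev(lt$tracks))
    expect_equal(p1$product, p2$product, tolerance = 1e-15)
    expect_equal(p1$product, bruteForceProducts(lt$tracks),
                 tolerance = 1e-12)
    expect_equal(p1$product[which.min(p1$E_invcm)], 1)
  }

  # mismatched excitation sets are refused with the difference listed
  bad <- makeConstantTracks(wl = c(407, 458, 515, 568, 594))
  expect_error(ammProduct(list(cts[[1]], bad[[2]])), "594|648")
})

test_that("dispersion fitting recovers exact slopes and flags flat series", {
  # constant tracks: D exactly 0, fit error not applicable
  f0 <- fitDispersion(makeConstantTracks())
  expect_lt(abs(f0@D_cm), 1e-15)
  expect_false(f0@significant)
  expect_true(is.na(f0@fitErrorPct))

  # exactly linear products: a track built so that (nu/nu0)^2 is an
  # affine function of energy is recovered to machine precision, R2 = 1
  a <- 3e-6
  E <- seq(15400, 26700, length.out = 8)
  exactTrack <- makeConstantTracks(wl = invcmToNm(E))[[1]]
  exactTrack@points$center <- 1137 * sqrt(1 + a * (sort(E) - min(E)))
  exactTrack@reference$center <- exactTrack@points$center[1]
  fx <- fitDispersion(list(exactTrack))
  expect_equal(fx@D_cm, a, tolerance = 1e-12)
  expect_equal(fx@R2, 1, tolerance = 1e-12)
  expect_lt(fx@p, 1e-15)

  # noiseless linear tracks: near-perfect linearity of the product
  lt <- simulateLinearTracks(jitterSd = 0)
  fl <- fitDispersion(lt$tracks)
  expect_equal(fl@D_cm, lt$D_true_exact, tolerance = 1e-10)
  expect_gt(fl@R2, 0.9999)
  expect_lt(fl@p, 1e-10)

  # small-shift closed form: D ~ 2 * sum(s_b / nu0_b) within 1% when the
  # maximum shift stays below 1% of the reference wavenumber
  ltSmall <- simulateLinearTracks(jitterSd = 0, D_true = 1.5e-6)
  flS <- fitDispersion(ltSmall$tracks)
  expect_lt(abs(flS@D_cm / ltSmall$D_closed - 1), 0.01)

  # unit duality: identical R2/p on both axes, slopes tied by 8065.544
  fe <- fitDispersion(lt$tracks, energyAxis = "eV")
  expect_equal(fe@R2, fl@R2, tolerance = 1e-12)
  expect_equal(fe@p, fl@p, tolerance = 1e-12)
  expect_equal(fe@D_cm, fl@D_cm, tolerance = 1e-12)
  expect_equal(fl@D_eV, fl@D_cm * 8065.544)

  # |D| grows monotonically with the generator's dispersion slope
  dGrid <- c(1e-6, 3e-6, 6e-6, 1e-5)
  dHat <- vapply(dGrid, function(d)
    abs(fitDispersion(simulateLinearTracks(D_true = d,
                                           jitterSd = 0)$tracks)@D_cm),
    numeric(1))
  expect_true(all(diff(dHat) > 0))

  # zero variance in excitation energy is a singular design
  ct <- makeConstantTracks(wl = c(532, 532.0000001, 532.0000002))
  ct[[1]]@points$E_invcm <- rep(18796.99, 3)
  ct[[1]]@points$E_eV <- invcmToEv(ct[[1]]@points$E_invcm)
  ct[[2]]@points$E_invcm <- rep(18796.99, 3)
  ct[[2]]@points$E_eV <- invcmToEv(ct[[2]]@points$E_invcm)
  ct[[1]]@reference$E_invcm <- 18796.99
  ct[[2]]@reference$E_invcm <- 18796.99
  expect_error(fitDispersion(ct), "singular")
})

test_that("per-band regressions and the 3 cm-1 significance rule behave", {
  lt <- simulateLinearTracks(jitterSd = 0, D_true = 3.5e-6)
  f <- fitDispersion(lt$tracks)
  pb <- perBandFits(f)
  expect_setequal(pb$band, c("CC", "CC2"))
  expect_true(all(pb$R2 > 0.99999))
  # max shift = slope * energy span (linear, noiseless)
  span <- diff(range(lt$tracks$CC@points$E_invcm))
  expect_equal(pb$maxShift[pb$band == "CC"],
               lt$slopes[["CC"]] * span, tolerance = 1e-9)
  # shifts here are ~11 and ~15 cm-1: sample-related
  expect_true(f@significant)

  # shrink the dispersion below the threshold: not significant
  ltSmall <- simulateLinearTracks(jitterSd = 0, D_true = 2e-7)
  expect_false(fitDispersion(ltSmall$tracks)@significant)
})

test_that("hue trends rank band positions along the colour scale", {
  # one record per hue, strictly increasing positions: perfect ranking
  rec <- data.frame(specimen_id = letters[1:4],
                    hue = c("magenta", "red", "orange", "yellow"),
                    nu_cc = c(1130, 1134, 1138, 1142),
                    nu_cc2 = c(1524, 1528, 1532, 1536))
  ht <- hueTrend(rec)
  expect_equal(ht$spearman$rho, c(1, 1))
  expect_equal(ht$summary$median[ht$summary$band == "nu_cc" &
                                   ht$summary$hue == "magenta"], 1130)

  # constant positions: rho defined as 0 under average ranks
  recC <- rec
  recC$nu_cc <- 1137
  recC$nu_cc2 <- 1531
  htC <- hueTrend(recC)
  expect_equal(htC$spearman$rho, c(0, 0))

  expect_error(hueTrend(rec[rec$hue == "red", ]), "degenerate")
  expect_error(hueTrend(data.frame(hue = c("red", "teal"),
                                   nu_cc = c(1, 2), nu_cc2 = c(1, 2))),
               "teal")

  # positive-trend generator yields rho > 0 in >= 95/100 seeds
  hits <- 0L
  for (seed in 1:100) {
    hp <- simulateHuePanel(trend = 3, noiseSd = 2, seed = seed)
    sp <- hueTrend(hp)$spearman
    if (all(sp$rho > 0)) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})
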