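#' Multi-feather survey workflow
#'
#' The colour-gamut survey: for every specimen in the manifest, the
#' replicate spectra are preprocessed (crop 900-1800 cm^-1,
#' Savitzky-Golay, baseline, 0-1 normalization), normalized replicates
#' are averaged, the psittacofulvin doublet is detected and its band
#' centers are tabulated; specimens carrying the doublet feed the hue
#' trend summary.
#'
#' @param manifest manifest path or data.frame with columns `path`,
#'   `specimen_id`, `region_label` (the hue), `replicate_id`.
#' @param min_snr doublet detection threshold, see
#'   [detectPsittacofulvin()].
#' @param method peak estimator, see [findBand()].
#' @param outDir optional directory: writes `survey_peaks.csv` and
#'   `survey.json`.
#' @param ... preprocessing overrides passed to [preprocessSpectrum()].
#' @return list(peaks, trend, provenance); `peaks` has one row per
#'   specimen, `trend` is the [hueTrend()] output (NULL when fewer than
#'   2 hue categories carry pigment).
#' @export
runSurvey <- function(manifest, min_snr = 5,
                      method = "argmax_parabolic", outDir = NULL, ...) {
  man <- if (is.character(manifest)) {
    m <- readManifest(manifest)
    if (!"specimen_id" %in% names(m))
      stop("survey manifest needs a specimen_id column")
    m
  } else manifest
  if (!nrow(man)) stop("empty manifest (usage error)")
  need <- c("path", "specimen_id", "replicate_id")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop("survey manifest lacks column(s): ", paste(miss, collapse = ", "))
  if (!"region_label" %in% names(man)) man$region_label <- NA_character_

  rows <- list()
  for (sid in unique(man$specimen_id)) {
    sub <- man[man$specimen_id == sid, , drop = FALSE]
    specs <- tryCatch({
      reps <- lapply(seq_len(nrow(sub)), function(i) {
        s <- readSpectrum(sub$path[i])
        if (is.na(s@region)) s@region <- as.character(sub$region_label[i])
        if (is.na(s@replicate)) s@replicate <- as.character(sub$replicate_id[i])
        preprocessSpectrum(s, ...)
      })
      if (length(reps) > 1L) {
        grid <- commonGrid(reps)
        reps <- lapply(reps, resampleSpectrum, grid = grid)
      }
      averageReplicates(reps)
    }, error = function(e)
      stop("specimen ", sid, ": ", conditionMessage(e), call. = FALSE))
    det <- detectPsittacofulvin(specs, min_snr = min_snr, method = method)
    rows[[sid]] <- data.frame(
      specimen_id = sid,
      hue = sub$region_label[1],
      n_replicates = nrow(sub),
      present = det$present,
      nu_cc = if (!is.null(det$pigment$CC)) det$pigment$CC@center
              else NA_real_,
      nu_cc2 = if (!is.null(det$pigment$CC2)) det$pigment$CC2@center
               else NA_real_,
      snr_cc = if (!is.null(det$pigment$CC)) det$pigment$CC@snr
               else NA_real_,
      snr_cc2 = if (!is.null(det$pigment$CC2)) det$pigment$CC2@snr
                else NA_real_,
      n_keratin = length(det$keratin),
      stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, rows)
  rownames(peaks) <- NULL

  pig <- peaks[peaks$present & peaks$hue %in% hueLevels(), , drop = FALSE]
  trend <- if (nrow(pig) >= 2L && length(unique(pig$hue)) >= 2L)
    hueTrend(data.frame(specimen_id = pig$specimen_id, hue = pig$hue,
                        nu_cc = pig$nu_cc, nu_cc2 = pig$nu_cc2,
                        stringsAsFactors = FALSE))
  else NULL

  out <- list(peaks = peaks, trend = trend,
              provenance = provenanceBlock(list(min_snr = min_snr,
                                                method = method)))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(peaks, file.path(outDir, "survey_peaks.csv"),
                     row.names = FALSE)
    jsonlite::write_json(out, file.path(outDir, "survey.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}

#' Excitation-series dispersion workflow
#'
#' The resonance workflow for one feather region: replicates are
#' preprocessed (crop, smooth, baseline), raw replicates are averaged
#' per excitation and the mean is 0-1 normalized; the C-C and C=C bands
#' are then tracked across excitations and the amplitude-mode-model
#' dispersion rate is fitted.
#'
#' @param x manifest path, manifest data.frame or an
#'   [ExcitationSeries-class] (already preprocessed).
#' @param exclude excitation wavelengths (nm) to leave out; defaults to
#'   the replication set `c(351, 448, 785)`, see [defaultExclusions()].
#' @param reasons named exclusion reasons; defaults to
#'   [defaultExclusions()].
#' @param bands bands to track and multiply (default the pigment
#'   doublet).
#' @param method peak estimator, see [findBand()].
#' @param shiftThreshold sample-related shift threshold (cm^-1).
#' @param outDir optional directory: writes `dispersion.json` and
#'   `products.csv`.
#' @return list(fit = [DispersionFit-class], peaks = per-excitation peak
#'   table, provenance).
#' @export
runDispersion <- function(x, exclude = c(351, 448, 785),
                          reasons = defaultExclusions(),
                          bands = c("CC", "CC2"),
                          method = "argmax_parabolic",
                          shiftThreshold = 3, outDir = NULL) {
  series <- if (is(x, "ExcitationSeries")) x
  else {
    pre <- function(s) preprocessSpectrum(s, normalize = FALSE)
    ser <- readSeries(x, preprocess = pre)
    ExcitationSeries(lapply(ser@spectra, normalize01),
                     region = ser@region)
  }
  tracks <- lapply(bands, function(b)
    trackBand(series, band = b, exclude = exclude, reasons = reasons,
              method = method))
  names(tracks) <- bands
  fit <- fitDispersion(tracks, shiftThreshold = shiftThreshold)
  peaks <- do.call(rbind, lapply(tracks, peakTable))
  rownames(peaks) <- NULL
  out <- list(fit = fit, peaks = peaks,
              provenance = provenanceBlock(list(exclude = exclude,
                                                bands = bands,
                                                method = method)))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(fit@products, file.path(outDir, "products.csv"),
                     row.names = FALSE)
    rep <- list(
      D_cm = fit@D_cm, D_eV = fit@D_eV, se_cm = fit@se_cm,
      R2 = fit@R2, p = fit@p, fit_error_pct = fit@fitErrorPct,
      fit_error_definition = "100 * SE(slope) / |slope| of the product regression",
      n_points = fit@nPoints, significant = fit@significant,
      shift_threshold_invcm = fit@shiftThreshold,
      per_band = fit@perBand, products = fit@products,
      peaks = peaks, provenance = out$provenance)
    jsonlite::write_json(rep, file.path(outDir, "dispersion.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}

# machine-readable run provenance
provenanceBlock <- function(params) {
  list(package = "RamanAMM",
       version = as.character(utils::packageVersion("RamanAMM")),
       parameters = params,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
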