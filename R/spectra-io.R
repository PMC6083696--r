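#' Read a two-column Raman spectrum file
#'
#' The file format is delimited text: optional `#key: value` metadata
#' header lines (keys `excitation_nm`, `region_label`, `replicate_id`)
#' followed by two numeric columns, wavenumber (cm^-1) and intensity
#' (a.u.). Comma, tab or whitespace delimiters are auto-detected. A
#' descending wavenumber axis is normalized to ascending.
#'
#' @param path path to the spectrum file.
#' @param dialect "auto" (default), "csv" or "tsv".
#' @return A [RamanSpectrum-class].
#' @seealso [writeSpectrum()], [readSeries()]
#' @export
readSpectrum <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  isMeta <- grepl("^\\s*#", lines)
  isBlank <- grepl("^\\s*$", lines)

  meta <- list()
  for (ln in lines[isMeta]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([^:]+?)\\s*:\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }

  bodyIdx <- which(!isMeta & !isBlank)
  if (!length(bodyIdx)) stop("no data rows in ", path)
  body <- lines[bodyIdx]

  sep <- switch(dialect,
    csv = ",", tsv = "\t",
    auto = if (grepl("\t", body[1])) "\t"
           else if (grepl(",", body[1])) "," else "[[:space:]]+")

  wn <- numeric(length(body))
  y  <- numeric(length(body))
  for (k in seq_along(body)) {
    parts <- strsplit(trimws(body[k]), sep)[[1]]
    parts <- parts[nzchar(parts)]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) < 2L || anyNA(vals[1:2]))
      stop(sprintf("parse error in %s at line %d: '%s' is not two numbers",
                   path, bodyIdx[k], body[k]))
    wn[k] <- vals[1]
    y[k]  <- vals[2]
  }
  if (anyDuplicated(wn))
    stop("duplicate wavenumbers in ", path)

  RamanSpectrum(
    wn, y,
    excitation = if (!is.null(meta$excitation_nm))
      as.numeric(meta$excitation_nm) else NA_real_,
    region = if (!is.null(meta$region_label)) meta$region_label
             else NA_character_,
    replicate = if (!is.null(meta$replicate_id)) meta$replicate_id
                else NA_character_,
    source = path)
}

#' Write a Raman spectrum to delimited text
#'
#' Metadata present on the object is written as `#key: value` header
#' lines; values are printed at full double precision so that
#' [readSpectrum()] inverts the file exactly.
#'
#' @param spec a [RamanSpectrum-class].
#' @param path output file path.
#' @param sep column delimiter (default comma).
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(spec, path, sep = ",") {
  stopifnot(is(spec, "RamanSpectrum"))
  validObject(spec)
  hdr <- character(0)
  if (!is.na(spec@excitation))
    hdr <- c(hdr, sprintf("#excitation_nm: %.17g", spec@excitation))
  if (!is.na(spec@region))
    hdr <- c(hdr, paste0("#region_label: ", spec@region))
  if (!is.na(spec@replicate))
    hdr <- c(hdr, paste0("#replicate_id: ", spec@replicate))
  body <- sprintf("%.17g%s%.17g", spec@wavenumber, sep, spec@intensity)
  ok <- tryCatch({
    writeLines(c(hdr, body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write spectrum to ", path)
  invisible(path)
}

#' Read a series manifest
#'
#' A manifest is a delimited table (comma or tab, with a header) whose
#' columns include `path`, `excitation_nm` and `replicate_id`, and
#' optionally `region_label`. Relative paths are resolved against the
#' manifest's directory.
#'
#' @param path manifest file path.
#' @return data.frame with resolved absolute paths.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  man <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#",
                           strip.white = TRUE)
  need <- c("path", "excitation_nm", "replicate_id")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  if (!"region_label" %in% names(man)) man$region_label <- NA_character_
  base <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                file.path(base, man$path))
  man$path <- abs
  man
}

#' Assemble an excitation series from a manifest
#'
#' Reads every listed spectrum, applies an optional per-spectrum
#' preprocessing function, resamples all replicates of one excitation to
#' a shared grid, averages them with [averageReplicates()] and returns
#' the series ordered by ascending excitation wavelength.
#'
#' @param manifest manifest path or a data.frame as from [readManifest()].
#' @param preprocess optional `function(RamanSpectrum) -> RamanSpectrum`
#'   applied to each replicate before averaging.
#' @param region region label for the series (default: common label of
#'   the members).
#' @return An [ExcitationSeries-class].
#' @export
readSeries <- function(manifest, preprocess = NULL, region = NULL) {
  man <- if (is.character(manifest)) readManifest(manifest) else manifest
  if (!nrow(man)) stop("empty manifest")
  key <- paste(man$excitation_nm, man$replicate_id, sep = "@")
  if (anyDuplicated(key))
    stop("duplicate (excitation, replicate) in manifest: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  missing <- !file.exists(man$path)
  if (any(missing))
    stop("manifest names missing file(s): ",
         paste(man$path[missing], collapse = ", "))

  specs <- lapply(seq_len(nrow(man)), function(i) {
    s <- readSpectrum(man$path[i])
    if (is.na(s@excitation)) s@excitation <- as.numeric(man$excitation_nm[i])
    if (is.na(s@replicate)) s@replicate <- as.character(man$replicate_id[i])
    if (is.na(s@region) && !is.na(man$region_label[i]))
      s@region <- as.character(man$region_label[i])
    if (!is.null(preprocess)) s <- preprocess(s)
    s
  })

  byExc <- split(specs, vapply(specs, function(s) s@excitation, numeric(1)))
  averaged <- lapply(byExc, function(reps) {
    if (length(reps) > 1L) {
      grid <- commonGrid(reps)
      reps <- lapply(reps, resampleSpectrum, grid = grid)
    }
    averageReplicates(reps)
  })

  # members must share one grid across excitations as well
  grid <- commonGrid(averaged)
  averaged <- lapply(averaged, resampleSpectrum, grid = grid)
  ExcitationSeries(averaged, region = region)
}

# largest grid covered by every spectrum, at the finest common spacing
commonGrid <- function(specs) {
  lo <- max(vapply(specs, function(s) min(s@wavenumber), numeric(1)))
  hi <- min(vapply(specs, function(s) max(s@wavenumber), numeric(1)))
  if (lo >= hi) stop("spectra have no overlapping wavenumber range")
  step <- min(vapply(specs, function(s) stats::median(diff(s@wavenumber)),
                     numeric(1)))
  seq(lo, hi, by = step)
}

#' Resample a spectrum onto a new wavenumber grid
#'
#' Linear interpolation only; extrapolation beyond the measured range is
#' refused.
#'
#' @param spec a [RamanSpectrum-class].
#' @param grid strictly increasing target wavenumber axis within the
#'   spectrum's range.
#' @return The resampled [RamanSpectrum-class] (metadata preserved).
#' @export
resampleSpectrum <- function(spec, grid) {
  stopifnot(is(spec, "RamanSpectrum"))
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("target grid must be strictly increasing")
  eps <- 1e-9 * max(abs(spec@wavenumber))
  if (min(grid) < min(spec@wavenumber) - eps ||
      max(grid) > max(spec@wavenumber) + eps)
    stop("target grid extends beyond the measured range (no extrapolation)")
  y <- stats::approx(spec@wavenumber, spec@intensity, xout = grid,
                     rule = 1)$y
  # guard the boundary against floating-point overhang
  if (anyNA(y)) {
    bad <- which(is.na(y))
    y[bad] <- stats::approx(spec@wavenumber, spec@intensity,
                            xout = pmin(pmax(grid[bad], min(spec@wavenumber)),
                                        max(spec@wavenumber)))$y
  }
  new("RamanSpectrum", wavenumber = grid, intensity = y,
      excitation = spec@excitation, region = spec@region,
      replicate = spec@replicate, source = spec@source)
}

#' Read / write a hyperspectral grid as a single matrix file
#'
#' The matrix format is delimited text: `#key: value` headers
#' (`n_rows`, `n_cols`, `pixel_size_um`, `excitation_nm`), then the
#' shared wavenumber axis as the first data row, then one row of
#' intensities per pixel in row-major order.
#'
#' @param path file path.
#' @return A [RamanHyperMap-class].
#' @export
readHyperMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  isMeta <- grepl("^\\s*#", lines)
  meta <- list()
  for (ln in lines[isMeta]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([^:]+?)\\s*:\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  need <- c("n_rows", "n_cols")
  if (!all(need %in% names(meta)))
    stop("hypermap file lacks #n_rows / #n_cols headers")
  body <- lines[!isMeta & !grepl("^\\s*$", lines)]
  rows <- lapply(body, function(ln)
    as.numeric(strsplit(trimws(ln), "[,\t ]+")[[1]]))
  wn <- rows[[1]]
  mat <- do.call(rbind, rows[-1])
  RamanHyperMap(mat, wn,
                nRow = as.integer(meta$n_rows),
                nCol = as.integer(meta$n_cols),
                pixelSize = if (!is.null(meta$pixel_size_um))
                  as.numeric(meta$pixel_size_um) else NA_real_,
                excitation = if (!is.null(meta$excitation_nm))
                  as.numeric(meta$excitation_nm) else NA_real_)
}

#' @rdname readHyperMap
#' @param map a [RamanHyperMap-class] to write.
#' @export
writeHyperMap <- function(map, path) {
  stopifnot(is(map, "RamanHyperMap"))
  hdr <- c(sprintf("#n_rows: %d", map@nRow),
           sprintf("#n_cols: %d", map@nCol))
  if (!is.na(map@pixelSize))
    hdr <- c(hdr, sprintf("#pixel_size_um: %.17g", map@pixelSize))
  if (!is.na(map@excitation))
    hdr <- c(hdr, sprintf("#excitation_nm: %.17g", map@excitation))
  fmt <- function(v) paste(sprintf("%.17g", v), collapse = ",")
  body <- c(fmt(map@wavenumber),
            apply(map@intensities, 1L, fmt))
  writeLines(c(hdr, body), path)
  invisible(path)
}
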