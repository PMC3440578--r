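## Delimited-text readers and writers.  All files carry a single `#` header
## line naming the columns/units and key=value metadata.

.headerMeta <- function(line) {
  kv <- regmatches(line, gregexpr("[A-Za-z0-9_.]+=[-+0-9.eE]+", line))[[1]]
  if (!length(kv)) return(list())
  parts <- strsplit(kv, "=", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) as.numeric(p[2])),
                  vapply(parts, `[`, "", 1))
}

.readHeaded <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#")) stop("missing '#' header line in ", path)
  list(meta = .headerMeta(first),
       data = utils::read.table(path, comment.char = "#"))
}

#' Read and write TCSPC decay histograms as delimited text
#'
#' Three-column text (time_ns, counts, irf_counts) with a one-line `#`
#' header carrying `channel_width_ns=` and `background=`.
#'
#' @param hist a [TCSPCHistogram-class].
#' @param path file path.
#' @return `readDecay` returns a [TCSPCHistogram-class]; `writeDecay`
#'   returns `path` invisibly.
#' @export
writeDecay <- function(hist, path) {
  stopifnot(is(hist, "TCSPCHistogram"))
  counts <- if (length(hist@counts)) hist@counts else rep(0, length(hist@irf))
  header <- sprintf("# time_ns counts irf_counts channel_width_ns=%.10g background=%.10g",
                    hist@channelWidth, hist@background)
  writeLines(header, path)
  utils::write.table(
    data.frame(time = timeAxis(hist), counts = counts, irf = hist@irf),
    path, append = TRUE, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeDecay
#' @export
readDecay <- function(path) {
  x <- .readHeaded(path)
  counts <- x$data[[2]]
  if (all(counts == 0)) counts <- numeric()
  TCSPCHistogram(counts = counts, irf = x$data[[3]],
                 channelWidth = x$meta$channel_width_ns,
                 background = if (is.null(x$meta$background)) 0
                              else x$meta$background)
}

#' Read and write polarized decay pairs as delimited text
#'
#' Four-column text (time_ns, ivv, ivh, irf_counts) with a `#` header
#' carrying `g_factor=`, `channel_width_ns=`, `background_vv=` and
#' `background_vh=`.
#'
#' @param pol a [PolarizedDecays-class].
#' @param path file path.
#' @return `readPolarized` returns a [PolarizedDecays-class];
#'   `writePolarized` returns `path` invisibly.
#' @export
writePolarized <- function(pol, path) {
  stopifnot(is(pol, "PolarizedDecays"))
  header <- sprintf(
    "# time_ns ivv ivh irf_counts g_factor=%.10g channel_width_ns=%.10g background_vv=%.10g background_vh=%.10g",
    pol@gFactor, pol@ivv@channelWidth, pol@ivv@background,
    pol@ivh@background)
  writeLines(header, path)
  utils::write.table(
    data.frame(time = timeAxis(pol), ivv = pol@ivv@counts,
               ivh = pol@ivh@counts, irf = pol@ivv@irf),
    path, append = TRUE, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writePolarized
#' @export
readPolarized <- function(path) {
  x <- .readHeaded(path)
  dt <- x$meta$channel_width_ns
  PolarizedDecays(
    ivv = TCSPCHistogram(x$data[[2]], x$data[[4]], dt,
                         x$meta$background_vv %||% 0),
    ivh = TCSPCHistogram(x$data[[3]], x$data[[4]], dt,
                         x$meta$background_vh %||% 0),
    gFactor = x$meta$g_factor %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write EPR spectra as delimited text
#'
#' Two-column text (field_mT, intensity) with a `#` header carrying
#' `frequency_GHz=` (additional acquisition metadata such as
#' `temperature_K=` is carried through untouched).
#'
#' @param spec an [EPRSpectrum-class].
#' @param path file path.
#' @param extra named numeric metadata appended to the header.
#' @return `readEPRSpectrum` returns an [EPRSpectrum-class];
#'   `writeEPRSpectrum` returns `path` invisibly.
#' @export
writeEPRSpectrum <- function(spec, path, extra = NULL) {
  stopifnot(is(spec, "EPRSpectrum"))
  meta <- sprintf("frequency_GHz=%.10g", spec@frequency)
  if (length(extra))
    meta <- paste(meta, paste(sprintf("%s=%.10g", names(extra),
                                      as.numeric(extra)), collapse = " "))
  writeLines(paste("# field_mT intensity", meta), path)
  utils::write.table(data.frame(spec@field, spec@intensity), path,
                     append = TRUE, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname writeEPRSpectrum
#' @export
readEPRSpectrum <- function(path) {
  x <- .readHeaded(path)
  EPRSpectrum(x$data[[1]], x$data[[2]], x$meta$frequency_GHz)
}

#' Read and write EPR power-saturation series as delimited text
#'
#' Two-column text (power_mW, intensity).
#'
#' @param series a [SaturationSeries-class].
#' @param path file path.
#' @return `readSaturation` returns a [SaturationSeries-class];
#'   `writeSaturation` returns `path` invisibly.
#' @export
writeSaturation <- function(series, path) {
  stopifnot(is(series, "SaturationSeries"))
  writeLines("# power_mW intensity", path)
  utils::write.table(data.frame(series@powers, series@intensities), path,
                     append = TRUE, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname writeSaturation
#' @export
readSaturation <- function(path) {
  x <- .readHeaded(path)
  SaturationSeries(x$data[[1]], x$data[[2]])
}

#' Read and write melting curves as delimited text
#'
#' Two-column text (temp_C, signal); the detection wavelength may be carried
#' as `wavelength_nm=` metadata.
#'
#' @param curve a [MeltCurve-class].
#' @param path file path.
#' @param wavelength optional detection wavelength (nm) recorded in the
#'   header.
#' @return `readMelt` returns a [MeltCurve-class]; `writeMelt` returns
#'   `path` invisibly.
#' @export
writeMelt <- function(curve, path, wavelength = NULL) {
  stopifnot(is(curve, "MeltCurve"))
  meta <- if (is.null(wavelength)) ""
          else sprintf(" wavelength_nm=%.10g", wavelength)
  writeLines(paste0("# temp_C signal", meta), path)
  utils::write.table(data.frame(curve@temperature, curve@signal), path,
                     append = TRUE, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname writeMelt
#' @export
readMelt <- function(path) {
  x <- .readHeaded(path)
  MeltCurve(x$data[[1]], x$data[[2]])
}
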