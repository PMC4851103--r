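# Reading multichannel recordings (CSV, EDF) and writing event annotations.
#
# CSV dialect: optional "# fs=<Hz>" comment line, then a header row of channel
# labels, then one row per sample (samples as rows, channels as columns).
# All sample indexing inside the package is 0-based; interval numbering shown
# to users is 1-based.

#' Read a multichannel recording
#'
#' @param path file to read.
#' @param format `"csv"` or `"edf"`; default guesses from the file extension.
#' @param fs sampling rate in Hz; required for CSV files without a
#'   `# fs=<Hz>` header line, ignored for EDF (taken from the header).
#' @param tStart time of the first sample in seconds.
#' @return A [MultichannelSignal-class]; channel order as in the file.
#' @seealso [writeSignal()] for the CSV dialect written by this package.
#' @export
readSignal <- function(path, format = c("auto", "csv", "edf"), fs = NULL,
                       tStart = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read signal file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("edf", "bdf")) "edf" else "csv"
  }
  if (format == "edf") return(readEDF(path, tStart = tStart))

  first <- readLines(path, n = 1L)
  skip <- 0L
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("fs\\s*=\\s*([0-9.eE+-]+)", first))[[1L]]
    if (length(m) == 2L) fs <- as.numeric(m[2L])
    skip <- 1L
  }
  if (is.null(fs) || !is.finite(fs) || fs <= 0)
    stop("sampling rate not found in '", path,
         "': pass fs= or add a '# fs=<Hz>' header line")
  df <- utils::read.csv(path, skip = skip, check.names = FALSE,
                        comment.char = "")
  m <- t(as.matrix(df))
  if (!is.numeric(m)) stop("non-numeric samples in ", path)
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-finite sample in '%s': channel %s, sample %d",
                 path, rownames(m)[bad[1L, 1L]], bad[1L, 2L]))
  }
  MultichannelSignal(m, fs = fs, channelLabels = colnames(df), tStart = tStart)
}

#' Write a multichannel recording as CSV
#'
#' Writes the dialect read back by [readSignal()]: a `# fs=<Hz>` line, a
#' header of channel labels, then samples as rows. Full double precision is
#' kept, so a write/read round trip is lossless.
#'
#' @param signal a [MultichannelSignal-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSignal <- function(signal, path) {
  stopifnot(is(signal, "MultichannelSignal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%s", format(signal@fs, digits = 17)), con)
  df <- as.data.frame(t(signal@samples))
  names(df) <- signal@channelLabels
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- minimal EDF reader -----------------------------------------------------
# Only the signal matrix and sampling rate are used; EDF annotation channels
# are dropped (events are this package's *output*). All ordinary channels must
# share one sampling rate.

readEDFHeaderField <- function(con, nchars) {
  trimws(rawToChar(readBin(con, "raw", nchars)))
}

readEDF <- function(path, tStart = 0) {
  con <- file(path, "rb")
  on.exit(close(con))
  readEDFHeaderField(con, 8L)                      # version
  readEDFHeaderField(con, 80L)                     # patient id
  readEDFHeaderField(con, 80L)                     # recording id
  readEDFHeaderField(con, 8L)                      # start date
  readEDFHeaderField(con, 8L)                      # start time
  readEDFHeaderField(con, 8L)                      # header bytes
  readEDFHeaderField(con, 44L)                     # reserved
  nRec <- as.integer(readEDFHeaderField(con, 8L))
  recDur <- as.numeric(readEDFHeaderField(con, 8L))
  ns <- as.integer(readEDFHeaderField(con, 4L))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header in ", path)
  fld <- function(w) vapply(seq_len(ns), function(i) readEDFHeaderField(con, w), "")
  labels <- fld(16L)
  fld(80L)                                         # transducer
  fld(8L)                                          # physical dimension
  physMin <- as.numeric(fld(8L))
  physMax <- as.numeric(fld(8L))
  digMin <- as.numeric(fld(8L))
  digMax <- as.numeric(fld(8L))
  fld(80L)                                         # prefiltering
  nSamp <- as.integer(fld(8L))
  fld(32L)                                         # reserved
  if (nRec < 1L || recDur <= 0) stop("malformed EDF record layout in ", path)

  keep <- !grepl("^EDF Annotations", labels)
  if (!any(keep)) stop("no signal channels in ", path)
  if (length(unique(nSamp[keep])) != 1L)
    stop("EDF channels have differing sampling rates in ", path)
  nr <- nSamp[keep][1L]
  fs <- nr / recDur
  scale <- (physMax - physMin) / (digMax - digMin)

  out <- matrix(NA_real_, nrow = sum(keep), ncol = nRec * nr)
  rowOf <- cumsum(keep)
  for (rec in seq_len(nRec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nSamp[ch], size = 2L,
                     signed = TRUE, endian = "little")
      if (keep[ch]) {
        phys <- physMin[ch] + (dig - digMin[ch]) * scale[ch]
        out[rowOf[ch], ((rec - 1L) * nr + 1L):(rec * nr)] <- phys
      }
    }
  }
  MultichannelSignal(out, fs = fs, channelLabels = trimws(labels[keep]),
                     tStart = tStart)
}

# --- event annotations ------------------------------------------------------

#' Write detected events to CSV (plus a JSON run report)
#'
#' One row per event state: `label`, `start_sample`, `end_sample`, `start_s`,
#' `end_s`, `duration_s`, at full precision. When `scan` is supplied, a JSON
#' sidecar (same path with extension `.json`) records the run parameters
#' (optimal window size, slide, group count, CCC, minimum S_Dbw).
#'
#' @param events an [EventSequence-class].
#' @param path output CSV path.
#' @param scan optional [ScanResult-class] the events came from.
#' @return `path`, invisibly.
#' @export
writeEvents <- function(events, path, scan = NULL) {
  stopifnot(is(events, "EventSequence"))
  st <- events@states
  df <- data.frame(label = st$label,
                   start_sample = st$startSample,
                   end_sample = st$endSample,
                   start_s = st$tE,
                   end_s = st$endSec,
                   duration_s = st$dE)
  con <- file(path, "w")
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  close(con)
  if (!is.null(scan)) {
    stopifnot(is(scan, "ScanResult"))
    report <- list(Lw = scan@LwH, d = scan@d, No = scan@NoH,
                   CCC = scan@CCCH, MIn = scan@MInH, fs = scan@fs,
                   prefixLength = scan@prefixLength,
                   baselineLabel = events@baselineLabel,
                   M = events@M,
                   grid = scan@grid)
    jsonlite::write_json(report, sidecarPath(path), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

sidecarPath <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Read back an events CSV written by [writeEvents()]
#'
#' @param path CSV file path.
#' @return data.frame with the columns written by [writeEvents()].
#' @export
readEvents <- function(path) {
  if (!file.exists(path)) stop("cannot read events file: ", path)
  utils::read.csv(path)
}
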