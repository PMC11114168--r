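#' Read an EEG recording from disk
#'
#' Two interchange formats are supported: EDF (European Data Format, the
#' widespread EEG standard; 16-bit samples with per-signal physical scaling)
#' and a plain CSV dialect (channels as columns with a header row of labels,
#' a leading `# rate=<Hz>` comment line, '.' decimal, UTF-8). In both formats
#' annotations travel in a CSV sidecar named `<path>_annotations.csv` with
#' columns `label,onset,duration`.
#'
#' @param path File to read.
#' @param format `"edf"` or `"csv"`; guessed from the extension by default.
#' @return An [eeg_recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (!file.exists(path)) stop("file does not exist: ", path)
  rec <- switch(format,
    edf = .read_edf(path),
    csv = .read_csv_recording(path))
  ann_path <- .annotation_sidecar(path)
  if (file.exists(ann_path)) {
    ann <- utils::read.csv(ann_path, stringsAsFactors = FALSE)
    rec <- eeg_recording(rec$data, rec$rate, rec$channel_labels, ann)
  }
  rec
}

#' Write an EEG recording to disk
#'
#' @param recording An [eeg_recording()].
#' @param path Destination file.
#' @param format `"edf"` or `"csv"`; guessed from the extension by default.
#'   CSV round-trips sample values exactly; EDF quantizes to 16 bits over the
#'   per-channel physical range.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, format = c("auto", "edf", "csv")) {
  stopifnot(inherits(recording, "eeg_recording"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  switch(format,
    edf = .write_edf(recording, path),
    csv = .write_csv_recording(recording, path))
  ann <- recording$annotations
  utils::write.csv(ann, .annotation_sidecar(path), row.names = FALSE)
  invisible(path)
}

.annotation_sidecar <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_annotations.csv")
}

## ---- CSV dialect -----------------------------------------------------------

.write_csv_recording <- function(recording, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# rate=%.10g", recording$rate), con)
  writeLines(paste(recording$channel_labels, collapse = ","), con)
  # samples as rows, full double precision so the round trip is exact
  txt <- apply(recording$data, 2, function(col)
    paste(formatC(col, digits = 17, format = "g"), collapse = ","))
  writeLines(txt, con)
}

.read_csv_recording <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^# *rate=", first))
    stop("CSV recording parse error: missing '# rate=' header line")
  rate <- as.numeric(sub("^# *rate=", "", first))
  if (!is.finite(rate) || rate <= 0)
    stop("CSV recording parse error: invalid rate field")
  body <- utils::read.csv(path, skip = 1L, header = TRUE,
                          check.names = FALSE, colClasses = "numeric")
  if (any(is.na(as.matrix(body))))
    stop("CSV recording parse error: non-numeric or ragged sample rows")
  eeg_recording(t(as.matrix(body)), rate, colnames(body))
}

## ---- EDF -------------------------------------------------------------------
## Minimal EDF writer/reader: one data record spanning the whole recording,
## 16-bit little-endian samples, physical scaling from the header's
## per-signal physical/digital ranges. Annotations use the CSV sidecar.

.write_edf <- function(recording, path) {
  data <- recording$data
  ns <- nrow(data)
  n_samp <- ncol(data)
  dur <- n_samp / recording$rate
  pmin <- apply(data, 1, min)
  pmax <- apply(data, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  # Header stores ranges as <=8-char ASCII; quantize against the *stored*
  # values so writer and reader agree exactly.
  num8 <- function(v) {
    for (d in 7:1) {
      s <- formatC(v, digits = d, format = "g")
      if (nchar(s) <= 8) return(s)
    }
    stop("cannot format physical range into 8 bytes: ", v)
  }
  pmin <- pmin - base::pmax(abs(pmin) * 1e-5, 1e-5)  # widen: data in range
  pmax <- pmax + base::pmax(abs(pmax) * 1e-5, 1e-5)
  pmin_s <- vapply(pmin, num8, "")
  pmax_s <- vapply(pmax, num8, "")
  pmin <- as.numeric(pmin_s); pmax <- as.numeric(pmax_s)
  bad <- pmin > apply(data, 1, min) | pmax < apply(data, 1, max)
  if (any(bad)) {  # rounding shrank the range: widen once more decade-wise
    pmin[bad] <- pmin[bad] - abs(pmin[bad]) * 1e-3 - 1e-3
    pmax[bad] <- pmax[bad] + abs(pmax[bad]) * 1e-3 + 1e-3
    pmin_s[bad] <- vapply(pmin[bad], num8, "")
    pmax_s[bad] <- vapply(pmax[bad], num8, "")
    pmin <- as.numeric(pmin_s); pmax <- as.numeric(pmax_s)
  }

  header_bytes <- 256L + 256L * ns
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(.pad_field(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)                          # version
  wr("X X X X", 80)                   # patient id (anonymous)
  wr("Startdate X X X X", 80)         # recording id
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(header_bytes, 8)
  wr("", 44)
  wr(1L, 8)                           # one data record
  wr(formatC(dur, digits = 7, format = "g"), 8)
  wr(ns, 4)
  for (lab in recording$channel_labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)   # transducer
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(pmin_s[i], 8)
  for (i in seq_len(ns)) wr(pmax_s[i], 8)
  for (i in seq_len(ns)) wr(-32768L, 8)
  for (i in seq_len(ns)) wr(32767L, 8)
  for (i in seq_len(ns)) wr("", 80)   # prefiltering
  for (i in seq_len(ns)) wr(n_samp, 8)
  for (i in seq_len(ns)) wr("", 32)
  scale <- (pmax - pmin) / 65535
  for (i in seq_len(ns)) {
    dig <- as.integer(round((data[i, ] - pmin[i]) / scale[i]) - 32768L)
    dig[dig > 32767L] <- 32767L
    dig[dig < -32768L] <- -32768L
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}

.read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    raw <- readBin(con, "raw", n = width)
    if (length(raw) < width) stop("EDF parse error: truncated header")
    trimws(rawToChar(raw))
  }
  num <- function(width, field) {
    v <- suppressWarnings(as.numeric(rd(width)))
    if (!is.finite(v)) stop("EDF parse error: invalid field '", field, "'")
    v
  }
  version <- rd(8)
  if (version != "0") stop("EDF parse error: invalid field 'version'")
  rd(80); rd(80); rd(8); rd(8)
  num(8, "header bytes"); rd(44)
  n_rec <- num(8, "number of data records")
  rec_dur <- num(8, "record duration")
  ns <- as.integer(num(4, "number of signals"))
  if (ns < 1) stop("EDF parse error: invalid field 'number of signals'")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- vapply(seq_len(ns), function(i) num(8, "physical minimum"), 0)
  pmax <- vapply(seq_len(ns), function(i) num(8, "physical maximum"), 0)
  dmin <- vapply(seq_len(ns), function(i) num(8, "digital minimum"), 0)
  dmax <- vapply(seq_len(ns), function(i) num(8, "digital maximum"), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) num(8, "samples per record"), 0)
  for (i in seq_len(ns)) rd(32)
  if (any(pmax <= pmin)) stop("EDF parse error: invalid field 'physical range'")
  if (any(dmax <= dmin)) stop("EDF parse error: invalid field 'digital range'")
  data <- matrix(0, nrow = ns, ncol = spr[1] * n_rec)
  if (length(unique(spr)) != 1L)
    stop("EDF parse error: heterogeneous samples-per-record not supported")
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr[i]) stop("EDF parse error: truncated data record")
      phys <- pmin[i] + (dig - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
      data[i, (r - 1) * spr[i] + seq_len(spr[i])] <- phys
    }
  }
  rate <- spr[1] / rec_dur
  eeg_recording(data, rate, labels)
}
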