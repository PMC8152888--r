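#' Write a WAV file
#'
#' Minimal RIFF/WAVE writer supporting 16-bit PCM and 32-bit IEEE float,
#' mono or multichannel (samples interleaved across channels).
#'
#' @param samples numeric vector (mono) or channels x samples matrix.
#' @param rate sampling rate in samples/s.
#' @param path output path.
#' @param bits 16 (PCM) or 32 (float).
#' @return invisibly, `path`.
#' @export
write_wav <- function(samples, rate, path, bits = 16L) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  stopifnot(bits %in% c(16L, 32L))
  n_ch <- nrow(samples)
  n <- ncol(samples)
  interleaved <- as.numeric(samples) # column-major = frame-interleaved
  block_align <- n_ch * bits / 8L
  data_bytes <- n * block_align
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(as.integer(if (bits == 16L) 1L else 3L), con, size = 2L,
           endian = "little") # 1 = PCM, 3 = IEEE float
  writeBin(as.integer(n_ch), con, size = 2L, endian = "little")
  writeBin(as.integer(rate), con, size = 4L, endian = "little")
  writeBin(as.integer(rate * block_align), con, size = 4L,
           endian = "little")
  writeBin(as.integer(block_align), con, size = 2L, endian = "little")
  writeBin(as.integer(bits), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4L, endian = "little")
  if (bits == 16L) {
    scaled <- pmax(pmin(interleaved, 1), -1)
    writeBin(as.integer(round(scaled * 32767)), con, size = 2L,
             endian = "little")
  } else {
    writeBin(interleaved, con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file
#'
#' Reads 16-bit PCM or 32-bit float RIFF/WAVE files written by
#' [write_wav()] or other tools.
#'
#' @param path input path.
#' @return list with `data` (channels x samples matrix, 16-bit data scaled
#'   to \eqn{[-1, 1]}), `rate` and `bits`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4L) != "RIFF") stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4L, endian = "little"))
  if (readChar(con, 4L) != "WAVE") stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4L)
    if (length(id) == 0L || nchar(id) < 4L)
      stop("malformed WAV (no data chunk): ", path)
    size <- readBin(con, integer(), size = 4L, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        format = readBin(con, integer(), size = 2L, endian = "little"),
        n_ch = readBin(con, integer(), size = 2L, endian = "little"),
        rate = readBin(con, integer(), size = 4L, endian = "little"),
        byte_rate = readBin(con, integer(), size = 4L, endian = "little"),
        block_align = readBin(con, integer(), size = 2L,
                              endian = "little"),
        bits = readBin(con, integer(), size = 2L, endian = "little"))
      if (size > 16L) invisible(readBin(con, raw(), size - 16L))
    } else if (id == "data") {
      if (is.null(fmt)) stop("malformed WAV (data before fmt): ", path)
      n_vals <- size / (fmt$bits / 8L)
      vals <- if (fmt$bits == 16L)
        readBin(con, integer(), n_vals, size = 2L, signed = TRUE,
                endian = "little") / 32767
      else
        readBin(con, numeric(), n_vals, size = 4L, endian = "little")
      data <- matrix(vals, nrow = fmt$n_ch)
      return(list(data = data, rate = fmt$rate, bits = fmt$bits))
    } else {
      invisible(readBin(con, raw(), size))
    }
  }
}

#' Write a multichannel signal as columnar text
#'
#' Tab-separated text with a time column followed by one column per
#' channel.
#'
#' @param x channels x samples matrix (or vector).
#' @param rate sampling rate in samples/s.
#' @param path output path.
#' @param labels channel labels.
#' @return invisibly, `path`.
#' @export
write_columnar <- function(x, rate, path, labels = NULL) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(x)))
  df <- data.frame(time = (seq_len(ncol(x)) - 1L) / rate, t(x))
  names(df) <- c("time", labels)
  utils::write.table(format(df, digits = 10, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read columnar-text signals
#'
#' @param path input path (as written by [write_columnar()]).
#' @return list with `data` (channels x samples), `rate` (inferred from
#'   the time column) and `labels`.
#' @export
read_columnar <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (!"time" %in% names(df) || ncol(df) < 2L)
    stop("malformed columnar file (need time + channel columns): ", path)
  dt <- diff(df$time)
  if (any(dt <= 0)) stop("time column is not strictly increasing: ", path)
  rate <- 1 / stats::median(dt)
  list(data = t(as.matrix(df[, -1L, drop = FALSE])),
       rate = round(rate, 6), labels = names(df)[-1L])
}

# fixed-width ascii field for EDF headers
edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  formatC(s, width = -width)
}

#' Write a minimal EDF file
#'
#' European Data Format writer with one data record holding the whole
#' recording (record duration = total duration). Samples are scaled to
#' 16-bit integers over the physical range of each channel.
#'
#' @param x channels x samples matrix (or vector).
#' @param rate sampling rate in samples/s.
#' @param path output path.
#' @param labels channel labels.
#' @return invisibly, `path`.
#' @export
write_edf <- function(x, rate, path, labels = NULL) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  ns <- nrow(x)
  n <- ncol(x)
  if (is.null(labels)) labels <- paste0("ch", seq_len(ns))
  dur <- n / rate
  phys_min <- apply(x, 1L, min)
  phys_max <- apply(x, 1L, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8L), edf_field("synthetic", 80L),
    edf_field("synthetic", 80L),
    edf_field("01.01.00", 8L), edf_field("00.00.00", 8L),
    edf_field(256L + ns * 256L, 8L), edf_field("", 44L),
    edf_field(1L, 8L), edf_field(format(dur, nsmall = 0), 8L),
    edf_field(ns, 4L))
  writeChar(hdr, con, eos = NULL)
  wf <- function(vals, width)
    writeChar(paste0(vapply(vals, edf_field, "", width = width),
                     collapse = ""), con, eos = NULL)
  wf(labels, 16L)
  wf(rep("", ns), 80L)                      # transducer
  wf(rep("uV", ns), 8L)                     # physical dimension
  wf(signif(phys_min, 7), 8L)
  wf(signif(phys_max, 7), 8L)
  wf(rep(-32768L, ns), 8L)
  wf(rep(32767L, ns), 8L)
  wf(rep("", ns), 80L)                      # prefiltering
  wf(rep(n, ns), 8L)                        # samples per record
  wf(rep("", ns), 32L)                      # reserved
  for (ch in seq_len(ns)) {
    pmin_ <- as.numeric(edf_field(signif(phys_min[ch], 7), 8L))
    pmax_ <- as.numeric(edf_field(signif(phys_max[ch], 7), 8L))
    dig <- round((x[ch, ] - pmin_) / (pmax_ - pmin_) * 65535 - 32768)
    writeBin(as.integer(pmax(pmin(dig, 32767), -32768)), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read a minimal EDF file
#'
#' Reads continuous EDF recordings (as written by [write_edf()] or other
#' tools using equal-length records without annotations).
#'
#' @param path input path.
#' @return list with `data` (channels x samples, in physical units),
#'   `rate` and `labels`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256L, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256L)
    stop("malformed EDF header: ", path)
  n_records <- as.integer(substr(hdr, 237L, 244L))
  rec_dur <- as.numeric(substr(hdr, 245L, 252L))
  ns <- as.integer(substr(hdr, 253L, 256L))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header: ", path)
  rd <- function(width) {
    block <- readChar(con, ns * width, useBytes = TRUE)
    vapply(seq_len(ns), function(i)
      trimws(substr(block, (i - 1L) * width + 1L, i * width)), "")
  }
  labels <- rd(16L); rd(80L); rd(8L)
  phys_min <- as.numeric(rd(8L)); phys_max <- as.numeric(rd(8L))
  dig_min <- as.numeric(rd(8L)); dig_max <- as.numeric(rd(8L))
  rd(80L)
  spr <- as.integer(rd(8L)); rd(32L)
  data <- vector("list", ns)
  for (ch in seq_len(ns)) data[[ch]] <- numeric(0)
  for (r in seq_len(n_records)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- phys_min[ch] + (dig - dig_min[ch]) /
        (dig_max[ch] - dig_min[ch]) * (phys_max[ch] - phys_min[ch])
      data[[ch]] <- c(data[[ch]], phys)
    }
  }
  rate <- spr[1L] / rec_dur
  list(data = do.call(rbind, data), rate = rate, labels = labels)
}

#' Read a recording in any supported format
#'
#' Dispatches on `format` (or the file extension for `"auto"`): EDF,
#' columnar text, or WAV. Tapping-sensor WAV input must be single-channel;
#' pass `expect_mono = TRUE` to enforce this.
#'
#' @param path input path.
#' @param format `"auto"`, `"edf"`, `"columnar"` or `"wav"`.
#' @param expect_mono error if the recording has more than one channel.
#' @return list with `data` (channels x samples), `rate` and `labels`.
#' @export
read_signals <- function(path, format = c("auto", "edf", "columnar",
                                          "wav"),
                         expect_mono = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", wav = "wav", "columnar")
  }
  rec <- switch(format,
    edf = read_edf(path),
    wav = {
      w <- read_wav(path)
      list(data = w$data, rate = w$rate,
           labels = paste0("ch", seq_len(nrow(w$data))))
    },
    columnar = read_columnar(path))
  if (expect_mono && nrow(rec$data) != 1L)
    stop("expected a single-channel recording, got ", nrow(rec$data),
         " channels: ", path)
  rec
}

#' Read a trial manifest
#'
#' Tab-separated manifest pairing trials with directions, stimulus seeds,
#' file paths and onset times. Checks that trial ids are unique per
#' participant.
#'
#' @param path manifest TSV path.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("participant", "trial", "direction")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols) > 0L)
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "))
  dup <- duplicated(m[, c("participant", "trial")])
  if (any(dup))
    stop("duplicated trial id(s) within participant: ",
         paste(unique(m$trial[dup]), collapse = ", "))
  m
}
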