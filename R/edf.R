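#' Read a European Data Format (EDF) file
#'
#' Minimal reader for standard continuous EDF: ASCII header, per-signal
#' header block, then data records of 16-bit little-endian integers, mapped
#' to physical units by each signal's physical/digital calibration range.
#' Signals whose sampling rates differ from the first selected signal are
#' rejected rather than resampled.
#'
#' @param path Path to an `.edf` file.
#' @param channels Optional character vector of channel labels to keep.
#' @return List with `samples` (time x channel matrix in physical units),
#'   `fs`, `channels`, and `header` (selected header fields).
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- rd_str(8)
  patient <- rd_str(80)
  recording <- rd_str(80)
  startdate <- rd_str(8); starttime <- rd_str(8)
  header_bytes <- as.integer(rd_str(8))
  rd_str(44)                                   # reserved
  n_records <- as.integer(rd_str(8))
  record_dur <- as.numeric(rd_str(8))
  ns <- as.integer(rd_str(4))
  if (is.na(ns) || ns < 1) stop("unreadable EDF header: ", path, call. = FALSE)
  field <- function(width) vapply(seq_len(ns), function(i) rd_str(width),
                                  character(1))
  labels <- field(16)
  field(80)                                    # transducer
  phys_dim <- field(8)
  phys_min <- as.numeric(field(8)); phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8)); dig_max <- as.numeric(field(8))
  field(80)                                    # prefiltering
  spr <- as.integer(field(8))                  # samples per record
  field(32)                                    # reserved
  keep <- if (is.null(channels)) seq_len(ns) else match(channels, labels)
  if (anyNA(keep)) {
    stop("channel label(s) not in EDF: ",
         paste(channels[is.na(keep)], collapse = ", "), call. = FALSE)
  }
  if (length(unique(spr[keep])) != 1) {
    stop("selected channels have differing sampling rates", call. = FALSE)
  }
  raw_rec <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    rec <- lapply(seq_len(ns), function(i) {
      readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
              endian = "little")
    })
    raw_rec[[r]] <- rec
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  samples <- vapply(keep, function(i) {
    dig <- unlist(lapply(raw_rec, `[[`, i), use.names = FALSE)
    (dig - dig_min[i]) * gain[i] + phys_min[i]
  }, numeric(n_records * spr[keep[1]]))
  colnames(samples) <- labels[keep]
  list(samples = samples, fs = spr[keep[1]] / record_dur,
       channels = labels[keep],
       header = list(version = version, patient = patient,
                     recording = recording, startdate = startdate,
                     starttime = starttime, header_bytes = header_bytes,
                     n_records = n_records, record_duration = record_dur,
                     physical_dim = phys_dim[keep]))
}

#' Write an EDF file
#'
#' Minimal standard-EDF writer (1 s data records, 16-bit quantization over
#' each channel's observed amplitude range).  Used to produce synthetic
#' fixtures and to round-trip the reader; `duration_s x fs` must be an
#' integer multiple of `fs`.
#'
#' @param samples Time x channel numeric matrix.
#' @param fs Sampling rate in Hz (integer samples per 1 s record).
#' @param path Output path.
#' @param channels Channel labels (default from column names).
#' @param physical_dim Physical dimension string (default `"uV"`).
#' @return Invisibly, `path`.
#' @export
write_edf <- function(samples, fs, path, channels = NULL,
                      physical_dim = "uV") {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  if (is.null(channels)) channels <- colnames(samples) %||%
      paste0("ch", seq_len(ncol(samples)))
  fs <- as.integer(fs)
  n <- nrow(samples); ns <- ncol(samples)
  n_records <- n %/% fs
  if (n_records * fs != n) {
    stop("sample count must be a whole number of 1 s records", call. = FALSE)
  }
  phys_max <- apply(abs(samples), 2, max)
  phys_max[phys_max == 0] <- 1
  # Serialize the range into <= 8 ASCII chars, then reuse the parsed value
  # so writer gain and reader gain agree exactly.
  fmt8 <- function(x) {      # <= 7 chars so the negated value also fits in 8
    s <- sprintf("%.5g", x)
    if (nchar(s) > 7) s <- sprintf("%.1e", x * 1.05)
    s
  }
  phys_max_str <- vapply(phys_max * 1.001, fmt8, character(1))  # headroom so
  phys_max <- as.numeric(phys_max_str)                # rounding cannot clip
  phys_min <- -phys_max
  phys_min_str <- paste0("-", phys_max_str)
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, width) {
    x <- substr(as.character(x), 1, width)
    writeChar(formatC(x, width = -width), con, nchars = width, eos = NULL)
  }
  pad("0", 8); pad("X synthetic", 80); pad("Startdate X strokeeg", 80)
  pad("01.01.26", 8); pad("00.00.00", 8)
  pad(256 * (1 + ns), 8); pad("", 44)
  pad(n_records, 8); pad(1, 8); pad(ns, 4)
  for (lab in channels) pad(lab, 16)
  for (i in seq_len(ns)) pad("synthetic", 80)
  for (i in seq_len(ns)) pad(physical_dim, 8)
  for (i in seq_len(ns)) pad(phys_min_str[i], 8)
  for (i in seq_len(ns)) pad(phys_max_str[i], 8)
  for (i in seq_len(ns)) pad(dig_min, 8)
  for (i in seq_len(ns)) pad(dig_max, 8)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad(fs, 8)
  for (i in seq_len(ns)) pad("", 32)
  gain <- (dig_max - dig_min) / (phys_max - phys_min)
  dig <- vapply(seq_len(ns), function(i) {
    as.integer(round((samples[, i] - phys_min[i]) * gain[i] + dig_min))
  }, integer(n))
  dig <- matrix(dig, nrow = n)
  for (r in seq_len(n_records)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      writeBin(dig[idx, i], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
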