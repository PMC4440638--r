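# Minimal RIFF/WAVE I/O (PCM 16-bit and IEEE float32), enough to read
# and write the 2-channel 8 kHz recordings this package works with.

#' Read a WAV file
#'
#' Supports uncompressed PCM 8/16/24/32-bit and IEEE float32 WAV files
#' with any number of channels. Samples are returned as doubles in
#' [-1, 1].
#'
#' @param path path to a .wav file.
#' @return for 2-channel files, a [binaural_epoch()]; otherwise a list
#'   with `samples` (channels x n matrix) and `sampling_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file", call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file", call. = FALSE)
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        channels     = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        sample_rate  = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(raw[15:16], "integer", 1, 2, endian = "little"))
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + size %% 2)
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("malformed WAV file", call. = FALSE)
  x <- decode_wav_samples(data, fmt)
  s <- matrix(x, nrow = fmt$channels)
  if (fmt$channels == 2)
    binaural_epoch(s[1, ], s[2, ], fmt$sample_rate)
  else
    list(samples = s, sampling_rate = fmt$sample_rate)
}

decode_wav_samples <- function(data, fmt) {
  if (fmt$audio_format == 3 && fmt$bits == 32) {
    readBin(data, "numeric", length(data) / 4, 4, endian = "little")
  } else if (fmt$audio_format == 1 && fmt$bits == 16) {
    readBin(data, "integer", length(data) / 2, 2, signed = TRUE,
            endian = "little") / 32768
  } else if (fmt$audio_format == 1 && fmt$bits == 8) {
    (readBin(data, "integer", length(data), 1, signed = FALSE) - 128) / 128
  } else if (fmt$audio_format == 1 && fmt$bits %in% c(24, 32)) {
    b <- fmt$bits / 8
    n <- length(data) / b
    m <- matrix(as.integer(data), nrow = b)
    v <- colSums(m * 256^(0:(b - 1)))
    hi <- 256^b
    v[v >= hi / 2] <- v[v >= hi / 2] - hi
    v / (hi / 2)
  } else stop("unsupported WAV encoding", call. = FALSE)
}

#' Write a WAV file
#'
#' Writes a [binaural_epoch()] (or a channels-by-samples matrix) as an
#' uncompressed stereo/mono WAV file.
#'
#' @param x a `binaural_epoch` or numeric matrix (channels in rows).
#' @param path output path.
#' @param sampling_rate sampling rate in Hz (taken from `x` if a
#'   `binaural_epoch`).
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, sampling_rate = NULL, bits = 16) {
  if (inherits(x, "binaural_epoch")) {
    sampling_rate <- x$sampling_rate
    x <- rbind(x$left, x$right)
  }
  x <- as.matrix(x)
  stopifnot(!is.null(sampling_rate), bits %in% c(16, 32))
  ch <- nrow(x)
  inter <- as.numeric(x)                        # column-major = interleaved
  bytes_per <- bits / 8
  data_size <- length(inter) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(as.integer(if (bits == 32) 3 else 1), con, 2, endian = "little")
  writeBin(as.integer(ch), con, 2, endian = "little")
  writeBin(as.integer(sampling_rate), con, 4, endian = "little")
  writeBin(as.integer(sampling_rate * ch * bytes_per), con, 4,
           endian = "little")
  writeBin(as.integer(ch * bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16) {
    v <- pmin(pmax(round(inter * 32767), -32768), 32767)
    writeBin(as.integer(v), con, 2, endian = "little")
  } else {
    writeBin(inter, con, 4, endian = "little")
  }
  invisible(path)
}

#' Write sector labels as a sidecar CSV
#'
#' Companion to [write_wav()] for labelled epoch sets: one row per epoch
#' with columns `epoch_index`, `azimuth_deg`, `sector`.
#'
#' @param epoch_set an `epoch_set` from [circling_recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sector_csv <- function(epoch_set, path) {
  df <- data.frame(epoch_index = seq_along(epoch_set$epochs),
                   azimuth_deg = epoch_set$azimuth,
                   sector = epoch_set$sector)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
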