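#' Write a waveform as 16-bit PCM WAV
#'
#' Minimal mono RIFF/WAVE writer (16-bit little-endian PCM). Values are
#' clipped to [-1, 1] before quantization.
#'
#' @param waveform numeric vector in [-1, 1].
#' @param sample_rate sampling rate in Hz.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_wav <- function(waveform, sample_rate, path) {
  x <- pmin(pmax(waveform, -1), 1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' Counterpart to [write_wav()]; handles mono 16-bit PCM only.
#'
#' @param path file path.
#' @return list with `waveform` (numeric in [-1, 1]) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file: ", path)
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    sz <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("only mono PCM supported")
      sample_rate <- readBin(con, integer(), 1, size = 4, endian = "little")
      invisible(readBin(con, "raw", sz - 8))
    } else if (id == "data") {
      pcm <- readBin(con, integer(), sz / 2, size = 2, endian = "little",
                     signed = TRUE)
      return(list(waveform = pcm / 32767, sample_rate = sample_rate))
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
}

#' Write an interval (alignment) track as TSV
#'
#' Columns: start_s, stop_s, phone, word, excerpt_id.
#'
#' @param intervals data frame of intervals.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  utils::write.table(intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an interval track written by [write_intervals()]
#' @param path TSV path.
#' @return data frame of intervals.
#' @export
read_intervals <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
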