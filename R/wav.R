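#' Write a waveform as a 16-bit PCM mono WAV file
#'
#' Minimal RIFF/WAVE writer for the ultrasonic fixtures generated by
#' [gen_audio()]. Samples are clipped to \[-1, 1\] and scaled to 16-bit.
#'
#' @param wave Numeric waveform in \[-1, 1\] (values outside are clipped).
#' @param path Output file path.
#' @param sample_rate Sampling rate in Hz (default: the waveform's
#'   `sample_rate` attribute).
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, sample_rate = attr(wave, "sample_rate")) {
  if (is.null(sample_rate)) stop("`sample_rate` is required")
  pcm <- as.integer(round(pmax(pmin(as.numeric(wave), 1), -1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' Counterpart of [write_wav()]; only uncompressed 16-bit mono files are
#' supported.
#'
#' @param path WAV file path.
#' @return Numeric waveform in \[-1, 1\] with attribute `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    len <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L)
        stop("only PCM mono WAV is supported")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      bits <- readBin(con, integer(), n = 2, size = 2, endian = "little")[2]
      if (bits != 16L) stop("only 16-bit WAV is supported")
      if (len > 16) invisible(readBin(con, raw(), n = len - 16L))
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = len / 2, size = 2,
                     endian = "little", signed = TRUE)
      x <- pcm / 32767
      attr(x, "sample_rate") <- sample_rate
      return(x)
    } else {
      invisible(readBin(con, raw(), n = len))
    }
  }
}
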