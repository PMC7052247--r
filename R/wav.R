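#' Minimal mono PCM WAV input/output
#'
#' Reads and writes 16-bit PCM mono RIFF/WAVE files, the interchange format
#' for the utterance recordings. Samples are normalised floats in
#' `[-1, 1]`.
#'
#' @param path File path.
#' @param samples Numeric vector in `[-1, 1]` (values are clipped).
#' @param sample_rate Samples per second.
#' @return `read_wav()` returns `list(samples, sample_rate)`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  sample_rate <- NULL
  bits <- NULL
  channels <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      if (fmt[1] != 1L) stop("only PCM WAV is supported")
      channels <- fmt[2]
      sample_rate <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))  # byte rate
      invisible(readBin(con, "integer", 1, 2, endian = "little"))  # block align
      bits <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("data chunk before fmt chunk in ", path)
      if (bits != 16L) stop("only 16-bit PCM is supported")
      n <- size %/% 2L
      raw <- readBin(con, "integer", n, 2, endian = "little", signed = TRUE)
      if (channels > 1L) raw <- raw[seq(1, length(raw), by = channels)]
      return(list(samples = raw / 32767, sample_rate = sample_rate))
    } else {
      invisible(readBin(con, "raw", size + (size %% 2L)))
    }
  }
}

#' @rdname read_wav
#' @export
write_wav <- function(samples, sample_rate, path) {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate > 0)
  pcm <- as.integer(round(pmax(pmin(samples, 1), -1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # PCM
  writeBin(1L, con, size = 2, endian = "little")                 # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")                 # block align
  writeBin(16L, con, size = 2, endian = "little")                # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
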