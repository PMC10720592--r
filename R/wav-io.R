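# Minimal RIFF/WAV I/O for 16-bit PCM, the interchange format for scenes.

#' Write a waveform as a 16-bit PCM WAV file
#'
#' @param x Numeric vector (mono) or matrix with one column per channel,
#'   values in \[-1, 1\]; values outside are clipped.
#' @param path Output file path.
#' @param sample_rate Sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".wav")
#' write_wav(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 22050)), f)
#' w <- read_wav(f)
#' w$sample_rate
write_wav <- function(x, path, sample_rate = 22050L) {
  x <- as.matrix(x)
  n_ch <- ncol(x)
  x <- pmin(pmax(x, -1), 1)
  pcm <- as.integer(round(t(x) * 32767))  # interleaved
  data_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2L, endian = "little")           # PCM
  writeBin(as.integer(n_ch), con, size = 2L, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sample_rate * n_ch * 2L), con, size = 4L, endian = "little")
  writeBin(as.integer(n_ch * 2L), con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' Only uncompressed 16-bit PCM is supported, matching what [write_wav()]
#' produces and what the study's stimulus format prescribes.
#'
#' @param path File path.
#' @return List with `samples` (numeric matrix, one column per channel,
#'   values in \[-1, 1\]) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4L) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (readChar(con, 4L) != "WAVE") stop("not a WAVE file: ", path)
  sample_rate <- NULL; n_ch <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4L)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2L, size = 2L, endian = "little")
      if (fmt[1L] != 1L) stop("only PCM WAV supported")
      n_ch <- fmt[2L]
      sample_rate <- readBin(con, "integer", 1L, size = 4L, endian = "little")
      readBin(con, "integer", 1L, size = 4L, endian = "little")
      readBin(con, "integer", 1L, size = 2L, endian = "little")
      bits <- readBin(con, "integer", 1L, size = 2L, endian = "little")
      if (bits != 16L) stop("only 16-bit PCM supported")
      if (sz > 16L) readBin(con, "raw", sz - 16L)
    } else if (id == "data") {
      pcm <- readBin(con, "integer", sz %/% 2L, size = 2L,
                     signed = TRUE, endian = "little")
      samples <- matrix(pcm / 32767, ncol = n_ch, byrow = TRUE)
      break
    } else {
      readBin(con, "raw", sz)
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  list(samples = samples, sample_rate = sample_rate)
}
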