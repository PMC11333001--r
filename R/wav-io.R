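#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for 16-bit PCM mono files, the interchange format
#' used for synthetic syllables. Samples are returned rescaled to `[-1, 1]`.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric vector in `[-1, 1]`) and `rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  rate <- NULL
  bits <- NULL
  channels <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV supported")
      channels <- fmt[2]
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      extra <- size - 16L
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("malformed WAV: data chunk before fmt")
      if (bits != 16L) stop("only 16-bit PCM supported")
      n <- size %/% 2L
      samples <- readBin(con, "integer", n, size = 2, signed = TRUE,
                         endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
  }
  if (is.null(samples)) stop("malformed WAV: no data chunk")
  if (channels != 1L) stop("only mono WAV supported")
  list(samples = samples / 32768, rate = rate)
}

#' Write a mono PCM WAV file
#'
#' @param samples Numeric vector in `[-1, 1]`; values are clipped then
#'   quantised to 16-bit PCM.
#' @param rate Sample rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path) {
  stopifnot(is.numeric(samples), length(samples) > 0, rate > 0)
  x <- pmax(-1, pmin(1, samples))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
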