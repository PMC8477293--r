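#' Minimal PCM WAV I/O
#'
#' Reader and writer for 16-bit little-endian PCM mono WAV files, the format
#' used for the sustained-phonation recordings. Only the canonical
#' RIFF/fmt/data layout is supported; samples are exchanged as numeric
#' vectors in `[-1, 1]`.
#'
#' @param samples numeric vector in `[-1, 1]`; values outside are clipped
#' @param fs sampling rate in Hz
#' @param path output file path
#' @return `write_wav()` returns `path` invisibly; `read_wav()` returns a
#'   list with elements `samples` (numeric in `[-1, 1]`) and `fs`.
#' @export
write_wav <- function(samples, fs, path) {
  if (!is.numeric(samples) || length(samples) == 0)
    stop_bad_arg("samples must be a non-empty numeric vector")
  x <- pmin(pmax(samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")         # PCM
  writeBin(1L, con, size = 2, endian = "little")         # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")         # block align
  writeBin(16L, con, size = 2, endian = "little")        # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop_bad_arg("not a RIFF file: %s", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop_bad_arg("not a WAVE file: %s", path)
  fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop_bad_arg("no data chunk in %s", path)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L)
        stop_bad_arg("only PCM mono WAV supported: %s", path)
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      ba <- readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (bits != 16L) stop_bad_arg("only 16-bit WAV supported: %s", path)
      if (size > 16) invisible(readBin(con, "raw", size - 16L))
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", size %/% 2L, size = 2, endian = "little")
      if (is.null(fs)) stop_bad_arg("data chunk precedes fmt in %s", path)
      return(list(samples = pcm / 32767, fs = fs))
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
}
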