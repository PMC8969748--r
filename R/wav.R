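# Minimal mono RIFF/WAVE I/O (PCM 16/24-bit and IEEE float32). No audio
# package exists in the supported environment, so the container is read and
# written directly. Calibration is never stored in the WAV itself: it lives in
# a sidecar JSON next to the file (<path>.cal.json).

.wav_sidecar <- function(path) paste0(path, ".cal.json")

#' Write a waveform to a WAV file with a calibration sidecar
#'
#' @param x a [waveform()].
#' @param path output path; a sidecar `<path>.cal.json` holding the
#'   calibration convention is written next to it.
#' @param format `"pcm16"`, `"pcm24"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, format = c("pcm16", "pcm24", "float32")) {
  stopifnot(inherits(x, "waveform"))
  format <- match.arg(format)
  fs <- as.integer(x$sample_rate_hz)
  n <- length(x$samples)
  bits <- switch(format, pcm16 = 16L, pcm24 = 24L, float32 = 32L)
  fmt_code <- if (format == "float32") 3L else 1L
  block <- bits %/% 8L
  data_bytes <- n * block

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little") # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * block), con, size = 4, endian = "little")
  writeBin(as.integer(block), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")

  s <- pmin(pmax(x$samples, -1), 1)
  if (format == "pcm16") {
    writeBin(as.integer(round(s * 32767)), con, size = 2, endian = "little")
  } else if (format == "pcm24") {
    v <- as.integer(round(s * 8388607))
    v[v < 0] <- v[v < 0] + 16777216L
    bytes <- rbind(v %% 256L, (v %/% 256L) %% 256L, (v %/% 65536L) %% 256L)
    writeBin(as.raw(bytes), con)
  } else {
    writeBin(s, con, size = 4, endian = "little")
  }

  jsonlite::write_json(
    list(calibration_db_spl_at_fullscale = x$calibration_db_spl_at_fullscale),
    .wav_sidecar(path), auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a mono WAV file written with the package conventions
#'
#' Calibration is taken from the `<path>.cal.json` sidecar if present,
#' otherwise from the `calibration_db_spl_at_fullscale` argument.
#'
#' @param path WAV path (mono; PCM 16/24-bit or IEEE float32).
#' @param calibration_db_spl_at_fullscale fallback calibration when no sidecar
#'   exists.
#' @return A [waveform()].
#' @export
read_wav <- function(path, calibration_db_spl_at_fullscale = 100) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)

  fmt_code <- NULL
  fs <- NULL
  bits <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, integer(), size = 2, endian = "little")
      n_chan <- readBin(con, integer(), size = 2, endian = "little")
      if (n_chan != 1L) stop("only mono WAV files are supported")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16) readBin(con, raw(), n = sz - 16)
    } else if (id == "data") {
      if (is.null(fmt_code)) stop("malformed WAV: data chunk before fmt")
      if (fmt_code == 3L && bits == 32L) {
        samples <- readBin(con, numeric(), n = sz %/% 4, size = 4,
                           endian = "little")
      } else if (fmt_code == 1L && bits == 16L) {
        samples <- readBin(con, integer(), n = sz %/% 2, size = 2,
                           endian = "little") / 32767
      } else if (fmt_code == 1L && bits == 24L) {
        b <- as.integer(readBin(con, raw(), n = sz))
        m <- matrix(b, nrow = 3)
        v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
        v[v >= 8388608] <- v[v >= 8388608] - 16777216
        samples <- v / 8388607
      } else {
        stop("unsupported WAV format (code ", fmt_code, ", ", bits, " bit)")
      }
      if (sz %% 2 == 1) readBin(con, raw(), n = 1)
    } else {
      readBin(con, raw(), n = sz + sz %% 2)
    }
    if (!is.null(samples) && !is.null(fs)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)

  cal <- calibration_db_spl_at_fullscale
  side <- .wav_sidecar(path)
  if (file.exists(side)) {
    cal <- jsonlite::read_json(side)$calibration_db_spl_at_fullscale
  }
  waveform(pmin(pmax(samples, -1), 1), fs, cal)
}
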