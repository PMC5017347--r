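# Minimal RIFF/WAVE reader and writer (float32 and 16-bit PCM).
# Baseband I/Q and microphone audio travel as WAV files: stereo float
# (channel 1 = I, channel 2 = Q) for the radar, mono for the microphone.

#' Write samples to a WAV file
#'
#' @param samples Numeric vector (mono) or matrix with one column per
#'   channel, values in baseband units (float) or \[-1, 1\] (pcm16).
#' @param sampling_rate Sampling rate in Hz.
#' @param path Output file path.
#' @param format `"float32"` (IEEE float, default) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sampling_rate, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  check_finite(samples, "samples")
  n_ch <- ncol(samples)
  n_frames <- nrow(samples)
  interleaved <- as.vector(t(samples))
  bytes_per <- if (format == "float32") 4L else 2L
  data_bytes <- n_frames * n_ch * bytes_per
  fmt_code <- if (format == "float32") 3L else 1L

  con <- tryCatch(file(path, "wb"), error = function(e) {
    abort(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  })
  on.exit(close(con))
  w_str <- function(s) writeChar(s, con, eos = NULL)
  w_u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")

  # fact chunk is required for non-PCM formats
  fact_bytes <- if (fmt_code == 3L) 12L else 0L
  w_str("RIFF"); w_u32(4 + 24 + fact_bytes + 8 + data_bytes); w_str("WAVE")
  w_str("fmt "); w_u32(16)
  w_u16(fmt_code); w_u16(n_ch); w_u32(round(sampling_rate))
  w_u32(round(sampling_rate) * n_ch * bytes_per)  # byte rate
  w_u16(n_ch * bytes_per)                         # block align
  w_u16(8L * bytes_per)                           # bits per sample
  if (fmt_code == 3L) { w_str("fact"); w_u32(4); w_u32(n_frames) }
  w_str("data"); w_u32(data_bytes)
  if (format == "float32") {
    writeBin(interleaved, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(pmax(pmin(interleaved, 1), -1) * 32767)),
             con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file
#'
#' Supports IEEE-float (32-bit) and integer PCM (16-bit) encodings.
#'
#' @param path WAV file path.
#' @return List with `samples` (frames x channels matrix, float scale) and
#'   `sampling_rate` (Hz).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) abort(sprintf("WAV file not found: '%s'", path))
  con <- file(path, "rb")
  on.exit(close(con))
  r_str <- function(n) readChar(con, n, useBytes = TRUE)
  r_u32 <- function() readBin(con, "integer", size = 4, endian = "little")
  r_u16 <- function() readBin(con, "integer", size = 2, endian = "little", signed = FALSE)

  if (r_str(4) != "RIFF") abort(sprintf("'%s' is not a RIFF file", path))
  r_u32()
  if (r_str(4) != "WAVE") abort(sprintf("'%s' is not a WAVE file", path))

  fmt <- NULL; dat <- NULL
  repeat {
    id <- r_str(4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- r_u32()
    if (id == "fmt ") {
      fmt <- list(code = r_u16(), n_ch = r_u16(), fs = r_u32(),
                  byte_rate = r_u32(), block = r_u16(), bits = r_u16())
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (id == "data") {
      if (is.null(fmt)) abort("malformed WAV: data chunk before fmt")
      bytes_per <- fmt$bits / 8
      n_vals <- sz %/% bytes_per
      if (fmt$code == 3 && fmt$bits == 32) {
        dat <- readBin(con, "numeric", n = n_vals, size = 4, endian = "little")
      } else if (fmt$code == 1 && fmt$bits == 16) {
        dat <- readBin(con, "integer", n = n_vals, size = 2, endian = "little") / 32767
      } else {
        abort(sprintf("unsupported WAV encoding (format %d, %d-bit)", fmt$code, fmt$bits))
      }
      break
    } else {
      readBin(con, "raw", sz + sz %% 2)  # chunks are word-aligned
    }
  }
  if (is.null(dat)) abort(sprintf("no data chunk found in '%s'", path))
  list(samples = matrix(dat, ncol = fmt$n_ch, byrow = TRUE), sampling_rate = fmt$fs)
}

#' Read a stereo WAV as a quadrature recording
#'
#' Channel 1 is the in-phase (I) baseband, channel 2 the quadrature (Q).
#'
#' @param path Stereo WAV path.
#' @return A `quadrature_recording` tibble (`time_s`, `i`, `q`).
#' @export
read_quadrature_wav <- function(path) {
  w <- read_wav(path)
  if (ncol(w$samples) != 2) {
    abort(sprintf("expected a stereo I/Q WAV, got %d channel(s): '%s'",
                  ncol(w$samples), path))
  }
  n <- nrow(w$samples)
  new_signal_tbl(
    tibble::tibble(time_s = (seq_len(n) - 1) / w$sampling_rate,
                   i = w$samples[, 1], q = w$samples[, 2]),
    w$sampling_rate, "quadrature_recording"
  )
}
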