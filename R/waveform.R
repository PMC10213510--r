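#' Apply a frame schedule to a sampled waveform
#'
#' Each consecutive frame of the input (of the schedule's original duration)
#' is resampled by linear interpolation onto a uniform grid of its scheduled
#' new duration, and the frames are concatenated. Samples beyond the warped
#' region (the sub-frame remainder and anything after the region) are passed
#' through unchanged, so total duration is conserved to within one sample.
#'
#' @param samples Numeric vector of audio samples (mono).
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param schedule A [build_frame_schedule()] result.
#' @return Numeric vector of warped samples.
#' @export
warp_waveform <- function(samples, sample_rate, schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(samples) == 0) stop("empty input waveform")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be positive")
  n <- schedule$n_frames
  frame_ms <- schedule$original_frame_ms
  sr_ms <- sample_rate / 1000
  in_bounds <- round(c(0, seq_len(n) * frame_ms) * sr_ms)
  if (length(samples) < in_bounds[n + 1])
    stop("waveform shorter than the scheduled warp region")
  out_bounds <- round(c(0, cumsum(schedule$new_durations_ms)) * sr_ms)
  out <- vector("list", n + 1L)
  for (i in seq_len(n)) {
    frame <- samples[(in_bounds[i] + 1):in_bounds[i + 1]]
    m <- out_bounds[i + 1] - out_bounds[i]
    out[[i]] <- resample_linear(frame, m)
  }
  # trailing unwarped samples: sub-frame remainder plus anything after
  if (in_bounds[n + 1] < length(samples))
    out[[n + 1L]] <- samples[(in_bounds[n + 1] + 1):length(samples)]
  unlist(out, use.names = FALSE)
}

# linear interpolation of a frame onto m uniformly spaced samples;
# exact passthrough when m equals the frame length
resample_linear <- function(frame, m) {
  k <- length(frame)
  if (m <= 0) return(numeric(0))
  if (k == m) return(frame)
  if (k == 1L) return(rep(frame, m))
  stats::approx(x = seq(0, 1, length.out = k), y = frame,
                xout = seq(0, 1, length.out = m))$y
}

#' Read / write mono WAV files
#'
#' Minimal RIFF/WAVE I/O for mono PCM 16-bit and IEEE float32 files, the two
#' encodings used for experiment stimuli. Samples are represented in R as
#' doubles in `[-1, 1]`.
#'
#' @param path File path.
#' @param samples Numeric vector in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz.
#' @param format `"pcm16"` or `"float32"`.
#' @return `read_wav()` returns a list with `samples` and `sample_rate`;
#'   `write_wav()` returns `path` invisibly.
#' @export
write_wav <- function(samples, path, sample_rate, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  bytes_per <- if (format == "pcm16") 2L else 4L
  data_size <- n * bytes_per
  fmt_tag <- if (format == "pcm16") 1L else 3L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_tag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")             # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")      # block align
  writeBin(8L * bytes_per, con, size = 2, endian = "little") # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "pcm16") {
    x <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
    writeBin(x, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file: ", path)
  fmt_tag <- NA_integer_; sr <- NA_integer_; bits <- NA_integer_
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_tag <- readBin(con, "integer", 1, size = 2, endian = "little")
      channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (channels != 1L) stop("only mono WAV is supported")
      sr <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")  # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little")  # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (id == "data") {
      if (fmt_tag == 1L && bits == 16L) {
        x <- readBin(con, "integer", size %/% 2, size = 2, signed = TRUE,
                     endian = "little") / 32767
      } else if (fmt_tag == 3L && bits == 32L) {
        x <- readBin(con, "numeric", size %/% 4, size = 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (format tag ", fmt_tag,
             ", ", bits, " bits)")
      }
      return(list(samples = x, sample_rate = sr))
    } else {
      readBin(con, "raw", size + size %% 2)
    }
  }
}

#' Read an Audacity-style label track
#'
#' Plain-text annotation sidecar: one region per line,
#' `start_s<TAB>end_s<TAB>label`, as exported by Audacity. Used to identify
#' the warped region of a recorded sentence.
#'
#' @param path Label file path.
#' @return A data.frame with columns `start_s`, `end_s`, `label`.
#' @export
read_labels <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("start_s", "end_s", "label"),
                         colClasses = c("numeric", "numeric", "character"))
  if (any(d$end_s < d$start_s)) stop("label with end before start in ", path)
  d
}

#' Synthesize a word-like noise burst
#'
#' Amplitude-modulated Gaussian noise with a raised-cosine onset/offset ramp,
#' used as a stand-in for recorded words when rendering synthetic trials. The
#' observer model consumes timing only, so phonetic content is irrelevant;
#' bursts carry a slow (4 Hz) syllabic amplitude modulation to keep the
#' stimulus speech-envelope-like.
#'
#' @param dur_ms Burst duration in ms.
#' @param sample_rate Sampling rate in Hz.
#' @param ramp_ms Raised-cosine ramp duration (each side), ms.
#' @param am_hz Syllabic amplitude-modulation rate, Hz.
#' @return Numeric vector of samples in `[-1, 1]`.
#' @export
am_noise_word <- function(dur_ms, sample_rate, ramp_ms = 10, am_hz = 4) {
  n <- round(dur_ms * sample_rate / 1000)
  if (n <= 0) return(numeric(0))
  t <- seq_len(n) / sample_rate
  env <- 0.6 + 0.4 * sin(2 * pi * am_hz * t)^2
  nr <- min(round(ramp_ms * sample_rate / 1000), n %/% 2)
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    env[seq_len(nr)] <- env[seq_len(nr)] * ramp
    env[(n - nr + 1):n] <- env[(n - nr + 1):n] * rev(ramp)
  }
  x <- stats::rnorm(n) * env
  0.95 * x / max(abs(x))
}
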