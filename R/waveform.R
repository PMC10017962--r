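#' Waveform objects
#'
#' A waveform is a mono audio signal: a numeric vector of samples in
#' `[-1, 1]` together with a sampling rate in Hz. All extraction functions
#' in the package operate on waveforms; [read_wav()] and [write_wav()]
#' convert to and from 16-bit PCM WAV files.
#'
#' @param samples Numeric vector of amplitudes. Must be finite.
#' @param rate Sampling rate in Hz (positive scalar).
#' @return An object of class `waveform` with fields `samples` and `rate`.
#' @examples
#' w <- waveform(sin(2 * pi * 220 * seq(0, 1, by = 1 / 16000)), 16000)
#' wave_duration(w)
#' @export
waveform <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("waveform must contain at least one sample")
  if (!all(is.finite(samples))) stop("waveform samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a positive scalar (Hz)")
  }
  structure(list(samples = samples, rate = rate), class = "waveform")
}

#' @rdname waveform
#' @param w A `waveform`.
#' @export
wave_duration <- function(w) length(w$samples) / w$rate

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf(
    "<waveform: %d samples @ %g Hz (%.3f s), peak %.3f>\n",
    length(x$samples), x$rate, wave_duration(x), max(abs(x$samples))
  ))
  invisible(x)
}

#' Read and write mono 16-bit PCM WAV files
#'
#' Minimal RIFF/WAVE codec for the PCM subset the pipeline produces and
#' consumes (mono, 16-bit, linear PCM). Multi-channel files are mixed down
#' by averaging.
#'
#' @param path File path.
#' @return `read_wav()` returns a [waveform()]; `write_wav()` returns `path`
#'   invisibly.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  rate <- NULL; n_channels <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", size / 2, 2, endian = "little", signed = FALSE)
      if (fmt[1] != 1L) stop("only linear PCM WAV is supported")
      n_channels <- fmt[2]
      rate <- fmt[3] + fmt[4] * 65536
      bits <- fmt[8]
      if (bits != 16L) stop("only 16-bit PCM WAV is supported")
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", size / 2, 2, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
  }
  if (is.null(rate) || is.null(samples)) stop("malformed WAV file: ", path)
  x <- samples / 32768
  if (n_channels > 1L) {
    x <- colMeans(matrix(x, nrow = n_channels))
  }
  waveform(x, rate)
}

#' @rdname read_wav
#' @param w A [waveform()] to write. Samples are clipped to `[-1, 1]`.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  pcm <- as.integer(round(pmax(-1, pmin(1, w$samples)) * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, 4, endian = "little")
  writeBin(as.integer(c(1, 1)), con, 2, endian = "little")        # PCM, mono
  writeBin(as.integer(w$rate), con, 4, endian = "little")
  writeBin(as.integer(w$rate * 2), con, 4, endian = "little")     # byte rate
  writeBin(as.integer(c(2, 16)), con, 2, endian = "little")       # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

#' Resample a waveform
#'
#' Band-limited rational-ratio resampling (polyphase FIR, via the signal
#' package). Duration is preserved to within one sample period.
#'
#' @param w A [waveform()].
#' @param rate Target sampling rate in Hz. Default 16000, the rate the
#'   contour and segmentation algorithms expect.
#' @return A [waveform()] at `rate`.
#' @export
resample_wave <- function(w, rate = 16000) {
  stopifnot(inherits(w, "waveform"))
  if (rate <= 0) stop("target rate must be positive")
  if (w$rate == rate) return(w)
  frac <- gcd_int(round(rate), round(w$rate))
  p <- round(rate) / frac
  q <- round(w$rate) / frac
  y <- signal::resample(w$samples, p, q)
  n_target <- round(length(w$samples) * rate / w$rate)
  if (length(y) > n_target) y <- y[seq_len(n_target)]
  if (length(y) < n_target) y <- c(y, numeric(n_target - length(y)))
  waveform(y, rate)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Normalize integrated loudness
#'
#' Scales a recording so that its integrated loudness proxy — the
#' energy-weighted mean level (dB) over active frames — hits a target level.
#' Active frames are those above a floor relative to the loudest frame, so
#' long silences do not drag the estimate down. This is a simplified
#' integrated-loudness procedure (no K-weighting or two-stage gating); it is
#' used only upstream of intensity biomarkers, which as standard deviations
#' of a dB contour are invariant to the overall level shift anyway.
#'
#' @param w A [waveform()].
#' @param target Target integrated level in dBFS. Default -23.
#' @param frame,hop Frame and hop lengths in seconds.
#' @return A rescaled [waveform()].
#' @export
normalize_loudness <- function(w, target = -23, frame = 0.4, hop = 0.1) {
  stopifnot(inherits(w, "waveform"))
  current <- integrated_loudness(w, frame, hop)
  if (!is.finite(current)) stop("cannot normalize an all-zero signal")
  waveform(w$samples * 10^((target - current) / 20), w$rate)
}

#' @rdname normalize_loudness
#' @export
integrated_loudness <- function(w, frame = 0.4, hop = 0.1) {
  p <- frame_power(w$samples, w$rate, frame, hop)
  if (all(p == 0)) return(-Inf)
  lev <- 10 * log10(p + 1e-12)
  active <- lev > max(lev) - 40      # absolute-silence gate
  10 * log10(mean(p[active]))
}

# mean squared amplitude per frame
frame_power <- function(x, rate, frame, hop) {
  flen <- max(1L, round(frame * rate))
  hlen <- max(1L, round(hop * rate))
  starts <- seq(1L, max(1L, length(x) - flen + 1L), by = hlen)
  vapply(starts, function(s) mean(x[s:min(s + flen - 1L, length(x))]^2), numeric(1))
}

#' Concatenate task repetitions speaker-wise
#'
#' Short text-dependent utterances are analyzed as one recording per speaker:
#' each repetition is trimmed of leading and trailing silence (using the same
#' energy criterion as [detect_speech_pauses()]) and the trimmed signals are
#' concatenated in order.
#'
#' @param recordings List of [waveform()]s sharing one sampling rate.
#' @param margin Seconds of audio retained on each side of the first/last
#'   detected speech sample. Default 0.05.
#' @return A single [waveform()].
#' @export
concatenate_tdu <- function(recordings, margin = 0.05) {
  if (length(recordings) == 0L) stop("no recordings to concatenate")
  rates <- vapply(recordings, function(w) w$rate, numeric(1))
  if (length(unique(rates)) != 1L) {
    stop("all recordings must share one sampling rate; got ", toString(unique(rates)))
  }
  trimmed <- lapply(recordings, trim_edge_silence, margin = margin)
  waveform(unlist(lapply(trimmed, `[[`, "samples")), rates[1])
}

trim_edge_silence <- function(w, margin = 0.05) {
  seg <- detect_speech_pauses(w)
  sp <- seg[seg$label == "speech", , drop = FALSE]
  if (nrow(sp) == 0L) return(w)   # nothing detected: keep as-is
  lo <- max(1L, floor((min(sp$start) - margin) * w$rate) + 1L)
  hi <- min(length(w$samples), ceiling((max(sp$end) + margin) * w$rate))
  waveform(w$samples[lo:hi], w$rate)
}
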