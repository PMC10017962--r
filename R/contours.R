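#' Frame a signal into an analysis matrix
#'
#' @param x Numeric sample vector.
#' @param flen,hlen Frame and hop lengths in samples.
#' @return Matrix with one column per frame.
#' @keywords internal
frame_matrix <- function(x, flen, hlen) {
  n_frames <- max(0L, 1L + floor((length(x) - flen) / hlen))
  if (n_frames < 1L) return(matrix(numeric(0), nrow = flen, ncol = 0))
  idx <- outer(seq_len(flen), (seq_len(n_frames) - 1L) * hlen, `+`)
  matrix(x[idx], nrow = flen)
}

new_contour <- function(time, value, voiced, frame_step, unit) {
  out <- tibble::tibble(time = time, value = value, voiced = voiced)
  attr(out, "frame_step") <- frame_step
  attr(out, "unit") <- unit
  class(out) <- c("contour", class(out))
  out
}

#' Fundamental frequency contour
#'
#' Autocorrelation pitch tracking: 40 ms Hann-windowed frames every 10 ms;
#' the highest normalized autocorrelation peak in the candidate lag range is
#' refined by parabolic interpolation. A frame is voiced when that peak is at
#' least `voicing_threshold` and the frame level is above the recording's
#' silence floor. Octave jumps are suppressed with a running median of
#' width 5 over voiced frames.
#'
#' @param w A [waveform()].
#' @param floor,ceiling Pitch search range in Hz (default 60-400).
#' @param frame,hop Frame and hop durations in seconds.
#' @param voicing_threshold Minimum normalized autocorrelation peak.
#' @return A contour tibble with columns `time` (frame center, s), `value`
#'   (F0 in Hz, `NA` when unvoiced) and `voiced`.
#' @export
f0_contour <- function(w, floor = 60, ceiling = 400, frame = 0.04, hop = 0.01,
                       voicing_threshold = 0.45) {
  stopifnot(inherits(w, "waveform"))
  if (floor >= ceiling) stop("pitch floor must be below ceiling")
  fs <- w$rate
  flen <- round(frame * fs)
  hlen <- round(hop * fs)
  if (length(w$samples) < 2L * flen) stop("waveform too short for pitch analysis")
  fm <- frame_matrix(w$samples, flen, hlen)
  fm <- sweep(fm, 2, colMeans(fm))          # remove DC per frame
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(flen) / (flen + 1))
  fmw <- fm * win
  lag_min <- max(2L, floor(fs / ceiling))
  lag_max <- min(flen - 1L, ceiling(fs / floor))
  # autocorrelation of every frame in one FFT pass
  nfft <- stats::nextn(flen + lag_max + 1L, 2)
  spec <- stats::mvfft(rbind(fmw, matrix(0, nfft - flen, ncol(fmw))))
  ac <- Re(stats::mvfft(spec * Conj(spec), inverse = TRUE)) / nfft
  r0 <- ac[1L, ]
  r0[r0 <= 0] <- Inf                        # silent frame: never voiced
  nac <- sweep(ac[(lag_min + 1L):(lag_max + 1L), , drop = FALSE], 2, r0, "/")
  peak_rel <- apply(nac, 2, which.max)
  peak_val <- nac[cbind(peak_rel, seq_along(peak_rel))]
  # parabolic interpolation around the integer-lag peak
  lag <- vapply(seq_along(peak_rel), function(j) {
    i <- peak_rel[j]
    if (i <= 1L || i >= nrow(nac)) return(lag_min + i - 1)
    y1 <- nac[i - 1L, j]; y2 <- nac[i, j]; y3 <- nac[i + 1L, j]
    denom <- y1 - 2 * y2 + y3
    d <- if (abs(denom) < 1e-12) 0 else 0.5 * (y1 - y3) / denom
    lag_min + i - 1 + max(-0.5, min(0.5, d))
  }, numeric(1))
  level <- 10 * log10(colMeans(fm^2) + 1e-12)
  energetic <- level > max(level) - 35
  voiced <- is.finite(peak_val) & peak_val >= voicing_threshold & energetic
  f0 <- ifelse(voiced, fs / lag, NA_real_)
  if (sum(voiced) >= 3L) {
    f0[voiced] <- stats::runmed(f0[voiced], k = min(5L, 2L * (sum(voiced) %/% 2L) - 1L))
  }
  f0[voiced & (f0 < floor | f0 > ceiling)] <- NA_real_
  voiced <- voiced & !is.na(f0)
  time <- (seq_len(ncol(fm)) - 1L) * hop + frame / 2
  new_contour(time, f0, voiced, hop, "Hz")
}

#' Intensity contour
#'
#' Per-frame level in dB (`10 log10` of the mean squared amplitude relative
#' to full scale), 40 ms frames every 10 ms. Frames more than `silence_range`
#' dB below the loudest frame are masked as inactive so that silence does not
#' enter contour statistics.
#'
#' @inheritParams f0_contour
#' @param silence_range dB below the maximum frame level at which frames are
#'   masked. Default 40.
#' @return A contour tibble (`value` in dB, `voiced` marking active frames).
#' @export
intensity_contour <- function(w, frame = 0.04, hop = 0.01, silence_range = 40) {
  stopifnot(inherits(w, "waveform"))
  fs <- w$rate
  flen <- round(frame * fs)
  hlen <- round(hop * fs)
  if (length(w$samples) < 2L * flen) stop("waveform too short for intensity analysis")
  fm <- frame_matrix(w$samples, flen, hlen)
  level <- 10 * log10(colMeans(fm^2) + 1e-12)
  active <- level > max(level) - silence_range
  time <- (seq_len(ncol(fm)) - 1L) * hop + frame / 2
  new_contour(time, ifelse(active, level, NA_real_), active, hop, "dB")
}

#' First-formant contour
#'
#' Linear-prediction estimate of the first vocal-tract resonance on voiced
#' frames: pre-emphasized, Hamming-windowed 40 ms frames; autocorrelation-
#' method LPC; F1 is the lowest complex root of the prediction polynomial
#' whose frequency lies in `[200, 1200]` Hz with bandwidth under 700 Hz.
#'
#' @param w A [waveform()].
#' @param f0mask A contour from [f0_contour()] on the same waveform; frames
#'   unvoiced there are skipped.
#' @param order LPC order. Default 12 (adequate for 16 kHz audio).
#' @param range Admissible F1 range in Hz.
#' @return A contour tibble (`value` in Hz). If no voiced frames exist the
#'   contour is empty and carries attribute `flag = "no-voiced-frames"`.
#' @export
f1_contour <- function(w, f0mask, order = 12, range = c(200, 1200)) {
  stopifnot(inherits(w, "waveform"))
  fs <- w$rate
  hop <- attr(f0mask, "frame_step")
  frame <- 0.04
  flen <- round(frame * fs)
  hlen <- round(hop * fs)
  if (!any(f0mask$voiced)) {
    out <- new_contour(numeric(0), numeric(0), logical(0), hop, "Hz")
    attr(out, "flag") <- "no-voiced-frames"
    return(out)
  }
  x <- w$samples - c(0, 0.97 * w$samples[-length(w$samples)])  # pre-emphasis
  fm <- frame_matrix(x, flen, hlen)
  n_frames <- min(ncol(fm), nrow(f0mask))
  win <- 0.54 - 0.46 * cos(2 * pi * (seq_len(flen) - 1) / (flen - 1))
  f1 <- rep(NA_real_, n_frames)
  for (j in which(f0mask$voiced[seq_len(n_frames)])) {
    s <- fm[, j] * win
    r <- as.numeric(stats::acf(s, lag.max = order, plot = FALSE,
                               demean = FALSE, type = "covariance")$acf)
    if (r[1] <= 0) next
    a <- tryCatch(solve(stats::toeplitz(r[seq_len(order)]), r[2:(order + 1L)]),
                  error = function(e) NULL)
    if (is.null(a)) next
    rts <- polyroot(c(1, -a))
    ang <- Arg(rts)
    keep <- ang > 0
    freq <- ang[keep] * fs / (2 * pi)
    bw <- -log(pmin(Mod(rts[keep]), 0.9999)) * fs / pi
    cand <- freq[freq >= range[1] & freq <= range[2] & bw < 700]
    if (length(cand)) f1[j] <- min(cand)
  }
  voiced <- !is.na(f1)
  new_contour(f0mask$time[seq_len(n_frames)], f1, voiced, hop, "Hz")
}
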