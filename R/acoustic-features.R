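#' Standard deviation of a contour
#'
#' Sample standard deviation (denominator n-1) of a contour's values over
#' valid (voiced/active) frames — the statistic behind the pitch-, formant-
#' and loudness-variability biomarkers.
#'
#' @param c A contour tibble (see [f0_contour()]).
#' @return A single numeric value in the contour's units, or `NA` (with a
#'   `reason` attribute) when fewer than two valid frames exist.
#' @export
contour_std <- function(c) {
  v <- c$value[c$voiced & !is.na(c$value)]
  if (length(v) < 2L) {
    out <- NA_real_
    attr(out, "reason") <- "fewer than 2 valid frames"
    return(out)
  }
  stats::sd(v)
}

#' Pause and speech-time biomarkers
#'
#' Computes the six segmentation-based biomarkers from a speech/pause
#' segmentation:
#' \describe{
#'   \item{SPTIME}{net speech time, s}
#'   \item{SILTIME}{total pause time, s}
#'   \item{SILPERC}{pause time as a percentage of total duration}
#'   \item{SILSPRAT}{pause-to-speech time ratio}
#'   \item{SILDUR}{mean pause duration, s (0 when no pauses)}
#'   \item{SILVAR}{median absolute deviation of pause durations, s
#'     (0 when fewer than 2 pauses)}
#' }
#' SILPERC and SILSPRAT are strictly increasing functions of one another at
#' fixed total duration, so every rank-based statistic downstream is
#' identical for the two.
#'
#' @param seg A segmentation tibble from [detect_speech_pauses()].
#' @return A one-row tibble with the six values and a `flag` column noting
#'   degenerate inputs (no pauses / single pause).
#' @export
pause_features <- function(seg) {
  sp <- seg$end[seg$label == "speech"] - seg$start[seg$label == "speech"]
  pa <- seg$end[seg$label == "pause"] - seg$start[seg$label == "pause"]
  if (length(sp) == 0L) {
    return(tibble::tibble(
      SPTIME = NA_real_, SILTIME = NA_real_, SILPERC = NA_real_,
      SILSPRAT = NA_real_, SILDUR = NA_real_, SILVAR = NA_real_,
      flag = "no-speech-detected"
    ))
  }
  sptime <- sum(sp)
  siltime <- sum(pa)
  flag <- if (length(pa) == 0L) "no-pauses" else if (length(pa) == 1L) "single-pause" else NA_character_
  tibble::tibble(
    SPTIME = sptime,
    SILTIME = siltime,
    SILPERC = 100 * siltime / (sptime + siltime),
    SILSPRAT = siltime / sptime,
    SILDUR = if (length(pa)) mean(pa) else 0,
    SILVAR = if (length(pa) >= 2L) stats::median(abs(pa - stats::median(pa))) else 0,
    flag = flag
  )
}

#' All acoustic biomarkers of one recording
#'
#' Runs the contour and segmentation primitives and assembles the ten
#' acoustic biomarkers: F0STD, F1STD, INTSTD (contour standard deviations)
#' plus the six pause biomarkers of [pause_features()].
#'
#' Loudness normalization is applied internally before the intensity
#' contour (the remaining biomarkers are invariant to the overall level).
#'
#' @param w A [waveform()] (resampled to 16 kHz internally if needed).
#' @param pitch_floor,pitch_ceiling Pitch search range, Hz.
#' @param min_pause,min_speech VAD smoothing parameters, s.
#' @return A long tibble with columns `biomarker`, `value`, `flag`.
#' @export
acoustic_features <- function(w, pitch_floor = 60, pitch_ceiling = 400,
                              min_pause = 0.15, min_speech = 0.10) {
  w <- resample_wave(w, 16000)
  f0 <- f0_contour(w, pitch_floor, pitch_ceiling)
  int <- intensity_contour(normalize_loudness(w))
  f1 <- f1_contour(w, f0)
  seg <- detect_speech_pauses(w, min_pause, min_speech)
  pf <- pause_features(seg)
  std_row <- function(name, contour) {
    v <- contour_std(contour)
    tibble::tibble(biomarker = name, value = as.numeric(v),
                   flag = attr(v, "reason") %||% NA_character_)
  }
  dplyr::bind_rows(
    std_row("F0STD", f0),
    std_row("F1STD", f1),
    std_row("INTSTD", int),
    tidyr::pivot_longer(pf, -"flag", names_to = "biomarker",
                        values_to = "value")[, c("biomarker", "value", "flag")]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
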