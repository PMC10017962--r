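#' Energy-based voice activity detection
#'
#' Segments a recording into alternating speech and pause intervals. Each
#' 30 ms frame (10 ms hop) is classified by its level in dB against an
#' adaptive threshold, `max(noise floor + 12 dB, 30th percentile of frame
#' levels)`, where the noise floor is the 5th percentile of frame levels,
#' capped at 25 dB below the loudest frame so a recording with no true
#' pauses (whose noise floor lies inside the speech itself) does not have
#' its quieter words misclassified as pause.
#' The frame decisions are then smoothed morphologically: pauses shorter
#' than `min_pause` are merged into the surrounding speech, after which
#' speech islands shorter than `min_speech` are merged into pause. The
#' resulting intervals tile `[0, duration]` exactly.
#'
#' @param w A [waveform()].
#' @param min_pause Minimum reportable pause duration in seconds (default 0.15).
#' @param min_speech Minimum speech-island duration in seconds (default 0.10).
#' @param frame,hop Analysis frame and hop in seconds.
#' @param margin_db dB above the noise floor for the adaptive threshold.
#' @return A `segmentation` tibble with columns `start`, `end` (seconds) and
#'   `label` (`"speech"`/`"pause"`), and attribute `total_duration`.
#' @export
detect_speech_pauses <- function(w, min_pause = 0.15, min_speech = 0.10,
                                 frame = 0.03, hop = 0.01, margin_db = 12) {
  stopifnot(inherits(w, "waveform"))
  duration <- wave_duration(w)
  if (duration <= min_pause) stop("recording shorter than min_pause")
  fs <- w$rate
  flen <- round(frame * fs)
  hlen <- round(hop * fs)
  fm <- frame_matrix(w$samples, flen, hlen)
  if (ncol(fm) == 0L) {
    return(new_segmentation(tibble::tibble(
      start = 0, end = duration, label = "pause"), duration))
  }
  level <- 10 * log10(colMeans(fm^2) + 1e-12)
  noise_floor <- stats::quantile(level, 0.05, names = FALSE)
  threshold <- max(noise_floor + margin_db,
                   stats::quantile(level, 0.30, names = FALSE))
  threshold <- min(threshold, max(level) - 25)
  speech <- level > threshold
  # frame i labels the span [(i-1) hop, i hop); smooth by duration
  speech <- smooth_runs(speech, TRUE,  min_len = ceiling(min_pause / hop))
  speech <- smooth_runs(speech, FALSE, min_len = ceiling(min_speech / hop))
  r <- rle(speech)
  ends <- cumsum(r$lengths) * hop
  starts <- c(0, ends[-length(ends)])
  ends[length(ends)] <- duration
  seg <- tibble::tibble(
    start = starts, end = ends,
    label = ifelse(r$values, "speech", "pause")
  )
  seg <- seg[seg$end > seg$start, , drop = FALSE]
  new_segmentation(seg, duration)
}

# merge runs of !value shorter than min_len into value
smooth_runs <- function(x, value, min_len) {
  r <- rle(x)
  short <- r$values != value & r$lengths < min_len
  # never flip the record's edges into speech: only interior gaps are merged
  if (value) {
    short[c(1L, length(short))] <- FALSE
  }
  r$values[short] <- value
  inverse.rle(r)
}

new_segmentation <- function(df, total_duration) {
  # collapse adjacent intervals sharing a label
  if (nrow(df) > 1L) {
    keep <- c(TRUE, df$label[-1] != df$label[-nrow(df)])
    grp <- cumsum(keep)
    df <- dplyr::summarise(
      dplyr::group_by(df, grp = grp),
      start = min(.data$start), end = max(.data$end),
      label = .data$label[1], .groups = "drop"
    )[, c("start", "end", "label")]
  }
  df <- df[order(df$start), , drop = FALSE]
  attr(df, "total_duration") <- total_duration
  class(df) <- c("segmentation", class(df))
  df
}

#' Read/write a segmentation as TSV
#'
#' Three columns (`start`, `end`, `label`), seconds with three decimals.
#'
#' @param seg A segmentation tibble.
#' @param path File path.
#' @export
write_segmentation <- function(seg, path) {
  out <- data.frame(start = sprintf("%.3f", seg$start),
                    end = sprintf("%.3f", seg$end), label = seg$label)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segmentation
#' @export
read_segmentation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  new_segmentation(tibble::as_tibble(df), max(df$end))
}
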