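# shared helpers for the test suite

# a pure tone waveform
tone <- function(freq, duration, rate = 16000, amplitude = 0.3) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  waveform(sin(2 * pi * freq * t) * amplitude, rate)
}

# a pulse train carrying the first 8 harmonics of a (possibly time-varying) f0
harmonic_tone <- function(f0, duration, rate = 16000, amplitude = 0.5) {
  n <- round(duration * rate)
  f <- if (length(f0) == 1L) rep(f0, n) else stats::approx(
    seq(0, duration, length.out = length(f0)), f0,
    xout = (seq_len(n) - 1) / rate, rule = 2)$y
  ph <- 2 * pi * cumsum(f) / rate
  x <- rowSums(sapply(1:8, function(k) sin(k * ph) / k))
  waveform(x / max(abs(x)) * amplitude, rate)
}

# mean generative parameters as a plain named list
baseline_params <- function() {
  bp <- base_subject_params()
  as.list(stats::setNames(bp$mean, bp$param))
}

# a small hand-annotated transcript used by the linguistic tests:
# sentence 1: "the boy washes two red plates" (DET NOUN VERB NUM ADJ NOUN)
# sentence 2: "water overflows quickly" (NOUN VERB ADV)
# phrases: NP(1-2), NP(4-6), VP(3-3), NP(7-7), VP(8-8), PP(1-2)
toy_transcript <- function(with_times = TRUE) {
  tokens <- tibble::tibble(
    form = c("the", "boy", "washes", "two", "red", "plates",
             "water", "overflows", "quickly"),
    lemma = c("the", "boy", "wash", "two", "red", "plate",
              "water", "overflow", "quickly"),
    upos = c("DET", "NOUN", "VERB", "NUM", "ADJ", "NOUN",
             "NOUN", "VERB", "ADV"),
    is_function_word = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                         FALSE, FALSE, FALSE),
    sentence = c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L),
    start_time = if (with_times) seq(0.2, by = 0.4, length.out = 9) else NA_real_,
    end_time = if (with_times) seq(0.5, by = 0.4, length.out = 9) else NA_real_
  )
  phrases <- tibble::tibble(
    label = c("NP", "NP", "VP", "NP", "VP", "PP"),
    start_token = c(1L, 4L, 3L, 7L, 8L, 1L),
    end_token = c(2L, 6L, 3L, 7L, 8L, 2L)
  )
  transcript(tokens, phrases)
}

# segmentation tibble from alternating interval durations starting with speech
segmentation_from_durations <- function(speech, pauses) {
  labels <- character(0); durs <- numeric(0)
  for (i in seq_along(speech)) {
    labels <- c(labels, "speech"); durs <- c(durs, speech[i])
    if (i <= length(pauses)) { labels <- c(labels, "pause"); durs <- c(durs, pauses[i]) }
  }
  ends <- cumsum(durs)
  tibble::tibble(start = c(0, ends[-length(ends)]), end = ends, label = labels)
}

# independent exact permutation p-value oracle (two groups, convention
# P(H >= observed)), written from the Mann-Whitney side: H is a monotone
# function of |U - n1 n2 / 2| for untied two-group data
exact_kw_oracle <- function(values, groups) {
  g <- as.integer(factor(groups))
  n <- length(values); n1 <- sum(g == 1)
  r <- rank(values)
  stat_of <- function(idx) abs(sum(r[idx]) - n1 * (n + 1) / 2)
  observed <- stat_of(which(g == 1))
  combos <- utils::combn(n, n1)
  stats <- apply(combos, 2, stat_of)
  mean(stats >= observed - 1e-9)
}

# independent Benjamini-Hochberg step-up oracle: find the largest k with
# p_(k) <= k alpha / m; reject all hypotheses with p <= that threshold
bh_reject_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * alpha / m)
  rejected <- rep(FALSE, m)
  if (length(k)) rejected[p <= ps[max(k)]] <- TRUE
  rejected
}
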