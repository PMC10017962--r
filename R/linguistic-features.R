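#' Lexical biomarkers
#'
#' WORDCNT and WORDLEN are computed after removing function words (the
#' closed-class tokens flagged in the transcript); SENTCNT counts distinct
#' sentences and SENTLEN is the mean sentence length over all tokens
#' (function words included — sentence length is a measure of the whole
#' utterance, not of its content words).
#'
#' @param t A [transcript()].
#' @return A one-row tibble with `WORDCNT`, `WORDLEN`, `SENTCNT`, `SENTLEN`
#'   and a `flag` column.
#' @export
lexical_counts <- function(t) {
  stopifnot(inherits(t, "transcript"))
  tok <- t$tokens
  if (nrow(tok) == 0L) {
    return(tibble::tibble(WORDCNT = 0, WORDLEN = NA_real_, SENTCNT = 0,
                          SENTLEN = NA_real_, flag = "empty-transcript"))
  }
  content <- tok[!tok$is_function_word, , drop = FALSE]
  sentcnt <- length(unique(tok$sentence))
  tibble::tibble(
    WORDCNT = nrow(content),
    WORDLEN = if (nrow(content)) mean(nchar(content$form)) else NA_real_,
    SENTCNT = sentcnt,
    SENTLEN = nrow(tok) / sentcnt,
    flag = if (nrow(content) == 0L) "all-function-words" else NA_character_
  )
}

#' Part-of-speech biomarkers
#'
#' Raw token counts per universal POS class: NOUN, VERB, ADJ, ADV, NUM, AUX.
#' Counts (not rates) are deliberate — differences in narrative length are
#' themselves part of the phenomenon being measured.
#'
#' @param t A [transcript()].
#' @return A one-row tibble with `NOUNCNT`, `VERBCNT`, `ADJCNT`, `ADVCNT`,
#'   `NUMCNT`, `AUXCNT`.
#' @export
pos_counts <- function(t) {
  stopifnot(inherits(t, "transcript"))
  cls <- c(NOUNCNT = "NOUN", VERBCNT = "VERB", ADJCNT = "ADJ",
           ADVCNT = "ADV", NUMCNT = "NUM", AUXCNT = "AUX")
  counts <- vapply(cls, function(u) sum(t$tokens$upos == u), numeric(1))
  tibble::as_tibble(as.list(counts))
}

#' Phrase-count biomarkers
#'
#' Counts of noun, verb, and prepositional phrase spans. When a transcript
#' carries no phrase layer (e.g., no parser exists for its language) the
#' three biomarkers are returned missing with a reason — analysis proceeds
#' on the remaining biomarkers.
#'
#' @param t A [transcript()].
#' @return A one-row tibble with `NPCNT`, `VPCNT`, `PPCNT` and `flag`.
#' @export
phrase_counts <- function(t) {
  stopifnot(inherits(t, "transcript"))
  if (is.null(t$phrases)) {
    return(tibble::tibble(NPCNT = NA_real_, VPCNT = NA_real_, PPCNT = NA_real_,
                          flag = "no-phrase-layer"))
  }
  tibble::tibble(
    NPCNT = sum(t$phrases$label == "NP"),
    VPCNT = sum(t$phrases$label == "VP"),
    PPCNT = sum(t$phrases$label == "PP"),
    flag = NA_character_
  )
}

#' All 13 linguistic biomarkers of one transcript
#'
#' @param t A [transcript()].
#' @return A long tibble with columns `biomarker`, `value`, `flag`.
#' @export
linguistic_features <- function(t) {
  lx <- lexical_counts(t)
  ps <- pos_counts(t)
  ph <- phrase_counts(t)
  long <- function(df) {
    flag <- if ("flag" %in% names(df)) df$flag else NA_character_
    vals <- df[setdiff(names(df), "flag")]
    tibble::tibble(biomarker = names(vals), value = as.numeric(vals[1, ]),
                   flag = flag)
  }
  dplyr::bind_rows(long(lx), long(ps), long(ph))
}

#' Default function-word POS classes
#'
#' The closed-class universal POS tags treated as function words when a
#' transcript does not carry explicit flags: determiners, pronouns,
#' adpositions, conjunctions, particles, auxiliaries, interjections.
#' Configurable per language profile.
#'
#' @export
function_word_upos <- function() {
  c("DET", "PRON", "ADP", "CCONJ", "SCONJ", "PART", "AUX", "INTJ")
}
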