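#' Speech-rhythm variability (RHYSTD)
#'
#' Sample standard deviation of the intervals between consecutive word
#' onsets. Defined on inter-onset intervals, not on the raw timestamps (the
#' SD of raw timestamps grows without bound with recording length and does
#' not measure rhythm). Invariant to time translation; scales linearly under
#' time dilation.
#'
#' @param onsets Strictly increasing numeric vector of word start times (s).
#' @return RHYSTD in seconds, or `NA` with a `reason` attribute when fewer
#'   than three onsets (two intervals) are available.
#' @examples
#' rhythm_std(c(0, 0.4, 1.2)) # sd of intervals {0.4, 0.8}
#' @export
rhythm_std <- function(onsets) {
  onsets <- onsets[!is.na(onsets)]
  if (length(onsets) < 3L) {
    out <- NA_real_
    attr(out, "reason") <- "fewer than 3 word onsets"
    return(out)
  }
  if (any(diff(onsets) <= 0)) stop("word onsets must be strictly increasing")
  stats::sd(diff(onsets))
}

#' Informational-unit checklists
#'
#' A checklist names the salient events of a picture-description task; each
#' item carries one or more acceptable lemmas (multi-word items match on
#' their head lemmas). Stored as JSON:
#' `{"task": ..., "language": ..., "items": [["wash"], ["try","help"], ...]}`.
#'
#' @param path JSON checklist path.
#' @return A list with `task`, `language`, `items` (list of character vectors).
#' @export
read_iu_checklist <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  items <- lapply(x$items, function(it) as.character(unlist(it)))
  if (length(items) == 0L || any(lengths(items) == 0L)) {
    stop("checklist must have at least one item, each with at least one lemma")
  }
  list(task = x$task, language = x$language, items = items)
}

#' Informational-unit count (IU)
#'
#' Number of checklist items for which at least one acceptable lemma occurs
#' in the transcript. Item-level and type-based: an item is either mentioned
#' or not, however many times its lemmas recur. Bounded by the checklist
#' size and monotone under transcript extension.
#'
#' @param t A [transcript()].
#' @param checklist A checklist from [read_iu_checklist()] (or an equivalent
#'   list with an `items` field).
#' @return Integer count in `[0, length(checklist$items)]`.
#' @export
informational_units <- function(t, checklist) {
  stopifnot(inherits(t, "transcript"))
  lemmas <- unique(t$tokens$lemma)
  sum(vapply(checklist$items, function(it) any(it %in% lemmas), logical(1)))
}

#' Cognitive biomarkers of one transcript
#'
#' RHYSTD from the transcript's word time anchors, and IU when a checklist
#' applies to the task. Transcripts without time anchors (no aligner exists
#' for the language) yield a missing RHYSTD with a reason, mirroring how
#' cohorts without a forced-alignment model are handled.
#'
#' @param t A [transcript()].
#' @param checklist Optional IU checklist; when `NULL`, IU is not emitted.
#' @return A long tibble with columns `biomarker`, `value`, `flag`.
#' @export
cognitive_features <- function(t, checklist = NULL) {
  onsets <- t$tokens$start_time
  if (all(is.na(onsets))) {
    r <- NA_real_
    rflag <- "no-word-alignment"
  } else {
    r <- rhythm_std(onsets)
    rflag <- attr(r, "reason") %||% NA_character_
  }
  out <- tibble::tibble(biomarker = "RHYSTD", value = as.numeric(r), flag = rflag)
  if (!is.null(checklist)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      biomarker = "IU", value = as.numeric(informational_units(t, checklist)),
      flag = NA_character_))
  }
  out
}
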