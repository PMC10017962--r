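#' Annotated transcript objects
#'
#' An annotated transcript couples a token table (form, lemma, universal POS
#' tag, function-word flag, sentence index, optional word-level time anchors
#' in seconds) with an optional phrase-span table (`NP`/`VP`/`PP` chunks over
#' global token indices). Transcripts arrive pre-annotated — tagging and
#' parsing are upstream concerns; the synthetic cohort generator emits
#' annotations directly.
#'
#' @param tokens A data frame with columns `form`, `lemma`, `upos`,
#'   `is_function_word`, `sentence`, and optionally `start_time`, `end_time`.
#' @param phrases Optional data frame with columns `label` (`NP`/`VP`/`PP`),
#'   `start_token`, `end_token` (1-based global token indices), or `NULL`
#'   when no phrase layer exists.
#' @return An object of class `transcript`.
#' @export
transcript <- function(tokens, phrases = NULL) {
  tokens <- tibble::as_tibble(tokens)
  required <- c("form", "lemma", "upos", "is_function_word", "sentence")
  missing_cols <- setdiff(required, names(tokens))
  if (length(missing_cols)) stop("tokens lack columns: ", toString(missing_cols))
  if (nrow(tokens) && is.unsorted(tokens$sentence)) {
    stop("sentence indices must be non-decreasing")
  }
  if (!"start_time" %in% names(tokens)) tokens$start_time <- NA_real_
  if (!"end_time" %in% names(tokens)) tokens$end_time <- NA_real_
  if (!is.null(phrases)) {
    phrases <- tibble::as_tibble(phrases)
    if (nrow(phrases) && (any(phrases$start_token < 1) ||
                          any(phrases$end_token > nrow(tokens)) ||
                          any(phrases$start_token > phrases$end_token))) {
      stop("phrase spans must lie within the token range")
    }
  }
  structure(list(tokens = tokens, phrases = phrases), class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript: %d tokens, %d sentences, %s phrase spans>\n",
              nrow(x$tokens),
              length(unique(x$tokens$sentence)),
              if (is.null(x$phrases)) "no" else nrow(x$phrases)))
  invisible(x)
}

parse_misc <- function(misc) {
  out <- list()
  if (misc == "_" || misc == "") return(out)
  for (kv in strsplit(misc, "|", fixed = TRUE)[[1]]) {
    parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
    if (length(parts) == 2L) out[[parts[1]]] <- parts[2]
  }
  out
}

#' Read an annotated transcript from CoNLL-U
#'
#' Standard ten-column CoNLL-U. Recognized MISC keys: `Func=Yes` (function
#' word), `StartTime=`/`EndTime=` (word time anchors, seconds), and
#' `Chunk=B-NP`/`I-NP` etc. (phrase spans, BIO-tagged). A sidecar span file
#' (TSV: `label`, `start_token`, `end_token`) may be supplied instead of
#' chunk tags.
#'
#' @param path CoNLL-U file path.
#' @param spans_path Optional sidecar phrase-span TSV.
#' @return A [transcript()].
#' @export
read_conllu <- function(path, spans_path = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  sent <- 0L
  in_sentence <- FALSE
  rows <- list()
  chunk_tags <- character()
  for (ln in lines) {
    if (startsWith(ln, "#")) next
    if (!nzchar(trimws(ln))) { in_sentence <- FALSE; next }
    if (!in_sentence) { sent <- sent + 1L; in_sentence <- TRUE }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 10L || grepl("[.-]", f[1])) next  # skip ranges/empty nodes
    misc <- parse_misc(f[10])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      form = f[2], lemma = f[3], upos = f[4],
      is_function_word = identical(misc$Func, "Yes"),
      sentence = sent,
      start_time = as.numeric(misc$StartTime %||% NA),
      end_time = as.numeric(misc$EndTime %||% NA)
    )
    chunk_tags <- c(chunk_tags, misc$Chunk %||% "O")
  }
  tokens <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(form = character(), lemma = character(), upos = character(),
                   is_function_word = logical(), sentence = integer(),
                   start_time = numeric(), end_time = numeric())
  phrases <- NULL
  if (!is.null(spans_path)) {
    sp <- utils::read.delim(spans_path, stringsAsFactors = FALSE)
    phrases <- tibble::as_tibble(sp[, c("label", "start_token", "end_token")])
  } else if (any(chunk_tags != "O")) {
    phrases <- chunks_to_spans(chunk_tags)
  }
  transcript(tokens, phrases)
}

chunks_to_spans <- function(tags) {
  spans <- list()
  open_label <- NULL; open_start <- NA_integer_
  close_open <- function(i) {
    if (!is.null(open_label)) {
      spans[[length(spans) + 1L]] <<- tibble::tibble(
        label = open_label, start_token = open_start, end_token = i)
    }
  }
  for (i in seq_along(tags)) {
    t <- tags[i]
    if (startsWith(t, "B-")) {
      close_open(i - 1L)
      open_label <- sub("^B-", "", t); open_start <- i
    } else if (startsWith(t, "I-") && identical(sub("^I-", "", t), open_label)) {
      # span continues
    } else {
      close_open(i - 1L)
      open_label <- NULL
    }
  }
  close_open(length(tags))
  if (length(spans)) dplyr::bind_rows(spans) else NULL
}

#' @rdname read_conllu
#' @param x A [transcript()] to serialize.
#' @export
write_conllu <- function(x, path, spans_path = NULL) {
  stopifnot(inherits(x, "transcript"))
  tok <- x$tokens
  chunk <- rep("O", nrow(tok))
  if (!is.null(x$phrases) && is.null(spans_path) && nrow(x$phrases)) {
    for (i in seq_len(nrow(x$phrases))) {
      rng <- x$phrases$start_token[i]:x$phrases$end_token[i]
      chunk[rng] <- paste0("I-", x$phrases$label[i])
      chunk[rng[1]] <- paste0("B-", x$phrases$label[i])
    }
  }
  lines <- character()
  for (s in unique(tok$sentence)) {
    idx <- which(tok$sentence == s)
    lines <- c(lines, sprintf("# sent_id = %d", s))
    for (k in seq_along(idx)) {
      i <- idx[k]
      misc <- c(
        if (isTRUE(tok$is_function_word[i])) "Func=Yes",
        if (!is.na(tok$start_time[i])) sprintf("StartTime=%.3f", tok$start_time[i]),
        if (!is.na(tok$end_time[i])) sprintf("EndTime=%.3f", tok$end_time[i]),
        if (chunk[i] != "O") paste0("Chunk=", chunk[i])
      )
      lines <- c(lines, paste(
        k, tok$form[i], tok$lemma[i], tok$upos[i], "_", "_", "0", "dep", "_",
        if (length(misc)) paste(misc, collapse = "|") else "_",
        sep = "\t"))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path, useBytes = TRUE)
  if (!is.null(spans_path) && !is.null(x$phrases)) {
    utils::write.table(x$phrases, spans_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
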