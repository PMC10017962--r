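#' Extract all biomarkers for a cohort manifest
#'
#' Runs the full extraction pipeline over a manifest: audio is resampled to
#' 16 kHz; repeated recordings of a subject x task (e.g., several short
#' utterances) are concatenated speaker-wise with edge silences trimmed;
#' acoustic biomarkers are computed for every task; linguistic and
#' informational-unit biomarkers for spontaneous speech only; rhythm
#' variability wherever word time anchors exist. Unreadable rows are
#' recorded as errors and skipped; the run fails only if nothing could be
#' extracted.
#'
#' @param manifest Tibble with `subject_id`, `group`, `dataset`, `task`,
#'   `audio_path`, `transcript_path` (paths relative to `root`; transcript
#'   may be `NA` for audio-only rows).
#' @param root Directory the manifest paths are relative to.
#' @param checklist Optional IU checklist (see [read_iu_checklist()]) or a
#'   named list of checklists keyed by dataset.
#' @param ... Passed to [acoustic_features()] (pitch range, VAD smoothing).
#' @return A long tibble `subject_id`, `dataset`, `task`, `biomarker`,
#'   `value`, `flag`, with attribute `errors` (tibble of skipped rows).
#' @export
run_extract <- function(manifest, root = ".", checklist = NULL, ...) {
  keys <- dplyr::distinct(manifest[, c("subject_id", "dataset", "task")])
  rows <- list(); errors <- list()
  for (i in seq_len(nrow(keys))) {
    key <- keys[i, ]
    sub <- dplyr::semi_join(manifest, key, by = c("subject_id", "dataset", "task"))
    res <- tryCatch(
      extract_one(sub, root, resolve_checklist(checklist, key$dataset), ...),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <- tibble::tibble(
        subject_id = key$subject_id, dataset = key$dataset, task = key$task,
        error = conditionMessage(res))
      next
    }
    rows[[length(rows) + 1L]] <- tibble::add_column(
      res, subject_id = key$subject_id, dataset = key$dataset,
      task = key$task, .before = 1)
  }
  if (length(rows) == 0L) stop("extraction failed for every manifest row")
  out <- dplyr::bind_rows(rows)
  attr(out, "errors") <- dplyr::bind_rows(errors)
  out
}

resolve_checklist <- function(checklist, dataset) {
  if (is.null(checklist)) return(NULL)
  if (!is.null(checklist$items)) return(checklist)   # single checklist
  checklist[[dataset]]
}

extract_one <- function(sub, root, checklist, ...) {
  waves <- lapply(file.path(root, sub$audio_path), read_wav)
  waves <- lapply(waves, resample_wave, rate = 16000)
  w <- if (length(waves) > 1L) concatenate_tdu(waves) else waves[[1]]
  out <- acoustic_features(w, ...)
  has_tr <- !is.na(sub$transcript_path)
  tr_paths <- sub$transcript_path[has_tr]
  if (length(tr_paths)) {
    trs <- lapply(file.path(root, tr_paths), read_conllu)
    # word time anchors refer to each source recording: shift them by the
    # total duration of the recordings that precede each transcript
    offsets <- cumsum(c(0, vapply(waves[has_tr], wave_duration,
                                  numeric(1))))[seq_along(trs)]
    tr <- if (length(trs) > 1L) concat_transcripts(trs, offsets) else trs[[1]]
    is_ss <- sub$task[1] == "SS"
    cog <- cognitive_features(tr, checklist = if (is_ss) checklist else NULL)
    out <- dplyr::bind_rows(out, cog)
    if (is_ss) out <- dplyr::bind_rows(out, linguistic_features(tr))
  }
  out
}

concat_transcripts <- function(trs, time_offsets = rep(0, length(trs))) {
  offset_tok <- 0L; offset_sent <- 0L
  toks <- list(); spans <- list()
  for (j in seq_along(trs)) {
    tr <- trs[[j]]
    tk <- tr$tokens
    if (nrow(tk)) {
      tk$sentence <- tk$sentence + offset_sent
      tk$start_time <- tk$start_time + time_offsets[j]
      tk$end_time <- tk$end_time + time_offsets[j]
    }
    toks[[length(toks) + 1L]] <- tk
    if (!is.null(tr$phrases)) {
      sp <- tr$phrases
      sp$start_token <- sp$start_token + offset_tok
      sp$end_token <- sp$end_token + offset_tok
      spans[[length(spans) + 1L]] <- sp
    }
    offset_tok <- offset_tok + nrow(tk)
    if (nrow(tk)) offset_sent <- max(tk$sentence)
  }
  transcript(dplyr::bind_rows(toks),
             if (length(spans)) dplyr::bind_rows(spans) else NULL)
}

#' Analyze a biomarker table
#'
#' The statistical stage of the pipeline: group-comparison tests with FDR
#' control per biomarker family ([group_tests()]), severity correlations on
#' PD subjects ([correlate_severity()]), and the robustness adjudication
#' ([adjudicate_robustness()]).
#'
#' @param table Long biomarker table (see [run_extract()]).
#' @param metadata Subject metadata: `subject_id`, `group`, and optionally
#'   severity scores `updrs3`, `updrs3_1`, `hy`.
#' @param expected Expected-behavior table (defaults to the shipped
#'   reference catalog).
#' @param alpha FDR level.
#' @return A `biomarker_analysis` object: list with `tests`,
#'   `correlations`, `verdicts`, `alpha`.
#' @export
run_analyze <- function(table, metadata,
                        expected = reference_expected_behavior(),
                        alpha = 0.05) {
  tests <- group_tests(table, metadata, alpha = alpha)
  correlations <- correlate_severity(table, metadata, alpha = alpha)
  verdicts <- adjudicate_robustness(tests, correlations, expected)
  structure(list(tests = tests, correlations = correlations,
                 verdicts = verdicts, alpha = alpha),
            class = "biomarker_analysis")
}

#' @export
print.biomarker_analysis <- function(x, ...) {
  cat(sprintf(
    "<biomarker_analysis: %d tests (%d significant at FDR %.2f), %d correlations (%d significant), %d/%d biomarkers robust>\n",
    nrow(x$tests), sum(x$tests$significant), x$alpha,
    nrow(x$correlations), sum(x$correlations$significant),
    sum(x$verdicts$robust), nrow(x$verdicts)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a biomarker analysis
#'
#' `tidy()` returns the per-cell test results (one row per dataset x task x
#' biomarker, with H, p, adjusted p, observed behavior, eta-squared and
#' AUROC) augmented with the robustness verdict of each biomarker name;
#' `glance()` returns a one-row summary.
#'
#' @param x A `biomarker_analysis`.
#' @param ... Unused.
#' @method tidy biomarker_analysis
#' @export
tidy.biomarker_analysis <- function(x, ...) {
  dplyr::left_join(x$tests,
                   x$verdicts[, c("biomarker", "robust")], by = "biomarker")
}

#' @rdname tidy.biomarker_analysis
#' @method glance biomarker_analysis
#' @export
glance.biomarker_analysis <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x$tests),
    n_significant = sum(x$tests$significant),
    n_correlations = nrow(x$correlations),
    n_correlations_significant = sum(x$correlations$significant),
    n_biomarkers = nrow(x$verdicts),
    n_robust = sum(x$verdicts$robust),
    alpha = x$alpha
  )
}

#' Write analysis outputs
#'
#' Serializes the three result tables as CSV and the verdicts as JSON plus a
#' human-readable text report.
#'
#' @param analysis A `biomarker_analysis`.
#' @param dir Output directory (created if needed).
#' @export
write_analysis <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(analysis$tests, file.path(dir, "tests.csv"), row.names = FALSE)
  utils::write.csv(analysis$correlations, file.path(dir, "correlations.csv"),
                   row.names = FALSE)
  v <- analysis$verdicts
  jsonlite::write_json(
    list(robust = v$biomarker[v$robust],
         verdicts = v[, c("biomarker", "robust")]),
    file.path(dir, "verdicts.json"), auto_unbox = TRUE, digits = NA)
  lines <- c(
    sprintf("Robust biomarkers (%d/%d):", sum(v$robust), nrow(v)),
    paste(" ", v$biomarker[v$robust]),
    "",
    "Per-dataset significant biomarker counts:",
    utils::capture.output(print.data.frame(
      as.data.frame(count_significant_biomarkers(analysis$tests))))
  )
  writeLines(lines, file.path(dir, "report.txt"))
  invisible(dir)
}
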