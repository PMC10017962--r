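#' Adjudicate cross-cohort biomarker robustness
#'
#' A biomarker is deemed robust when, within some task class for which it
#' has an expected direction, all three conditions hold:
#' \enumerate{
#'   \item it is significant (after FDR correction) in at least two distinct
#'     datasets;
#'   \item every significant result's observed behavior equals the expected
#'     direction for that task class;
#'   \item every significant correlation with a clinical severity scale has
#'     the sign implied by the expected direction (expected up: positive rho
#'     with severity; expected down: negative) — vacuously true when no
#'     significant correlation exists.
#' }
#' Conditions are evaluated per task class because two biomarkers (speech
#' time, rhythm variability) carry opposite expectations in spontaneous
#' versus read speech; a name passing in one class is robust even if another
#' class shows a protocol-driven reversal (task robustness and language
#' robustness are distinct questions).
#'
#' @param tests Test results with columns `dataset`, `task`, `biomarker`,
#'   `OB` (`"up"`/`"down"`/`"tie"`), `significant`.
#' @param correlations Correlation results with columns `dataset`, `task`,
#'   `biomarker`, `scale`, `rho`, `significant`; may be `NULL` or empty.
#' @param expected Expected-behavior table with columns `biomarker`,
#'   `task_class` (`"SS"`, `"RP"`, `"TDU"` or `"All"`) and `direction`
#'   (`"up"`/`"down"`). Defaults to the shipped reference table.
#' @return A tibble with one row per biomarker name: `robust`,
#'   `datasets_significant` (list-column), and `conditions` (list-column of
#'   per-task-class evidence: the three condition flags and the rows behind
#'   them).
#' @export
adjudicate_robustness <- function(tests, correlations = NULL,
                                  expected = reference_expected_behavior()) {
  stopifnot(all(c("dataset", "task", "biomarker", "OB", "significant")
                %in% names(tests)))
  if (is.null(correlations) || nrow(correlations) == 0L) {
    correlations <- tibble::tibble(dataset = character(), task = character(),
                                   biomarker = character(), scale = character(),
                                   rho = numeric(), significant = logical())
  }
  lookup <- function(bm, task) {
    hit <- expected[expected$biomarker == bm &
                    expected$task_class %in% c(task, "All"), , drop = FALSE]
    if (nrow(hit) == 0L) return(NA_character_)
    # an exact task row overrides an All row
    hit$direction[order(hit$task_class == "All")][1]
  }
  tested <- dplyr::distinct(tests[, c("biomarker", "task")])
  for (i in seq_len(nrow(tested))) {
    if (is.na(lookup(tested$biomarker[i], tested$task[i]))) {
      stop(sprintf("no expected direction configured for biomarker %s in task %s",
                   tested$biomarker[i], tested$task[i]))
    }
  }
  verdict_for <- function(bm) {
    classes <- unique(tests$task[tests$biomarker == bm])
    per_class <- purrr::map(classes, function(cl) {
      dir <- lookup(bm, cl)
      sig <- tests[tests$biomarker == bm & tests$task == cl &
                   tests$significant, , drop = FALSE]
      sig_cor <- correlations[correlations$biomarker == bm &
                              correlations$task == cl &
                              correlations$significant, , drop = FALSE]
      cond1 <- length(unique(sig$dataset)) >= 2L
      cond2 <- nrow(sig) == 0L || all(sig$OB == dir)
      cond3 <- nrow(sig_cor) == 0L ||
        all(ifelse(sig_cor$rho > 0, "up", "down") == dir)
      tibble::tibble(
        task_class = cl, expected = dir,
        n_datasets_significant = length(unique(sig$dataset)),
        datasets = list(sort(unique(sig$dataset))),
        cond1_two_datasets = cond1,
        cond2_direction_consistent = cond2,
        cond3_correlations_consistent = cond3,
        pass = cond1 && cond2 && cond3
      )
    })
    per_class <- dplyr::bind_rows(per_class)
    tibble::tibble(
      biomarker = bm,
      robust = any(per_class$pass),
      datasets_significant = list(sort(unique(unlist(
        per_class$datasets[per_class$pass | !any(per_class$pass)])))),
      conditions = list(per_class)
    )
  }
  out <- dplyr::bind_rows(purrr::map(sort(unique(tests$biomarker)), verdict_for))
  class(out) <- c("robustness_verdict", class(out))
  out
}

#' @export
print.robustness_verdict <- function(x, ...) {
  cat(sprintf("Robustness verdicts: %d biomarkers adjudicated, %d robust\n",
              nrow(x), sum(x$robust)))
  if (any(x$robust)) {
    cat("robust:", paste(x$biomarker[x$robust], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Count significant biomarker names per dataset
#'
#' Number of distinct biomarker names with at least one significant result
#' (in any task) within each dataset.
#'
#' @param tests Test results with `dataset`, `biomarker`, `significant`.
#' @return A tibble with `dataset` and `n_significant`.
#' @export
count_significant_biomarkers <- function(tests) {
  sig <- tests[tests$significant, , drop = FALSE]
  all_ds <- unique(tests$dataset)
  counts <- tapply(sig$biomarker, factor(sig$dataset, levels = all_ds),
                   function(b) length(unique(b)))
  tibble::tibble(dataset = all_ds,
                 n_significant = as.integer(ifelse(is.na(counts), 0L, counts)))
}

ref_path <- function(file) {
  system.file("extdata", file, package = "robustmark", mustWork = TRUE)
}

#' Reference results from a published six-cohort multilingual PD study
#'
#' Machine-readable encodings of the expected-behavior catalog, the
#' significant group-comparison results (acoustic plus linguistic/cognitive),
#' and the significant severity correlations reported by a published
#' six-cohort multilingual study of PD speech (American English, Castilian
#' Spanish, Colombian Spanish, Italian, German, Czech). Cells whose printed
#' typography conflicted with the running text of the source are annotated
#' in the `note` column and encoded per the running text.
#'
#' All rows in the test/correlation tables are significant after FDR
#' correction (the source reports only significant results), so
#' `significant` is `TRUE` throughout.
#'
#' @return `reference_results()`: list with `expected`, `tests`,
#'   `correlations`. The individual loaders return the corresponding tibble.
#' @export
reference_results <- function() {
  list(expected = reference_expected_behavior(),
       tests = reference_tests(),
       correlations = reference_correlations())
}

#' @rdname reference_results
#' @export
reference_expected_behavior <- function() {
  tibble::as_tibble(utils::read.csv(ref_path("reference_expected_behavior.csv"),
                                    stringsAsFactors = FALSE))
}

#' @rdname reference_results
#' @export
reference_tests <- function() {
  acoustic <- utils::read.csv(ref_path("reference_tests_acoustic.csv"),
                              stringsAsFactors = FALSE)
  lingcog <- utils::read.csv(ref_path("reference_tests_linguistic.csv"),
                             stringsAsFactors = FALSE)
  out <- tibble::as_tibble(rbind(acoustic, lingcog))
  out$significant <- TRUE
  out
}

#' @rdname reference_results
#' @export
reference_correlations <- function() {
  out <- tibble::as_tibble(utils::read.csv(ref_path("reference_correlations.csv"),
                                           stringsAsFactors = FALSE))
  out$significant <- TRUE
  out
}
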