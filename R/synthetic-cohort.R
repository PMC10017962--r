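#' Effect plans
#'
#' An effect plan states, per biomarker and task class, the direction and
#' standardized magnitude of the group difference to plant in a synthetic
#' cohort, and the strength of the rank correlation between the shifted PD
#' parameter and clinical severity. Magnitudes are Cohen's d on the
#' generative parameter (PD mean shifted by `magnitude` between-subject SDs
#' in `direction`).
#'
#' @param biomarker,task_class,direction,magnitude,severity_link Vectors
#'   defining the plan rows. `direction` is `"up"`, `"down"` or `"null"`
#'   (which forces `magnitude = 0`); `task_class` is `"SS"`, `"RP"`, `"TDU"`
#'   or `"All"`; `|severity_link| <= 1`.
#' @return A validated `effect_plan` tibble.
#' @export
effect_plan <- function(biomarker, task_class, direction, magnitude,
                        severity_link = 0) {
  plan <- tibble::tibble(biomarker = biomarker, task_class = task_class,
                         direction = direction, magnitude = magnitude,
                         severity_link = severity_link)
  unknown <- setdiff(plan$biomarker, all_biomarkers())
  if (length(unknown)) stop("unknown biomarker name(s): ", toString(unknown))
  if (!all(plan$task_class %in% c("SS", "RP", "TDU", "All"))) {
    stop("task_class must be SS, RP, TDU or All")
  }
  if (!all(plan$direction %in% c("up", "down", "null"))) {
    stop("direction must be up, down or null")
  }
  if (any(plan$magnitude < 0)) stop("magnitude must be nonnegative")
  if (any(plan$direction == "null" & plan$magnitude != 0)) {
    stop("direction 'null' implies magnitude 0")
  }
  if (any(abs(plan$severity_link) > 1)) stop("|severity_link| must be <= 1")
  class(plan) <- c("effect_plan", class(plan))
  plan
}

all_biomarkers <- function() {
  c("F0STD", "F1STD", "INTSTD", "SPTIME", "SILTIME", "SILPERC", "SILSPRAT",
    "SILDUR", "SILVAR", "WORDCNT", "WORDLEN", "SENTCNT", "SENTLEN",
    "NOUNCNT", "VERBCNT", "ADJCNT", "ADVCNT", "NUMCNT", "AUXCNT",
    "NPCNT", "VPCNT", "PPCNT", "IU", "RHYSTD")
}

#' Default effect plan: the expected PD behaviors
#'
#' Plants every biomarker in the expected direction of the reference
#' catalog (lower pitch/loudness/formant variability, more and longer
#' pauses, shorter and syntactically poorer narratives, fewer informational
#' units, more static spontaneous rhythm, more irregular read rhythm), all
#' at one magnitude, with severity links signed to match (pathological
#' shifts track higher severity).
#'
#' @param magnitude Standardized shift, default 1.2.
#' @param severity_link Absolute rank-correlation strength with severity,
#'   default 0.5.
#' @return An [effect_plan()].
#' @export
default_effect_plan <- function(magnitude = 1.2, severity_link = 0.5) {
  eb <- reference_expected_behavior()
  effect_plan(
    biomarker = eb$biomarker, task_class = eb$task_class,
    direction = eb$direction, magnitude = magnitude,
    severity_link = ifelse(eb$direction == "up", 1, -1) * severity_link
  )
}

#' Null effect plan
#'
#' Same coverage as [default_effect_plan()] but with all magnitudes zero:
#' CN and PD are generatively identical. Used for type-I error studies.
#' @export
null_effect_plan <- function() {
  eb <- reference_expected_behavior()
  effect_plan(eb$biomarker, eb$task_class, "null", 0, 0)
}

#' Prototype subject parameters
#'
#' The generative parametrization of one synthetic speaker: pitch mean and
#' variability, loudness variability, first-formant center and variability,
#' pause process (Poisson rate; lognormal durations), net speech target,
#' speaking rate and onset jitter, lexical profile (POS class weights,
#' sentence length, word length, phrase rates per sentence), and checklist
#' coverage. `mean` is the CN population mean; `sd` the between-subject SD.
#'
#' @return A tibble with columns `param`, `mean`, `sd`, `min`, `max`.
#' @export
base_subject_params <- function() {
  tibble::tribble(
    ~param,          ~mean,     ~sd,    ~min,  ~max,
    "f0_mean",       140,       15,     60,    400,
    "f0_sd",         25,        8,      0.5,   80,
    "intensity_sd",  4,         1.2,    0.3,   12,
    "f1_mean",       500,       30,     250,   900,
    "f1_sd",         60,        15,     1,     200,
    "pause_rate",    0.35,      0.08,   0.02,  1.2,
    "pause_log_mean", log(0.5), 0.25,   log(0.2), log(3),
    "pause_log_sd",  0.35,      0.10,   0.05,  1.0,
    "speech_total",  20,        4,      4,     90,
    "word_rate",     2.5,       0.4,    0.8,   6,
    "rhythm_jitter", 0.08,      0.025,  0.001, 0.4,
    "word_len",      4.5,       0.5,    2,     10,
    "sent_len",      9,         1.5,    3,     25,
    "np_rate",       3.0,       0.6,    0.2,   10,
    "vp_rate",       1.6,       0.4,    0.2,   10,
    "pp_rate",       1.2,       0.4,    0.1,   10,
    "pos_noun",      0.22,      0.035,  0.02,  0.6,
    "pos_verb",      0.14,      0.03,   0.02,  0.6,
    "pos_adj",       0.07,      0.02,   0.005, 0.4,
    "pos_adv",       0.06,      0.02,   0.005, 0.4,
    "pos_num",       0.02,      0.008,  0.001, 0.2,
    "pos_aux",       0.05,      0.015,  0.005, 0.4,
    "iu_coverage",   0.70,      0.12,   0,     1
  )
}

# which generative parameter an effect-plan biomarker shifts
param_for_biomarker <- function(biomarker) {
  map <- c(
    F0STD = "f0_sd", F1STD = "f1_sd", INTSTD = "intensity_sd",
    SPTIME = "speech_total", SILTIME = "pause_rate", SILPERC = "pause_rate",
    SILSPRAT = "pause_rate", SILDUR = "pause_log_mean",
    SILVAR = "pause_log_sd", WORDCNT = "speech_total", WORDLEN = "word_len",
    SENTCNT = "speech_total", SENTLEN = "sent_len", NOUNCNT = "pos_noun",
    VERBCNT = "pos_verb", ADJCNT = "pos_adj", ADVCNT = "pos_adv",
    NUMCNT = "pos_num", AUXCNT = "pos_aux", NPCNT = "np_rate",
    VPCNT = "vp_rate", PPCNT = "pp_rate", IU = "iu_coverage",
    RHYSTD = "rhythm_jitter"
  )
  unname(map[biomarker])
}

#' Plant an effect plan onto group parameter distributions
#'
#' Resolves an effect plan against the generative parametrization for one
#' task class: each planted biomarker shifts its generative parameter's PD
#' mean by `magnitude` between-subject SDs in `direction`, and records the
#' severity link. When several biomarkers map to one parameter (the pause
#' fraction drives SILTIME, SILPERC and SILSPRAT alike; narrative length
#' drives WORDCNT and SENTCNT), the largest-magnitude entry wins rather than
#' stacking.
#'
#' @param plan An [effect_plan()].
#' @param base Parameter prototype, see [base_subject_params()].
#' @param task Task class the recording belongs to (`"SS"`, `"RP"`, `"TDU"`).
#' @return `base` with extra columns `mean_pd`, `shift_sd` (signed, in SD
#'   units) and `severity_link`.
#' @export
plant_effects <- function(plan, base = base_subject_params(), task = "SS") {
  unknown <- setdiff(plan$biomarker, all_biomarkers())
  if (length(unknown)) stop("unknown biomarker name(s): ", toString(unknown))
  active <- plan[plan$task_class %in% c(task, "All") & plan$direction != "null", ,
                 drop = FALSE]
  base$shift_sd <- 0
  base$severity_link <- 0
  if (nrow(active)) {
    active$param <- param_for_biomarker(active$biomarker)
    active <- active[order(-active$magnitude), , drop = FALSE]
    active <- active[!duplicated(active$param), , drop = FALSE]  # largest wins
    i <- match(active$param, base$param)
    base$shift_sd[i] <- ifelse(active$direction == "up", 1, -1) * active$magnitude
    base$severity_link[i] <- active$severity_link
  }
  base$mean_pd <- base$mean + base$shift_sd * base$sd
  base
}

# Gaussian-copula coefficient giving a target Spearman correlation
rho_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Draw per-subject generative parameters for one group
#'
#' CN parameters are normal around the prototype means; PD parameters are
#' normal around the planted means and coupled to a per-subject latent
#' severity through a Gaussian copula whose coefficient is chosen so the
#' Spearman correlation between each planted parameter and the severity
#' score equals its `severity_link` in expectation. Severity scores (a
#' motor-exam total, its speech item, and an ordinal 1-5 stage) are monotone
#' transforms of the latent severity and exist for PD only.
#'
#' @param planted Output of [plant_effects()].
#' @param n Number of subjects.
#' @param group `"CN"` or `"PD"`.
#' @param prefix Subject-id prefix.
#' @return A tibble: `subject_id`, `group`, one column per parameter,
#'   and `updrs3`, `updrs3_1`, `hy` (NA for CN).
#' @export
draw_subject_params <- function(planted, n, group = c("CN", "PD"),
                                prefix = "S") {
  group <- match.arg(group)
  if (n < 1L) stop("empty group: n must be at least 1")
  z_sev <- stats::rnorm(n)
  draw_one <- function(i) {
    mu <- if (group == "PD") planted$mean_pd else planted$mean
    r <- if (group == "PD") rho_to_pearson(planted$severity_link) else 0
    z <- r * z_sev[i] + sqrt(1 - r^2) * stats::rnorm(nrow(planted))
    pmin(pmax(mu + planted$sd * z, planted$min), planted$max)
  }
  vals <- t(vapply(seq_len(n), draw_one, numeric(nrow(planted))))
  colnames(vals) <- planted$param
  out <- tibble::as_tibble(vals)
  out <- tibble::add_column(out,
    subject_id = sprintf("%s%03d", prefix, seq_len(n)),
    group = group, .before = 1)
  if (group == "PD") {
    out$updrs3 <- round(pmin(pmax(25 + 10 * z_sev, 3), 80))
    out$updrs3_1 <- round(pmin(pmax(1.2 + 0.8 * z_sev, 0), 4))
    out$hy <- pmin(pmax(round((2.3 + 0.5 * z_sev) * 2) / 2, 1), 5)
  } else {
    out$updrs3 <- NA_real_; out$updrs3_1 <- NA_real_; out$hy <- NA_real_
  }
  out
}

#' Synthesize one recording with its annotated transcript
#'
#' Audio is an alternating sequence of voiced words and lognormal silences:
#' each word is a pulse train of the first eight harmonics (1/k roll-off) of
#' a subject-specific F0 trajectory (first-order autoregressive fluctuation
#' scaled to the subject's pitch SD), shaped by a per-word second-order
#' resonator (center drawn from the subject's F1 distribution) and a
#' per-word amplitude whose dB spread equals the subject's intensity SD.
#' Word onsets advance at the subject's speaking rate perturbed by onset
#' jitter; pause count is Poisson at the subject's pause rate and pause
#' durations are lognormal. The transcript carries forms from a synthetic
#' closed-class lexicon, lemmas, POS tags from the subject's lexical
#' profile, sentence boundaries, NP/VP/PP spans, and per-token time anchors
#' consistent with the audio.
#'
#' @param params One row of [draw_subject_params()] (or a named list).
#' @param task `"SS"`, `"RP"` or `"TDU"` (recorded in the transcript only;
#'   the planted parameters already reflect the task).
#' @param speech_target Net speech seconds; defaults to the subject's
#'   `speech_total` parameter.
#' @param rate Sample rate, Hz.
#' @param checklist Optional IU checklist whose items the subject mentions
#'   with probability `iu_coverage` each.
#' @param noise_db Level of the additive noise floor in dBFS.
#' @return A list with `wave` (a [waveform()]) and `transcript`
#'   (a [transcript()]).
#' @export
synthesize_recording <- function(params, task = "SS", speech_target = NULL,
                                 rate = 16000, checklist = NULL,
                                 noise_db = -60) {
  p <- as.list(params)
  speech_target <- speech_target %||% p$speech_total
  if (speech_target <= 1) stop("duration target must exceed 1 s")
  mean_pause <- exp(p$pause_log_mean + p$pause_log_sd^2 / 2)
  if (p$pause_rate * mean_pause >= 1) {
    stop("infeasible pause configuration: expected pause time >= total time")
  }
  n_words <- max(3L, round(speech_target * p$word_rate))
  gaps <- pmax(0.25 / p$word_rate,
               1 / p$word_rate + stats::rnorm(n_words, 0, p$rhythm_jitter))
  total_dur_est <- speech_target / (1 - p$pause_rate * mean_pause)
  n_pauses <- stats::rpois(1, p$pause_rate * total_dur_est)
  n_pauses <- min(n_pauses, n_words - 1L)
  pause_after <- sort(sample(seq_len(n_words - 1L), n_pauses))
  pause_dur <- pmax(0.25, stats::rlnorm(n_pauses, p$pause_log_mean, p$pause_log_sd))
  onset <- numeric(n_words)
  t_cur <- 0.25                                 # lead-in silence
  k <- 1L
  for (i in seq_len(n_words)) {
    onset[i] <- t_cur
    t_cur <- t_cur + gaps[i]
    if (k <= n_pauses && i == pause_after[k]) {
      t_cur <- t_cur + pause_dur[k]
      k <- k + 1L
    }
  }
  total_dur <- t_cur + 0.25                     # trail-out silence
  n <- ceiling(total_dur * rate)
  x <- numeric(n)
  # continuous F0 track (AR(1) on a 10 ms grid, stationary SD = f0_sd)
  phi <- 0.98
  grid_n <- ceiling(total_dur / 0.01) + 2L
  e <- stats::rnorm(grid_n, 0, p$f0_sd * sqrt(1 - phi^2))
  f0_dev <- as.numeric(stats::filter(e, phi, method = "recursive"))
  f0_grid <- pmax(60, pmin(400, p$f0_mean + f0_dev))
  f0_samp <- stats::approx(seq_len(grid_n) * 0.01 - 0.01, f0_grid,
                           xout = (seq_len(n) - 1) / rate, rule = 2)$y
  phase <- 2 * pi * cumsum(f0_samp) / rate
  word_end <- onset + gaps * 0.95
  amp_db <- stats::rnorm(n_words, 0, p$intensity_sd)
  f1_word <- pmin(pmax(stats::rnorm(n_words, p$f1_mean, p$f1_sd), 250), 1100)
  for (i in seq_len(n_words)) {
    lo <- floor(onset[i] * rate) + 1L
    hi <- min(n, ceiling(word_end[i] * rate))
    if (hi <= lo + 8L) next
    idx <- lo:hi
    s <- numeric(length(idx))
    for (h in 1:8) s <- s + sin(h * phase[idx]) / h
    # per-word formant: second-order resonator
    r1 <- exp(-pi * 80 / rate)
    a1 <- c(1, -2 * r1 * cos(2 * pi * f1_word[i] / rate), r1^2)
    s <- as.numeric(stats::filter(s, -a1[2:3], method = "recursive"))
    ramp_n <- min(round(0.005 * rate), length(s) %/% 4L)
    env <- rep(1, length(s))
    if (ramp_n > 0) {
      ramp <- 0.5 - 0.5 * cos(pi * seq_len(ramp_n) / ramp_n)
      env[seq_len(ramp_n)] <- ramp
      env[length(s) - ramp_n + seq_len(ramp_n)] <- rev(ramp)
    }
    s <- s * env
    rms <- sqrt(mean(s^2))
    if (rms > 0) s <- s / rms * 10^(amp_db[i] / 20) * 0.1
    x[idx] <- s
  }
  x <- x + stats::rnorm(n, 0, 10^(noise_db / 20))
  x <- x / max(abs(x)) * 0.7
  tr <- synth_transcript(p, n_words, onset, word_end, checklist)
  list(wave = waveform(x, rate), transcript = tr, task = task)
}

# lexical/syntactic layer of a synthetic recording
synth_transcript <- function(p, n_words, onset, word_end, checklist = NULL) {
  content <- c("NOUN", "VERB", "ADJ", "ADV", "NUM", "AUX")
  func <- c("DET", "PRON", "ADP", "CCONJ", "SCONJ", "PART", "INTJ")
  wc <- c(p$pos_noun, p$pos_verb, p$pos_adj, p$pos_adv, p$pos_num, p$pos_aux)
  func_w <- c(0.12, 0.09, 0.11, 0.05, 0.03, 0.02, 0.02)
  w <- c(wc, func_w * (1 - sum(wc)) / sum(func_w))
  upos <- sample(c(content, func), n_words, replace = TRUE, prob = w)
  lemma <- paste0(tolower(upos), "_",
                  sample.int(max(20L, n_words %/% 3L), n_words, replace = TRUE))
  # word forms: lengths around the subject's mean word length
  len <- pmax(1L, round(stats::rnorm(n_words, p$word_len, 1)))
  form <- vapply(len, function(l)
    paste(sample(letters, l, replace = TRUE), collapse = ""), character(1))
  if (!is.null(checklist)) {
    mention <- which(stats::runif(length(checklist$items)) < p$iu_coverage)
    slots <- which(upos %in% c("VERB", "NOUN"))
    slots <- utils::head(slots, length(mention))
    for (j in seq_along(slots)) {
      lemma[slots[j]] <- checklist$items[[mention[j]]][1]
    }
  }
  # sentence segmentation at the subject's mean sentence length
  sentence <- integer(n_words)
  s <- 1L; i <- 1L
  while (i <= n_words) {
    l <- max(2L, round(stats::rnorm(1, p$sent_len, p$sent_len * 0.2)))
    sentence[i:min(n_words, i + l - 1L)] <- s
    i <- i + l; s <- s + 1L
  }
  # phrase spans: per sentence, Poisson counts at the subject's phrase rates
  spans <- list()
  for (si in unique(sentence)) {
    tok <- which(sentence == si)
    counts <- c(NP = stats::rpois(1, p$np_rate), VP = stats::rpois(1, p$vp_rate),
                PP = stats::rpois(1, p$pp_rate))
    for (lbl in names(counts)) {
      k <- counts[[lbl]]
      if (k == 0L) next
      starts <- sort(sample(tok, min(k, length(tok))))
      for (st in starts) {
        spans[[length(spans) + 1L]] <- tibble::tibble(
          label = lbl, start_token = st,
          end_token = min(st + sample(0:2, 1), max(tok)))
      }
    }
  }
  tokens <- tibble::tibble(
    form = form, lemma = lemma, upos = upos,
    is_function_word = upos %in% func, sentence = sentence,
    start_time = onset, end_time = word_end
  )
  transcript(tokens, if (length(spans)) dplyr::bind_rows(spans) else NULL)
}

#' Generate a multi-dataset synthetic cohort
#'
#' Draws subject parameters per dataset and group under an effect plan,
#' synthesizes one recording per subject and task, and writes a cohort
#' bundle: WAV audio, CoNLL-U transcripts with time anchors and chunk tags,
#' a manifest CSV, and a ground-truth JSON of every subject's generative
#' parameters. All randomness flows from `seed` through a deterministic
#' per-subject stream (subject streams can be regenerated independently).
#'
#' @param config A list: `datasets` (character), `n_cn`, `n_pd`, `tasks`
#'   (subset of SS/RP/TDU), `plan` (an [effect_plan()]), and optional
#'   `speech_target` seconds per task recording and `checklist`.
#' @param seed Integer master seed.
#' @param out_dir Output directory (created). Ignored when
#'   `materialize = "manifest"`.
#' @param materialize `"full"` writes audio and transcripts; `"manifest"`
#'   generates parameters and manifest only (fast path for planning and
#'   determinism checks; file paths are the ones a full run would write).
#' @return A list: `manifest` (tibble), `truth` (subject-parameter tibble),
#'   `config`, and `out_dir`.
#' @export
generate_cohort <- function(config, seed, out_dir = NULL,
                            materialize = c("full", "manifest")) {
  materialize <- match.arg(materialize)
  datasets <- config$datasets
  tasks <- config$tasks %||% c("SS", "RP", "TDU")
  plan <- config$plan %||% null_effect_plan()
  n_cn <- config$n_cn; n_pd <- config$n_pd
  if (is.null(n_cn) || is.null(n_pd) || n_cn < 1L || n_pd < 1L) {
    stop("config must give positive group sizes n_cn and n_pd")
  }
  if (materialize == "full") {
    if (is.null(out_dir)) stop("out_dir required to materialize audio")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  manifest <- list(); truth <- list()
  for (di in seq_along(datasets)) {
    ds <- datasets[di]
    for (task in tasks) {
      planted <- plant_effects(plan, base_subject_params(), task)
      set.seed(stream_seed(seed, di * 1000L + match(task, c("SS", "RP", "TDU"))))
      cn <- draw_subject_params(planted, n_cn, "CN", prefix = paste0(ds, "_CN"))
      pd <- draw_subject_params(planted, n_pd, "PD", prefix = paste0(ds, "_PD"))
      subj <- dplyr::bind_rows(cn, pd)
      if (anyDuplicated(subj$subject_id)) stop("duplicate subject ids")
      subj$dataset <- ds; subj$task <- task
      truth[[length(truth) + 1L]] <- subj
      for (i in seq_len(nrow(subj))) {
        stem <- sprintf("%s_%s", subj$subject_id[i], task)
        audio_path <- file.path(ds, paste0(stem, ".wav"))
        tr_path <- file.path(ds, paste0(stem, ".conllu"))
        if (materialize == "full") {
          set.seed(stream_seed(seed, di * 1e6L + match(task, tasks) * 1e5L + i))
          rec <- synthesize_recording(
            subj[i, ], task = task,
            speech_target = config$speech_target %||% subj$speech_total[i],
            checklist = config$checklist
          )
          dir.create(file.path(out_dir, ds), showWarnings = FALSE)
          write_wav(rec$wave, file.path(out_dir, audio_path))
          write_conllu(rec$transcript, file.path(out_dir, tr_path))
        }
        manifest[[length(manifest) + 1L]] <- tibble::tibble(
          subject_id = subj$subject_id[i], group = subj$group[i],
          dataset = ds, task = task,
          audio_path = audio_path, transcript_path = tr_path,
          updrs3 = subj$updrs3[i], updrs3_1 = subj$updrs3_1[i],
          hy = subj$hy[i]
        )
      }
    }
  }
  manifest <- dplyr::bind_rows(manifest)
  truth <- dplyr::bind_rows(truth)
  if (materialize == "full") {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         digits = NA)
  }
  list(manifest = manifest, truth = truth, config = config, out_dir = out_dir)
}

# deterministic per-stream seed below 2^31
stream_seed <- function(seed, counter) {
  (as.numeric(seed) * 48271 + as.numeric(counter) * 16807) %% 2147483647
}

#' Simulate a biomarker table directly from an effect plan
#'
#' The parametric fast path of the generator: biomarker values are drawn
#' from plausible population distributions with the planted group shifts
#' and severity links applied at the biomarker level, with no audio or
#' transcript synthesis. The pause percentage and pause-speech ratio are
#' computed from the simulated speech and pause times (not drawn
#' independently), preserving their rank identity. Each task emits only the
#' biomarkers defined for it (linguistic and informational-unit biomarkers
#' in spontaneous speech only, mirroring the extraction pipeline).
#'
#' @param plan An [effect_plan()].
#' @param datasets Character vector of dataset names.
#' @param n_cn,n_pd Group sizes per dataset.
#' @param tasks Task classes to emit.
#' @param seed Integer seed.
#' @return A list: `table` (long biomarker tibble) and `metadata`
#'   (subject_id, group, dataset, severity scores).
#' @export
simulate_biomarker_table <- function(plan, datasets = "synthA", n_cn = 40,
                                     n_pd = 40, tasks = c("SS", "RP", "TDU"),
                                     seed = 1) {
  eb <- reference_expected_behavior()
  levels <- biomarker_population_levels()
  tables <- list(); metas <- list()
  for (di in seq_along(datasets)) {
    ds <- datasets[di]
    set.seed(stream_seed(seed, di))
    n <- n_cn + n_pd
    group <- rep(c("CN", "PD"), c(n_cn, n_pd))
    sid <- sprintf("%s_%s%03d", ds, group, c(seq_len(n_cn), seq_len(n_pd)))
    z_sev <- stats::rnorm(n)   # latent severity (used for PD rows)
    metas[[di]] <- tibble::tibble(
      subject_id = sid, group = group, dataset = ds,
      updrs3 = ifelse(group == "PD", round(pmin(pmax(25 + 10 * z_sev, 3), 80)), NA),
      updrs3_1 = ifelse(group == "PD", round(pmin(pmax(1.2 + 0.8 * z_sev, 0), 4)), NA),
      hy = ifelse(group == "PD", pmin(pmax(round((2.3 + 0.5 * z_sev) * 2) / 2, 1), 5), NA)
    )
    for (task in tasks) {
      emit <- unique(eb$biomarker[eb$task_class %in% c(task, "All")])
      direct <- setdiff(emit, c("SILPERC", "SILSPRAT"))
      vals <- list()
      for (bm in direct) {
        lv <- levels[levels$biomarker == bm, ]
        entry <- plan[plan$biomarker == bm &
                      plan$task_class %in% c(task, "All") &
                      plan$direction != "null", , drop = FALSE]
        shift <- 0; link <- 0
        if (nrow(entry)) {
          entry <- entry[which.max(entry$magnitude), ]
          shift <- ifelse(entry$direction == "up", 1, -1) * entry$magnitude
          link <- entry$severity_link
        }
        r <- rho_to_pearson(link)
        z <- ifelse(group == "PD",
                    r * z_sev + sqrt(1 - r^2) * stats::rnorm(n),
                    stats::rnorm(n))
        mu <- lv$mean + ifelse(group == "PD", shift, 0) * lv$sd
        vals[[bm]] <- pmax(lv$min, mu + lv$sd * z)
      }
      if (all(c("SILPERC", "SILSPRAT") %in% emit)) {
        vals$SILPERC <- 100 * vals$SILTIME / (vals$SPTIME + vals$SILTIME)
        vals$SILSPRAT <- vals$SILTIME / vals$SPTIME
      }
      tables[[length(tables) + 1L]] <- tidyr::pivot_longer(
        tibble::as_tibble(c(list(subject_id = sid, dataset = ds, task = task),
                            vals)),
        cols = -c("subject_id", "dataset", "task"),
        names_to = "biomarker", values_to = "value")
    }
  }
  list(table = dplyr::bind_rows(tables), metadata = dplyr::bind_rows(metas))
}

# plausible population levels for the direct biomarker simulation
biomarker_population_levels <- function() {
  tibble::tribble(
    ~biomarker, ~mean, ~sd,  ~min,
    "F0STD",    25,    8,    0.5,
    "F1STD",    120,   30,   5,
    "INTSTD",   4,     1.2,  0.2,
    "SPTIME",   20,    5,    2,
    "SILTIME",  8,     2.5,  0.3,
    "SILDUR",   0.6,   0.2,  0.05,
    "SILVAR",   0.15,  0.06, 0.005,
    "WORDCNT",  110,   25,   5,
    "WORDLEN",  4.5,   0.5,  1,
    "SENTCNT",  12,    3,    1,
    "SENTLEN",  9,     1.5,  2,
    "NOUNCNT",  24,    6,    0,
    "VERBCNT",  16,    4,    0,
    "ADJCNT",   8,     3,    0,
    "ADVCNT",   7,     3,    0,
    "NUMCNT",   2,     1,    0,
    "AUXCNT",   6,     2,    0,
    "NPCNT",    30,    7,    0,
    "VPCNT",    15,    4,    0,
    "PPCNT",    12,    4,    0,
    "IU",       9,     2,    0,
    "RHYSTD",   0.35,  0.1,  0.01
  )
}
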