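test_that("effect plans are validated", {
  expect_s3_class(effect_plan("F0STD", "All", "down", 1), "effect_plan")
  expect_error(effect_plan("BOGUS", "All", "down", 1), "unknown biomarker")
  expect_error(effect_plan("F0STD", "All", "null", 1), "magnitude 0")
  expect_error(effect_plan("F0STD", "All", "down", -1), "nonnegative")
  expect_error(effect_plan("F0STD", "All", "down", 1, 1.5), "severity_link")
  expect_error(effect_plan("F0STD", "Weird", "down", 1), "task_class")
})

test_that("plant_effects shifts the mapped parameter in the stated direction", {
  plan <- effect_plan(c("F0STD", "SILDUR"), "All", c("down", "up"), c(1, 2),
                      c(-0.5, 0.5))
  planted <- plant_effects(plan)
  f0 <- planted[planted$param == "f0_sd", ]
  expect_equal(f0$mean_pd, f0$mean - 1 * f0$sd)
  expect_equal(f0$severity_link, -0.5)
  pl <- planted[planted$param == "pause_log_mean", ]
  expect_equal(pl$mean_pd, pl$mean + 2 * pl$sd)
  # unplanted parameters unchanged
  wr <- planted[planted$param == "word_rate", ]
  expect_equal(wr$mean_pd, wr$mean)
  expect_equal(wr$severity_link, 0)
})

test_that("when several biomarkers share a parameter the largest magnitude wins", {
  plan <- effect_plan(c("SILTIME", "SILPERC"), "All", "up", c(0.5, 2))
  planted <- plant_effects(plan)
  pr <- planted[planted$param == "pause_rate", ]
  expect_equal(pr$shift_sd, 2)
})

test_that("task-specific plan rows apply only to their task class", {
  plan <- effect_plan("SPTIME", c("SS", "RP"), c("down", "up"), 1.5)
  ss <- plant_effects(plan, task = "SS")
  rp <- plant_effects(plan, task = "RP")
  expect_equal(ss$shift_sd[ss$param == "speech_total"], -1.5)
  expect_equal(rp$shift_sd[rp$param == "speech_total"], 1.5)
})

test_that("drawn parameters respect bounds and severity exists for PD only", {
  planted <- plant_effects(default_effect_plan())
  set.seed(31)
  cn <- draw_subject_params(planted, 25, "CN")
  pd <- draw_subject_params(planted, 25, "PD")
  expect_true(all(is.na(cn$updrs3)))
  expect_true(all(!is.na(pd$updrs3)))
  expect_true(all(pd$hy >= 1 & pd$hy <= 5))
  for (j in seq_len(nrow(planted))) {
    p <- planted$param[j]
    expect_true(all(cn[[p]] >= planted$min[j] & cn[[p]] <= planted$max[j]),
                label = p)
  }
  expect_error(draw_subject_params(planted, 0, "CN"), "at least 1")
})

test_that("the severity link realizes its target Spearman correlation", {
  # planted up-shift on mean pause duration with rank link 0.6: over many
  # draws of 200 PD subjects the mean sample Spearman lands within 0.1
  plan <- effect_plan("SILDUR", "All", "up", 1, 0.6)
  planted <- plant_effects(plan)
  rhos <- vapply(1:50, function(s) {
    set.seed(s)
    pd <- draw_subject_params(planted, 200, "PD")
    cor(pd$pause_log_mean, pd$updrs3, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos) - 0.6), 0.1)
})

test_that("synthesized recordings honor feasibility checks", {
  p <- baseline_params()
  p$speech_total <- 0.5
  expect_error(synthesize_recording(p), "exceed 1 s")
  p2 <- baseline_params()
  p2$pause_rate <- 3
  p2$pause_log_mean <- log(2)
  expect_error(synthesize_recording(p2), "infeasible pause")
})

test_that("a no-pause configuration yields near-zero extracted pause time", {
  p <- baseline_params()
  p$pause_rate <- 1e-9
  set.seed(9)
  rec <- synthesize_recording(p)
  pf <- pause_features(detect_speech_pauses(rec$wave))
  # only the 2 x 0.25 s lead-in/out edge silences remain
  expect_lt(pf$SILTIME, 1)
})

test_that("a planted mean pause duration is recovered downstream within 15%", {
  p <- baseline_params()
  p$pause_log_sd <- 0.3
  p$pause_log_mean <- log(0.8) - 0.3^2 / 2     # lognormal mean 0.8 s
  p$pause_rate <- 0.8
  p$speech_total <- 30
  set.seed(7)
  rec <- synthesize_recording(p)
  seg <- detect_speech_pauses(rec$wave)
  expect_gte(sum(seg$label == "pause"), 20)
  pf <- pause_features(seg)
  expect_lt(abs(pf$SILDUR - 0.8) / 0.8, 0.15)
})

test_that("transcripts from synthesis are valid and carry time anchors", {
  p <- baseline_params()
  p$speech_total <- 8
  cl <- read_iu_checklist(system.file("extdata", "iu_checklist_picture_en.json",
                                      package = "robustmark"))
  set.seed(33)
  rec <- synthesize_recording(p, checklist = cl)
  t <- rec$transcript
  expect_s3_class(t, "transcript")
  expect_true(all(diff(t$tokens$start_time) > 0))
  expect_true(all(t$tokens$end_time <= wave_duration(rec$wave)))
  expect_false(is.null(t$phrases))
  iu <- informational_units(t, cl)
  expect_gte(iu, 0)
  expect_lte(iu, length(cl$items))
})

test_that("cohort manifests are deterministic in the seed", {
  config <- list(datasets = c("A", "B"), n_cn = 5, n_pd = 5,
                 tasks = c("SS", "RP"), plan = null_effect_plan())
  a <- generate_cohort(config, seed = 77, materialize = "manifest")
  b <- generate_cohort(config, seed = 77, materialize = "manifest")
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(config, seed = 78, materialize = "manifest")
  expect_false(identical(a$truth, c$truth))
})

test_that("manifest covers every dataset, subject, and task", {
  config <- list(datasets = paste0("D", 1:6), n_cn = 20, n_pd = 20,
                 tasks = c("SS", "RP", "TDU"), plan = null_effect_plan())
  out <- generate_cohort(config, seed = 5, materialize = "manifest")
  expect_equal(nrow(out$manifest), 6 * 40 * 3)
  expect_false(anyDuplicated(
    out$manifest[, c("subject_id", "task")]) > 0)
  expect_error(generate_cohort(list(datasets = "D", n_cn = 0, n_pd = 5),
                               seed = 1, materialize = "manifest"),
               "positive group sizes")
})

test_that("simulated biomarker tables express planted shifts and null plans do not", {
  plan <- effect_plan("F0STD", "All", "down", 1.5)
  sim <- simulate_biomarker_table(plan, n_cn = 150, n_pd = 150,
                                  tasks = "SS", seed = 9)
  df <- dplyr::inner_join(sim$table, sim$metadata[, c("subject_id", "group")],
                          by = "subject_id")
  f0 <- df[df$biomarker == "F0STD", ]
  expect_lt(mean(f0$value[f0$group == "PD"]), mean(f0$value[f0$group == "CN"]))

  null_sim <- simulate_biomarker_table(null_effect_plan(), n_cn = 150,
                                       n_pd = 150, tasks = "SS", seed = 9)
  nd <- dplyr::inner_join(null_sim$table,
                          null_sim$metadata[, c("subject_id", "group")],
                          by = "subject_id")
  nf0 <- nd[nd$biomarker == "F0STD", ]
  gap <- abs(mean(nf0$value[nf0$group == "PD"]) -
             mean(nf0$value[nf0$group == "CN"]))
  expect_lt(gap, 3 * 8 * sqrt(2 / 150))   # 3 SEs of the group-mean difference

  # derived pause ratios preserve their rank identity
  wide <- tidyr::pivot_wider(sim$table, names_from = "biomarker",
                             values_from = "value")
  expect_equal(rank(wide$SILPERC), rank(wide$SILSPRAT))
})

test_that("task classes emit the correct biomarker sets", {
  sim <- simulate_biomarker_table(null_effect_plan(), n_cn = 5, n_pd = 5,
                                  tasks = c("SS", "RP"), seed = 2)
  ss <- unique(sim$table$biomarker[sim$table$task == "SS"])
  rp <- unique(sim$table$biomarker[sim$table$task == "RP"])
  expect_true(all(c("WORDCNT", "IU", "RHYSTD") %in% ss))
  expect_false(any(c("WORDCNT", "IU") %in% rp))
  expect_true(all(c("F0STD", "SPTIME", "RHYSTD") %in% rp))
})
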