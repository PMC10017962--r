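# robustmark

Language-robust speech and language biomarkers for Parkinson's disease.

## The problem

Parkinson's disease changes the way people speak — pitch and loudness become
monotonous (hypokinetic dysarthria), pauses multiply and lengthen, narratives
shrink and simplify. Each of these changes can be quantified from a recording
and its transcript as an *interpretable biomarker*: a single number a
clinician can read (pitch variability in Hz, total pause time in seconds,
noun count). But a biomarker measured in one clinic, language, and elicitation
protocol often fails to transfer to another. The question this package
operationalizes is: **which biomarkers discriminate PD from controls
consistently across language cohorts, with a consistent direction of change,
and coherent correlations with clinical severity?**

`robustmark` implements the full evaluation pipeline:

1. **Extraction.** From 16 kHz mono audio: pitch (F0), intensity, and
   first-formant (F1) contours, and an energy-based voice-activity
   segmentation yielding nine acoustic biomarkers (F0STD, F1STD, INTSTD,
   SPTIME, SILTIME, SILPERC, SILSPRAT, SILDUR, SILVAR). From time-aligned
   CoNLL-U transcripts: thirteen linguistic biomarkers (word/sentence counts
   and lengths, POS counts, NP/VP/PP phrase counts) and two cognitive
   biomarkers (RHYSTD, the SD of inter-word-onset intervals; IU, checklist
   informational units for picture descriptions).
2. **Statistics.** Per dataset, task, and biomarker: Kruskal–Wallis tests
   with tie correction, Benjamini–Hochberg FDR control *within each biomarker
   family* (acoustic / linguistic / cognitive), H-based effect sizes
   η² = (H − k + 1)/(n − k), orientation-free AUROC, the observed direction
   of the PD shift, and Spearman correlations with clinical severity scales
   (UPDRS-III, its speech item, Hoehn & Yahr) on PD subjects.
3. **Adjudication.** A biomarker is *robust* when, in some task class
   (spontaneous speech, read passage, or text-dependent utterances):
   it is significant in ≥ 2 distinct datasets; every significant result moves
   in the expected direction; and every significant severity correlation has
   the coherent sign.
4. **Synthesis.** Because clinical speech corpora are restricted, the package
   ships a synthetic two-group cohort generator with *plantable effects*:
   an `effect_plan()` states which biomarkers shift, how far (in
   between-subject SDs), and how strongly they track severity, and the
   generator emits WAV audio, annotated CoNLL-U transcripts, and ground-truth
   parameters, so the whole pipeline can be validated end to end.

## Worked example

Simulate three cohorts with the default pathological effect plan, analyze,
and adjudicate:

```r
library(robustmark)
library(dplyr)

sim <- simulate_biomarker_table(
  default_effect_plan(),          # expected PD shifts at magnitude 1.2 SD
  datasets = c("cohortA", "cohortB", "cohortC"),
  n_cn = 40, n_pd = 40, seed = 42
)
analysis <- run_analyze(sim$table, sim$metadata)
analysis
#> <biomarker_analysis: 132 tests (122 significant at FDR 0.05), 396 correlations (325 significant), 24/24 biomarkers robust>

tidy(analysis) |> filter(biomarker == "SILDUR", task == "SS")
#> # A tibble: 3 × 14
#>   dataset task  biomarker family    n_cn  n_pd     H          p OB     eta2
#>   <chr>   <chr> <chr>     <chr>    <int> <int> <dbl>      <dbl> <chr> <dbl>
#> 1 cohortA SS    SILDUR    acoustic    40    40  18.8 0.0000149  up    0.228
#> 2 cohortB SS    SILDUR    acoustic    40    40  22.4 0.00000220 up    0.275
#> 3 cohortC SS    SILDUR    acoustic    40    40  23.8 0.00000107 up    0.292
#> # ℹ 4 more variables: auroc <dbl>, p_adj <dbl>, significant <lgl>, robust <lgl>
```

`autoplot(analysis)` draws the per-dataset effect sizes;
`plot_biomarker_distributions(sim$table, sim$metadata)` draws the group
boxplots; `write_analysis(analysis, "out/")` serializes everything.

For a *full* end-to-end run — audio synthesis, WAV/CoNLL-U files on disk,
feature extraction — replace the fast parametric simulation with:

```r
config <- list(datasets = c("A", "B"), n_cn = 10, n_pd = 10, tasks = "SS",
               plan = default_effect_plan(),
               checklist = read_iu_checklist(system.file(
                 "extdata", "iu_checklist_picture_en.json",
                 package = "robustmark")))
cohort <- generate_cohort(config, seed = 1, out_dir = "cohort/")
table <- run_extract(cohort$manifest, root = "cohort/",
                     checklist = config$checklist)
analysis <- run_analyze(table, cohort$manifest)
```

## The reference study fixture

The package ships a machine-readable encoding of the significant results of a
published six-cohort multilingual PD speech study (American English,
Castilian Spanish, Colombian Spanish, Italian, German, Czech) in
`inst/extdata/`. Applying the adjudication rule to it reproduces the
published verdicts exactly:

```r
ref <- reference_results()
adjudicate_robustness(ref$tests, ref$correlations, ref$expected)
#> Robustness verdicts: 19 biomarkers adjudicated, 13 robust
#> robust: AUXCNT, F0STD, NOUNCNT, NPCNT, RHYSTD, SENTCNT, SILDUR, SILPERC, SILSPRAT, SILTIME, SILVAR, SPTIME, WORDCNT

count_significant_biomarkers(ref$tests)
#> # A tibble: 6 × 2
#>   dataset    n_significant
#>   <chr>              <int>
#> 1 NLS                    9
#> 2 GermanPD              15
#> 3 Neurovoz              13
#> 4 ItalianPVS             9
#> 5 CzechPD                7
#> 6 GITA                   4
```

## Documentation

The methods vignette (`vignettes/methods.Rmd`) documents the generative
model, every extractor's numerical choices, the statistical conventions, and
the adjudication semantics, with the rationale for each design decision.
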