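# rhythmshift

Simulation and analysis of a **temporal-shift detection** paradigm for
speech rhythm research. Listeners hear an intact sentence ("Ready Charlie
go to white six now"), then two versions in which "white six" is replaced
by silence: one gap has the correct duration *T*, the other is shortened to
*T*(1 − ΔT/T) or lengthened to *T*(1 + ΔT/T), so the final word resumes
early or late. Thresholds for detecting the shift are tracked adaptively,
with the sentence's early rhythm either intact or altered by frame-wise
sinusoidal time warping. Comparing conditions measures how much listeners
rely on speech rhythm to predict the timing of upcoming words — and whether
that reliance differs between young and older adults.

The package is aimed at auditory psychophysicists who want the complete
paradigm as auditable, testable code. It provides:

* **Rhythm warping** — each 50-ms frame of the early region is rescaled by
  `1 + m sin(2π f t + φ)` (depth *m* = 0.75; *f* = 1 or 3 cycles; φ ∈
  {kπ/4}), with total duration conserved exactly; works on abstract
  schedules and on sampled audio (mono WAV I/O included).
* **Trial assembly** — three-interval trials with randomized comparison
  order, 400–800 ms ISI jitter, a shared warp schedule within each trial,
  and synthetic word stand-ins (AM noise bursts).
* **Adaptive tracking** — interleaved 2-down/1-up staircases (start 1.0
  early / 1.5 late; bounds [0,1] / [0,2]; step = ½ the gap deviation until
  the second reversal, then ¼), thresholds from the mean of the last four
  reversals, averaged over three 40-trial blocks.
* **A generative observer** — Gaussian temporal-expectancy imprecision
  σ = σ_base × (rhythm penalty if altered) × (asymmetry if late), 2AFC
  probability `p = 0.5 + (0.5 − λ/2)·erf(d′/2)`, with closed-form 70.7%
  points; cohort sampling with between-subject spread and simulated
  GAP/S&C/RD/WM covariates.
* **Statistics** — difference scores, paired *t* with Cohen's *d*, Pearson
  *r*, and the 2 × 3 × 2 split-plot ANOVA with Greenhouse–Geisser
  correction and partial η².

See `vignettes/rhythmshift-methods.Rmd` for the model, the calibration of
the simulated cohorts, and every numerical convention.

## Worked example

Simulate the default cohort (11 young, 10 older listeners) and analyze it:

```sh
Rscript analysis/01_simulate.R 1     # master seed 1
Rscript analysis/02_analyze.R
Rscript analysis/03_replicates.R     # 100-cohort pattern study (~2 min)
Rscript analysis/04_figures.R
```

The first script prints the group mean thresholds (ΔT/T, lower = better):

```
      unaltered_early unaltered_late low_rate_early low_rate_late
older           0.329          0.397          0.368         0.591
young           0.241          0.332          0.262         0.457
      high_rate_early high_rate_late mean_threshold late_early rhythm_diff
older           0.434          0.381          0.417      0.079       0.081
young           0.304          0.413          0.335      0.131       0.073
```

and the second the inferential summary:

```
 older: unaltered 0.363 vs altered 0.443 (rhythm-alteration cost present)
 young: unaltered 0.286 vs altered 0.359 (rhythm-alteration cost present)
 young_early_vs_late: t = -9.40, p = 0.0000 -> direction asymmetry
 older_early_vs_late: t = -1.32, p = 0.2179 -> no reliable asymmetry
```

Both groups detect shifts better with intact rhythm (the rhythm main effect
in this run: GG-corrected p = 0.0021, partial η² = 0.29), young simulated
listeners are better with early than late onsets, and older ones (built
with asymmetry 1) show no reliable direction effect. Across 100 cohort
replicates the pattern rates are written to `results/pattern_rates.csv`
(young asymmetry significant in 97% of cohorts, older non-significant in
82%, rhythm-alteration cost in every aggregate).

Interactive use mirrors the scripts:

```r
library(rhythmshift)
run <- run_full_pipeline(experiment_config(seed = 1), cohort_spec())
run$analysis$anova
```

## Layout

```
R/                  package code: warping, trials, staircase, observer,
                    statistics, pipeline/config
analysis/01..04     numbered workflow drivers (simulate, analyze,
                    replicates, figures); outputs under results/
tests/testthat/     unit, property and end-to-end suites with independent
                    oracles
scripts/acceptance.R
inst/extdata/       default experiment config (YAML) and a synthetic
                    Audacity-style label file
vignettes/          methods vignette
```
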