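# hygrosense

Analysis pipeline for **quantitative sensory testing (QST) of skin wetness
perception** — the psychophysical assessment of how well a person senses
moisture on their skin. Skin has no humidity receptors: wetness is inferred
centrally from thermal and tactile cues, and the sense can degrade in
neurological disease. The package targets researchers running wet-probe QST
protocols (e.g. in multiple sclerosis cohorts) who need individual-patient
normative profiling alongside classical group statistics.

## What it computes

**Individual hygrosensory profiles.** A patient's wetness rating *x* (mm on
a 0–100 visual analog scale) for a given skin site and stimulus quality is
log-transformed and standardized against a pooled healthy-control normative
sample:

    z = (log10(x + 1) − mean_ctrl) / sd_ctrl

with `LOSS` declared for z < −1.96, `GAIN` for z > +1.96 (the two-sided 95 %
normative band), and per-patient abnormality patterns summarized across
sites and qualities.

**Body temperature processing.** Whole-body mean skin temperature as the
fixed-weight six-site sum

    T̄sk = 0.14·cheek + 0.19·chest + 0.11·forearm + 0.05·hand + 0.32·thigh + 0.19·back

averaged over the analysis window (final 15 min of a 50-min exposure), with
paired session contrasts and t-based 95 % CIs.

**Group statistics.** A from-first-principles two-way mixed-design ANOVA
(between group × within mode/session) with Greenhouse–Geisser corrected
degrees of freedom, percent-of-total-variation effect sizes, Tukey HSD post
hocs on a numerically integrated studentized-range distribution, Sidak
adjustment, Kolmogorov–Smirnov normality screening, and noncentral-F sample
size calculation.

**Synthetic cohorts.** A seeded generator drawing mean-calibrated
truncated-normal VAS ratings and analytically controlled temperature
traces, with injectable sensory-loss participants, so the whole chain is
testable end to end without any external data.

## Worked example

The individual-level tables of the 12-patient MS study cohort ship with the
package. Classifying the published z-scores with the strict ±1.96 rule:

```r
library(hygrosense)

w <- ms_wetness_table()   # 72 cells: 12 patients x 2 sites x 3 qualities
prof <- tibble::tibble(
  participant_id = w$participant_id, site = w$site, quality = w$quality,
  raw_value = w$wetness_mm, z = w$z, label = classify_z(w$z)
)
summarize_abnormalities(prof, group_size = 12)
#> <abnormality_summary>
#>   flagged 3 of 12 assessed (25%): 1, 10, 2
```

Three patients — IDs 1, 2 and 10, i.e. 25 % of the cohort — have at least
one cell below the normative 95 % band, reproducing the study's abnormality
summary (7 LOSS cells in total, z down to −16.47).

End to end on synthetic data — generate a cohort with one injected
loss participant, build normative references from the 51 controls, and
profile:

```r
inj <- loss_injections("MS07", "FINGER_PAD", "COLD_WET")
cfg <- simulation_config(seed = 2026, n_ms = 12, n_ctr = 51, injections = inj)
d <- generate_cohort(cfg, include_temperatures = FALSE)
refs <- normative_from_ratings(d)   # pooled CTR dynamic thermoneutral cells
prof <- profile_cohort(d, refs[grepl("FOREHEAD|FINGER_PAD", names(refs))])
subset(prof, participant_id == "MS07")
#>   participant_id       site     quality raw_value     z  label
#> 1           MS07 FINGER_PAD    COLD_WET      1.76 -9.49   LOSS
#> 2           MS07 FINGER_PAD NEUTRAL_WET     85.74  1.45 NORMAL
#> 3           MS07 FINGER_PAD    WARM_WET     26.13 -1.22 NORMAL
#> 4           MS07   FOREHEAD    COLD_WET     73.82  0.93 NORMAL
#> 5           MS07   FOREHEAD NEUTRAL_WET     17.62 -0.79 NORMAL
#> 6           MS07   FOREHEAD    WARM_WET     37.89  0.16 NORMAL
```

The injected cell is recovered at z = −9.49 while the participant's other
cells stay normal. (Healthy participants can still show isolated flags —
a per-cell 95 % band flags ~5 % of cells by design; see the methods
vignette, `vignettes/hygrosensory-profiling.Rmd`, for why per-participant
false-flag rates are structurally higher.)

A thin command-line front end covers the same stages
(`inst/cli/hygro.R`): `simulate`, `tsk`, `profile`, `anova`, `report` and
`run` subcommands over CSV/YAML files.

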