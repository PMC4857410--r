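# latereturn

When should an HIV clinic start tracing a patient who has missed a visit?
Patients on antiretroviral therapy (ART) collect a 2-, 4-, 8- or 12-week
drug supply at each visit, so every visit implies an expected return date
(visit date + 7 days per supply week). Most late patients come back on
their own within a few weeks; tracing them prematurely wastes scarce
outreach capacity, while waiting too long leaves truly lost patients
without drugs. `latereturn` derives a **clinical-management
lost-to-follow-up (LTFU) cut-off** — the weeks-late value at which
spontaneous return has become unlikely enough that tracing should begin —
from ordinary visit-level program data.

## Method

Every follow-up visit at which the patient returned ≥ 7 days after the
expected date (or never returned) is a *late episode*, with outcome the
weeks-late interval of the eventual return, k = floor(days late / 7).
Over weeks k = 1…26 the package estimates, with n_k episodes still
unreturned and d_k returning in week k:

- the discrete **hazard of return** h_k = d_k / n_k — of those still out,
  the share coming back this week;
- the **CDF of return** F_k = 1 − Π_{j≤k}(1 − h_j), the complement of the
  product-limit survival curve, with 95% intervals from **Greenwood's
  variance** v_k = S_k² Σ d_j / {n_j(n_j − d_j)};
- the **conditional one-week return proportion** among those still out
  who will eventually return.

Because episodes are only included when at least 12 months of potential
follow-up remain, there is no interior censoring: the product-limit CDF
equals the plain cumulative fraction, and the package asserts that
identity on every run. An explicit rule (`select_cutoff()`) then replaces
the traditional visual appraisal of the curves: recommend the earliest
week from which the hazard stays below a threshold (default 10%) for a
sustained run and through the rest of the table, tolerating isolated
blips below twice the threshold; a CDF-plateau variant and a sensitivity
scan over the rule's parameters are always reported alongside.

A synthetic cohort generator (`simulate_cohort()`) reproduces the
program's visit process — refill-cycle schedules, an ~17% late share,
late-return delays with modes at the 4- and 8-week refill cycles, a 30%
never-return share, and a small contamination of unrecorded early deaths
— with closed-form truth (`true_cdf()`), so the entire analysis runs and
is calibrated end to end without any patient data.

## Worked example

The numbered scripts under `analysis/` run the full study on a synthetic
cohort (each step reads the previous step's files under `results/`):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_filter_episodes.R
Rscript analysis/03_estimate_curves.R
Rscript analysis/04_select_cutoff.R
```

Output of the run at the committed seed:

```
Simulated 5000 patients with 45463 visits (seed 20070101).
Truth: 70% of late episodes eventually return; delay modes at weeks 4 and 8.

3993 of 45463 candidate visits remain as late episodes (2531 patients; median 1, max 6 episodes each).

By 4 weeks late 47.7% of late episodes had returned; by 9 weeks 69.8%; by 26 weeks 69.9%.
Hazard spikes at the refill cycles: week 4 = 19.2%, week 8 = 17.6% (neighbouring weeks 13.1%/13.4% and 8.8%/9.5%).
Of late patients still out at week 4 who will eventually return, 35.9% return that week.

With true late-return mass confined to weeks 1-8, the rule recommends week 9 in 200/200 replicates.
```

Reading the numbers: nearly half of late returners are back within 4
weeks; the CDF is flat between weeks 9 and 26 (69.8% → 69.9%), i.e.
essentially everyone who will return has done so by 9 weeks; and the
hazard shows the two refill-cycle spikes. The final line is the
structural result: when true return mass stops at the longest refill
cycle (week 8), the formal rule recovers a ≥ 9-weeks-late cut-off
essentially always. On the default cohort itself the jittered 8-week
mode leaves real return mass at week 9, so the headline recommendation
is seed-dependent and flagged `stable = FALSE` — the rule reporting
genuine ambiguity rather than hiding it (see the methods vignette).

The same analysis runs as one call on your own flat files:

```r
library(latereturn)
res <- run_pipeline(
  patients = read_patient_table("patients.csv"),
  visits   = read_visit_table("visits.csv"),
  config   = lateness_config(study_start = "2007-01-01", study_end = "2010-06-30"),
  out_dir  = "out"
)
res$cutoff
```

which writes `weekly_table.csv`, `filter_log.csv`, `cutoff.json`, CDF and
hazard plots, and a `report.md` whose numbers are rendered from those
artifacts.

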