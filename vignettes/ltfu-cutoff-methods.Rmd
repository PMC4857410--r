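---
title: "Deriving a clinical-management LTFU cut-off from weekly return curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving a clinical-management LTFU cut-off from weekly return curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latereturn)
```

## The problem

Patients on antiretroviral therapy (ART) collect a multi-week drug supply
at every clinic visit, so each visit carries an implicit appointment: the
visit date plus seven days per week of supply. When a patient does not
come back, the clinic must eventually decide that they are lost to
follow-up (LTFU) and start tracing — phone calls, then home visits.
Trace too early and scarce outreach effort is spent on people who would
have returned on their own; trace too late and patients who have run out
of drugs go unfound for months. The question this package answers is
operational: **after how many weeks of lateness has spontaneous return
become unlikely enough that tracing should begin?**

The analysis reframes that question as time-to-event estimation in which
the event is *returning to care*. Every follow-up visit at which the
patient was at least 7 days late defines an episode; the episode's
outcome is the week interval in which the patient came back (week $k$
covers days $7k$ to $7k+6$), or never. Seven days is the lateness
convention used for adherence monitoring in the Malawi national
guidelines, and the analysis is visit-level on purpose: the clinician's
decision is about *this* missed appointment, so a patient contributes one
episode per qualifying late visit and no clustering adjustment is made.

## Estimators

Let $n_k$ be the number of episodes still unreturned at the start of
week-late interval $k$ and $d_k$ the number returning during it. The
discrete hazard, product-limit survival and return CDF are

$$h_k = d_k / n_k, \qquad
  S_k = \prod_{j \le k} (1 - h_j), \qquad
  F_k = 1 - S_k,$$

with Greenwood's variance
$v_k = S_k^2 \sum_{j\le k} d_j / \{n_j (n_j - d_j)\}$ and a plain normal
interval $F_k \pm z_{1-\alpha/2}\sqrt{v_k}$, clamped to $[0,1]$. The
package deliberately avoids the log-log transformed interval by default
(it is the kind of refinement that breaks the method's main virtue —
every number here can be recomputed in a spreadsheet); the normal
interval's calibration is checked empirically below rather than assumed.

Two design facts make the discrete estimator exact rather than
approximate:

* **No interior censoring.** Episodes enter the analysis only if their
  expected return date precedes the study end by at least 12 months.
  Observation therefore always spans more than the 26 tabulated weeks, so
  a never-returner is genuinely at risk through week 26, the risk set
  follows $n_{k+1} = n_k - d_k$, and the product-limit CDF collapses to
  the empirical cumulative fraction $\sum_{j \le k} d_j / n_1$. The
  implementation computes both and *asserts* their equality on every
  call, so any future change that silently breaks the no-censoring
  argument fails loudly.
* **Pooled right tail.** Returns after week 26 stay in every risk set;
  ">= 26 weeks late" is the final category rather than a censoring time.

When every remaining episode returns in some week ($n_j = d_j$), the
Greenwood sum's term is infinite: the variance is flagged degenerate and
the interval collapses to the point $F_k$ (which is then exactly 1).
Weeks with an empty risk set carry a zero hazard and a `zero_risk` flag
rather than a `NaN`.

Two return proportions are reported side by side because the curves'
consumers ask two different questions. $F_k$ is the proportion of *all*
late episodes back by week $k$. The conditional one-week proportion
$d_k / \#\{\text{returners with return week} \ge k\}$ — among those still
out *who will eventually return*, the share coming back this week — is
what a clinic weighing "wait one more week?" actually needs; it equals
$h_k$ exactly when nobody is a never-returner and exceeds it otherwise.

## Formalizing the cut-off

Published practice picks the cut-off by visual appraisal of the curves.
The package replaces the eyeball with an explicit rule whose parameters
are honest about the judgement involved:

* **hazard_drop** (default): the earliest week $k \ge$ `min_week` from
  which $h_j < \theta$ holds for `run_length` consecutive weeks *and*
  through the rest of the table, tolerating isolated single-week blips
  below $2\theta$. The tail condition is what distinguishes a genuine
  collapse of return rates from the lull between two refill-cycle spikes.
* **cdf_plateau**: the earliest week from which the CDF's increment
  relative to the outstanding mass, $(F_{k+1}-F_k)/(1-F_k)$, stays below
  $\theta$ for `run_length` weeks. This is the "curve flattens" reading;
  it has no look-ahead, so on spiky hazards it will stop at a pre-spike
  lull where the hazard rule keeps scanning. Both answers are always
  reported; the `method` field only chooses the headline.

Defaults are $\theta = 0.10$, `run_length` 2, `min_week` 2. They were
chosen so that a hazard sequence shaped like the program data — spikes at
the 4- and 8-week refill cycles, collapse from week 9 — yields week 9.
`min_week` exists because the week-1 bin is often quiet for a mechanical
reason (day-level granularity of returns) and "trace everyone at 1 week"
is never an intended reading. Because $\theta$ is ultimately a judgement,
`select_cutoff()` reports whether a $\pm 20\%$ change of $\theta$ moves
the answer (`stable`), and `sensitivity_scan()` maps the full
$(\theta, m)$ grid. A table satisfying the rule nowhere returns an
explicit no-cut-off state, never a silent default.

## The synthetic cohort generator

No patient-level program data can be shipped, so the generator produces
cohorts with the structure the estimators assume, plus closed-form truth
(`true_cdf()`) for calibration studies. Its defaults are the package's
statement of the study conditions:

* **Visit schedule**: 2-week first refill, 4-week (monthly) refills
  through 6 months on ART, then 8- or 12-week refills (probability 0.3 of
  the longer one). Schedules cascade from *actual* return dates, as they
  do in a clinic.
* **`p_on_time` = 0.83**: the share of follow-up returns under 7 days
  late, matching the program's observation that roughly 17% of follow-up
  visits are at least a week late.
* **Late-delay mixture**: weight 0.5 on a geometric (weekly) drift-back
  with success 0.45, and weights 0.3/0.2 on refill-cycle modes at 4 and 8
  weeks, each spread $\pm 1$ week with probabilities (0.25, 0.5, 0.25).
  Within a drawn week, the day is uniform. Delay mass beyond week 25
  folds onto week 25, keeping the truth strictly inside the 26-week
  table so the CDF's asymptote identifies the never-return share.
* **`p_never_given_late` = 0.30**: the never-return share among late
  episodes, giving a CDF asymptote of 0.70.
* **Unascertained deaths**: with probability `p_death_early` = 0.01 a
  patient dies within 90 days of starting ART *and* that death surfaces
  only as an unexplained never-return; it is recorded in the register
  (and thus excluded by the filters) only with `p_known_outcome` = 0.3.
  This parameter is deliberately narrow — it is not total early
  mortality, most of which occurs before any follow-up visit or is
  eventually recorded, but the residual contamination of the analyzable
  episode set. It is kept small because the package's own calibration
  studies show the whole-curve Greenwood-band recovery criterion sits at
  its attainable boundary even for an unbiased estimator (weekly CDF
  errors are nearly perfectly correlated across weeks, so pointwise 95%
  bands give only ~90% whole-curve coverage); any larger unlabelled
  contamination makes the estimated curve measurably — and by design,
  *reportably* — biased below the truth. The residual bias at the
  default (~0.004 on $F_{26}$ at 5000 patients) keeps the
  LTFU-overestimation phenomenon present and measurable against the
  truth record without drowning the calibration checks.

What the generator does *not* emulate: site-level heterogeneity, secular
drift in refill policy, seasonal clinic closures, and any dependence of
return behaviour on age or time on ART. Passing calibration tests
therefore demonstrates that the estimators and the rule do what they
claim under the stated generative structure — not that any particular
program's data looks like this.

## What the calibration studies check

The test suite and `scripts/acceptance.R` recompute, from scratch:

* agreement of the weekly product-limit estimates with hand-enumerated
  small cohorts and with an independent survival-analysis implementation
  (to $10^{-9}$);
* the product-limit/empirical-fraction identity on every generated
  cohort;
* empirical coverage of the 95% Greenwood interval for $F_9$ over 1000
  cohorts of 500 episodes (nominal within [93%, 97%]);
* recovery, at 5000 patients through the *full* pipeline (simulate,
  filter, estimate), of the hazard modes at weeks 4 and 8, the
  never-return mass from the CDF asymptote, and the closed-form truth
  within the Greenwood band;
* cut-off recovery: when the true late-return mass is confined to weeks
  1–8 (nothing after the longest refill cycle), the rule recommends week
  9 — in 200/200 replicates of 2000 episodes at the defaults.

On the *default* cohort, by contrast, the jittered 8-week mode leaves
genuine return mass at week 9, so the estimated week-9 hazard hovers
near $\theta$ and the headline recommendation legitimately varies with
the seed (weeks 6–10, `stable = FALSE`). This is the rule reporting real
ambiguity in an ambiguous shape, and it is why the structural
recovery experiment — not the single default cohort — carries the
week-9 claim.

Problem sizes in the routine suite (50-replicate studies at 5000
patients; 1000 coverage replicates at 500 episodes; 200 recovery
replicates at 2000 episodes) were chosen so each study's Monte-Carlo
error is comfortably inside the asserted margins.

## Numerical and degenerate-input choices

* Dates are ISO-8601 in files and day-precision `Date`s internally;
  weeks are `floor(days/7)` with negative lateness mapped to week 0.
* Duplicate visits (same patient, same day) collapse to the larger
  supply: the conservative direction, since a longer expected gap flags
  fewer false "late" returns.
* The plateau rule's strict inequality carries a $10^{-9}$ guard so an
  increment exactly at $\theta$ never counts as flat regardless of
  floating-point rounding direction.
* Empty episode sets are an error with advice, not an empty table; empty
  *weekly* tables write header-only CSVs that round-trip.
* All randomness flows from a single integer seed; equal seeds give
  byte-identical artifacts.

## Known limitations

Death is not modelled as a competing risk, so everything labelled
"never returned" mixes true disengagement with unascertained death, and
the estimated never-return mass is an upper bound on true LTFU; the
generator makes this bias reproducible rather than hiding it. The
12-month minimum window trades recency for exactness: the most recent
year of visits never enters the analysis. The cut-off rule formalizes
one reading of "returns decreased substantially"; the sensitivity scan
is part of the method precisely because that reading is contestable.
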