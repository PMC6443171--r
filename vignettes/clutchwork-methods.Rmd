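---
title: "Clutch schedules, cohort rounds and the independence null model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clutch schedules, cohort rounds and the independence null model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clutchwork)
```

## The problem

Glossiphoniid leeches of the genus *Helobdella* are simultaneous
hermaphrodites with heavy parental investment: zygotes are deposited in
cocoons on the parental venter, brooded, and carried to the first
feedings. Several species are self-fertile, so a single animal reared in
isolation yields a complete, directly observed reproductive life history:
its birth day (day 0, the day it was itself deposited as a zygote), the
day and embryo count of every clutch it lays, and its death day. Species
that only reproduce by cross-fertilization must instead be followed as
interbreeding cohorts, where clutches cannot be attributed to parents and
per-individual schedules have to be *inferred*.

`clutchwork` implements the full analysis chain for both observation
modes:

1. summary statistics of individual clutch schedules (per-clutch-number
   sizes, generation time and inter-clutch intervals, reproductive
   capacity);
2. the quota counting rule that partitions a cohort's anonymous clutches
   into reproductive rounds, plus its diagnostics;
3. pseudo-cohorts (pooled, anonymized individual records) for validating
   the rule against known ground truth;
4. a seeded Monte Carlo simulator of reproductive schedules under an
   independence null model, with parameters estimated from records,
   inferred rounds, or published summary tables;
5. a synthetic ground-truth generator so every stage is testable without
   raw colony records.

## Data model and conventions

Days are non-negative integers (colonies were checked daily) counted from
day 0 = the focal animals' own zygote deposition. Three conventions are
applied everywhere and are worth stating once:

* **Day of death.** An animal whose death is recorded on day *d* was seen
  at that day's check, so it counts as *present* on day *d*:
  `alive(d) = n0 - #{death_day < d}`.
* **Censoring.** An animal alive (or lost) when recording ended has
  `death_day = NA`. Censored animals contribute to capacity totals (their
  totals are lower bounds) but are excluded from lifespan and
  post-last-clutch survival means.
* **Ties.** Clutches recorded on the same day keep their input order;
  every sort is stable. This matters only when a round boundary falls
  inside a same-day batch.

## Individual statistics

For records $i = 1..N$ with clutch days $d_{i1} < d_{i2} < \dots$ and
sizes $s_{ik}$:

* `clutch_number_stats()` reports, per clutch index $k$, the count of
  individuals possessing a $k$-th clutch and the mean, sample sd
  ($n-1$ denominator; reported absent when $n = 1$), min and max of
  $s_{ik}$.
* `interval_stats()` reports the generation time ZD-C1 (distribution of
  $d_{i1}$) and, for each transition, the *cumulative* day of the later
  clutch over the individuals possessing it, together with `step_mean`,
  the mean of the per-individual differences $d_{i,k+1} - d_{ik}$.
  Published interval tables print a step column that matches
  per-individual pairing rather than the difference of cumulative means;
  with heterogeneous drop-out the two genuinely differ, and only the
  per-individual definition is computable from records, so that is what
  the package reports.
* `reproductive_capacity()` is the per-individual lifetime embryo total
  (mean, max, grand total), plus clutches per individual, lifespan, and
  post-last-clutch survival. `capacity_from_stats()` reconstructs the
  mean capacity from a summary table as
  $\sum_k n_k \bar s_k / N$ — exactly the identity that links a
  per-clutch-number table to the capacity figures quoted alongside it,
  and an internal conservation check
  (`capacity_from_stats(clutch_number_stats(R), N)` equals the direct
  computation).

## The round counting rule

For a cohort the only usable assumptions are that animals reared
together breed in rough synchrony and that all of them reproduce. The
rule (`assign_rounds()`): the first round opens with the first clutch;
its quota is the number of animals alive on that opening day; the next
quota clutches (in day order) close the round; each subsequent round
opens with the next unassigned clutch. A trailing round with fewer
clutches than its quota is reported with `complete = FALSE` rather than
discarded — a lone final clutch is still evidence of a further round.

The rule's documented failure modes are reproducible with the synthetic
generator:

* an animal that dies after a round opens but before laying inflates the
  quota, so the round artifactually absorbs clutches of the next round
  (`inject_deaths()` + `misassignment_rate()` measure exactly this);
* when the temporal spread of laying approaches the gap between rounds,
  boundary clutches are exchanged between adjacent rounds. The five-day
  deposition histogram (`bin_depositions()`, half-open bins `[0,5)`,
  `[5,10)`, ...) is the diagnostic for judging whether gaps exist at all.

`round_summaries()` attaches per-round means and Student-t confidence
intervals, $\bar x \pm t_{n-1,\,1-\alpha/2}\, s/\sqrt n$, for both
deposition day and clutch size, omitted for singleton rounds. The t
interval is a deliberate, documented choice: the source material reports
95% intervals without stating a method, and rounded table moments cannot
reproduce its printed intervals consistently, so the package states its
method rather than fitting one.

## The Monte Carlo model

`simulate_individual()` draws one animal's schedule under independence:

1. clutch count $m$ from a categorical distribution;
2. first clutch day from the generation-time distribution `zd_c1`;
3. each later day by adding a per-transition inter-clutch interval
   (rounded, at least 1 day);
4. each clutch size from its per-index distribution (rounded, at least 1
   embryo);
5. death at the last clutch day plus a post-last-clutch survival draw,
   or from the lifespan distribution when $m = 0$.

Each metric is a `dist_spec` — the (mean, sd, min, max) quadruple that
life-history tables report. Cohorts (`simulate_cohort()`) are $n$
independent draws pooled and anonymized: there is **no interaction
between individuals**. That is the point of the model: it is the null
against which the observed tight, cohort-wide clustering of laying bouts
can be compared (via `compare_report()`'s per-round day spread and
clustering index). Because inter-clutch intervals accumulate variance
round after round, the null model cannot maintain tight clustering
beyond the first round — parameter sets estimated from isolated animals
reproduce pseudo-cohort behaviour, not true-cohort behaviour. The
package deliberately ships no coordination model; inventing one would go
beyond what the data define.

### Sampling law

A `dist_spec`'s four numbers describe data that lie *inside* the stated
range, so the sampler should reproduce the stated mean and sd while
respecting the bounds. Three laws are available in `draw_dist()`:

* `"calibrated"` (default): a winsorized normal whose underlying
  $(\mu, \sigma)$ are solved numerically (closed-form clamped-normal
  moments + Nelder-Mead) so that the clamped draw attains the stated
  mean and sd. Rationale: with bounds asymmetric about the mean, both
  rejection truncation and naive clamping shift the realized mean — for
  a spec like (140, 25.8) on [120, 180] rejection truncation inflates
  the mean by more than 6 days, which would misstate the very quantity
  the parameter encodes.
* `"clamp"`: normal(mean, sd) winsorized as-is.
* `"reject"`: normal(mean, sd) truncated by rejection — the textbook
  alternative, kept for comparison.

Two caveats are documented rather than hidden. First, winsorizing puts
point masses on the bounds; for strongly asymmetric specs the shape is
crude, but the first two moments and the range — all the information the
tables carry — are honoured. Second, a *sample* sd computed with the
$n-1$ denominator from very few points can exceed what any distribution
on the given range attains (e.g. two points always give
$\mathrm{sd} = \mathrm{range}/\sqrt2$, above the attainable maximum of
range/2); the calibrator then returns the closest attainable pair and
records it in the `attained` attribute.

### Parameter sets

* `estimate_params_from_individuals()`: sample moments of each metric,
  empirical clutch-count distribution.
* `estimate_params_from_cohort()`: runs the round inference first;
  generation time from round-1 days; interval $k$ mean as the difference
  of adjacent round day means with sd pooled from the two rounds' day
  spreads ($\sqrt{(s_k^2+s_{k+1}^2)/2}$ — with anonymous clutches,
  per-individual pairing is unknowable, so the between-round spread is
  the only available estimate); clutch sizes per round; clutch counts
  from round-to-round attrition of clutch numbers.
* `make_params(preset)`: parameters populated verbatim from the five
  published summary blocks (`hro_isolated`, `hro_cohort`,
  `hau_cohort23`, `hau_cohort60`, `hoc_isolated`). Three derivations are
  needed because summary tables do not print everything a generative
  model needs:
  * *inter-clutch step sds* — tables print cumulative sds only; the step
    sd is taken as $\sqrt{s_{k+1}^2 - s_k^2}$ (exact if steps were
    independent of the earlier cumulative time), falling back to the
    smaller adjacent cumulative sd where the printed values make the
    difference non-positive. Steps are bounded below at 1 day and
    unbounded above.
  * *clutch-count distribution* — from the attrition of the
    sample-size column: $P(m = k) \propto \max(S_k - S_{k+1}, 0)$.
    Observed S columns are occasionally non-monotone (a known
    inconsistency of such tables); negative differences are clipped.
  * *post-last-clutch survival* — anchored to the block's reported mean
    lifespan where one is stated (mean = lifespan − expected last-clutch
    day, sd = half the mean, floor 0); for cohort blocks, to the
    reported survival after the final clutch (e.g. last death 34 days
    after the last clutch, or "well over 100 days" for the other
    species). These choices affect only death days, not any clutch-
    timing or capacity quantity.

### Reproducibility

Every stochastic entry point takes a seed. Individual $i$ of run $r$
draws from a substream seeded by a fixed integer mix of
$(\mathrm{seed}, r, i)$, so enlarging `n` or `runs` extends a simulation
without reshuffling the animals already drawn, and identical inputs give
identical event logs on any platform. `run_replicates()` (default 100
runs, matching the replicate count of the original simulation study)
pools all simulated individuals and reports mean, sd, min, max and a
Student-t 95% interval per metric.

## The synthetic ground-truth generator

`generate_dataset()` simulates records under a chosen parameter set,
keeps the true per-clutch indices (under the independence null the true
round of a clutch *is* its index), and emits the anonymized cohort log
plus all files in the package's CSV/JSON formats. It emulates the
structure of real colony records — roughly normal per-index interval and
size distributions inside observed bounds, a categorical clutch count,
post-last-clutch survival, anonymization — and deliberately does *not*
emulate mate interaction, coordinated timing, diet effects, or
back-estimated laying dates (records carry an `estimated` flag but no
correction model). Tests that pass on synthetic data therefore validate
the *machinery* (statistics, inference rule, estimators, conservation
laws), not the biological fidelity of the null model — whose failure to
reproduce cohort clustering is, again, the scientific point.

Default study conditions used in the test suite mirror the study's
designs: 16 isolated individuals (up to 8 clutches), cohorts of 23/48/60,
100 simulation runs. Convergence checks use 5 000 simulated individuals;
moment-recovery assertions use 3-standard-error bounds at 1 600+ draws.

## Numerical choices and limitations

* Statistics are carried at full precision; any rounding (1 decimal for
  sizes/intervals, whole embryos for capacities) is display-only.
* Draws are rounded to whole days/embryos after bounding; intervals are
  at least 1 day, sizes at least 1 embryo, days at least 0.
* A cohort log whose every animal has died before a clutch day is
  invalid; `assign_rounds()` still guards quotas at a minimum of 1 so a
  malformed log cannot stall the scan (validation flags it instead).
* The round rule is implemented strictly; the "gap-based" alternative
  reading of ambiguous cohorts is supported only as a diagnostic (the
  deposition histogram), not as a second inference mode.
* No hypothesis tests between species or conditions are provided; the
  source analyses report none, and `compare_report()` intentionally
  returns a table without verdicts.
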