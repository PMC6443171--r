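# clutchwork

Reproductive life-history analysis for iteroparous, brooding
hermaphrodites — written for the *Helobdella* leech system, usable for
any organism observed as dated, counted clutch events.

Leeches of this genus deposit zygotes into cocoons in discrete clutches.
Self-fertile species can be reared in isolation, giving fully attributed
schedules: birth (day 0 = the animal's own deposition as a zygote),
every clutch's day and embryo count, and death. Obligately
cross-fertilizing species must be followed as interbreeding cohorts, in
which clutches are anonymous and per-individual behaviour has to be
inferred. `clutchwork` implements both sides and the machinery to
compare them:

* **Individual statistics** — per-clutch-number size distributions,
  generation time (ZD-C1) and inter-clutch intervals, and reproductive
  capacity: for records $i$ with clutch sizes $s_{ik}$, the mean
  capacity is $\sum_k n_k \bar s_k / N$, reconstructible from a summary
  table alone (`capacity_from_stats()`).
* **Cohort round inference** — the quota counting rule: a reproductive
  round opens at the first unassigned clutch, its quota is the number of
  animals alive that day, and the next quota clutches close it
  (`assign_rounds()`), with per-round Student-t 95% intervals
  (`round_summaries()`), survival/production series, and five-day
  deposition histograms.
* **Pseudo-cohorts** — pooled, anonymized individual records with ground
  truth attached (`build_pseudo_cohort()`), so the counting rule's error
  modes can be measured (`misassignment_rate()`, `inject_deaths()`).
* **A Monte Carlo null model** — independent simulated individuals
  (`simulate_cohort()`, `run_replicates()`): clutch count ~ categorical,
  clutch days by summed interval draws, each metric a (mean, sd, min,
  max) spec sampled by a moment-calibrated winsorized normal. Parameters
  come from records, inferred rounds, or built-in published summary
  blocks (`make_params("hro_isolated")`, ...).
* **A synthetic ground-truth generator** (`generate_dataset()`) so the
  whole pipeline is testable without raw colony records.

See `vignettes/clutchwork-methods.Rmd` for the model, conventions and
numerical choices.

## Worked example

Simulate a colony of 16 isolated animals from the built-in
self-fertilizing *H. robusta* summary block, compute its tables, then
pool it into a pseudo-cohort and infer rounds:

```r
library(clutchwork)
ds <- generate_dataset(make_params("hro_isolated"), n = 16, seed = 7)

interval_stats(ds$records)
#>   label  n cum_mean    cum_sd cum_min cum_max step_mean
#> 1 ZD-C1 16  54.8750  6.810531      46      67        NA
#> 2 C1-C2 16  82.8750 12.284814      64     106  28.00000
#> 3 C2-C3 16 106.2500 14.097281      78     132  23.37500
#> ...

reproductive_capacity(ds$records)
#> <capacity_summary> 16 individual(s): mean 304.2, max 469, total 4867
#>   embryos; 5.50 clutches/individual

log <- build_pseudo_cohort(ds$records)
asg <- assign_rounds(log)
round_summaries(asg, log)[, 1:7]
#>   round  n quota complete day_mean day_lo day_hi
#> 1     1 16    16     TRUE    54.69  51.23  58.14
#> 2     2 16    16     TRUE    80.56  75.63  85.50
#> 3     3 16    16     TRUE   108.31 102.95 113.68
#> ...

misassignment_rate(asg, ds$truth$true_round)
#> [1] 0.3068182
```

The interval table is the simulated analogue of a published
generation-time/interval block (ZD-C1 mean 54.9 d here vs the 56.3 d
the parameters encode); capacity is the lifetime embryo total per
animal. The misassignment rate shows the counting rule mislabelling ~31%
of clutches once individual schedules drift apart in later rounds — the
rule is reliable only while rounds stay separated, which is exactly what
real interbreeding cohorts (but not independent individuals) maintain.

Replicate summaries pool individuals over 100 seeded runs:

```r
rr <- run_replicates(make_params("hro_isolated"), n = 16, runs = 100, seed = 7)
subset(as.data.frame(rr), metric %in% c("zd_c1", "interval_all"))
#>         metric    n  mean     sd min max  ci_lo  ci_hi
#> 1        zd_c1 1600  56.5   8.56  37  68  56.08  56.92
#> 6 interval_all 7571  29.7  12.49   1 123  29.42  29.98
```

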