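# dietheart

Resampling re-analysis tools for the diet–heart hypothesis: does
replacing saturated dietary fat lower serum cholesterol, and does lower
cholesterol reduce cardiovascular (CVD) mortality?

The package targets analysts who want fully nonparametric alternatives
to the *t*-test and the Cox model for this class of data:

1. **Scenario 1 — permutation test.** Statistic
   `t = |mean(diet % change) − mean(control % change)|`; null built by
   relabelling the pooled changes into pseudo-arms;
   `p = (1/N) Σ 1{t_n ≥ t}`. Exhaustive enumeration replaces Monte-Carlo
   sampling automatically when the assignment space is small.
2. **Scenario 2 — bootstrap rank test on hazards.** Within one trial
   arm, participants split by the sign of their cholesterol change; each
   subgroup's cause-specific CVD hazard is summarised by the
   time-averaged Nelson–Aalen estimate `H(τ)/τ`; the null for the
   subgroup difference comes from resampling the pooled arm with
   replacement; two-tailed `p = (1/N) Σ 1{|h_n| ≥ |h|}`.
3. **Scenario 3 — binned bootstrap-CI comparison.** If the
   cholesterol–DBP Pearson correlation passes a screen (default
   |corr| ≥ 0.1), the cohort is stratified into 10-mmHg diastolic
   blood-pressure bins; per bin, a percentile-bootstrap CI of the mean
   cholesterol of all members is compared against the mean cholesterol
   of the bin's CVD cases, flagging bins where the case mean falls
   outside the interval.

Because the underlying participant-level studies cannot be
redistributed, the package ships calibrated synthetic-cohort generators:
a trial-style cohort (1179 diet / 1176 control, 4.5-year follow-up,
exponential event times) and an observational-style cohort (n = 3840,
bivariate-normal cholesterol/DBP with correlation 0.33, Bernoulli CVD
flag with a cholesterol effect active only for DBP in [60, 100] mmHg).
See `vignette source in vignettes/dietheart-methods.Rmd` for the models,
the hazard calibration, and known limitations of the flagging rule.

## Worked example

```r
library(dietheart)

cohort <- generate_mce(mce_config(seed = 1))
table(cohort$arm)
#> control    diet
#>    1176    1179

run_scenario1(cohort, n_perm = 2500, seed = 2)
#> Permutation test of mean percent cholesterol change
#>   arms: diet n=1179, control n=1176
#>   observed |mean difference|: 13.324 percentage points
#>   null rounds: 2500 (Monte-Carlo)
#>   empirical p-value: 0

run_scenario2(cohort, arm = "control", n_boot = 5000, seed = 3)
#> Bootstrap rank test of CVD hazards (control arm)
#>   subgroups: decrease n=640, increase n=536; tau = 4.500 y
#>   observed hazard difference: 0.1060 per year
#>   null iterations: 5000 (bootstrap)
#>   two-tailed p-value: 0

run_scenario2(cohort, arm = "diet", n_boot = 5000, seed = 3)
#> Bootstrap rank test of CVD hazards (diet arm)
#>   subgroups: decrease n=1014, increase n=165; tau = 4.500 y
#>   observed hazard difference: 0.0679 per year
#>   null iterations: 5000 (bootstrap)
#>   two-tailed p-value: 0.0048
```

The diet-arm test is intrinsically borderline at the calibrated
generator defaults (the observed difference sits about 1.8 null SDs
out), so its decision at the 0.05 level varies across generator seeds —
the replicate above rejects; many others do not. The control-arm test
rejects essentially always.

```r
fhs <- generate_fhs(fhs_config(seed = 4))
run_scenario3(fhs, seed = 5)
#> Binned bootstrap-CI A/B test (cholesterol vs CVD across DBP strata)
#>   cholesterol-DBP correlation: 0.333 (screen passed)
#>   95% population-mean CIs from 5000 bootstrap resamples per bin
#>          bin n_all n_cvd mean_all ci_low ci_high mean_cvd associated insufficient
#> 1        <40     1     0    173.0  173.0   173.0       NA         NA         TRUE
#> 2    [40,50)    15     5    189.6  162.8   218.9    172.7      FALSE         TRUE
#> 3    [50,60)    95    24    208.7  200.8   217.2    195.5       TRUE        FALSE
#> 4    [60,70)   482   109    215.5  211.8   219.1    238.8       TRUE        FALSE
#> 5    [70,80)   962   238    226.1  223.4   228.8    249.5       TRUE        FALSE
#> 6    [80,90)  1238   346    237.7  235.3   240.0    259.4       TRUE        FALSE
#> 7   [90,100)   746   244    249.6  246.7   252.5    268.7       TRUE        FALSE
#> 8  [100,110)   262    72    263.2  258.4   268.1    261.1      FALSE        FALSE
#> 9  [110,120]    37     7    268.0  257.1   278.5    271.5      FALSE        FALSE
#> 10      >120     2     0    283.9  261.7   306.1       NA         NA         TRUE
```

All four bins fully inside the generator's [60, 100] mmHg effect window
are flagged; note the false flag in [50, 60): the rule compares a noisy
case mean against a CI that reflects only the population mean's
uncertainty, so its false-positive rate well exceeds 1 − level (about
0.26 at a 25% case fraction — derivation in the methods vignette).

Cohorts round-trip exactly through CSV (`write_cohort()` /
`read_cohort()`), whole runs are driven by `run_all(run_config(...))`
with a single master seed, and reports written by `write_report()` store
every simulated null sequence so each p-value is recomputable from the
report alone. A command-line front-end lives at `inst/cli/dietheart.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "dietheart.R", package = "dietheart"))')" \
  simulate-mce --out mce.csv --seed 1
```

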