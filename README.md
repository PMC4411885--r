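# twinEEA

Meta-analysis of whether identical (MZ) and fraternal (DZ) twin pairs are
equally exposed to childhood social adversity — the equal-environment
assumption (EEA) on which the classical twin method rests — plus the tools
to quantify what its violation does to twin-based heritability estimates.

The package ships a corpus of 11 twin studies (9119 pairs) that published
intraclass correlations (ICCs) for childhood adversities by zygosity: 24
MZ-vs-DZ pairs of ICCs spanning bullying, sexual abuse, physical
maltreatment, emotional abuse/neglect and general trauma. For audiences in
psychiatric epidemiology and behavior genetics it provides:

* **Fisher's two-correlation test** — each ICC is transformed to
  `r' = 0.5 * ln((1+r)/(1-r))` and zygosity groups compared with
  `z = (r'_MZ - r'_DZ) / sqrt(1/(n_MZ - 3) + 1/(n_DZ - 3))`, one-tailed.
* **Pair-count-weighted pooling** — construct- and moderator-level pooled
  correlations `sum(r_i * n_i) / sum(n_i)`, tested with unique pair counts.
* **ICC estimators** for pair-level data (double-entry Pearson, one-way
  ANOVA) and a **synthetic twin-corpus generator** for calibration and
  power studies.
* A **variance-components (ACE) bias model**: with environmental
  correlations `rho_MZ`/`rho_DZ`, the Falconer estimate `2*(r_MZ - r_DZ)`
  equals `h2 + 2*c2*(rho_MZ - rho_DZ)` — unequal environments inflate
  heritability by twice the shared-environment variance times the gap.

## Worked example

```r
library(twinEEA)

ds <- load_twin_dataset()          # packaged corpus
summary_counts(ds)
#> $n_comparisons        [1] 24
#> $n_nominal_higher_mz  [1] 23
#> $pct_nominal          [1] 96
#> $n_significant        [1] 16

analyze_constructs(ds)[, c("group_label", "weighted_r_mz", "weighted_r_dz",
                           "z_display", "p_display")]
#>               group_label weighted_r_mz weighted_r_dz z_display p_display
#> 1                bullying          0.67          0.39     10.13   <0.0001
#> 2            sexual_abuse          0.64          0.55      3.53    <0.001
#> 3   physical_maltreatment          0.68          0.55      5.87   <0.0001
#> 4 emotional_abuse_neglect          0.47          0.29      4.73   <0.0001
#> 5          general_trauma          0.58          0.41      4.60   <0.0001
```

Of the 24 comparisons, 23 (96%) are nominally more correlated in MZ pairs
and 16 reject the one-tailed test at 0.05 (`z > 1.645`); every adversity
construct rejects at `p < 0.001`. Exposures are *not* equally correlated
across zygosity — and doubling the bullying correlation difference the way
a twin study would:

```r
falconer_h2(0.67, 0.39)
#> [1] 0.56
```

i.e. the exposure data alone would present as "56% heritable", the scale of
artifact the EEA's violation can feed into twin heritability estimates.

The numbered scripts under `analysis/` run the full workflow: table
reproduction (`01`), simulation calibration of the pooled test and the ICC
estimators (`02`), and the Falconer-bias grid with its Monte-Carlo check
(`03`); outputs land under `results/`.

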