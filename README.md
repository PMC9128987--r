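# scrrobust

Robustness of analytic strategies for fear conditioning and extinction
skin conductance data.

## What this package is for

Human fear conditioning and extinction studies measure skin conductance
responses (SCRs, in micro-Siemens) to a threat cue (CS+) and a safety cue
(CS-) across acquisition and extinction trials, but analyse those data in
many different published ways: different trial subsets, averaged versus
trial-by-trial, differential (CS+ − CS-) versus two-stimulus models, and
different ANOVA interaction terms. For researchers studying this analytic
flexibility — and for anyone planning an SCR study who wants to know
whether their choice of analysis matters — `scrrobust` provides a complete
simulation framework:

1. **Generate** synthetic trial-level null populations (3 phases × 5 trials
   × 2 stimuli per participant) with subject-level random intercepts,
   differential conditioning during acquisition and decaying CS+
   responding across extinction.
2. **Bootstrap** datasets of any sample size, phase-wise (chimeric rows)
   or by whole participants, and allocate three equal random groups.
3. **Inject** (optionally) one of three trial-wise group-level effect
   schedules — offsets in per-trial SD units added to Group 3's CS+
   scores — emulating distinct conditioning/extinction phenotypes.
4. **Evaluate** fifteen published analytic strategies, each reduced to the
   partial eta squared of its highest-order Group interaction,

   ηp² = SS_effect / (SS_effect + SS_error),

   from a balanced split-plot ANOVA (Group between; Phase/Trial/Stimulus
   within, each term tested against its own subject-within-group error
   stratum).
5. **Quantify robustness** as Kendall τb rank correlations between the
   effect sizes any two strategies of the same category assign to the same
   bootstrapped datasets, with bootstrap means and 95% percentile CIs,
   Pearson trends across sample size with Benjamini–Hochberg FDR control
   (Q = 0.1), and the effect-size-inflation analysis (category-average ηp²
   versus sample size).

## Worked example

```r
library(scrrobust)

# a synthetic null population standing in for a pooled 379-participant sample
src <- generate_null_population(generator_config(n_participants = 379, seed = 42))
src
#> <scr_dataset> 379 participant(s), 30 cells each, unlabelled

# one bootstrapped "study" of N = 120 with an injected group effect
set.seed(42)
d <- bootstrap_dataset(src, 120)
d$group <- allocate_groups(120)
d <- inject_effect(d, builtin_schedule("base"))
head(evaluate_all(d))
#>          id category     eta_p2 n_subjects degenerate
#> 1 ACQ_EXT.1  ACQ_EXT 0.05633730        120      FALSE
#> 2 ACQ_EXT.2  ACQ_EXT 0.05977425        120      FALSE
#> 3 ACQ_EXT.3  ACQ_EXT 0.03317071        120      FALSE
#> 4 ACQ_EXT.4  ACQ_EXT 0.04845027        120      FALSE
#> 5     EXT.1      EXT 0.16607172        120      FALSE
#> 6     EXT.2      EXT 0.10090557        120      FALSE
```

Each row is one strategy's effect size for this dataset: e.g. the
acquisition-to-extinction strategies (ACQ_EXT) see a Phase×Group
interaction of ηp² ≈ 0.03–0.06, while the static-extinction strategy EXT.1
(Group×Stimulus on extinction trials 3–10) sees 0.17 — the spread across
strategies on the *same* data is the phenomenon under study.

```r
# a reduced robustness sweep (the defaults are 16 sizes x 100 resamples
# x 1000 CI bootstraps)
res <- size_sweep(src, resample_config(sizes = c(30, 120, 480),
                                       n_resamples = 50, n_ci_boot = 200,
                                       seed = 42))
subset(res$pairs, category == "ACQ_EXT" & size == 120)[, 3:7]
#>    strategy_a strategy_b      taub mean_taub    ci_low
#> 34  ACQ_EXT.1  ACQ_EXT.2 ... 0.6367195 0.5228339 ...
#> 35  ACQ_EXT.1  ACQ_EXT.3 ... 0.8111875 0.7443406 ...
#> 36  ACQ_EXT.1  ACQ_EXT.4 ... 0.3228596 0.1884903 ...
```

Strategies 1 and 3 (near-duplicates differing only in how many final
extinction trials they average) rank the 50 resampled datasets much more
consistently (mean τb = 0.81) than strategies 1 and 4 (τb = 0.32), which
nominally measure the same construct.

```r
est <- effect_size_trend(res)
est
#>   category          r            p n_points
#> 1  ACQ_EXT -0.4944041 1.275136e-10      150
#> 2      EXT -0.6116885 9.182639e-17      150
#> 3  EXT_EXT -0.4576665 3.905050e-09      150
attr(est, "by_size")
#>   category size   mean_eta2
#> 1  ACQ_EXT   30 0.066847927
#> 2  ACQ_EXT  120 0.018397880
#> 3  ACQ_EXT  480 0.003487531
#> ...
```

Under the null, the average ηp² of every strategy category *decreases*
sharply with sample size (≈ 0.067 at N = 30 versus ≈ 0.003 at N = 480):
small samples systematically inflate group-interaction effect sizes even
when no group effect exists.

File-based workflows mirror these functions: `cmd_generate()`,
`cmd_evaluate()` and `cmd_sweep()` write CSV reports plus a JSON manifest
from which every output is byte-reproducible;
`inst/scripts/scr-sweep.R` wraps them for shell use.

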