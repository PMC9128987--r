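---
title: "Methods: simulating the robustness of fear-extinction analytic strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating the robustness of fear-extinction analytic strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrrobust)
```

## The problem

Human fear conditioning studies index learning with skin conductance
responses (SCRs) to a threat cue (CS+) and a safety cue (CS-), but the
literature analyses these data in strikingly heterogeneous ways: different
trial subsets, different aggregation rules, differential (CS+ minus CS-)
versus two-stimulus models, and different ANOVA terms. `scrrobust`
implements a simulation framework for asking whether such analytic
flexibility matters, and whether larger samples help: it bootstraps
trial-level datasets across a sweep of sample sizes, optionally injects a
known group-level effect, evaluates fifteen published analytic strategies
as partial eta squared (\(\eta_p^2\)) effect sizes of their highest-order
Group interaction, and measures cross-strategy agreement as bootstrapped
Kendall \(\tau_b\) rank correlations.

The unit of analysis is a participant's **trial grid**: 3 phases
(acquisition, early extinction, late extinction) x 5 trials x 2 stimuli
= 30 non-negative responses in micro-Siemens. Ten extinction trials are
stored as two 5-trial phases because the paradigm separates them with an
instruction screen; strategies that need "extinction trials 1-10"
concatenate the blocks in order.

## The synthetic null population

The real pooled sample this design emulates is not publicly deposited, so
the package generates a synthetic stand-in. Each response is

\[ y_{i,c} = \max\!\big(0,\; a_i + \mu_c + \varepsilon_{i,c}\big), \qquad
   a_i \sim N(0, \sigma_s^2), \quad \varepsilon_{i,c} \sim N(0, \sigma_e^2), \]

with a single additive participant intercept \(a_i\) (the simplest
structure that induces the within-subject correlation the bootstrap design
assumes) and i.i.d. cell noise. The floor at zero reproduces the
zero-inflation typical of scored SCRs while keeping SD-unit effect
injection interpretable; we use a censored-normal rather than a lognormal
model because it makes the injected offsets exactly additive on the
response scale.

Defaults (chosen once as plausible values for scored first-interval SCRs,
documented as defaults rather than claims about any real dataset): CS-
cells flat at 0.3 uS; CS+ rising from 0.5 to 0.8 uS across acquisition,
then decaying monotonically to the CS- level by late extinction;
\(\sigma_s = 0.2\), \(\sigma_e = 0.25\) uS; 379 participants. Any
30-cell mean profile can be supplied via `generator_config()`.

Per-participant RNG substreams are derived deterministically from the
master seed, so increasing `n_participants` extends the population without
reshuffling earlier participants, and the generator is byte-reproducible.

What the generator does **not** emulate: between-study heterogeneity of the
pooled sample, habituation-induced variance changes across trials,
participant-specific conditioning slopes, and the skewness structure of
real SCR amplitudes beyond zero-censoring. Passing tests therefore show
that the *pipeline* behaves as designed under a realistic null, not that
any particular empirical robustness value generalises to real data.

## Simulated group-level effects

Three built-in schedules (`builtin_schedule("base" | "a" | "b")`) add
trial-wise offsets, in per-trial SD units, to Group 3's CS+ scores only,
emulating three conditioning/extinction phenotypes (high acquisition with
rapid extinction; moderate acquisition with rapid extinction; no early
extinction). Offsets are converted to micro-Siemens with the per-(phase,
trial) SD of CS+ responses over the **whole bootstrapped sample before
injection** — the only reference that makes the offset independent of the
random group allocation; a group-specific SD can be selected instead via
`compute_sd_reference(dataset, group = )`.

Two genuinely open choices were resolved as follows:

* **Standalone versus stacked variants.** Schedules "a" and "b" are applied
  to raw bootstrapped values, not on top of the "base" schedule; a
  three-variant design in which each run uses one schedule only makes
  sense with independent schedules. `inject_effect(stacked = TRUE)`
  exposes the alternative reading.
* **SD source.** The SD reference is recomputed from each bootstrapped
  dataset rather than from the source population, matching the resampling
  design in which every bootstrapped sample stands for a fresh study.

## The ANOVA engine

Every strategy reduces to a balanced design with one between-subjects
factor (Group, 3 levels here) and zero to two fully-crossed within-subject
factors. The engine implements the classical univariate split-plot
decomposition: Group is tested against the subject-within-group stratum,
and each within-effect and its Group interactions against the matching
within-factor x subject-within-group stratum. Partial eta squared is
\(SS_{\text{effect}} / (SS_{\text{effect}} + SS_{\text{error}})\) with the
error taken from the term's own stratum; no sphericity correction is
applied because \(\eta_p^2\) depends only on sums of squares.

Group sizes can differ by the allocation remainder (at most 1). For that
case the engine uses the sequential (hierarchical) weighted decomposition
within each stratum, which has three useful properties: it agrees exactly
with `aov(y ~ group*W + Error(subject/W))` for any group sizes, it
preserves exact sums-of-squares conservation per stratum, and it keeps the
two-group identity \(\eta_p^2 = t^2/(t^2 + df)\). Under exact balance it
coincides with the unweighted-means analysis. The test suite verifies
term-by-term equality with `aov` to 1e-9 on hundreds of random instances.

Zero error variance in a required stratum (e.g. an all-constant resample)
raises a classed condition (`scrrobust_degenerate`) rather than returning
`NaN`; the robustness loops catch it, record the strategy's value as
missing, and report per-size degenerate counts, so pathological
configurations are visible instead of silently absorbed.

Two catalogued strategies are not factorial: the last-trial differential
strategy is a one-way Group ANOVA, and the acquisition-versus-extinction
contrast strategy is mapped to a one-way Group ANOVA on per-subject
phase-difference scores (`group_contrast_eta()`) — the unique reduction of
a paired-contrast analysis to a group-level interaction effect size.

## The strategy catalogue

`builtin_strategies()` encodes the fifteen strategies in three categories:
four comparing acquisition to extinction (ACQ_EXT), seven static extinction
measures (EXT), and four early-versus-late extinction contrasts (EXT_EXT).
Because the source studies used different trial counts, fractional
trial-selection rules are resolved on this paradigm's 5 + 10 layout with
round-half-up: "last three-quarters" of 10 extinction trials = trials
3-10, quarters = 3 trials, halves = 5; "last half" of 5 acquisition trials
= trials 3-5. The running-average rule maps the five early-extinction
differentials to four pseudo-trials ((1,2), (2,3), (3,4), (4,5) averaged).
The maximum-response rule takes the per-subject maximum of the acquisition
*differential*, since that strategy analyses differential scores.

One structural fact the simulations surface: in a 2 x 2 within design the
Group x Phase x Stim contrast is algebraically identical to the
Group x Phase contrast on differential scores, so the two extinction-half
strategies that differ only in this respect always produce identical
\(\eta_p^2\). Their rank correlation is exactly 1 — a designed-in extreme
of the robustness continuum.

## Bootstrap, robustness and trends

`bootstrap_dataset()` implements two resampling modes. The default
*phase-wise* mode draws each of the six phase x stimulus trial blocks
independently across participants, producing chimeric rows; *full-row*
mode resamples whole participants and serves as the check that phase-wise
chimerism does not drive the conclusions. Groups are allocated equally
(sizes differ by at most 1, remainder to randomly chosen groups).

At each sample size, `strategy_effect_matrix()` produces an
`n_resamples` x 15 matrix of \(\eta_p^2\). For every within-category
strategy pair (6 + 21 + 6 = 33 pairs), `pairwise_robustness()` computes
Kendall \(\tau_b\) over the paired effect sizes and bootstraps the
`n_resamples` paired observations (default 1,000 times) for the mean
\(\tau_b\) and a 95% percentile interval (linear interpolation between
order statistics). Resampling the \(\tau_b\) inputs — rather than
re-running the whole pipeline inside the CI loop — treats the paired
effect sizes as the exchangeable unit, which is the only resampling unit
available once the matrix is fixed, and keeps the full 16-size sweep
computationally feasible.

`trend_analysis()` correlates each pair's per-size mean \(\tau_b\) with
sample size (Pearson, two-sided) and applies Benjamini-Hochberg FDR
control at Q = 0.1 within each category's family of pairs.
`effect_size_trend()` addresses effect-size inflation: it averages
\(\eta_p^2\) across the strategies of a category and correlates the
average with sample size. By default each bootstrapped dataset contributes
one point per category (`aggregate = "resample"`); this is the resolution
at which the decay of null \(\eta_p^2\) with sample size is statistically
detectable — with only one mean per size, a handful of points on a
hyperbolic decay cannot reach conventional significance regardless of how
real the effect is. `aggregate = "size"` provides the per-size-means
alternative.

Determinism: one substream per (size, resample) and per (size, pair) is
derived from the master seed, so partial sweeps, reordered sweeps and full
serial runs agree bit-for-bit, and every report is reproducible from its
manifest alone.

## Numerical choices and edge cases

* Responses are analysed raw (no log or range correction): the strategies
  under study are defined on scored SCRs.
* \(\tau_b\) uses the tie-corrected denominator
  \(\sqrt{(C+D+T_x)(C+D+T_y)}\) and raises an error when either input is
  entirely tied; degenerate resamples are pairwise-deleted with counts
  reported.
* Percentile CIs use quantile type 7 (interpolated order statistics).
* All SD computations use the n-1 denominator.
* Injection offsets are non-negative and CS+-only, so non-negativity of
  responses is preserved without re-flooring.

## Problem sizes used in the shipped checks

The packaged tests exercise the full pipeline at 100 resamples per size
over the six-point grid {30, 60, 120, 240, 480, 960} — the range over
which the published per-size supplementary tables are reported and
effect-size inflation is visible — with reduced CI bootstrap counts where
intervals are not the quantity under test. These sizes were chosen to make
the scientific claims (inflation, effect recovery, structural robustness
ordering) testable with clear margins; the full 16-size grid up to
N = 2000 with 1,000 CI bootstraps remains the user-facing default of
`resample_config()`.

## Known limitations

* The generator's null has no between-study heterogeneity and no
  participant-level conditioning-slope variance; real multi-study pools
  are likely noisier, so absolute \(\tau_b\) levels here should not be
  read as predictions for real data.
* Only the fifteen catalogued strategies are implemented; the analytic
  universe of the field is larger.
* \(\eta_p^2\) is the only effect size, and p-values with sphericity
  corrections are out of scope, because cross-strategy comparison is
  defined on raw sums of squares.
* The mixed ANOVA handles only the one-between design with at most the
  remainder imbalance; it is not a general unbalanced linear-model engine.
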