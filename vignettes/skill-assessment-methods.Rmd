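---
title: "Skill assessment methods for ecosystem model output"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skill assessment methods for ecosystem model output}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoskill)
```

## The problem

End-to-end marine ecosystem models simulate everything from nutrients and
plankton through fish, mammals and fisheries. Before such a model can
inform strategic management decisions, its *skill* — how well its output
reproduces the observed system — must be quantified, both over the
historical period it was tuned to (the hindcast) and over years it never
saw (the forecast). `ecoskill` implements that workflow for annual time
series of species biomass, fishery landings and derived ecosystem
indicators: metric computation, survey swept-area expansion, indicator
derivation, hindcast/forecast comparison, and metric-redundancy analysis,
plus a synthetic-ecosystem generator so the whole pipeline is testable
with known ground truth.

## Skill metrics

For an aligned pair of observed values $O_i$ and model predictions $P_i$
($i = 1 \dots n$, $n \ge 3$), with $\bar O$ the mean of the observations,
the package computes seven metrics:

* **AE** $= \frac1n \sum (O_i - P_i)$ — signed average error
  (observed minus predicted). Positive and negative errors cancel, so AE
  close to zero is necessary but not sufficient for good fit.
* **AAE** $= \frac1n \sum |O_i - P_i|$ and
  **RMSE** $= \sqrt{\frac1n \sum (O_i - P_i)^2}$ — accuracy measures;
  $|\mathrm{AE}| \le \mathrm{AAE} \le \mathrm{RMSE}$ always.
* **MEF** $= 1 - \sum (P_i - O_i)^2 / \sum (O_i - \bar O)^2$ — modeling
  efficiency (Nash–Sutcliffe). MEF $= 1$ is perfect; MEF $= 0$ means the
  model does exactly as well as predicting $\bar O$ every year, the one
  objective threshold in the suite; MEF $< 0$ is worse than that.
* **S, P, K** — Spearman (average ranks for ties), Pearson, and Kendall
  tau-b correlations, measuring precision (covariation) irrespective of
  scale.

The multiplicative reliability index is deliberately omitted: biomass and
landings series are z-scored before comparison and therefore contain
negative values for which its logarithm is undefined.

Undefined cells (constant observations for MEF, zero-variance vectors for
a correlation) are carried through every table as flagged-missing values
with the reason attached — never dropped, never coerced to zero.

## Normalization

Biomass and landings series are standardized — $(x - \bar x)/s$ with the
sample standard deviation, per series, over each series' **full**
non-missing record — before pairing, and separately for observed and
modeled sources. Full-record (rather than hindcast-only) statistics keep
hindcast and forecast metrics on a single scale; this is a documented
choice where either window would be defensible. Indicators are computed
from **raw** series (sums in tons, ratios dimensionless) because their
definitions depend on absolute magnitudes; the resulting indicator series
are then standardized before scoring so that all three data categories
share one dimensionless metric scale.

## Survey expansion

Observed biomass in the emulated world comes from a stratified trawl
survey. Per-stratum catch rates combine with area weights
$W_h = A_h / \sum A_h$ into a stratified mean $\sum W_h \bar y_h$ with
variance $\sum W_h^2 s_h^2 / n_h$ (no finite-population correction — tows
sweep a negligible area fraction). The mean scales to a swept-area biomass
estimate by the constant $qA/a$ (catchability $\times$ total area /
area swept per tow) and the variance by its square, with a 95% band of
$\pm 1.96$ standard deviations. The default $q = 1$ yields a *minimum*
biomass estimate. The constant multiplies as written; note the
conventional design-based estimator divides by $q$, but the two coincide
at the default $q = 1$ and $q$ is exposed as a plain parameter.

## Ecosystem indicators

Twenty-two aggregate indicators (see `indicator_registry()`) span system
totals, guild components (demersal vs pelagic), protected-species biomass,
trophic structure (biomass- and catch-weighted mean trophic level), ratios
to primary production, exploitation ratios, a depletion proportion and
catch value. Composition is driven entirely by the metadata table (guild,
`is_fish`, `is_commercial`, `is_tep`, trophic level, price), not by
hard-coded taxa. Two definitions require explicit choices:

* **Proportion overfished** has no reference point in common currency; the
  package uses a depletion proxy — mean biomass over the final
  `end_window` (default 3) years relative to the series maximum, below
  `depletion_threshold` (default 0.2) — with both knobs exposed. The
  annual indicator series applies the same relative-biomass test year by
  year.
* **Catch value** uses a static per-group price table (a single reference
  year's average prices); no deflation.

Indicator years are restricted to years where *every* required input
exists, so staggered data onsets (seals from 1981, whales from 1990,
satellite primary production from 1998) propagate honestly into observed
indicator coverage.

## Periods and the hindcast/forecast comparison

`define_periods()` returns the full hindcast 1964–2004, a no-spin-up
hindcast 1974–2004, four decadal windows, and the forecast 2005–2013.
The forecast bounds resolve an ambiguity (the calibration data end in
2004, observations in 2013); all bounds are arguments.

The comparison (`compare_hindcast_forecast()`) orientation-corrects every
metric to "larger is more skill" (MEF and correlations as-is, AAE and
RMSE negated, AE folded to $-|AE|$), then places each forecast cell at
its midrank empirical percentile within the hindcast values of the same
metric across all series of the same data category. Cells below the 40th
percentile are "worse", 40–60 "same", above 60 "better"; midranks make a
forecast equal to the hindcast median score exactly 50. The reference-set
construction is an explicit design choice (the underlying method leaves it
open) and is isolated in one function.

## Metric redundancy (PCA)

`pca_of_metrics()` arranges series × (metric, period) values — 14 columns
for two periods — drops incomplete rows and zero-variance columns, scales
columns to unit variance (metrics are incommensurate, so correlation
rather than covariance scaling), and decomposes by singular values.
Metrics whose loading vectors align are redundant: they order the series'
skill identically. Signs follow a deterministic convention (largest
loading per component positive), and tests verify agreement with a
brute-force eigendecomposition of the correlation matrix.

## The synthetic world

`generate_ecosystem()` emulates the structure of a data-rich shelf
ecosystem, not any particular one:

* 30 functional groups (default) across seven guilds; ~50 annual steps
  (1964–2013); hindcast/forecast split after 2004.
* Latent truth per group: logistic growth with harvest
  $B_{t+1} = (B_t + rB_t(1 - B_t/K_t) - hB_t)\,e^{\varepsilon_t}$.
  Fish and invertebrates get recruitment-scale process noise
  ($\sigma = 0.25$ on the log scale) and a multi-decadal environmental
  forcing of $K_t$ (log-amplitude 0.1–0.25, period 20–40 y); mammals get
  small process noise (0.05) and start depleted (10–30% of $K$), their
  signal being the slow recovery. These magnitudes were fixed while
  designing the generator so that latent signal and survey noise have
  realistic relative size; with a noise-free equilibrium world the
  observation error would dominate and no model, however faithful, could
  beat the observation-mean predictor.
* Observed biomass = truth × lognormal error (CV 0.3, typical of trawl
  surveys), with 95% bands attached through the swept-area expansion;
  observed landings = true catch × small reporting error, capped at true
  biomass.
* The model-skill knob: `high` = truth × small noise (0.10);
  `medium` = larger noise (0.30) plus a mild multiplicative drift;
  `noise_only` = an independently generated trajectory.
* Everything is a deterministic function of `(config, seed)`.

What a green test establishes — and what it does not: the generator
reproduces the *structure* of the real analysis (staggered onsets, paired
sources, guild composition, observation error) but none of the real
system's interactions (no trophic coupling between groups, no spatial
structure, no fleet dynamics). Green pipeline tests demonstrate the
machinery is correct and that skill levels propagate as designed; they say
nothing about any real model's skill.

### Window length and forecast comparisons

One subtlety the synthetic world makes visible: MEF computed over a short
window is systematically lower than over a long window of the same
autocorrelated process, because the within-window variance of the
observations (the MEF denominator) shrinks with window length while white
observation-error variance does not. A 9-year forecast therefore scores
below a 41-year hindcast even when model fidelity is identical. Skill
recovery tests accordingly compare the forecast against the
matched-length decadal hindcast window; pipeline users comparing windows
of different lengths should expect this bias and prefer the quantile
comparison, which ranks within, not across, periods.

## Numerical choices

* Minimum paired points $n = 3$ for any metric; fewer is an
  "insufficient overlap" error (rank correlation is meaningless below 3).
* Standardization requires sample sd $> 0$; constant series are a
  "degenerate series" error.
* Skill CSVs store values at full precision (`%.17g`) so round trips are
  bit-exact; flagged-missing cells serialize as empty fields.
* Percentile ties get midranks; the class boundary treats the interval
  [40, 60] as "same".
* PCA components beyond the matrix rank are not reported as meaningful;
  tests only compare well-defined leading components.

## Known limitations

* The generator has no interactions between groups; indicator dynamics
  are aggregates of independent populations.
* Prices and trophic levels are static.
* The depletion proxy behind "proportion overfished" is a convention, not
  a stock-assessment reference point.
* Quantile comparison requires at least 5 reference values per metric and
  category; very small ecosystems cannot use it.

## A worked example

```{r example, eval = FALSE}
eco <- generate_ecosystem(ecosystem_config(seed = 7, n_groups = 20))
tab <- run_assessment(eco$dataset)
cmp <- compare_hindcast_forecast(tab)
cmp$summary
pca_of_metrics(tab, "biomass")
```
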