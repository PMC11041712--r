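---
title: "Methods: from memory phenotype to miRNA expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from memory phenotype to miRNA expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirstm)
library(dplyr)
```

`mirstm` chains five analysis stages: behavioral phenotyping in the
six-different-object recognition task, two-channel miRNA microarray
preprocessing, 2^−ΔΔCt qPCR quantification, cross-platform integration, and
target-network description. This vignette documents the models behind each
stage, the parameters that matter, the design decisions taken where the
methodology is genuinely open, and what the synthetic-data generators do and
do not emulate.

## Behavioral classification

In the high-load task a mouse studies six different objects (study phase,
total exploration capped at 210 s = 35 s per object), then meets five
familiar objects and one novel replacement (test phase). A subject with
intact short-term memory concentrates exploration on the novel object; the
classification criterion formalizes this as

$$ \text{Unimpaired} \iff N > \bar F + k\,\mathrm{SD}(F), $$

with $N$ the novel-object time, $\bar F$ and $\mathrm{SD}(F)$ the mean and
SD of the five familiar times, and $k = 1.5$.

Three choices here are not forced by the criterion as usually stated, and
`mirstm` fixes them explicitly:

* **SD flavor.** Whether the SD uses denominator $n-1$ or $n$ is a
  convention. `classify_subjects()` defaults to the sample SD ($n-1$), the
  usual behavioral-statistics choice, and exposes
  `sd_type = "population"` as a switch (for five familiar objects the two
  differ by the fixed factor $\sqrt{4/5}$, so the labels can differ only for
  borderline subjects).
* **Ties.** Unimpaired requires *strict* exceedance; a subject exactly at
  its threshold is Impaired. This matters mostly in the degenerate zero-SD
  case (all familiar times equal).
* **Percent rounding.** Cohort percentages are rounded to one decimal,
  half away from zero, the convention behind reported splits such as
  55.2 % / 44.8 %.

A property worth knowing before trusting any phenotype split: for a subject
whose novel-object time is just another draw from its familiar-time
distribution (the natural null model of impairment), the probability of
exceeding $\bar F + 1.5\,\mathrm{SD}(F)$ estimated from five familiar times
is about 12–14 % for normal-to-lognormal time distributions. The criterion
therefore has an irreducible false-positive rate near one-in-eight on truly
impaired animals; it is a property of the thresholding rule itself, not of
any implementation. Recovery claims for the classifier are framed
accordingly (sensitivity for unimpaired animals and overall accuracy, not
per-class specificity above that bound).

Group statistics use the pooled-variance unpaired t-test
(`unpaired_t()`, $df = n_A + n_B - 2$; zero pooled variance with equal
means returns $t = 0$, $p = 1$ by convention, and with unequal means is an
error), one-way repeated-measures ANOVA (`anova_rm_oneway()`,
$df = (K-1),\ (K-1)(N-1)$) and the split-plot two-way ANOVA
(`anova_rm_mixed()`, between $df = (G-1, N-G)$, within/interaction
$df = (K-1),\ (K-1)(N-G)$). No sphericity correction is applied, matching
the uncorrected degrees of freedom conventionally reported for this task.
Completely flat data have zero effect sums of squares; the F statistic is
reported as 0 with $p = 1$ rather than NaN. Both fits go through
`stats::aov()` with subject error strata; the test suite checks them against
independently-written sums-of-squares oracles to $10^{-10}$.

## Microarray processing

Input is a probe-level table per technical-replicate slide: two channel
intensities (Hy3/green carrying the Impaired pool, Hy5/red the Unimpaired
pool), a scanner quality flag, and an endogenous-control indicator. The
pipeline (`array_pipeline()`) is a chain of subset filters:

1. **Flags** (`filter_flags()`): only `ok` spots survive; marginal and
   absent spots are dropped and counted.
2. **Normalization** (`normalize_slides()`): per-probe raw ratio
   $r = \log_2(\mathrm{Hy3}/\mathrm{Hy5})$, centred per slide by the median
   raw ratio of that slide's control probes. Median-centring on controls is
   one concrete reading of "normalize against endogenous controls"; it is
   robust to a control outlier and absorbs any channel-wide multiplicative
   bias exactly (a dye-bias factor $b$ adds $\log_2 b$ to every probe and to
   the control median alike). A slide without controls falls back to its
   global median with a message; `normalize = FALSE` passes raw ratios
   through. Probes with a non-positive intensity in either channel are
   dropped before the log transform, never imputed. The sign convention is
   fixed: positive means higher in the Impaired pool, and swapping the
   channel columns negates every ratio and mirrors up/down calls exactly.
3. **Intensity window** (`intensity_filter()`): keep
   $8 < \tfrac{1}{2}(\log_2 \mathrm{Hy3} + \log_2 \mathrm{Hy5}) < 14$,
   a strict open interval, excluding the noise floor and saturation.
   "Log intensity" is read as log2 of fluorescence.
4. **Replicate averaging** (`average_replicates()`): per-miRNA mean and
   sample SD ($n-1$; for the typical two technical replicates the SD equals
   $|r_1 - r_2|/\sqrt 2$; a single replicate has SD 0).
5. **Retention rule** (`retention_filter()`): $|\text{mean}| > 0.5$
   combined with an SD arm. The SD comparator is genuinely ambiguous in the
   field: "SD > 0.4" reads literally as *keeping* noisy probes, while
   reproducibility filtering would keep SD < 0.4. Both are implemented
   (`sd_mode = "as_printed"` default, `"reproducibility"` alternate) and
   neither is asserted as the only correct reading.
6. **Calling** (`call_expression()`): *up* above +0.7, *down* below −0.7,
   *unchanged* otherwise, strict bounds, applied to the replicate mean.

The retention rule and the ±0.7 call rule overlap (any |mean| > 0.7 call
passes the 0.5 fold-change arm automatically). `mirstm` treats them as
separate annotations on the same per-miRNA table: the category comes from
the ±0.7 rule alone, and `passed_retention` records the 0.5/0.4 rule, so a
"considered" subset can be reported without the two thresholds silently
gating each other. `summarize_calls()` then tallies categories; the counts
always partition the total.

## qPCR quantification

`delta_ct()` averages technical-replicate Ct values per sample × assay and
subtracts the same sample's reference-assay mean (U6 small nuclear RNA by
default): $\Delta Ct = \overline{Ct}_{target} - \overline{Ct}_{ref}$, with
replicate SDs propagated in quadrature. `fold_changes()` then references a
calibrator pool: $\Delta\Delta Ct = \Delta Ct - \Delta Ct_{cal}$ and
$\mathrm{FC} = 2^{-\Delta\Delta Ct}$. The calibrator's own fold change is
exactly 1 for every assay — an identity the tests assert, not a rounded
value.

Error bars are the standard asymmetric propagation

$$ \mathrm{upper} = 2^{-(\Delta\Delta Ct - s)} - \mathrm{FC}, \qquad
   \mathrm{lower} = \mathrm{FC} - 2^{-(\Delta\Delta Ct + s)}, $$

with $s$ the propagated ΔCt SD. Because the transform is convex,
upper ≥ lower always, reproducing the characteristic upper-heavy error
pattern of published ΔΔCt tables. Published tables rarely state their exact
error-bar formula; this propagation is documented here as the
implementation's interpretation. No efficiency correction (Pfaffl) is
applied — pooled samples with technical triplicates only, which is what the
SDs describe. An optional validator (`validate_ct_replicates()`) warns when
a replicate triplet spans more than a configurable Ct range (default 1
cycle) but removes nothing.

## Integration and target networks

`platform_pairs()` joins array and qPCR log2 fold changes by miRNA,
dropping (with a warning) any miRNA missing on one platform.
`platform_pearson()` is the standard Pearson correlation with the two-sided
t-transform p-value on $n-2$ df; it refuses fewer than 3 pairs or a
zero-variance platform. `select_candidates()` keeps miRNAs above a +0.5
log2 threshold, ranked descending with lexicographic tie-breaks so output
order is deterministic.

`consensus_targets()` applies the two-of-three rule over TaPmiR (counting
only when its binding probability strictly exceeds 0.95), TargetScan and
miRDB, with experimentally validated genes kept unconditionally. The rule is
monotone: adding a prediction can never remove a gene. `degree_stats()`
reports node/edge counts, average degree $2E/V$ and the maximum-degree
nodes of a simple undirected interaction graph; isolated genes count in the
denominator, the whole-target-set convention, so a 101-gene set with 71
interactions has average degree 1.41 regardless of how the edges are
arranged. Enrichment p-values against a genome background are out of scope
— they depend on an external interaction database's background model, and
only descriptive statistics are computed here.

## The synthetic-data generators

The generators exist so that every pipeline stage can be tested against
known ground truth; their defaults encode the study design the package
addresses.

* `simulate_cohort()` — 29 subjects, 13 latently impaired, per-object times
  log-normal with median 20 s and log-scale SD 0.25 (non-negative,
  right-skewed, the usual shape of exploration durations; ~35 s-scale totals
  per object would be unrealistic for every object, and 20 s medians put
  study-phase totals near 120 s, comfortably under the cap with occasional
  capping). Unimpaired subjects explore the novel object
  `novelty_boost = 2.5`× longer on average — a strong but realistic
  preference that leaves classification imperfect in the way real cohorts
  are. Study totals over 210 s are rescaled proportionally to the cap
  (mimicking the timed cutoff while keeping the cohort size fixed; a
  rejection scheme would bias times downward). Truth labels are returned
  separately from the records.
* `simulate_array()` — 179 miRNAs, of which 38 planted upregulated at
  log2 FC 1.2, 10 endogenous controls, 2 technical-replicate slides,
  channel noise SD 0.1 on the log2 scale, baselines uniform on (9, 13) so
  probes sit inside the intensity window, optional dye bias multiplying one
  channel (which normalization must absorb), and a 2 % flag rate. Channel
  truth: $\log_2 I_{Hy3} = b + fc/2 + \varepsilon$,
  $\log_2 I_{Hy5} = b - fc/2 + \varepsilon'$.
* `simulate_qpcr()` — Ct = baseline − expression + noise, triplicates,
  noise SD 0.2 cycles, with the five validated assays planted by default at
  latent log2 differences matching fold changes 13.16, 1.22, 6.04, 8.01 and
  2.49, and a zero-difference U6 reference sharing each sample's baseline.

Each generator takes a single integer seed and restores the caller's RNG
state afterwards; scripts that need several independent streams derive
sub-seeds from one master seed. What the generators deliberately do *not*
emulate: biophysical hybridization chemistry, amplification-efficiency
differences between assays, spatial slide artefacts (print-tip or regional
effects), biological replication (the study design pools animals, so only
technical noise exists to model), and session-to-session behavioral drift.
Passing recovery tests on these synthetics therefore demonstrates that the
pipeline's arithmetic and filtering logic are correct under the stated noise
model — not that the thresholds would achieve the same sensitivity on data
with structured artefacts.

## Numerical conventions and problem sizes

All thresholds are strict inequalities ((8, 14) window, ±0.7 calls, 0.5/0.4
retention, 0.95 TaPmiR probability, the classification criterion itself).
Degenerate inputs fail loudly: zero total exploration, missing cells in an
ANOVA design, zero variance in a correlation, non-positive fold changes.
Zero-intensity probes are dropped with a warning before log transforms.
ANOVA F-statistics are validated against brute-force sums-of-squares
oracles at $10^{-10}$; exact identities (calibrator fold change 1, degree
handshake $\sum d_i = 2E$) are asserted exactly.

The test suite exercises cohorts of 20–100 subjects, slides of 20–179
miRNAs with 1–2 replicates, 10,000-draw error-propagation sweeps and
1,000-graph handshake sweeps — sizes chosen so the full suite documents the
properties at meaningful scale while running in well under a minute.
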