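---
title: "Methods: pathway reporter screening with metabolic activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway reporter screening with metabolic activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepascreen)
```

## The screening problem

Hepatotoxic compounds — natural products especially — act through
heterogeneous cellular stress pathways, and many become toxic only after
hepatic metabolism. The screen this package analyses addresses both
questions at once. Four HepG2-derived reporter lines each carry GFP under
a transcription-factor response element: AP1 (proliferative stress), P53
(DNA damage), Nrf2 (oxidative stress) and NF-kB (inflammation). Each line
is exposed to every compound as a serial dilution, both without (`S9minus`)
and with (`S9plus`) liver S9 fraction, which supplies the phase I/II
drug-metabolizing enzymes HepG2 cells lack. Wells are imaged in three
channels — Hoechst (all nuclei), GFP (reporter), Calcein (live cells) —
and quantified per cell.

The analysis output per compound is (i) a 0–3 activity tier per pathway
and condition, (ii) the per-condition sum of the four tiers (0–12), used
as a hazard call, and (iii) an S9-dependence class saying whether toxicity
requires, is abolished by, or is independent of metabolic activation.

## The tier score

Every compound x pathway x condition dose series is scored at a single
concentration: the highest dose whose viability is at least 50% of the
plate's negative-control level. The rationale is that reporter intensity
is unreliable in dying cells, so induction is read at the strongest
exposure that the cells still tolerate. If every dose is below 50% the
lowest dose is carried forward, flagged `all_cytotoxic` (it scores 0 in
practice).

With `v` the viability (% of negative control), `r_pos` the GFP fold over
the plate's positive-chemical mean, `r_neg` the fold over the
negative-control mean, and `p` the two-sided t-test p-value vs the
negative controls:

| tier | rule |
|------|------|
| 3 | `v > 70` and `r_pos > 1` |
| 2 | `50 <= v <= 70` and `r_pos > 1` |
| 1 | `v > 50`, `r_pos <= 1`, `r_neg > 1`, `p < 0.05` |
| 0 | otherwise |

Boundary handling makes the three viability bands a partition: exactly
70% falls in tier 2, exactly 50% can reach tier 2 but not tier 1 (tier 1
requires viability strictly above 50%). Ratios of exactly 1 never
qualify. These choices are deliberate: the verbal rules ("over 70%",
"50–70%") leave the edges open, and a partition guarantees
`assign_score()` is a total function — verified in the tests by an
exhaustive grid sweep against an independently coded rule table.

Tier 1 requires statistical significance; "higher than the control" alone
is too weak a criterion at plate noise levels, and the screen's stated
significance convention (two-sided t-test, alpha 0.05) supplies the
natural threshold for the 0-vs-1 distinction.

## Hazard sums and S9 classification

The per-condition sum of the four tiers is at most 12 (all pathways at
tier 3); a sum of 3 or more flags likely toxicity. A compound is then
classified by comparing conditions:

* active in neither condition → `non_responsive`;
* active in exactly one → `s9_minus_more_active` / `s9_plus_more_active`;
* active in both → "more active" under the condition whose sum leads by
  at least 2 points, else `consistent`.

The 2-point margin operationalizes "more active", which the screen design
does not define numerically; one point is the smallest possible scoring
fluctuation (a single pathway slipping one tier), so requiring two points
avoids classifying on the score's own granularity. The margin is the
`delta_threshold` argument. The hazard threshold itself is applied as
"3 or higher"; a strict `> 3` variant is available (`strict_hazard`)
because the figure legends of screens of this kind are occasionally read
either way.

Pathway-level activity groups (`classify_pathway_group()`) and the
four-set Venn summaries use a floor of tier >= 1, i.e. any significant
GFP increase over control counts as pathway activation.

## Plate statistics

Each plate carries six negative and six positive control wells; all
normalization is strictly per plate, because controls exist precisely to
absorb plate-to-plate variation. The viability metric is the live-cell
count (Calcein-positive fraction x nuclei count) normalized to the
negative-control mean; a total-nuclei variant is available
(`live_metric = "nuclei_count"`) since either reading of "cell viability"
is defensible. The GFP metric defaults to the mean per-cell reporter
intensity; GFP-positive counts and total GFP area are carried through the
tables and can be selected (`gfp_metric`).

Induction p-values come from a two-sided two-sample t-test of the
replicate wells of one compound x dose against the plate's negative
controls, Welch by default (unequal variances are the safe assumption for
induced vs baseline wells); Student's t is available (`var_equal`). Two
zero-variance corner cases are defined rather than errors: identical
constant groups give p = 1, distinct constant levels give p = 0. No
multiple-testing correction is applied — the screen's convention is
per-comparison alpha = 0.05 — and the tests confirm the Welch test holds
its nominal size on the actual 3-vs-6 replicate design (empirical type-I
error ~0.05).

## Image quantification

The per-cell quantification mirrors a high-content imager's "count
nuclei" / "cell scoring" modules with open, parameter-light defaults:

* nuclei: Gaussian smoothing (sigma 2 px) → Otsu threshold →
  distance-transform watershed splitting of touching objects (optional)
  → area filter (20–800 px^2). Otsu was chosen as the automatic
  threshold because it is standard and parameter-free; vendor numerics
  are not reproduced.
* cell regions: the nucleus dilated by a 5 px disc, overlaps resolved by
  nearest-nucleus propagation. Full cytoplasm segmentation is
  unnecessary because the reporter signal is cell-centered.
* GFP positivity: region mean above background mean + 3 SD, background
  estimated from non-cell pixels. The k-sigma rule makes calls invariant
  to constant intensity offsets; a fixed absolute threshold is available.
  `gfp_mean` is background-subtracted so it scales linearly with the true
  per-cell signal, which keeps control-relative ratios comparable between
  the image path and the table path.
* live calls: the analogous k-sigma criterion on the Calcein channel.

Coordinates are 1-based (row, col) pixel centers, the R convention.

## The synthetic-data generator

No raw well-level data are published for screens of this kind, so the
generator is the package's test bed: it produces the full well table (and
optionally field images) from a declared ground truth per compound, and
the downstream stages are validated by recovery of that truth.

The generative model, per well:

* viability follows a four-parameter Hill decline (top 100%, bottom 0%)
  in dose, with a per-condition EC50 and shared slope — the standard
  cytotoxicity shape, since no functional form is prescribed by the
  assay itself;
* expected per-cell GFP is baseline x induction fold, multiplied by the
  viability fraction once viability drops below 50%, reflecting reporter
  loss in dying cells;
* negative controls sit at baseline, positive controls at the line's
  positive-chemical induction level (default fold 3) with full
  viability;
* all well metrics receive multiplicative log-normal noise with unit
  mean and configurable CV (default 0.1, a typical well-to-well
  variation for imaging readouts); field images additionally receive
  Gaussian read noise.

Each plate draws from its own RNG stream, derived from the master seed by
a fixed counter over the plate enumeration, so single plates can be
regenerated independently and the whole screen is byte-reproducible.

The default truth set (`default_truths()`) plants 6 compounds per
S9-dependence class. Active compounds induce two of the four pathways
(pairs cycled for diversity) at fold 4.5 — comfortably above the
positive-chemical reference of 3 — with EC50s of 250–400 uM so the top
100 uM dose stays in the high-viability band; non-responders are strongly
cytotoxic (EC50 30 uM) but reporter-silent, emulating compounds whose
toxicity runs through unmonitored pathways. These values were fixed once
as a realistic, decisively-classifiable screen: at the default noise the
planted class is recovered for >= 90% of compounds, and exactly at zero
noise.

What the generator does *not* emulate: dose-dependent induction shapes
(folds are constant below the cytotoxic range), edge effects and spatial
plate gradients, illumination bias, channel bleed-through, and
compound-specific cell-loss morphology. Passing recovery tests therefore
demonstrates correctness of the analysis logic under the declared model,
not robustness to every artifact of real plates.

## Numerical and design notes

* Dose lists must be strictly decreasing with a constant dilution factor
  (checked to relative 1e-6); the default is five 4-fold steps from
  100 uM. The number of dose levels is configurable.
* Clustering of the compounds x 8 score matrix uses Euclidean distance
  with average linkage (configurable); `stats::hclust` is deterministic,
  with ties resolved by original index order.
* Degenerate inputs are defined, not fatal: a constant nuclei channel
  yields zero nuclei with a warning; an empty cell-record list summarizes
  to zero counts flagged `no_cells`; a zero control mean is a hard error
  naming the plate (the plate is unusable).
* The image path (`quantify_screen()`) renders and segments every well
  and is intended for small designs; its agreement with the table path is
  checked on a noise-free 64-well screen. Test problem sizes (a
  24-compound table-level screen, image fields of 50–500 nuclei at
  512 px, 10^4 null replicates for t-test calibration) were chosen as the
  smallest sizes at which the respective guarantees are meaningful.

## Known limitations

Scores are read at a single selected dose, so compounds active only in a
narrow mid-dilution window can be missed if that dose is not the highest
tolerated one; no dose-response curve fitting (EC50 estimation) is
performed, matching the discrete-dose scoring design. The S9
classification compares integer sums and is deliberately coarse; it will
not resolve subtle quantitative shifts in potency. The image simulator's
Gaussian-blob cells are a benchmark for the quantification logic, not a
substitute for validation on real microscopy.
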