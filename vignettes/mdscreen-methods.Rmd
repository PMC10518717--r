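---
title: "Methods: models, parameters and design choices in mdscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in mdscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdscreen)
```

mdscreen covers four quantitative workflows of an MDSC-directed
drug-discovery campaign: TMT profiling with differential expression,
coculture screen hit calling, competition-pulldown target deconvolution, and
solvent-induced protein precipitation (SIP) stabilization analysis. This
vignette documents the statistical models, the parameters a user can turn,
the numerical decisions, and what the synthetic-data generators do and do not
emulate.

## Reporter matrices and row filters

All proteomic stages operate on a `reporter_matrix`: a protein-by-channel
matrix of raw (unlogged) reporter intensities with per-row evidence and
flags, and per-channel design metadata. Two conventions matter:

* A MaxQuant reporter intensity of zero is a *non-detection*, so the readers
  convert zeros to `NA`. This keeps downstream log transforms well defined
  and prevents zeros from deflating channel sums.
* Protein-group ids with semicolon-separated accessions keep the leading
  accession; site ids are `protein_aa+position___multiplicity`, and both
  collapsed and multiplicity-expanded site tables are accepted, because the
  two MaxQuant versions in circulation emit either.

`filter_entries()` applies the standard row filters: contaminants, reversed
(decoy) sequences, proteins only identified by modified peptides, a minimum
unique-peptide count (2 in the SIP workflow), and a minimum number of valid
values per condition group (3 in the profiling workflow, enforced in *every*
group so each side of the t test is estimable). Filtering is idempotent and
logs per-rule removal counts.

## Normalization

Four procedures, all multiplicative on raw intensities:

* **Total sum** (`total_sum_normalize`): channel totals are equalized to the
  mean of the original totals. The target constant is arbitrary — any
  positive target produces identical downstream ratios — the mean keeps the
  data near its original scale.
* **Median centering** (`median_center`): channel medians are equalized to
  the grand median of all intensities, computed before centering. Whether
  the centering should be multiplicative on the raw scale or additive on the
  log scale is genuinely open; multiplicative-on-raw is the default and an
  `on_log = TRUE` option provides the additive variant. Both are idempotent.
* **Bridge normalization** (`bridge_normalize`): within each plex every
  protein is divided by its intensity in that plex's common bridge channel
  (the untreated reference), and plexes are joined on row id. The division
  is per protein, not a per-channel global factor: that is what a bridge
  channel is for, and only a per-protein ratio cancels protein-specific
  batch effects. A global ×2 plex batch factor cancels exactly. Rows
  without a valid bridge value in any plex are dropped and counted.
* **Phosphosite-by-proteome** (`normalize_phospho_by_proteome`): site
  channels are multiplied by the full-proteome total-sum factors, so site
  fold changes are corrected for sample loading without absorbing true
  site-level regulation.

## Differential expression

The moderated statistic is `d = (mean(a) − mean(b)) / (s + S0)` with `s` the
pooled two-sample standard error. A pooled-variance (Student) t is used
rather than Welch, matching the analysis environment this pipeline mirrors;
the p-value reported alongside always comes from the ordinary Student t
(`S0 = 0`). `estimate_s0()` implements the percentile search: candidates are
the 5%-step percentiles of the `s` distribution, rows are binned into windows
of `s`, and the candidate minimizing the coefficient of variation of the
within-window MADs of `d` is chosen — i.e. the `S0` that makes the spread of
`d` most independent of `s`. With constant `s` all candidates are equivalent
and the smallest is returned; a degenerate `s` distribution falls back to
`median(s)` with a message.

Permutation FDR (`permutation_fdr`) recomputes `|d|` under balanced label
shuffles. When the requested number of permutations covers all
`choose(n, n1)` distinct shuffles they are enumerated exactly (a 3-vs-3
design has only 20), otherwise a seeded random sample is drawn. For a
threshold Δ, `FDR(Δ) = mean permuted count of |d| ≥ Δ / observed count ≥ Δ`,
capped at 1; rows with `|d|` exactly at Δ are included (≥). The per-row q is
the minimal FDR over thresholds at or below the row's `|d|` (monotone by
cumulative minimum), and significance at level α is equivalent to q ≤ α.
The estimator uses the mean of permuted counts without a π₀ correction —
the simplest variant; it is conservative when many rows are truly changed.
Two-sidedness is via `|d|`. Defaults: α = 0.05, 250 permutations, fixed
seed. BH mode uses the Student-t p-values with `stats::p.adjust`.

Fold-change band labels use closed boundaries: `|log2FC|` in [1, 2] is the
inner band, > 2 the outer, so a row at exactly 1 falls in the inner band.

## Screen analysis

Percent effect anchors 0% at the median of the neutral (DMSO) wells and 100%
at the median of the stimulator wells; medians resist edge-well outliers and
make the scale invariant under positive affine transformations of the raw
signal. Controls are aggregated per plate (campaign-wide control pooling is
not implemented; per-plate is the conservative choice when plates drift).
Hits require a percent effect *strictly* above the threshold (default 50) in
at least one readout; the boundary case 50 is therefore not a hit. The
counter-screen filter validates hits whose direct T-cell effects stay below
an inactivity threshold — 20% by default, a configurable convention rather
than a measured constant. Screen dose-response uses a 4PL (bottom, top,
EC50, Hill) with box bounds (bottom ≥ −20%, top ≤ 120%) on the log10 dose
axis; the 5PL is reserved for pulldown curves where the fixed-top asymmetric
model is required. Fits with span below 20% are classified inactive. Donor
binning: strong > 40%, mild in (0, 40] (closed at 40), none ≤ 0.

## Competition pulldown

Relative binding is the per-dose ratio to the vehicle, so it is
scale-invariant per series. The 5PL (Richards) curve

$$y(c) = \mathrm{bottom} + \frac{1 - \mathrm{bottom}}
  {\left(1 + (c/x_\mathrm{mid})^{\mathrm{slope}}\right)^{\mathrm{asym}}}$$

is fit with the top fixed at 1 and bottom bounded to [0, 1], on log10 dose;
the vehicle point itself is excluded (log 0 is undefined) and the `y → 1`
limit is enforced by the fixed top. Because the 5PL inflection is not the
half-response point, the EC50 is defined as the crossing of
`(1 + bottom)/2`, with closed form `x_mid (2^{1/asym} − 1)^{1/slope}`; at
`asym = 1` this reduces to the 4PL identity EC50 = x_mid, which is unit
tested. Convergence failures or spans below 0.2 mark non-binders without an
EC50.

The depletion correction factor is `cf = PDPD/PD` from two consecutive
pulldowns of the vehicle sample: the more completely the beads deplete a
protein, the less remains for the second pulldown and the smaller cf. The
orientation (PDPD over PD, giving cf < 1 under strong depletion) follows
from cf being a measure of depletion that multiplies EC50 *downward* to the
apparent Kd: `Kd_app = EC50 × cf ≤ EC50`. cf is clipped to (1e-3, 1] with a
warning; a missing PDPD leaves cf undefined and the EC50 is reported alone.
Target annotation requires a converged sigmoid with span ≥ 0.5, R² ≥ 0.8, a
monotone dose trend (Spearman ≤ −0.7) and ≥ 2 unique peptides; every
threshold is configurable and attached to the result.

The default dose ladder is the eight-dose design (vehicle, 10, 30, 100, 300,
1000, 3000, 30000 nM). The printed ladder skips 10 µM; it is configurable.

## SIP stabilization

The assay denatures lysate aliquots over an 8-step solvent gradient
(8–22%), pools equal amounts of the soluble fractions, and quantifies the
pool — so the pooled intensity is the primary observable, and per-fraction
melting curves are never fit. `pool_soluble_fractions()` (mean over the
grid) exists for the simulator and for per-fraction input. Stabilization is
tested per contrast — each active-compound dose against the matched
inactive-analog dose (a vehicle-reference mode is also available) — with
Student t on log2 pooled intensities and BH across proteins within the
contrast; `S0` defaults to 0 here, with the profiling estimator available as
an option. Dose trends report, per protein, the median treated/reference
ratio and the range of per-replicate ratios (each treated replicate over
the reference median — the range of extremes-over-median variant was
rejected as less interpretable), plus a flag for
`ratio(high) > ratio(low) > 1`.

## Synthetic-data generators

Every generator is seeded, bit-reproducible, and returns ground truth
sufficient to score its downstream stage.

* `gen_tmt_profile`: log-normal baselines (log2 N(20, 1.5)), Gaussian log2
  noise (default SD 0.2, typical TMT replicate scatter), regulated rows with
  random sign and magnitude `effect_log2 ± effect_sd`, per-plex batch
  factors, optional per-channel loading offsets, bridge channels carrying
  the untreated reference, and missing values injected completely at random
  by default (an intensity-dependent mode exists; real missingness is
  intensity-biased, but the analysis makes no use of that structure). The
  default design is the 5-vs-5 single-plex layout of the profiling
  experiment.
* `gen_phospho_profile`: site intensity = parent-protein intensity × a
  per-site stoichiometry factor × an optional site-level effect, so
  proteome-ratio normalization can be validated to remove loading while
  preserving site-level regulation.
* `gen_pulldown_series`: targets follow `r(c) = 1/(1 + (c/K_d^{eff})^h)`
  with `K_d^{eff} = Kd/cf`, which ties the simulator to the correction
  identity `EC50 × cf = Kd` and makes parameter recovery well-posed;
  non-targets are flat with cf = 1. PD/PDPD pairs satisfy `PDPD = PD × cf`.
  Noise is multiplicative log-normal at a given CV.
* `gen_plate`: control wells at their role means, compound wells at their
  true percent effect on the control-defined scale, well noise expressed in
  percent-effect units. Default 384-well layout with 16 + 16 control wells
  (the real screen's control layout is unpublished, so it is configurable
  and never asserted).
* `gen_solvent_profiles`: per-protein survival is a descending logistic in
  solvent percentage with midpoints drawn from `midpoint_range` (default
  10–20%, spanning the gradient interior) and transition width 1.5 points;
  stabilized proteins shift right by `midpoint_shift × shift_weight` under
  active conditions (weights 0.5/1 for the low/high dose). The reported
  intensity is baseline × mean survival over the grid — in-silico pooling —
  with log-normal replicate noise (default 0.05 log2).

What the generators do *not* emulate: peptide/spectrum-level structure,
isotope impurity, chromatographic effects, plate-positional drift, and
intensity-dependent missingness (by default). Passing tests therefore
validate the statistical machinery, not robustness to those artefacts.

## Power of the SIP design: a known limitation

Because pooling integrates survival over the gradient, a midpoint shift of
Δm raises the pooled fraction by about Δm/(gradient span) — roughly 0.14 for
a 2-point shift — regardless of the transition width. The resulting log2
stabilization ratio ranges from ~0.2 (late-precipitating proteins) to ~0.7
(early precipitators). With triplicates the Student t has 4 degrees of
freedom, and BH across ~1000 proteins demands very small p-values, so
2-point shifts are only partially detectable: the acceptance script's SIP
recovery section measures this sensitivity directly (and verifies that the
false discovery proportion stays controlled). Detecting subtle stabilizers
reliably requires larger shifts, more replicates, or a focused candidate
list; the headline targets of such an experiment are the strongly shifted,
early-precipitating proteins.

## Numerical choices and degenerate inputs

* Nonlinear fits use Levenberg–Marquardt with box bounds
  (`minpack.lm::nlsLM`, 200 iterations); failures are caught and reported
  as non-converged rather than raised.
* Zero-variance rows with zero fold change get p = 1; with nonzero fold
  change and `S0 = 0` the statistic is infinite and p = 0 (the S0 mode damps
  these; rows with fewer than two finite values per group are untestable,
  flagged, never an exception).
* Ties at a permutation threshold are included (≥); q-values are made
  monotone by cumulative minimum.
* `cf` clipping bounds (1e-3, 1], annotation thresholds, the counter-screen
  inactivity threshold and the hit threshold are all arguments with the
  defaults stated above.
* Equal control medians make the percent-effect scale undefined and raise an
  error naming the problem.

## Problem sizes

The test and acceptance suites run the simulations at desk scale: 1000–2000
proteins per profiling matrix, 250 permutations, 20 seeds for the
Monte-Carlo suites, 40-protein pulldown panels, and the 15-channel SIP
design at 1000 proteins. These sizes give Monte-Carlo errors comfortably
below the margins being tested while keeping a full run in the minutes
range.
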