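# mdscreen

Analysis toolkit for the computational backbone of a myeloid-derived
suppressor cell (MDSC) drug-discovery campaign. MDSCs suppress T-cell
proliferation and IFN-γ secretion; a campaign against them combines
quantitative proteomics of the in vitro MDSC model, a 384-well coculture
high-throughput screen for compounds that relieve the suppression, and
chemoproteomic target deconvolution of the resulting chemical matter. This
package implements every quantitative step of that pipeline as tested R
functions, together with seeded synthetic-data generators that produce each
input with known ground truth, so every stage can be validated end to end.

## What it computes

**TMT quantification and differential expression.** Reporter-intensity
matrices (read from MaxQuant-style `proteinGroups.txt` / `Phospho
(STY)Sites.txt` tables, with contaminant/decoy/only-by-site and evidence
filters) are normalized by total sum, median centering, a common
bridge-channel ratio per plex, or proteome total-sum factors for
phosphosites. Two-group testing uses the S0-moderated statistic

    d = (mean(a) − mean(b)) / (s + S0)

with `s` the pooled standard error and `S0` the variance-stabilizing fudge
constant chosen by the percentile search of the SAM procedure. False
discovery control is either permutation-based — `FDR(Δ) = E_perm #{|d| ≥ Δ} /
#{|d|obs ≥ Δ}` over balanced label shuffles, exhaustively enumerated whenever
possible — or Benjamini–Hochberg on the Student-t p-values.

**Coculture screen.** Raw well readouts are rescaled to percent effect,
`100·(x − median(neutral)) / (median(stimulator) − median(neutral))`, hits
are compounds with > 50% effect in at least one readout, a T-cell
counter-screen filter removes compounds directly active on T cells, 4PL
dose-response fits report EC50, and per-donor effects are binned
(none / mild ≤ 40% / strong > 40%).

**Competition pulldown (apparent Kd).** Relative binding `r(c) =
I(c)/I(vehicle)` is fit with a five-parameter logistic with the top plateau
fixed at 1; the EC50 is the half-span crossing `x_mid·(2^(1/asym) − 1)^(1/slope)`.
The bead-depletion correction factor `cf = I(PDPD)/I(PD)` from two
consecutive vehicle pulldowns converts it to the apparent dissociation
constant `Kd_app = EC50 × cf ≤ EC50`. Targets are annotated by curve span,
R², monotone dose trend and peptide evidence.

**Solvent-induced protein precipitation (SIP).** Pooled soluble-fraction
intensities over an 8–22% solvent gradient are compared between treatment
and inactive-analog conditions by Student t tests with BH correction;
dose-trend summaries report median treated/reference ratios with
per-replicate ranges and a dose-dependence flag.

**Assay calculators.** Arginase activity from the colorimetric urea formula,
and replicate-level ANOVA + Tukey HSD for per-cell ROS imaging intensities.

## Worked example

Simulate a competition pulldown with one true target (Kd = 50 nM, bead
depletion cf = 0.4) and deconvolve it:

```r
library(mdscreen)
sim <- gen_pulldown_series(pulldown_sim_config(
  n_proteins = 3, n_targets = 1, true_kd = 5e-8, depletion_cf = 0.4,
  noise_cv = 0.05, seed = 7))
res <- fit_pulldown(sim$series)
res[, c("protein", "ec50", "cf", "kd_app", "r2", "target")]
#>   protein         ec50        cf       kd_app        r2 target
#> 1    T001 1.402422e-07 0.3820509 5.357968e-08 0.9958881   TRUE
#> 2    T002           NA 1.0000000           NA        NA  FALSE
#> 3    T003           NA 1.0000000           NA        NA  FALSE
```

The target's fitted EC50 (140 nM) is inflated by bead depletion; multiplying
by the measured cf (0.38) recovers the true Kd within 7% (53.6 vs 50 nM),
while the two non-binders get no EC50 at all.

Differential expression of a simulated 5-vs-5 TMT plex:

```r
sim2 <- gen_tmt_profile(profile_sim_config(n_proteins = 2000, seed = 7))
de <- differential_expression(
  log2(intensities(sim2$matrix)), channel_meta(sim2$matrix)$condition,
  test_config(correction = "permutation", n_permutations = 250,
              s0 = "auto", seed = 7))
de
#> diffexp_result: 2000 rows, groups A vs B, s0 = 0.2916
#>   significant: 192; fold-change bands: |FC| 1-2: 101, >2: 0
```

192 of the 200 truly regulated proteins are recovered at permutation FDR
0.05, with the estimated S0 (0.29) keeping low-variance rows from dominating.

A full multi-stage run is one call: `run_pipeline("pipeline.yaml")` (or the
`inst/cli/mdscreen` wrapper) executes simulate/normalize/test stages in
dependency order and writes TSVs with provenance headers.

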