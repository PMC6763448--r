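---
title: "Methods: differential methylation, rescue classification and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation, rescue classification and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical methods: what is
computed at each stage, which parameters matter and why their defaults were
chosen, what the synthetic generator does and does not emulate, and where
the design was genuinely open.

## 1. Data model

The unit of input is one RRBS sample: ordered per-CpG methylated and
unmethylated read counts (`sample_profile`). All internal coordinates are
0-based half-open; the Bismark coverage dialect (1-based) is converted on
read, and the percent column of either dialect is ignored because counts
are authoritative. Strand handling is delegated upstream: both dialects
normally carry already-destranded CpG counts, and an optional
`destrand_profile()` merges dyad calls at positions *p* and *p*+1 by count
summation for inputs that do not.

`build_cohort()` applies the coverage filter **per sample** (default
`min_cov = 15` reads, the embryo-data convention; 10 is conventional for
cell-line data) and then intersects: only CpGs covered in *every* sample of
every group enter the analysis. Filtering before intersection follows the
"included in analysis" reading of per-sample depth thresholds, and the
intersection guarantees that group comparisons are always made on the same
sites. Two views of methylation are kept:

* **pooled group percents** — counts summed across replicates, percent
  from pooled counts (equivalently a coverage-weighted mean of replicate
  percents). These drive effect-size decisions (DMC deltas, ICR means,
  dependence re-tests), because pooling is the natural estimator for
  group-level methylation at n = 2 replicates.
* **per-sample per-CpG percents** — retained because a rank test needs
  sample-level observations.

Pooling versus replicate averaging for deltas was an open choice; both are
available (averaging via `pool_group()` on single profiles), pooling is the
default.

## 2. DMC and DMR calling

A **DMC** is a common CpG whose pooled test-minus-reference difference is
at least `min_diff = 30` percent points. The threshold is read as
inclusive: a change of exactly 30.0 qualifies. Direction is the sign of
the difference (test − reference), so a KO-vs-WT comparison reports
hypomethylation as negative deltas.

A **DMR** (`segment_dmrs()`) is a maximal run of DMCs satisfying, in
order:

1. same chromosome and direction;
2. consecutive among *covered common CpGs* — an intervening covered CpG
   that is not a DMC breaks the run. This is the strictest reading of
   "consecutive"; `allow_skip` (default 0) relaxes it;
3. each consecutive pair at most `max_gap = 50` bp apart. Published
   descriptions of this analysis family alternate between a 50/100 bp
   inter-DMC gap and a 200 bp figure; we treat the gap (50 embryo / 100
   cell-line) as the operative parameter because it is the more specific
   statement, and expose an optional `max_span` cap on total region
   length (unset by default; 200 or 100 reproduce the alternative
   wording). Both values are echoed into run manifests so the dialect in
   force is never ambiguous;
4. at least `min_dmcs = 3` members and |mean member delta| ≥ `min_diff`;
5. a two-sided Mann–Whitney U test at `alpha = 0.05` comparing **all
   per-sample per-CpG percents** of the two groups within the run (e.g.
   3 CpGs × 2 replicates = 6 observations per group). The test inputs are
   not fixed by the published method descriptions; per-CpG-per-replicate
   values are the finest observations available and give the rank test
   usable sample sizes at n = 2 replicates.

Runs are grown greedily left to right; under maximality there are no
ties to break. The span cap, when set, also splits greedily. No
multiple-testing correction is applied anywhere because the emulated
analyses report raw p < 0.05; a BH option would be a one-line addition but
is deliberately absent from defaults.

The Mann–Whitney implementation switches to an exact null distribution
(dynamic-programming count of rank assignments) when n₁ + n₂ ≤ 16 and
there are no ties: region tests typically sit at 6–10 observations per
side, where the normal approximation is poor and the exact two-sided
p-value (2 · min(P(U ≤ u), P(U ≥ u)), capped at 1) is cheap. Larger or
tied samples use the normal approximation with tie correction and a 0.5
continuity correction. A practical consequence worth knowing: with a
single replicate per group, a 3-CpG region has an exact p-value floor of
0.1, so no 3-CpG region can pass `alpha = 0.05` — the p-gate implicitly
requires replication.

## 3. Rescue classification

`classify_rescue()` labels a KO DMR **strong** iff it overlaps at least
1 bp of a same-direction CI DMR, else **weak**. Any-overlap is the weakest
assumption consistent with "overlapped with"; a reciprocal-fraction option
(`min_overlap_frac`) exists for sensitivity analysis. CI DMRs overlapping
no KO DMR are counted separately (`n_ci_only`) and excluded from the
weak/strong partition. An optional stricter reading of "rescued to
wild-type levels" — re-testing the CI-vs-WT mean delta over the KO DMR
interval — is available through `classify_dependence()`-style re-tests but
interval overlap is the default, matching the set-arithmetic style of the
published counts.

## 4. Annotation and the ICR panel

Promoter and gene-body windows are derived from TSSs, strand-aware:
long promoter [TSS−1500, TSS+500), core promoter [TSS−300, TSS+150),
gene body [TSS+500, transcript end). A DMR is assigned to an element kind
iff a single element of that kind covers at least `min_overlap_frac = 0.5`
of the DMR length (inclusive, per-element as with `bedtools intersect
-f 0.5`). Kinds are non-exclusive — a DMR may count as both CGI and core
promoter — matching per-category counting; an exclusive-priority mode is
intentionally not the default.

The ICR report gives per-locus mean pooled percents per genotype over the
covered CpGs. The qualitative calls use two declared thresholds that are
**not** literature values: hypomethylated-in-KO = WT − KO drop ≥ 30 points
(matching the DMC scale), restored-in-CI = |CI − WT| ≤ 10 points. Both are
exposed (`hypo_drop`, `restore_window`) and the 10-point window is shared
with the temporal accessory/catalytic split so there is a single
restoration notion in the package.

## 5. Temporal (de novo) analysis

`temporal_dmrs()` is the same caller with reference = early stage and test
= late stage on a cohort intersected across all four samples; hyper = gain
(de novo), hypo = loss. Dependence of a WT gain on Dnmt3b is decided by a
**per-region re-test** rather than interval overlap with the KO DMR list:
the mean pooled KO−WT difference over the gain interval at the late stage
must be ≤ −`min_diff`. Among dependent gains, mechanism is *accessory* if
|CI − WT| over the interval is within the 10-point restoration window,
*catalytic* otherwise. The re-test was chosen because per-genotype
hypomethylation status of a fixed region is the quantity of interest;
overlap with independently segmented DMRs would conflate boundary effects
with biology.

## 6. Expression integration

The differential-expression stage is a deliberate stand-in: log2 fold
change on pseudocount-stabilised group mean FPKM
(`log2((m_t + 0.5)/(m_r + 0.5))`) with a Welch t-test on per-sample
`log2(FPKM + 0.5)`. Count-based negative-binomial inference is out of
scope here — the integration logic downstream, not the DE engine, is what
this package contributes — and the stand-in is labelled as such in output
metadata. The 0.5 pseudocount stabilises zero-FPKM genes; its visible
side-effect is that genes expressed far below 0.5 FPKM are damped toward
"unchanged", which slightly biases against calling very low expressors.

Gates: *up* means FC ≥ `fc_min = 2` (inclusive) and p < 0.05; *down* is
symmetric. The promoter classifier uses `wt_fpkm_level` = high iff mean WT
FPKM ≥ `fpkm_high_cutoff` (default 1.0 FPKM — the high/low boundary is
never stated in the emulated analyses, so it is a declared parameter) and
`expression_change` = up iff the DE status is up **and** the fold change
exceeds 2 strictly (the classifier's own "> 2-fold increase" wording).
Group 1 = (high, unchanged), Group 2 = (low, unchanged), Group 3 =
(low, up); (high, up) genes fall outside the published scheme and are
reported `unassigned`; down-regulated inputs are folded into "unchanged"
and flagged. Group means are normalised to the Group-3 WT mean.

## 7. Chromatin meta-profiles

Signal is consumed as pre-binned bedGraph — no BAM/bigWig machinery — so
the integration logic can be tested download-free; the generator emits the
same format. TSS profiles are strand-oriented (upstream negative);
scaled-region profiles map each region body onto 100 bins with 100 bp
unscaled 10 bp-binned flanks. Enrichment comparisons summarise each region
by its mean signal over the body (flanks excluded) and compare region sets
with a two-sided Welch t-test; per-region summaries were chosen over
per-bin tests because regions, not bins, are the independent units.
Strata with fewer than two regions on a side are reported as no-test
rather than a p-value.

## 8. The synthetic generator

`sim_config()` defaults encode the emulated study design: 2 RRBS
replicates per genotype, mean 30× coverage, 3 expression replicates,
planted region classes at the published scales (4133 weak, 205 strong,
110 CI-only; 133 gains of which 18 Dnmt3b-dependent and 6 of those
catalytic; 196 losses; 22 + 9 ICR loci with the described per-locus
states; 253 up / 819 down genes among 12,000; promoter groups of
150/163/34 genes).

The methylation model: each CpG carries a latent level drawn once from a
Beta distribution around its context mean (CGIs ≈ 0.07, background ≈
0.85, rescue-class regions 0.90, losses 0.90, gains exactly 0 — de novo
targets start unmethylated; ICRs 0.80) with precision 60, chosen so the
observed single-sample percent SD at 30× and high methylation is ≈ 9
points — large enough to be honest noise, small enough that a 50-point
effect is cleanly detectable and a zero effect cleanly null. Planted
effects shift the latent level deterministically; the level is shared
across samples, so replicate and genotype contrasts see binomial counting
noise around a common site effect (marginally, single-sample counts are
beta-binomial). Coverage is negative-binomial with mean 30 and size 50 —
a tight spread, reflecting that sites surviving the common-coverage
filter have homogeneous depth; heavier overdispersion would mostly model
the sites that filter removes. Planted regions hold 5 CpGs at a fixed
25 bp spacing (mean spacing 25 bp), so that a single coverage-dropped CpG
leaves a 50 bp gap that still satisfies the default `max_gap` — region
recovery then degrades only through genuine effect-size noise, not
through spacing artefacts.

Expression: log-normal FPKM (sdlog 0.2 within genes) with multiplicative
planted folds in KO and full rescue in CI; Group-3 genes are a subset of
the planted up genes with low WT level (0.2 FPKM) and an 8-fold KO shift.
Tracks: smooth positive background per mark with multiplicative
enrichment over designated region classes (3× H3K27me3 over strong, 3×
H3K36me3 and 2× H3K4me2/3 over weak).

What the generator does **not** emulate — and therefore what passing
recovery tests do and do not show: read-level artefacts (bisulfite
conversion failure, mapping bias, PCR duplicates), spatial correlation of
methylation beyond planted regions, coverage dependence on CpG density,
biological replicate heterogeneity beyond counting noise, and
count-distribution features of RNA-seq (the expression model is
log-normal, matching the stand-in, not a negative-binomial count model).
Recovery results validate the *pipeline logic* under the declared noise
model; they are not an error-rate claim about any particular real
dataset.

Calibration facts used by the test-suite oracles: under the shared-latent
model a zero-effect pooled-percent difference has variance
2·μ(1−μ)/N with N the pooled per-group coverage, integrated over the Beta
site-level law; at the default thresholds the null DMC rate is ~10⁻³ per
site at μ = 0.5 (and orders of magnitude lower at μ = 0.85), and null
DMRs essentially never occur — the observed false-positive DMR rate in
null simulations is 0, far below alpha.

## 9. Problem sizes and determinism

Everything is seed-deterministic: each `simulate_*` function derives its
RNG state from `config$seed` plus a fixed offset, so stages can be rerun
independently. The validation suite uses desk-scale instances chosen to
keep the full test run around half a minute: 200-site brute-force
segmentation oracles, cohorts of 2–12 × 10³ CpGs, a 100-region
boundary-recovery study, and full-scale planted cohorts (≈ 44 × 10³ CpGs,
4448 regions; 12,000-gene matrices) for the headline recovery numbers.
The acceptance script rebuilds those full-scale scenarios from scratch in
about a minute.

## 10. Known limitations

* The weak/strong split is interval-based; a methylation-level rescue
  score (continuous restoration fraction per region) is not implemented.
* `allow_skip > 0` uses greedy run-joining; it does not search for the
  optimal member subset under the span cap.
* The DE stand-in's p-values are anti-conservative for genes with very
  few counts and should not be used for real count data; swap in a
  count-based engine upstream and feed its results into the integration
  functions instead.
* ICR call thresholds are declared analysis parameters; per-locus calls
  on real panels should be read together with the reported per-genotype
  means, not only the Boolean flags.
* Meta-profiles hold the whole (gene × bin) value matrix in memory;
  genome-scale tracks at 10 bp bins are fine on a laptop but per-base
  resolution is not the target.
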