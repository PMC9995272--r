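---
title: "Models and methods behind polwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polwave)
```

`polwave` quantifies two kinetic steps of RNA polymerase II (RNAPII)
transcription from perturbation time courses: the residence time of
promoter-proximally paused polymerase (triptolide block + mNET-seq-like
3'-end occupancy) and the productive elongation rate (DRB release +
TT-seq-like labeled coverage). This vignette describes the models, the
parameters that matter, the numerical choices, and what the built-in
simulator does and does not emulate.

## Coordinate conventions

Genomic intervals are 0-based half-open, the BED/bedGraph dialect. All
distances that the analyses report are *strand-aware offsets from the TSS*:
offset 0 is the TSS base, positive offsets run in the direction of
transcription. "A 300-bp window downstream of the TSS" is therefore
unambiguous: offsets `[0, 300)`. Tracks are held as run-length-encoded
per-base vectors, one per strand, on a single contig; per-base expansion of
bedGraph intervals treats missing positions as zero.

## Spike-in normalization

Between-sample comparisons use multiplicative factors
`factor(s) = spike(reference) / spike(s)` from exogenous spike-in read
totals, which equalizes spike totals across samples exactly. The reference
is the untreated/0-min sample by convention; since a different reference
rescales all samples jointly, no downstream ratio or rate depends on the
choice. RPKM and rpm, in contrast, are *within-sample* measures and use
raw counts against the sample's own library size.

## Pausing index

For gene *g* and track *s*,

\[ \mathrm{PI}_g = \frac{\text{mean density, offsets } [-50, 300)}
                       {\text{mean density, offsets } [300, L_g)} . \]

The window defaults are configurable and recorded in the output metadata;
the promoter window deliberately includes 50 bp upstream so that summit
jitter around the TSS does not leak signal out of the numerator. Genes with
zero body density are flagged undefined and dropped from both sides of any
comparison (keeping a paired gene universe); genes too short to hold a body
interval are skipped, not errors. Indices are summarized on the log scale,
and conditions are compared with a two-sided Wilcoxon rank-sum test on the
shared gene universe. ChIP-seq-derived and mNET-seq-derived indices share
one code path; the assay label only selects the input track.

## Paused-RNAPII half-life

Triptolide blocks initiation via TFIIH/XPB; the model assumes the block is
instant and complete, so the promoter-window signal is a pure decay of the
standing paused pool:

\[ N(t) = N_0 e^{-kt}, \qquad t_{1/2} = \ln 2 / k . \]

Replicate densities are averaged and normalized to the 0-min value before
fitting (`fit_decay()`), so `N0` is free near 1 and the fit is scale
invariant — multiplying all densities by a constant changes only the
recorded scale. The fit is Levenberg-Marquardt nonlinear least squares with
a deterministic initialization from a log-linear pre-fit of `log N` on `t`,
a lower bound `k >= 1e-4`/min, and tight convergence tolerances
(`ftol = ptol = 1e-14`); on noiseless exponential input the recovered
half-life is exact to well below 1e-6 relative over the 1-60 min range
(asserted in the test suite). A course whose post-zero densities never drop
below the 0-min level carries no decay information; it is flagged
degenerate (`k` at the lower bound) and excluded from summaries rather than
reported.

No plateau term is fitted: with five timepoints and desk-scale counts a
plateau is unidentifiable, and the pure single exponential is the stated
model of the experiment. Genes enter summaries only if all three selection
criteria hold, each a strict inequality:

1. detectable expression — whole-transcript RPKM at 0 min `> 1`;
2. the replicate-mean density is maximal at 0 min (an initiation block can
   only remove signal);
3. replicate variability `sigma < 0.05`, where sigma is the mean over
   timepoints of the across-replicate standard deviation of densities
   normalized to the replicate-mean 0-min value. Normalizing first makes
   sigma dimensionless, so the 0.05 threshold is sequencing-depth
   independent. With a single replicate sigma is undefined and the
   criterion passes with a warning.

Fitting the replicate mean (rather than all replicates jointly) was chosen
because the replicate-variability filter already guards against divergent
replicates, and the mean-fit makes the noiseless-recovery properties exact.

## Elongation rate from DRB-release waves

After washout of DRB, transcription restarts synchronously and the labeled
(4SU, 10-min) coverage advances along genes. The analysis:

1. **Gene selection** (`select_rate_genes()`): protein-coding genes with
   length strictly between 60 and 300 kb that overlap no other gene on
   either strand. Shorter genes are outrun by the wave; overlapping units
   confound strand-projected coverage.
2. **Metagene** (`metagene()`): per offset bin (default 100 bp), the
   symmetric trimmed mean (default 10% per tail) over genes of
   spike-scaled, strand-projected coverage, replicates pooled after
   scaling. Genes shorter than the profiled region are dropped so every
   gene contributes to every bin.
3. **Smoothing** (`smooth_profile()`): cubic smoothing spline with the
   penalty chosen by generalized cross-validation (overridable via `spar`
   or `df`); the parameter used is recorded on the profile. A constant
   profile passes through unchanged.
4. **Wave-peak calling** (`call_wave_peaks()`): at t = 0 the spline maximum
   over the full grid (the promoter pause peak); at each later timepoint
   the maximum over offsets strictly greater than the previous peak plus an
   exclusion margin (default 2 kb) — the requirement that the wave must
   advance. The unconstrained maximum is recorded too, and a series is
   accepted only if every constrained peak exists and the free maxima
   themselves advance strictly. This automatic advance/anchoring flagging
   replaces interactive manual review of called peaks.
5. **Rate fit** (`fit_rate()`): OLS of peak position (kb) on time (min)
   over the post-release points; the rate is the slope. Per-timepoint
   ratios peak/t are reported alongside, the position-over-time variant
   used in per-gene tables; summaries use the OLS slope.

Per-gene rates (`gene_wave_rates()`) run the same path on single-gene
binned profiles and apply the filter cascade: expression `> 100` rpm in the
0-min control (strict), the 0-min peak anchored within 10.3 kb of the TSS
(10 kb plus the 300-bp pause window, configurable), and strictly advancing
free peaks across all timepoints.

### Why per-gene rates are the primary readout

The metagene is an average over genes whose velocities differ. For a cohort
with a wide velocity spread, the aggregated wave at time *t* is smeared
over `[v_min t, v_max t]`: a flat-topped bump whose spline maximum is an
intrinsically unstable estimator of "the" front, even with generous
smoothing. The trimmed mean sharpens this further: at late times only a
small fraction of genes have their crest near any given offset, and a 10%
trim can remove the crest signal entirely unless the waves broaden with
time. The package therefore reports metagene rates (they are the standard
visualization, and for kinetically homogeneous cohorts they recover the
shared velocity to within one grid bin), but treats the per-gene OLS slopes
as the quantitative readout — in simulations with fourfold velocity
heterogeneity the per-gene median relative error is a few percent while the
metagene slope can err by tens of percent. The acceptance script computes
both so the difference is visible.

## Elongation-velocity proxy

Synthesis per polymerase: the gene body (offset 300 to the TES) is split
into 100 equal strand-aware bins, and each bin's ratio
`(TT density + eps_tt) / (mNET density + eps_mnet)` is computed per gene
first, matching per-gene heat-map semantics (the metagene of ratios equals
the ratio of metagenes only for uniform signal). The genewise velocity is
the median bin ratio. Pseudocounts default to each assay's 5th percentile
of nonzero bin densities, keeping ratios positive and finite where
occupancy bins are empty; joint rescaling of both tracks cancels exactly.
Under strong overdispersion the pseudocounts bias absolute ratios slightly
(a known limitation; the proxy is a relative measure and is not calibrated
to kb/min).

## The simulator

`simulate_genome()` places non-overlapping genes with alternating strands
on one synthetic contig (defaults: 60-300 kb lengths, 10-kb gaps) and draws
per-gene truth: half-life log-uniform 2-15 min, velocity uniform
1-4 kb/min, pause amplitude ~1.0-1.7 expected counts/base at the summit
(so the 300-bp window holds ~100 expected counts at t = 0), body level
0.03-0.08 counts/base. Counts are negative-binomial with a single
dispersion (default 0.1; variance `mu + 0.1 mu^2`), plus an optional 2%
log-normal per-sample depth jitter that the spike-in normalization must
undo; spike totals are drawn Poisson around a common mean scaled by the
same jitter. `dispersion = 0` switches the generator to noise-free
expected values, which is what makes the closed-form assertions in the
test suite exact. Every draw derives from the configured seed.

*Triptolide tracks*: the pause peak is a Gaussian with summit at TSS+50 and
sd 30 bp truncated to offsets `[0, 300)` — the analyses fix only the
300-bp quantification window, so any unimodal shape inside it is
equivalent — decaying as `2^(-t / t1/2)`; the gene body stays constant
(only the promoter window is modeled kinetically because only it is
fitted). The promoter window is simulated per base; gene bodies as 500-bp
uniform-valued runs, which leaves every window sum and density identical in
expectation while keeping 60-300 kb cohorts tractable.

*DRB-release tracks*: at release time *t* the labeled interval spans
`[v max(0, t - 10), v t]` kb from the TSS at the gene's body level, with
pnorm-smoothed edges, plus a wave crest — a Gaussian centered on the front
`v t` with amplitude three times the body level — representing the bolus of
formerly paused polymerases released together at washout; without such a
crest the maximum of the labeled plateau would not track the front and no
wave-peak method could recover rates. The crest broadens with time,
`sd = sqrt(front_sd^2 + (0.2 v t)^2)`, emulating the wave broadening that
cell-to-cell rate variability produces in real DRB time courses (and which
keeps late-time crests visible through the metagene's trimmed mean). Signal
beyond the TES is dropped. At t = 0 only the residual pause peak is
present. Coverage is simulated as 50-bp runs.

*Not emulated*: uaRNA/PROMPT and enhancer transcription, termination
zones, splicing intermediates, read-level artifacts (mappability, PCR
duplicates), antisense bias or cross-contamination of the TT protocol, and
initiation re-entry after triptolide. Passing tests therefore demonstrate
that the estimators recover the kinetics their models describe at
realistic counting noise — not that real libraries satisfy those models.

## Problem sizes and determinism

The validation suite uses cohorts of 200-300 genes with two replicates
(the half-life cohorts on 5-20 kb genes, since promoter kinetics do not
depend on gene length; the wave cohorts on the 60-300 kb selection regime),
which keeps a full run in tens of seconds while leaving counting noise
realistic. All simulated outputs are bit-reproducible given the seed, and
`run_pipeline()` writes a manifest with MD5 checksums of every output, so
identical configuration plus seed yields byte-identical manifests.

## Known limitations

* The metagene wave peak is unreliable for kinetically heterogeneous
  cohorts (see above); prefer per-gene rates.
* The half-life model assumes an instant, complete initiation block and no
  re-entry; slow triptolide uptake would inflate apparent half-lives.
* The velocity proxy is relative, pseudocount-dependent in sparse bins,
  and not calibrated to kb/min.
* Exact promoter/body windows for the pausing index vary across the
  literature; defaults here are recorded in the output so comparisons stay
  explicit.
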