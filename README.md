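# polwave

Kinetics of RNA polymerase II (RNAPII) pausing and elongation from
strand-specific nascent-transcription coverage tracks.

Genome-wide nascent-transcription assays expose two rate-limiting steps of
transcription. mNET-seq maps the 3'-most nucleotide of RNAPII-engaged RNA —
the polymerase active site — at single-nucleotide resolution, so blocking
initiation (triptolide) and watching the promoter-proximal signal decay
measures how long RNAPII dwells in the paused state. TT-seq labels nascent
RNA (4SU) so that, after washout of the reversible CDK9 inhibitor DRB,
transcription restarts synchronously and the labeled coverage advances as a
wave whose front position over time gives the elongation rate. `polwave`
implements the quantitative layer of both experiments for anyone working
with such time courses, plus a ground-truth simulator so that the whole
pipeline can be validated end to end without external data.

## What it computes

* **Pausing index** — the ratio of mean RNAPII density in a
  promoter-proximal window (default offsets `[-50, 300)` around the TSS) to
  mean gene-body density (`[+300, TES)`), with cumulative-index curves and
  two-sided Wilcoxon rank-sum comparisons between conditions.
* **Paused-RNAPII half-life** — promoter-window densities
  (300 bp downstream of the TSS) across a triptolide time course
  (0/5/10/20/40 min) are fitted to an exponential decay
  `N(t) = N0 * exp(-k t)` by nonlinear least squares; `t1/2 = ln 2 / k`.
  Genes are filtered by the three criteria: transcript RPKM > 1 at 0 min,
  density maximal at 0 min, and replicate variability sigma < 0.05.
* **Elongation rate** — spike-in-scaled TT coverage after DRB release
  (0/10/20/30 min, 10-min label) is profiled as a trimmed-mean metagene,
  smoothed with a cubic spline, and wave peaks are called at the spline
  maxima under the constraint that the peak must advance with time; the
  rate (kb/min) is the OLS slope of peak position on time. Per-gene rates
  apply the filter cascade: > 100 rpm at 0 min, 0-min peak within 10 kb of
  the pause region, strictly advancing peaks.
* **Elongation-velocity proxy** — per-gene-body-bin ratio of nascent
  synthesis (TT) to polymerase occupancy (mNET): synthesis per polymerase.
* **Spike-in normalization** — per-sample factors
  `spike(reference) / spike(sample)`.
* **Simulation** — negative-binomial tracks with known per-gene half-life,
  velocity, pause amplitude and body level; BED12/bedGraph/TSV fixtures.

## Worked example

Simulate a 50-gene cohort with known kinetics, then recover them:

```r
library(polwave)

cfg <- sim_config(n_genes = 50, gene_length_range = c(100e3, 200e3), seed = 42)
sim <- simulate_genome(cfg)

## --- paused-RNAPII half-life from the triptolide mNET-seq time course
tracks <- simulate_triptolide_timecourse(sim$genes, sim$truth, cfg)
tracks <- apply_scale_factors(tracks, spikein_scale_factors(tracks, "mnet_t00_r1"))
fits <- halflife_table(tracks, sim$genes)
halflife_summary(fits)
#> <halflife_summary>
#>  condition  n mean_half_life_min median_half_life_min
#>    control 27           4.027535             3.215439

fit_decay(build_timecourse(tracks, sim$genes[1, ]))
#> <decay_fit> g0001 k = 0.1506 /min, half-life = 4.6 min, n0 = 1, rmse = 0.0111
# (simulated truth for g0001: 3.92 min)

## --- elongation rates from the DRB-release TT time course
drb <- simulate_drb_release(sim$genes, sim$truth, cfg)
drb <- apply_scale_factors(drb, spikein_scale_factors(drb, "ttseq_t00_r1"))
rg  <- select_rate_genes(sim$genes)          # 60-300 kb, non-overlapping
mg  <- metagene_rate(drb, rg, region_kb = 95)
as.data.frame(mg$series)
#>   timepoint_min peak_offset_kb free_peak_kb
#> 1             0           0.05         0.05
#> 2            10          27.95        27.95
#> 3            20          55.75        55.75
#> 4            30          85.95        85.95
mg$fit
#> <rate_fit> metagene: 2.9 kb/min (intercept -1.45 kb, r2 = 0.9994, n = 3)

rates <- gene_wave_rates(drb, rg)
median(rates$rate_kb_min[rates$eligible])    # 2.69 kb/min
mean(sim$truth$velocity_kb_min)              # 2.691 kb/min (truth)
```

The half-life summary averages only genes passing all three filters; the
wave-peak series shows the pause peak at t = 0 and the labeled front
advancing ~28 kb per 10 min; per-gene OLS slopes recover the simulated
cohort mean velocity to within about 2%.

A full run (simulate -> pausing -> halflife -> wave -> velocity) with TSV
outputs and a checksummed manifest:

```r
run_pipeline(list(outdir = "out", seed = 7, sim = list(n_genes = 50)))
```

or from the shell via the thin wrapper `inst/cli/polwave.R`.

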