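#' Simulation configuration
#'
#' Collects every parameter of the synthetic-data generator, with defaults
#' mirroring the perturbation designs the downstream analyses expect:
#' triptolide initiation block sampled at 0/5/10/20/40 min, DRB release
#' sampled at 0/10/20/30 min with a 10-min 4SU label, two biological
#' replicates, and non-overlapping genes in the 60-300 kb length regime used
#' for wave-peak analysis.
#'
#' Ground-truth kinetics are drawn per gene: half-life log-uniform over
#' `half_life_range` (default 2-15 min), elongation velocity uniform over
#' `velocity_range` (default 1-4 kb/min). `pause_amplitude_range` is chosen so
#' the expected 300-bp promoter-window total at t = 0 is on the order of 100
#' counts; `dispersion` is the negative-binomial dispersion (variance
#' mu + dispersion * mu^2). `dispersion = 0` makes the generator fully
#' deterministic: tracks carry exact expected values, spike counts are exact
#' and replicate jitter is off, so closed-form ratios are assertable.
#'
#' @param n_genes number of genes (>= 0).
#' @param gene_length_range numeric length-2, min < max, gene lengths in bp.
#' @param intergenic_gap minimum gap between adjacent genes in bp.
#' @param timepoints_triptolide minutes, sorted ascending, must include 0.
#' @param timepoints_drb minutes, sorted ascending, must include 0.
#' @param label_duration 4SU labeling time in minutes (> 0).
#' @param replicates biological replicates per timepoint.
#' @param read_depth nominal expected total counts per sample (bookkeeping;
#'   actual library size is the sum of simulated counts).
#' @param front_sd wave-front Gaussian sd at release, in kb.
#' @param wave_broadening_cv per-minute fractional broadening of the wave
#'   crest (sd grows as `sqrt(front_sd^2 + (cv * v * t)^2)`), emulating
#'   cell-to-cell elongation-rate variability.
#' @param wave_gain crest amplitude as a multiple of the gene's body level.
#' @param half_life_range minutes; half-lives drawn log-uniformly.
#' @param velocity_range kb/min; velocities drawn uniformly.
#' @param pause_amplitude_range expected counts/base at the pause summit.
#' @param body_level_range expected counts/base in the gene body.
#' @param dispersion negative-binomial dispersion (>= 0; 0 = noise-free).
#' @param replicate_jitter sd of the log-normal per-sample depth jitter
#'   (default 2%; ignored when `dispersion = 0`).
#' @param spike_mean expected spike-in total per sample.
#' @param contig name of the single synthetic contig.
#' @param seed integer seed; every generator draw derives from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 300,
                       gene_length_range = c(60e3, 300e3),
                       intergenic_gap = 10e3,
                       timepoints_triptolide = c(0, 5, 10, 20, 40),
                       timepoints_drb = c(0, 10, 20, 30),
                       label_duration = 10,
                       replicates = 2,
                       read_depth = 2e6,
                       front_sd = 2,
                       wave_broadening_cv = 0.2,
                       wave_gain = 3,
                       half_life_range = c(2, 15),
                       velocity_range = c(1, 4),
                       pause_amplitude_range = c(1.0, 1.7),
                       body_level_range = c(0.03, 0.08),
                       dispersion = 0.1,
                       replicate_jitter = 0.02,
                       spike_mean = 1e5,
                       contig = "chrS",
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), gene_length_range = gene_length_range,
    intergenic_gap = intergenic_gap,
    timepoints_triptolide = timepoints_triptolide,
    timepoints_drb = timepoints_drb, label_duration = label_duration,
    replicates = as.integer(replicates), read_depth = read_depth,
    front_sd = front_sd, wave_broadening_cv = wave_broadening_cv,
    wave_gain = wave_gain, half_life_range = half_life_range,
    velocity_range = velocity_range,
    pause_amplitude_range = pause_amplitude_range,
    body_level_range = body_level_range, dispersion = dispersion,
    replicate_jitter = replicate_jitter, spike_mean = spike_mean,
    contig = contig, seed = as.integer(seed)
  )
  if (cfg$n_genes < 0) stop("n_genes must be >= 0", call. = FALSE)
  if (length(cfg$gene_length_range) != 2 ||
      cfg$gene_length_range[1] >= cfg$gene_length_range[2])
    stop("gene_length_range must be (min, max) with min < max", call. = FALSE)
  for (tp in c("timepoints_triptolide", "timepoints_drb")) {
    t <- cfg[[tp]]
    if (is.unsorted(t, strictly = TRUE) || t[1] != 0)
      stop(tp, " must be strictly ascending and start at 0", call. = FALSE)
  }
  if (cfg$replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (cfg$dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d genes (%.0f-%.0f kb), %d replicate(s), dispersion %g, seed %d\n",
    x$n_genes, x$gene_length_range[1] / 1e3, x$gene_length_range[2] / 1e3,
    x$replicates, x$dispersion, x$seed))
  cat("  triptolide t:", paste(x$timepoints_triptolide, collapse = "/"),
      "min; DRB release t:", paste(x$timepoints_drb, collapse = "/"),
      "min; label", x$label_duration, "min\n")
  invisible(x)
}
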