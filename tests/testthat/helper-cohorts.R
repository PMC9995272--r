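# Lazily built simulated cohorts shared between unit and acceptance tests.
# Everything derives from fixed seeds; builders are pure given the seed.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .cohort_cache))
    assign(key, builder(), envir = .cohort_cache)
  get(key, envir = .cohort_cache)
}

# triptolide cohort at the generator's study conditions (promoter counts
# ~100 at t = 0, NB dispersion 0.1, 2 replicates); short genes keep the
# contig small without touching promoter kinetics
noisy_halflife_cohort <- function(n_genes = 300, seed = 1,
                                  half_life_range = c(2, 15)) {
  key <- sprintf("hl_%d_%d_%g_%g", n_genes, seed, half_life_range[1],
                 half_life_range[2])
  cached(key, function() {
    cfg <- sim_config(n_genes = n_genes, gene_length_range = c(5e3, 2e4),
                      intergenic_gap = 2e3, dispersion = 0.1,
                      half_life_range = half_life_range, seed = seed)
    sim <- simulate_genome(cfg)
    tracks <- simulate_triptolide_timecourse(sim$genes, sim$truth, cfg)
    tracks <- apply_scale_factors(tracks,
                                  spikein_scale_factors(tracks, "mnet_t00_r1"))
    fits <- halflife_table(tracks, sim$genes)
    list(config = cfg, sim = sim, tracks = tracks, fits = fits)
  })
}

# DRB-release cohort at the study conditions of the wave analysis
drb_cohort <- function(n_genes = 200, seed = 1) {
  key <- sprintf("drb_%d_%d", n_genes, seed)
  cached(key, function() {
    cfg <- sim_config(n_genes = n_genes, dispersion = 0.1, front_sd = 2,
                      seed = seed)
    sim <- simulate_genome(cfg)
    tracks <- simulate_drb_release(sim$genes, sim$truth, cfg)
    tracks <- apply_scale_factors(tracks,
                                  spikein_scale_factors(tracks, "ttseq_t00_r1"))
    genes <- select_rate_genes(sim$genes)
    list(config = cfg, sim = sim, tracks = tracks, genes = genes)
  })
}
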