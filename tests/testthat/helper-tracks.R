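# Small constructors used across the suite.

# track from explicit per-base vectors (both strands padded to equal length)
make_track <- function(plus, minus = numeric(0), sample_id = "s1",
                       assay = "mnet", timepoint_min = 0, replicate = 1L,
                       spike_count = 1000, condition = "control",
                       library_size = NULL) {
  len <- max(length(plus), length(minus), 1)
  pad <- function(x) c(x, numeric(len - length(x)))
  occupancy_track(
    sample_id = sample_id,
    counts = list("+" = pad(plus), "-" = pad(minus)),
    assay = assay, condition = condition, timepoint_min = timepoint_min,
    replicate = replicate, spike_count = spike_count,
    library_size = library_size
  )
}

# one-row gene table
make_gene <- function(start, end, strand = "+", gene_id = "gX",
                      chrom = "chrS", biotype = "protein_coding") {
  gene_models(gene_id, chrom, start, end, strand, biotype)
}

# hand-built promoter time course (for filter/fit tests)
make_tc <- function(times, densities, rpkm0 = 10, gene_id = "gX") {
  if (!is.matrix(densities)) densities <- cbind(densities)
  structure(list(gene_id = gene_id, times = times, densities = densities,
                 rpkm0 = rpkm0, window = c(0, 300)),
            class = "timecourse")
}

# hand-built smoothed profile with a spike at a given offset (for peak tests)
make_profile <- function(peak_bp, timepoint, region_bp = 80000,
                         grid_bp = 100, width_bp = 2000, amp = 1) {
  offs <- seq(grid_bp / 2, region_bp - grid_bp / 2, by = grid_bp)
  y <- amp * exp(-(offs - peak_bp)^2 / (2 * width_bp^2))
  structure(list(offsets = offs, raw = y, smooth = y,
                 timepoint_min = timepoint, n_genes = 1L, scope = "toy",
                 grid_bp = grid_bp),
            class = "metagene_profile")
}
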