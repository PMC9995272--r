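# Shape of the promoter-proximal pause peak: Gaussian summit at TSS+50,
# sd 30 bp, truncated to offsets [0, 300). Only the 300-bp quantification
# window is fixed by the analyses; any unimodal shape inside it works.
pause_kernel <- function(center = 50, sd = 30, width = 300) {
  k <- dnorm(seq_len(width) - 1, mean = center, sd = sd)
  k / max(k)
}

#' Simulate a synthetic genome with ground-truth kinetics
#'
#' Places `n_genes` strictly non-overlapping genes on one synthetic contig,
#' separated by at least `intergenic_gap`, with alternating strands, and draws
#' per-gene ground-truth kinetic parameters: pause-release half-life
#' (log-uniform over `half_life_range`), elongation velocity (uniform over
#' `velocity_range`), pause amplitude, body level and dispersion.
#'
#' @param config a [sim_config].
#' @return A list with elements `genes` (a [gene_models] table) and `truth`
#'   (a `data.frame` with one row per gene: `gene_id`, `half_life_min`,
#'   `velocity_kb_min`, `pause_amplitude`, `body_level`, `dispersion`).
#'   Deterministic given `config$seed`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  if (n == 0) {
    genes <- gene_models(character(0), character(0), numeric(0) + 1,
                         numeric(0) + 2, character(0))
    genes <- genes[0, ]
    class(genes) <- c("gene_models", "data.frame")
    truth <- data.frame(gene_id = character(0), half_life_min = numeric(0),
                        velocity_kb_min = numeric(0),
                        pause_amplitude = numeric(0),
                        body_level = numeric(0), dispersion = numeric(0))
    return(list(genes = genes, truth = truth))
  }
  lens <- round(runif(n, config$gene_length_range[1],
                      config$gene_length_range[2]))
  gap <- config$intergenic_gap
  starts <- gap + c(0, cumsum(lens + gap))[seq_len(n)]
  genes <- gene_models(
    gene_id = sprintf("g%04d", seq_len(n)),
    chrom = config$contig,
    start = starts, end = starts + lens,
    strand = rep_len(c("+", "-"), n)
  )
  lu <- function(r) exp(runif(n, log(r[1]), log(r[2])))
  truth <- data.frame(
    gene_id = genes$gene_id,
    half_life_min = lu(config$half_life_range),
    velocity_kb_min = runif(n, config$velocity_range[1],
                            config$velocity_range[2]),
    pause_amplitude = runif(n, config$pause_amplitude_range[1],
                            config$pause_amplitude_range[2]),
    body_level = runif(n, config$body_level_range[1],
                       config$body_level_range[2]),
    dispersion = config$dispersion
  )
  stopifnot(all(truth$half_life_min > 0), all(truth$velocity_kb_min > 0))
  list(genes = genes, truth = truth)
}

# contig length implied by a gene set (last end + gap)
sim_contig_length <- function(genes, config) {
  if (!nrow(genes)) return(config$intergenic_gap)
  max(genes$end) + config$intergenic_gap
}

# NB draw with mean mu and dispersion a (var = mu + a mu^2); a = 0 is
# noise-free: the expected value itself is returned.
nb_draw <- function(mu, dispersion) {
  if (dispersion <= 0) return(mu)
  rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

# Assemble one strand's Rle from non-overlapping gene pieces.
# pieces: list of list(start = 0-based genome pos, lengths =, values =)
assemble_strand <- function(pieces, contig_len) {
  if (!length(pieces)) return(S4Vectors::Rle(0, contig_len))
  ord <- order(vapply(pieces, `[[`, numeric(1), "start"))
  pieces <- pieces[ord]
  lens <- numeric(0); vals <- numeric(0); pos <- 0
  for (p in pieces) {
    if (p$start > pos) {
      lens <- c(lens, p$start - pos); vals <- c(vals, 0)
    }
    lens <- c(lens, p$lengths); vals <- c(vals, p$values)
    pos <- p$start + sum(p$lengths)
  }
  if (pos < contig_len) {
    lens <- c(lens, contig_len - pos); vals <- c(vals, 0)
  }
  S4Vectors::Rle(values = vals, lengths = lens)
}

# Turn per-offset run encoding (offset 0 = TSS, advancing with transcription)
# into a genome-ordered piece for assemble_strand().
offset_runs_to_piece <- function(gene, lengths, values) {
  total <- sum(lengths)
  if (gene$strand == "+") {
    list(start = gene$tss, lengths = lengths, values = values)
  } else {
    list(start = gene$tss - total + 1, lengths = rev(lengths),
         values = rev(values))
  }
}

# Simulate one sample track from per-gene expected-value generators.
# mu_fun(gene, truth_row) must return list(lengths =, values = mu per base
# within each run) in offset order starting at offset 0.
simulate_track <- function(genes, truth, config, mu_fun, sample_id, assay,
                           condition, timepoint, replicate, depth_factor) {
  contig_len <- sim_contig_length(genes, config)
  pieces <- list("+" = list(), "-" = list())
  for (i in seq_len(nrow(genes))) {
    gene <- genes[i, ]
    tr <- truth[truth$gene_id == gene$gene_id, ]
    if (!nrow(tr))
      stop("no ground-truth record for gene ", gene$gene_id)
    runs <- mu_fun(gene, tr)
    if (is.null(runs)) next
    mu_run_totals <- runs$values * runs$lengths * depth_factor
    counts <- nb_draw(mu_run_totals, tr$dispersion)
    piece <- offset_runs_to_piece(gene, runs$lengths, counts / runs$lengths)
    pieces[[gene$strand]] <- c(pieces[[gene$strand]], list(piece))
  }
  spike <- if (config$dispersion <= 0) config$spike_mean else
    rpois(1, config$spike_mean * depth_factor)
  occupancy_track(
    sample_id = sample_id,
    counts = list("+" = assemble_strand(pieces[["+"]], contig_len),
                  "-" = assemble_strand(pieces[["-"]], contig_len)),
    contig = config$contig, assay = assay, condition = condition,
    timepoint_min = timepoint, replicate = replicate, spike_count = spike
  )
}

#' Simulate a triptolide initiation-block mNET-seq time course
#'
#' For each timepoint and replicate, generates a single-nucleotide 3'-end
#' occupancy track in which the promoter-proximal pause peak (Gaussian summit
#' at TSS+50, truncated to offsets \[0, 300)) decays as
#' `pause_amplitude * 2^(-t / half_life_min)` — pure exponential decay of the
#' paused pool under an instant, complete initiation block — while the
#' gene-body expectation stays at `body_level`. Counts are negative-binomial
#' with the configured dispersion; per-sample spike-in totals are drawn around
#' a common mean and recorded on each track. The promoter window is simulated
#' at single-base resolution, the gene body as 500-bp uniform-valued runs
#' (every downstream window sum has the same expectation).
#'
#' @param genes a [gene_models] table.
#' @param truth matching ground-truth table (see [simulate_genome()]).
#' @param config a [sim_config].
#' @return A named list of [occupancy_track] objects (assay `"mnet"`), one
#'   per timepoint x replicate. Deterministic given `config$seed`.
#' @export
simulate_triptolide_timecourse <- function(genes, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  missing <- setdiff(genes$gene_id, truth$gene_id)
  if (length(missing))
    stop("no ground-truth record for gene(s): ",
         paste(missing, collapse = ", "))
  set.seed(config$seed + 1L)
  kern <- pause_kernel()
  tracks <- list()
  for (t in config$timepoints_triptolide) {
    for (r in seq_len(config$replicates)) {
      d <- if (config$dispersion <= 0) 1 else
        exp(rnorm(1, 0, config$replicate_jitter))
      mu_fun <- function(gene, tr) {
        prom <- tr$pause_amplitude * kern * 2^(-t / tr$half_life_min)
        body_len <- gene$length - 300
        if (body_len > 0) {
          nb <- ceiling(body_len / 500)
          bl <- rep(500, nb)
          bl[nb] <- body_len - 500 * (nb - 1)
          list(lengths = c(rep(1, 300), bl),
               values = c(prom, rep(tr$body_level, nb)))
        } else {
          list(lengths = rep(1, 300), values = prom)
        }
      }
      id <- sprintf("mnet_t%02d_r%d", t, r)
      tracks[[id]] <- simulate_track(genes, truth, config, mu_fun, id,
                                     "mnet", "control", t, r, d)
    }
  }
  tracks
}

#' Simulate a DRB-release TT-seq time course
#'
#' Models transcription restart after washout of the reversible CDK9 inhibitor
#' DRB. At release time `t`, the 4SU-labeled interval of each gene spans
#' `[v * max(0, t - label), v * t]` kb from the TSS (the advancing front sits
#' at `v * t`): labeled coverage is `body_level` inside that interval, with
#' both edges smoothed by a Gaussian of sd `front_sd`, plus a wave crest — a
#' Gaussian centered on the front — representing the bolus of formerly paused
#' polymerases released together at washout. The crest has amplitude
#' `wave_gain * body_level` and broadens with time
#' (`sd = sqrt(front_sd^2 + (wave_broadening_cv * v * t)^2)`), emulating the
#' widening wave produced by cell-to-cell rate variability. Signal beyond the
#' TES is dropped (the wave terminates). At `t = 0` only the residual
#' promoter pause peak is present. Coverage is simulated as 50-bp
#' uniform-valued runs; strand-aware throughout.
#'
#' @inheritParams simulate_triptolide_timecourse
#' @return A named list of [occupancy_track] objects (assay `"ttseq"`), one
#'   per release timepoint x replicate. Deterministic given `config$seed`.
#' @export
simulate_drb_release <- function(genes, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$label_duration <= 0)
    stop("label_duration must be > 0", call. = FALSE)
  missing <- setdiff(genes$gene_id, truth$gene_id)
  if (length(missing))
    stop("no ground-truth record for gene(s): ",
         paste(missing, collapse = ", "))
  set.seed(config$seed + 2L)
  kern <- pause_kernel()
  binw <- 50
  tracks <- list()
  for (t in config$timepoints_drb) {
    for (r in seq_len(config$replicates)) {
      d <- if (config$dispersion <= 0) 1 else
        exp(rnorm(1, 0, config$replicate_jitter))
      mu_fun <- function(gene, tr) {
        if (t == 0) {
          return(list(lengths = rep(1, 300), values = tr$pause_amplitude * kern))
        }
        v_bp <- tr$velocity_kb_min * 1000
        front <- v_bp * t
        lab_start <- v_bp * max(0, t - config$label_duration)
        sd_bp <- sqrt((config$front_sd * 1000)^2 +
                      (config$wave_broadening_cv * v_bp * t)^2)
        lim <- min(gene$length, front + 5 * sd_bp)
        if (lim <= 0) return(NULL)
        nb <- ceiling(lim / binw)
        mids <- (seq_len(nb) - 0.5) * binw
        lens <- rep(binw, nb)
        lens[nb] <- lim - binw * (nb - 1)
        plateau <- tr$body_level *
          (pnorm((front - mids) / sd_bp) - pnorm((lab_start - mids) / sd_bp))
        crest <- if (front <= gene$length)
          config$wave_gain * tr$body_level *
            exp(-(mids - front)^2 / (2 * sd_bp^2)) else 0
        list(lengths = lens, values = pmax(plateau + crest, 0))
      }
      id <- sprintf("ttseq_t%02d_r%d", t, r)
      tracks[[id]] <- simulate_track(genes, truth, config, mu_fun, id,
                                     "ttseq", "control", t, r, d)
    }
  }
  tracks
}

#' Simulate a steady-state TT-seq track
#'
#' Labeled-RNA coverage at steady state is synthesis per base, i.e. local
#' polymerase occupancy times elongation velocity; here the expectation is
#' `body_level * velocity_kb_min` uniformly over the gene. Paired with a
#' t = 0 mNET-seq track (occupancy `body_level`), the TT/mNET ratio recovers
#' velocity up to a common constant — the construction used to validate the
#' elongation-velocity proxy.
#'
#' @inheritParams simulate_triptolide_timecourse
#' @param replicate replicate number for the track's metadata.
#' @return An [occupancy_track] (assay `"ttseq"`).
#' @export
simulate_steady_state_tt <- function(genes, truth, config, replicate = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  mu_fun <- function(gene, tr) {
    nb <- ceiling(gene$length / 500)
    lens <- rep(500, nb)
    lens[nb] <- gene$length - 500 * (nb - 1)
    list(lengths = lens,
         values = rep(tr$body_level * tr$velocity_kb_min, nb))
  }
  simulate_track(genes, truth, config, mu_fun,
                 sprintf("ttseq_ss_r%d", replicate), "ttseq", "control",
                 0, replicate, 1)
}

#' Write a synthetic fixture to disk
#'
#' Emits BED12 gene models (`genes.bed`), a ground-truth TSV (`truth.tsv`),
#' per-sample bedGraph strand pairs, and a sample sheet (`samples.tsv`).
#' Files round-trip losslessly through [read_fixture()].
#'
#' @param outdir output directory (created if needed).
#' @param genes a [gene_models] table.
#' @param truth ground-truth `data.frame`.
#' @param tracks list of [occupancy_track] objects (may be empty).
#' @return `outdir`, invisibly.
#' @export
write_fixture <- function(outdir, genes, truth, tracks = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_gene_models(genes, file.path(outdir, "genes.bed"))
  write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (tr in tracks) write_bedgraph(tr, outdir)
  write_sample_sheet(tracks_to_sample_sheet(tracks),
                     file.path(outdir, "samples.tsv"))
  invisible(outdir)
}

#' Read a fixture written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @param contig_length optional contig length for the tracks (bp); inferred
#'   from the data if `NULL`.
#' @return list with `genes`, `truth`, `sheet`, `tracks`.
#' @export
read_fixture <- function(dir, contig_length = NULL) {
  genes <- read_gene_models(file.path(dir, "genes.bed"), "bed12")
  truth <- read.delim(file.path(dir, "truth.tsv"), stringsAsFactors = FALSE)
  sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
  tracks <- load_tracks(dir, sheet, contig_length = contig_length)
  list(genes = genes, truth = truth, sheet = sheet, tracks = tracks)
}
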