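#' Construct an occupancy track
#'
#' An occupancy track holds strand-specific per-base signal for one sample on
#' one contig, as run-length-encoded vectors, together with the sample's
#' metadata, library size and spike-in total. For mNET-seq-like samples the
#' per-base value is the count of read 3' ends (the polymerase active-site
#' position); for TT-seq-like samples it is plain labeled-RNA coverage. The
#' file format does not distinguish the two - the `assay` field does.
#'
#' @param sample_id sample identifier.
#' @param counts named list with elements `"+"` and `"-"`, each a numeric
#'   vector or [S4Vectors::Rle] of non-negative per-base values covering the
#'   contig from position 0.
#' @param contig contig name.
#' @param assay `"mnet"` or `"ttseq"`.
#' @param condition condition label.
#' @param timepoint_min timepoint in minutes (>= 0).
#' @param replicate replicate number.
#' @param spike_count spike-in read total (> 0 for normalization).
#' @param library_size total signal; computed from `counts` when `NULL`.
#' @param scale multiplicative scale factor applied by density accessors
#'   (default 1; set by [apply_scale_factors()]).
#' @return An object of class `occupancy_track`.
#' @export
occupancy_track <- function(sample_id, counts, contig = "chrS",
                            assay = c("mnet", "ttseq"),
                            condition = "control", timepoint_min = 0,
                            replicate = 1L, spike_count = NA_real_,
                            library_size = NULL, scale = 1) {
  assay <- match.arg(assay)
  stopifnot(is.list(counts), all(c("+", "-") %in% names(counts)))
  counts <- lapply(counts[c("+", "-")], function(x) {
    x <- methods::as(x, "Rle")
    if (any(S4Vectors::runValue(x) < 0)) stop("negative values in track")
    x
  })
  n <- vapply(counts, length, numeric(1))
  if (n[1] != n[2]) {
    len <- max(n)
    counts <- lapply(counts, function(x)
      if (length(x) < len) c(x, S4Vectors::Rle(0, len - length(x))) else x)
  }
  if (is.null(library_size))
    library_size <- sum(as.numeric(sum(counts[["+"]])),
                        as.numeric(sum(counts[["-"]])))
  if (timepoint_min < 0) stop("timepoint_min must be >= 0")
  structure(
    list(sample_id = sample_id, assay = assay, condition = condition,
         timepoint_min = timepoint_min, replicate = as.integer(replicate),
         contig = contig, counts = counts,
         library_size = library_size, spike_count = spike_count,
         scale = scale),
    class = "occupancy_track"
  )
}

#' @export
print.occupancy_track <- function(x, ...) {
  cat(sprintf(
    "<occupancy_track> %s [%s] condition=%s t=%g min rep=%d\n  contig %s (%d bp), library %.4g, spike %.4g, scale %.4g\n",
    x$sample_id, x$assay, x$condition, x$timepoint_min, x$replicate,
    x$contig, length(x$counts[["+"]]), x$library_size, x$spike_count, x$scale))
  invisible(x)
}

#' Contig length of a track
#' @param track an [occupancy_track].
#' @return length in bp.
#' @export
track_length <- function(track) length(track$counts[["+"]])

#' Per-base values of a track over a strand-aware offset window
#'
#' Extracts raw (unscaled) per-base values for `gene` over offsets
#' `[offset_start, offset_end)` from the TSS, in transcription direction.
#'
#' @param track an [occupancy_track].
#' @param gene one row of a [gene_models] table.
#' @param offset_start,offset_end offsets in bp, `offset_start < offset_end`.
#' @return numeric vector of length `offset_end - offset_start`.
#' @export
window_counts <- function(track, gene, offset_start, offset_end) {
  stopifnot(offset_start < offset_end)
  len <- track_length(track)
  if (gene$strand == "+") {
    lo <- gene$tss + offset_start
    hi <- gene$tss + offset_end - 1
  } else {
    lo <- gene$tss - offset_end + 1
    hi <- gene$tss - offset_start
  }
  if (lo < 0 || hi >= len)
    stop(sprintf("window [%d, %d) outside contig for gene %s",
                 offset_start, offset_end, gene$gene_id))
  v <- as.numeric(S4Vectors::window(track$counts[[gene$strand]],
                                    start = lo + 1, end = hi + 1))
  if (gene$strand == "-") rev(v) else v
}

#' Read a strand pair of bedGraph files into an occupancy track
#'
#' bedGraph intervals are 0-based half-open; values are expanded per base and
#' missing positions are zero. Overlapping intervals are rejected.
#'
#' @param path_plus,path_minus bedGraph files for the two strands.
#' @param meta named list of sample metadata (`sample_id`, `assay`,
#'   `condition`, `timepoint_min`, `replicate`, `spike_count`, optional
#'   `library_size`).
#' @param contig_length contig length in bp; inferred from the data if `NULL`.
#' @return An [occupancy_track]. `library_size` is the sum of all values
#'   unless supplied in `meta`.
#' @export
read_bedgraph <- function(path_plus, path_minus, meta = list(),
                          contig_length = NULL) {
  read_one <- function(path) {
    gr <- tryCatch(
      rtracklayer::import(path, format = "bedGraph"),
      error = function(e) stop("failed to parse bedGraph ", path, ": ",
                               conditionMessage(e))
    )
    if (length(gr) && any(gr$score < 0))
      stop("negative value in bedGraph ", path)
    if (length(gr) > 1 && !IRanges::isDisjoint(IRanges::ranges(gr)))
      stop("overlapping intervals in bedGraph ", path)
    gr
  }
  grp <- read_one(path_plus)
  grm <- read_one(path_minus)
  contig <- unique(c(as.character(GenomicRanges::seqnames(grp)),
                     as.character(GenomicRanges::seqnames(grm))))
  if (length(contig) > 1) stop("multiple contigs in bedGraph pair")
  if (!length(contig)) contig <- "chrS"
  maxend <- max(0, BiocGenerics::end(grp), BiocGenerics::end(grm))
  len <- if (is.null(contig_length)) maxend else contig_length
  if (len < maxend) stop("contig_length shorter than bedGraph extent")
  to_rle <- function(gr) {
    if (!length(gr)) return(S4Vectors::Rle(0, max(len, 1)))
    IRanges::coverage(IRanges::ranges(gr), weight = gr$score, width = len)
  }
  meta_def <- list(sample_id = "sample", assay = "mnet", condition = "control",
                   timepoint_min = 0, replicate = 1L, spike_count = NA_real_,
                   library_size = NULL)
  meta <- utils::modifyList(meta_def, meta)
  occupancy_track(
    sample_id = meta$sample_id,
    counts = list("+" = to_rle(grp), "-" = to_rle(grm)),
    contig = contig, assay = meta$assay, condition = meta$condition,
    timepoint_min = meta$timepoint_min, replicate = meta$replicate,
    spike_count = meta$spike_count, library_size = meta$library_size
  )
}

#' Write an occupancy track as a strand pair of bedGraph files
#'
#' Intervals are run-length encoded, sorted, 0-based half-open; zero runs are
#' omitted. Round-trips losslessly through [read_bedgraph()].
#'
#' @param track an [occupancy_track].
#' @param outdir output directory (created if needed).
#' @return Named character vector with the two file paths, invisibly.
#' @export
write_bedgraph <- function(track, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_one <- function(rle, path) {
    rv <- S4Vectors::runValue(rle)
    rl <- S4Vectors::runLength(rle)
    ends <- cumsum(as.numeric(rl))
    starts <- ends - as.numeric(rl)
    keep <- which(rv != 0)
    df <- data.frame(
      chrom = rep(track$contig, length(keep)),
      start = format(starts[keep], scientific = FALSE, trim = TRUE),
      end = format(ends[keep], scientific = FALSE, trim = TRUE),
      value = format(rv[keep], scientific = FALSE, trim = TRUE, digits = 15)
    )
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    path
  }
  paths <- c(
    plus = write_one(track$counts[["+"]],
                     file.path(outdir, paste0(track$sample_id, ".plus.bedgraph"))),
    minus = write_one(track$counts[["-"]],
                      file.path(outdir, paste0(track$sample_id, ".minus.bedgraph")))
  )
  invisible(paths)
}

#' Read or write a sample sheet
#'
#' The sample sheet is a TSV with columns `sample`, `assay` (`mnet`/`ttseq`),
#' `condition`, `timepoint_min`, `replicate`, `spike_count`, `library_size`.
#'
#' @param path TSV file path.
#' @return `read_sample_sheet`: a `data.frame`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample", "assay", "condition", "timepoint_min", "replicate",
           "spike_count")
  miss <- setdiff(req, names(sheet))
  if (length(miss))
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  sheet
}

#' @rdname read_sample_sheet
#' @param sheet a sample-sheet `data.frame`.
#' @return `write_sample_sheet`: `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a sample sheet from a list of tracks
#' @param tracks list of [occupancy_track] objects.
#' @return a sample-sheet `data.frame` (header only if `tracks` is empty).
#' @export
tracks_to_sample_sheet <- function(tracks) {
  if (!length(tracks))
    return(data.frame(sample = character(), assay = character(),
                      condition = character(), timepoint_min = numeric(),
                      replicate = integer(), spike_count = numeric(),
                      library_size = numeric()))
  do.call(rbind, lapply(tracks, function(tr) data.frame(
    sample = tr$sample_id, assay = tr$assay, condition = tr$condition,
    timepoint_min = tr$timepoint_min, replicate = tr$replicate,
    spike_count = tr$spike_count, library_size = tr$library_size
  )))
}

#' Load all tracks referenced by a sample sheet
#'
#' Expects `<sample>.plus.bedgraph` / `<sample>.minus.bedgraph` under `dir`.
#'
#' @param dir directory holding bedGraph pairs.
#' @param sheet sample sheet `data.frame` (see [read_sample_sheet()]).
#' @param contig_length optional contig length in bp.
#' @return named list of [occupancy_track] objects.
#' @export
load_tracks <- function(dir, sheet, contig_length = NULL) {
  tracks <- lapply(seq_len(nrow(sheet)), function(i) {
    s <- sheet[i, ]
    read_bedgraph(
      file.path(dir, paste0(s$sample, ".plus.bedgraph")),
      file.path(dir, paste0(s$sample, ".minus.bedgraph")),
      meta = list(sample_id = s$sample, assay = s$assay,
                  condition = s$condition, timepoint_min = s$timepoint_min,
                  replicate = s$replicate, spike_count = s$spike_count,
                  library_size = if ("library_size" %in% names(s))
                    s$library_size else NULL),
      contig_length = contig_length
    )
  })
  names(tracks) <- sheet$sample
  tracks
}
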